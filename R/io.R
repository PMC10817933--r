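#' Read an undirected edge list
#'
#' Plain-text interchange format: one edge per line, two whitespace-
#' separated non-negative integer node ids (0-based on disk), `#` starts a
#' comment. Self-loops are rejected with the offending line number;
#' duplicate edges are removed with a warning. Node ids are compacted to
#' the in-memory ids `1..N` and the mapping is attached.
#'
#' @param path file path.
#' @param n_nodes optional node count; by default the number of distinct
#'   ids seen (isolated nodes cannot be represented in an edge list).
#' @return A [static_network()]; attribute `"id_map"` maps in-memory id
#'   (position) to original 0-based id.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "0 1", "1 2"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines_clean <- sub("#.*$", "", lines)
  keep <- which(trimws(lines_clean) != "")
  if (length(keep) == 0) stop("no edges found in ", path)
  parts <- strsplit(trimws(lines_clean[keep]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad))
    stop(sprintf("line %d: expected two node ids", keep[bad[1]]))
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1)))
  v <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  bad <- which(is.na(u) | is.na(v) | u < 0 | v < 0)
  if (length(bad))
    stop(sprintf("line %d: node ids must be non-negative integers",
                 keep[bad[1]]))
  loops <- which(u == v)
  if (length(loops))
    stop(sprintf("line %d: self-loop (%d %d) is not allowed",
                 keep[loops[1]], u[loops[1]], v[loops[1]]))
  ids <- sort(unique(c(u, v)))
  n <- if (is.null(n_nodes)) length(ids) else as.integer(n_nodes)
  ui <- match(u, ids)
  vi <- match(v, ids)
  key <- paste0(pmin(ui, vi), ":", pmax(ui, vi))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate edge(s) removed", sum(dup)))
    ui <- ui[!dup]
    vi <- vi[!dup]
  }
  net <- static_network(n, cbind(ui, vi))
  attr(net, "id_map") <- ids
  net
}

#' Write an undirected edge list
#'
#' Inverse of [read_edge_list()]: writes 0-based ids, one edge per line.
#'
#' @param network a [static_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "static_network"))
  lines <- c(sprintf("# undirected edge list, %d nodes, %d edges (0-based ids)",
                     network$n_nodes, nrow(network$edges)),
             sprintf("%d %d", network$edges[, 1] - 1, network$edges[, 2] - 1))
  writeLines(lines, path)
  invisible(path)
}

fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits (h exceeds 32-bit bitwXor)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit multiply by the FNV prime 2^24 + 403, kept exact in doubles:
    # h * 2^24 mod 2^32 only involves the low 8 bits of h
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration object
#'
#' Short stable hex digest (FNV-1a over the deparsed object) used to stamp
#' result artefacts so that tables and metadata from one run can be matched
#' up later.
#'
#' @param config any R object.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a(deparse(config, control = c("keepNA", "keepInteger")))
}

format_full <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.12g", x) else x
}

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  out <- df
  for (j in seq_along(out)) out[[j]] <- format_full(out[[j]])
  write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write result tables and metadata
#'
#' Writes each table as CSV (atomic: temp file then rename, stable column
#' order, 12 significant digits) plus a `metadata.json` carrying the
#' configuration hash, the master seed and the package version.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if missing).
#' @param config configuration object to hash into the metadata.
#' @param seed master seed to record.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_csv_atomic(tables[[nm]], p)
    paths <- c(paths, p)
  }
  meta <- list(package = "tempdeffuant",
               version = as.character(utils::packageVersion("tempdeffuant")),
               config_hash = if (is.null(config)) NA else config_hash(config),
               seed = seed,
               tables = names(tables),
               written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  mp <- file.path(out_dir, "metadata.json")
  tmp <- paste0(mp, ".tmp")
  jsonlite::write_json(meta, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, mp)
  invisible(c(paths, mp))
}

#' Per-run cluster report
#'
#' Flattens cluster summaries into the tabular report format
#' `run_id, cluster_id, size, position, omega, delta_x` (one row per kept
#' cluster), plus a per-run summary `run_id, n_f, unclustered, t_f`.
#'
#' @param summaries list of `cluster_summary` objects.
#' @param t_f optional numeric vector of stabilisation times per run.
#' @param run_ids optional run identifiers (default `seq_along`).
#' @return List with data frames `clusters` and `runs`.
#' @export
cluster_report <- function(summaries, t_f = NULL, run_ids = NULL) {
  stopifnot(is.list(summaries))
  if (is.null(run_ids)) run_ids <- seq_along(summaries)
  if (is.null(t_f)) t_f <- rep(NA_real_, length(summaries))
  cl <- do.call(rbind, lapply(seq_along(summaries), function(k) {
    s <- summaries[[k]]
    if (s$n_clusters == 0) return(NULL)
    data.frame(run_id = run_ids[k], cluster_id = seq_len(s$n_clusters),
               size = s$sizes, position = s$positions, omega = s$omega,
               delta_x = s$delta_x, stringsAsFactors = FALSE)
  }))
  if (is.null(cl))
    cl <- data.frame(run_id = integer(0), cluster_id = integer(0),
                     size = integer(0), position = numeric(0),
                     omega = numeric(0), delta_x = numeric(0))
  runs <- data.frame(run_id = run_ids,
                     n_f = vapply(summaries, `[[`, integer(1), "n_clusters"),
                     unclustered = vapply(summaries, function(s)
                       as.integer(s$unclustered), integer(1)),
                     t_f = t_f, stringsAsFactors = FALSE)
  list(clusters = cl, runs = runs)
}

#' Read a sweep configuration from a YAML file
#'
#' Expected sections: `networks` (list of network specs), `interevents`
#' (list of inter-event specs), `dynamics` (`mu`, `epsilon`, `min_frac`,
#' `t_max`, `burn_in_factor`, `max_events`, `stop_window`), `sweep`
#' (`d_grid`, `n_networks`, `n_runs`, `seed`). Missing dynamics fields
#' fall back to the [sweep_config()] defaults.
#'
#' @param path YAML file path.
#' @return A [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (sec in c("networks", "interevents", "sweep"))
    if (is.null(y[[sec]])) stop("config is missing the '", sec, "' section")
  # YAML 1.1 parses the bare key `n` as a boolean; map it back
  y$networks <- lapply(y$networks, function(spec) {
    names(spec)[names(spec) %in% c("FALSE", "no")] <- "n"
    spec
  })
  dyn <- if (is.null(y$dynamics)) list() else y$dynamics
  args <- c(list(networks = y$networks, interevents = y$interevents,
                 d_grid = y$sweep$d_grid,
                 n_networks = if (is.null(y$sweep$n_networks)) 15
                              else y$sweep$n_networks,
                 n_runs = if (is.null(y$sweep$n_runs)) 20 else y$sweep$n_runs,
                 seed = y$sweep$seed),
            dyn)
  do.call(sweep_config, args)
}
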
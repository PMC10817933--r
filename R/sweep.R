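#' Derive a replicate seed from a master seed
#'
#' Stable integer hashing of a master seed and index components via a
#' chained multiplicative congruence modulo `2^31 - 1`. Any single
#' replicate of a sweep can be reproduced exactly from the master seed and
#' its indices, independently of execution order.
#'
#' @param master master seed (integer).
#' @param ... non-negative integer index components.
#' @return An integer seed in `1 .. 2^31 - 2`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- as.double(master) %% m
  for (comp in c(...)) {
    s <- (s * 48271 + as.double(comp) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' Exponential comparator with matched mean
#'
#' Builds the exponential inter-event model whose mean waiting time equals
#' that of the given model: the convention used when comparing bursty
#' activity against the memoryless baseline. For usable analytic means the
#' rate is `1 / <dt>`; in the heavy-tail overflow regime the rate is matched
#' to the horizon-truncated moment under `t_max` (the only finite mean the
#' capped process has).
#'
#' @param model an [make_interevent_model()] object.
#' @param t_max event horizon used for the truncated moment in the overflow
#'   regime.
#' @return An exponential `interevent_model`.
#' @export
matched_exponential <- function(model, t_max = 1e6) {
  stopifnot(inherits(model, "interevent_model"))
  m <- if (model$mean_overflow)
         interevent_mean(model, horizon = t_max, conditional = TRUE)
       else model$analytic_mean
  make_interevent_model("exponential", rate = 1 / m)
}

normalize_interevent_spec <- function(spec) {
  if (inherits(spec, "interevent_model")) return(spec)
  stopifnot(is.list(spec), !is.null(spec$family))
  if (spec$family == "exponential") {
    make_interevent_model("exponential",
                          rate = if (is.null(spec$rate)) 1 else spec$rate)
  } else {
    make_interevent_model("lognormal",
                          meanlog = if (is.null(spec$meanlog)) 0
                                    else spec$meanlog,
                          sdlog = spec$sdlog)
  }
}

interevent_label <- function(model) {
  if (model$family == "exponential")
    sprintf("exponential_b%g", model$rate)
  else
    sprintf("lognormal_s%g", model$sdlog)
}

network_label <- function(spec) {
  if (!is.null(spec$label)) return(spec$label)
  switch(spec$model,
         er = sprintf("er_k%g", spec$mean_degree),
         ws = sprintf("ws_k%g_q%g", spec$k_nn, spec$rewire_prob),
         fitness = sprintf("fitness_b%g", spec$beta),
         fixed = "fixed",
         stop("unknown network model: ", spec$model))
}

generate_from_spec <- function(spec, seed) {
  n <- if (!is.null(spec$n)) spec$n else spec$n_nodes
  switch(spec$model,
         er = generate_er(n, spec$mean_degree, seed = seed),
         ws = generate_ws(n, spec$k_nn, spec$rewire_prob, seed = seed),
         fitness = generate_fitness(n, spec$m, spec$beta, seed = seed),
         fixed = spec$network,
         stop("unknown network model: ", spec$model))
}

#' Configure a replicated parameter sweep
#'
#' Describes the experimental design: network model(s), inter-event
#' model(s), a grid of confidence levels, and the replicate structure of
#' `n_networks` independent network samples times `n_runs` simulations per
#' network (default 15 x 20 = 300 replicates per cell). Each replicate's
#' network, initial opinions and activation stream are seeded by stable
#' hashing from the master seed.
#'
#' @param networks list of network specs; each a list with `model` one of
#'   `"er"` (`n`, `mean_degree`), `"ws"` (`n`, `k_nn`, `rewire_prob`),
#'   `"fitness"` (`n`, `m`, `beta`), or `"fixed"` (`network`), plus an
#'   optional `label`. A single spec may be given unwrapped.
#' @param interevents list of inter-event specs: [make_interevent_model()]
#'   objects or lists such as `list(family = "lognormal", sdlog = 2.7)`
#'   (`meanlog` defaults to 0, exponential `rate` to 1).
#' @param d_grid numeric vector of confidence levels.
#' @param n_networks independent network samples per cell (default 15).
#' @param n_runs simulations per network (default 20).
#' @param mu influence parameter (default 0.5).
#' @param epsilon cluster-gap threshold (default `1e-4`).
#' @param min_frac minimum cluster fraction (default 0.01).
#' @param t_max horizon in time units (default 1e6): both the waiting-time
#'   cap of the schedules and the simulation duration of each run
#'   (`max_time` of [run_temporal()]). Runs that converge earlier stop by
#'   the quiet-window rule; heavy-tailed runs are terminated here.
#' @param cap_mode horizon semantics passed to [build_schedule()] (default
#'   `"truncate"`).
#' @param burn_in_factor burn-in length in units of `|E|` events (default
#'   10); forced to 0 for overflow-regime inter-event models under
#'   `cap_mode = "dormant"`, whose finite streams have no stationary
#'   regime to converge to.
#' @param stop_window consecutive-failure stopping window; `NULL` (default)
#'   means the number of nodes.
#' @param max_events hard per-run event cap.
#' @param seed master seed.
#' @return An object of class `sweep_config`.
#' @examples
#' cfg <- sweep_config(
#'   networks = list(model = "er", n = 200, mean_degree = 10),
#'   interevents = list(list(family = "exponential")),
#'   d_grid = c(0.2, 0.5), n_networks = 2, n_runs = 2, seed = 1)
#' @export
sweep_config <- function(networks, interevents, d_grid, n_networks = 15,
                         n_runs = 20, mu = 0.5, epsilon = 1e-4,
                         min_frac = 0.01, t_max = 1e6,
                         cap_mode = c("truncate", "dormant"),
                         burn_in_factor = 10, stop_window = NULL,
                         max_events = 1e8, seed) {
  cap_mode <- match.arg(cap_mode)
  if (!is.null(networks$model)) networks <- list(networks)
  interevents <- lapply(interevents, normalize_interevent_spec)
  # numeric fields may arrive as strings from config files
  d_grid <- as.numeric(d_grid)
  for (nm in c("mu", "epsilon", "min_frac", "t_max", "burn_in_factor",
               "max_events"))
    assign(nm, as.numeric(get(nm)))
  if (length(d_grid) < 1 || anyNA(d_grid) || any(d_grid <= 0) ||
      any(d_grid > 1))
    stop("d_grid values must lie in (0,1]")
  if (n_networks < 1 || n_runs < 1)
    stop("n_networks and n_runs must be positive")
  structure(list(networks = networks, interevents = interevents,
                 d_grid = as.numeric(d_grid),
                 n_networks = as.integer(n_networks),
                 n_runs = as.integer(n_runs), mu = mu, epsilon = epsilon,
                 min_frac = min_frac, t_max = t_max, cap_mode = cap_mode,
                 burn_in_factor = burn_in_factor, stop_window = stop_window,
                 max_events = max_events, seed = as.integer(seed)),
            class = "sweep_config")
}

run_one_replicate <- function(net, model, d, cfg, seed_sched, seed_x) {
  # no transient is discarded in the heavy-tail overflow regime: the
  # stream's correlation time is of the order of the horizon itself, so
  # there is no stationary regime for a burn-in to reach
  n_burn <- if (model$mean_overflow) 0
            else round(cfg$burn_in_factor * nrow(net$edges))
  sch <- build_schedule(net, model, t_max = cfg$t_max,
                        cap_mode = cfg$cap_mode, seed = seed_sched)
  exhausted_in_burn <- FALSE
  if (n_burn > 0) {
    ok <- tryCatch({ burn_in(sch, n_burn); TRUE },
                   schedule_exhausted = function(e) FALSE)
    exhausted_in_burn <- !ok
  }
  x0 <- init_opinions(net$n_nodes, seed = seed_x)
  sw <- if (is.null(cfg$stop_window)) net$n_nodes else cfg$stop_window
  if (exhausted_in_burn) {
    return(list(n_f = NA_integer_, t_f = NA_real_, events = 0,
                successes = 0, termination = "exhausted_in_burn_in",
                max_omega = NA_real_, unclustered = NA_integer_))
  }
  res <- run_temporal(net, sch, d = d, mu = cfg$mu, opinions = x0,
                      stop_window = sw, max_events = cfg$max_events,
                      max_time = cfg$t_max)
  cs <- filter_major_clusters(detect_clusters(res$opinions, cfg$epsilon),
                              cfg$min_frac)
  list(n_f = cs$n_clusters, t_f = res$t_f, events = res$events,
       successes = res$successes, termination = res$termination,
       max_omega = if (cs$n_clusters > 0) max(cs$omega) else NA_real_,
       unclustered = cs$unclustered)
}

#' Run a replicated parameter sweep
#'
#' Executes every cell of the design in [sweep_config()]: for each
#' (network spec, inter-event model, confidence level) it generates the
#' seeded network samples, runs the temporal Deffuant dynamics with fresh
#' opinion and activation seeds per replicate, detects the final opinion
#' clusters, and records replicate-level outcomes. Networks are shared
#' across cells with the same network spec and sample index, enabling
#' paired comparisons across `d` and activation patterns. Replicates are
#' independent and fully determined by the master seed.
#'
#' A cell in which every replicate exhausts its schedule during burn-in is
#' flagged (`n_f` is `NA` for those replicates) but is not fatal.
#'
#' @param config a [sweep_config()].
#' @param checkpoint_dir optional directory; each finished cell is written
#'   there as CSV and already-checkpointed cells are skipped on re-run,
#'   making long sweeps resumable.
#' @param verbose print per-cell progress lines.
#' @return An object of class `sweep_result`: list with `raw` (one row per
#'   replicate: `network`, `pattern`, `d`, `net_idx`, `run_idx`, `n_f`,
#'   `t_f`, `events`, `successes`, `termination`, `max_omega`,
#'   `unclustered`) and the `config`.
#' @examples
#' cfg <- sweep_config(
#'   networks = list(model = "er", n = 100, mean_degree = 8),
#'   interevents = list(list(family = "exponential")),
#'   d_grid = 0.5, n_networks = 2, n_runs = 2, seed = 1)
#' res <- run_sweep(cfg)
#' aggregate_sweep(res)
#' @export
run_sweep <- function(config, checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  cells <- expand.grid(spec_idx = seq_along(config$networks),
                       ie_idx = seq_along(config$interevents),
                       d = config$d_grid, KEEP.OUT.ATTRS = FALSE)
  net_cache <- new.env(parent = emptyenv())
  get_network <- function(spec_idx, net_idx) {
    key <- paste0(spec_idx, ":", net_idx)
    if (!exists(key, envir = net_cache, inherits = FALSE)) {
      seed_net <- derive_seed(config$seed, 101, spec_idx, net_idx)
      assign(key, generate_from_spec(config$networks[[spec_idx]], seed_net),
             envir = net_cache)
    }
    get(key, envir = net_cache, inherits = FALSE)
  }
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    spec_idx <- cells$spec_idx[ci]
    ie_idx <- cells$ie_idx[ci]
    d <- cells$d[ci]
    nlab <- network_label(config$networks[[spec_idx]])
    model <- config$interevents[[ie_idx]]
    plab <- interevent_label(model)
    ck_file <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("cell_%03d.csv", ci)) else NULL
    if (!is.null(ck_file) && file.exists(ck_file)) {
      rows[[ci]] <- read.csv(ck_file, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("[%d/%d] %s %s d=%g: checkpointed, skipping",
                        ci, nrow(cells), nlab, plab, d))
      next
    }
    cell_rows <- vector("list", config$n_networks * config$n_runs)
    k <- 0
    for (ni in seq_len(config$n_networks)) {
      net <- get_network(spec_idx, ni)
      for (ri in seq_len(config$n_runs)) {
        seed_sched <- derive_seed(config$seed, 211, ci, ni, ri)
        seed_x <- derive_seed(config$seed, 307, ci, ni, ri)
        rep_out <- run_one_replicate(net, model, d, config, seed_sched,
                                     seed_x)
        k <- k + 1
        cell_rows[[k]] <- data.frame(
          network = nlab, pattern = plab, d = d, net_idx = ni, run_idx = ri,
          n_f = rep_out$n_f, t_f = rep_out$t_f, events = rep_out$events,
          successes = rep_out$successes, termination = rep_out$termination,
          max_omega = rep_out$max_omega, unclustered = rep_out$unclustered,
          stringsAsFactors = FALSE)
      }
    }
    cell_df <- do.call(rbind, cell_rows)
    if (!is.null(ck_file)) {
      tmp <- paste0(ck_file, ".tmp")
      write.csv(cell_df, tmp, row.names = FALSE)
      file.rename(tmp, ck_file)
    }
    rows[[ci]] <- cell_df
    if (verbose)
      message(sprintf("[%d/%d] %s %s d=%g: mean N_f = %.3g",
                      ci, nrow(cells), nlab, plab, d,
                      mean(cell_df$n_f, na.rm = TRUE)))
  }
  structure(list(raw = do.call(rbind, rows), config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d replicates over %d cell(s)\n",
              nrow(x$raw),
              nrow(unique(x$raw[, c("network", "pattern", "d")]))))
  invisible(x)
}

#' Aggregate sweep replicates into cell means
#'
#' Long-format summary per (network, pattern, d) cell: mean and standard
#' error (sample sd over `sqrt(m)`, pooled over all replicates) of the
#' number of final opinion clusters `N_f` and the stabilisation time `T_f`,
#' plus replicate counts. Deterministic given the raw replicate table:
#' re-aggregation reproduces the table exactly.
#'
#' @param x a `sweep_result` or its `raw` data frame.
#' @return Data frame with columns `network`, `pattern`, `d`, `n`,
#'   `mean_n_f`, `se_n_f`, `mean_t_f`, `se_t_f`, `n_exhausted` (replicates
#'   whose schedule ran dry before the stopping window closed). Standard
#'   errors are `NA` when a cell has a single replicate.
#' @export
aggregate_sweep <- function(x) {
  raw <- if (inherits(x, "sweep_result")) x$raw else x
  stopifnot(is.data.frame(raw))
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    sd(v) / sqrt(length(v))
  }
  key <- interaction(raw$network, raw$pattern, raw$d, drop = TRUE)
  parts <- split(raw, key)
  out <- do.call(rbind, lapply(parts, function(df) {
    data.frame(network = df$network[1], pattern = df$pattern[1], d = df$d[1],
               n = sum(!is.na(df$n_f)),
               mean_n_f = mean(df$n_f, na.rm = TRUE), se_n_f = se(df$n_f),
               mean_t_f = mean(df$t_f, na.rm = TRUE), se_t_f = se(df$t_f),
               n_exhausted = sum(df$termination %in%
                                   c("exhausted", "exhausted_in_burn_in")),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$network, out$pattern, out$d), ]
  rownames(out) <- NULL
  out
}
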
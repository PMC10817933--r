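#' Detect opinion clusters by the epsilon-gap rule
#'
#' Sorts the opinions in ascending order and opens a new cluster wherever
#' two successive values differ by at least `epsilon`; runs of opinions
#' whose consecutive gaps are all below `epsilon` form one cluster. In one
#' dimension this partition coincides with single-linkage clustering at
#' threshold `epsilon`, and it is independent of the input order.
#'
#' @param opinions non-empty numeric vector of final opinions.
#' @param epsilon positive gap threshold (default `1e-4`).
#' @return An object of class `opinion_partition`: list with `opinions`,
#'   `membership` (cluster label per original index, labelled in ascending
#'   opinion order), `n_clusters_raw` and `epsilon`.
#' @examples
#' detect_clusters(c(0.1, 0.10005, 0.3))
#' @export
detect_clusters <- function(opinions, epsilon = 1e-4) {
  if (length(opinions) == 0) stop("opinions must be non-empty")
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  ord <- order(opinions)
  x <- opinions[ord]
  newc <- c(TRUE, diff(x) >= epsilon)
  lab_sorted <- cumsum(newc)
  membership <- integer(length(opinions))
  membership[ord] <- lab_sorted
  structure(list(opinions = as.numeric(opinions), membership = membership,
                 n_clusters_raw = lab_sorted[length(lab_sorted)],
                 epsilon = epsilon),
            class = "opinion_partition")
}

#' Filter major opinion clusters
#'
#' Keeps only clusters holding at least `min_frac` of the population
#' (inclusive: size `>= ceiling(min_frac * n)`, the literal reading of the
#' "at least 1%" convention). Individuals in smaller groups -- typically
#' poorly connected nodes stuck near their initial opinion -- are counted
#' as unclustered.
#'
#' @param partition an [detect_clusters()] object.
#' @param min_frac minimum population fraction per cluster, in (0,1)
#'   (default 0.01).
#' @return An object of class `cluster_summary`: list with `n_clusters`
#'   (`N_f`), `sizes` (`S_f`), `positions` (mean member opinion), `omega`
#'   (relative sizes `S_f / n`), `delta_x` (`position - 0.5`),
#'   `unclustered`, `n_nodes` and `members` (list of index vectors).
#' @examples
#' p <- detect_clusters(c(rep(0.25, 60), rep(0.75, 40)))
#' filter_major_clusters(p)
#' @export
filter_major_clusters <- function(partition, min_frac = 0.01) {
  stopifnot(inherits(partition, "opinion_partition"))
  if (min_frac <= 0 || min_frac >= 1) stop("min_frac must lie in (0,1)")
  n <- length(partition$opinions)
  min_size <- ceiling(min_frac * n)
  sizes_all <- tabulate(partition$membership)
  keep <- which(sizes_all >= min_size)
  members <- lapply(keep, function(k) which(partition$membership == k))
  sizes <- sizes_all[keep]
  positions <- vapply(members, function(idx) mean(partition$opinions[idx]),
                      numeric(1))
  structure(list(n_clusters = length(keep), sizes = sizes,
                 positions = positions, omega = sizes / n,
                 delta_x = positions - 0.5,
                 unclustered = n - sum(sizes), n_nodes = n,
                 members = members),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("cluster_summary: N_f = %d, unclustered = %d of %d\n",
              x$n_clusters, x$unclustered, x$n_nodes))
  if (x$n_clusters > 0)
    print(data.frame(size = x$sizes, position = round(x$positions, 4),
                     omega = x$omega))
  invisible(x)
}

#' Size-position profile of opinion clusters
#'
#' Relates each cluster's relative size `Omega = S_f / n` to its offset
#' `delta_x = x_cluster - 0.5` from the centre of the opinion space. For a
#' single run the profile has one row per kept cluster. Across runs
#' (a list of summaries), offsets are binned and `Omega` averaged within
#' bins, giving the mean size of a cluster found at a given distance from
#' the moderate opinion.
#'
#' @param x a `cluster_summary`, or a list of them for cross-run
#'   aggregation.
#' @param bin_width bin width for aggregated profiles (default 0.05);
#'   ignored for a single summary.
#' @return Data frame. Single run: columns `delta_x`, `omega`. Aggregated:
#'   columns `delta_x` (bin centre), `omega` (mean within bin),
#'   `n_clusters` (clusters pooled into the bin).
#' @examples
#' p <- detect_clusters(c(rep(0.25, 60), rep(0.75, 40)))
#' cluster_profile(filter_major_clusters(p))
#' @export
cluster_profile <- function(x, bin_width = 0.05) {
  if (inherits(x, "cluster_summary")) {
    return(data.frame(delta_x = x$delta_x, omega = x$omega))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                   "cluster_summary")))
  if (bin_width <= 0) stop("bin_width must be positive")
  dx <- unlist(lapply(x, `[[`, "delta_x"))
  om <- unlist(lapply(x, `[[`, "omega"))
  if (length(dx) == 0)
    return(data.frame(delta_x = numeric(0), omega = numeric(0),
                      n_clusters = integer(0)))
  bin <- round(dx / bin_width)
  agg <- aggregate(list(omega = om), by = list(bin = bin), FUN = mean)
  cnt <- as.data.frame(table(bin = bin), stringsAsFactors = FALSE)
  agg$n_clusters <- cnt$Freq[match(agg$bin, as.numeric(cnt$bin))]
  data.frame(delta_x = agg$bin * bin_width, omega = agg$omega,
             n_clusters = agg$n_clusters)
}

#' Summarise a finished run into opinion clusters
#'
#' Convenience wrapper: [detect_clusters()] then [filter_major_clusters()]
#' on the final opinions of a [run_temporal()] / [run_static_baseline()]
#' result.
#'
#' @param result a `deffuant_result`.
#' @param epsilon gap threshold (default `1e-4`).
#' @param min_frac minimum cluster fraction (default 0.01).
#' @return A `cluster_summary`.
#' @export
summarize_clusters <- function(result, epsilon = 1e-4, min_frac = 0.01) {
  stopifnot(inherits(result, "deffuant_result"))
  filter_major_clusters(detect_clusters(result$opinions, epsilon), min_frac)
}
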
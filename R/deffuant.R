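#' Initialise opinions
#'
#' Assigns each individual an independent Uniform(0,1) opinion.
#'
#' @param n_nodes number of individuals.
#' @param seed optional integer seed (calls [set.seed()]); omit to draw from
#'   the current RNG state.
#' @return Numeric vector of `n_nodes` opinions in \[0,1\].
#' @examples
#' x <- init_opinions(10, seed = 1)
#' @export
init_opinions <- function(n_nodes, seed = NULL) {
  if (n_nodes < 1) stop("n_nodes must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  runif(n_nodes)
}

#' Attempt one bounded-confidence opinion exchange
#'
#' The exchange between `i` and `j` is gated by the confidence level: it
#' takes effect only if `|x_i - x_j| < d` (strict). A successful exchange
#' moves both opinions towards each other by the fraction `mu` of their
#' (pre-update) difference:
#' `x_i <- x_i + mu (x_j - x_i)`, `x_j <- x_j + mu (x_i - x_j)`.
#' The pair difference thus contracts by the factor `|1 - 2 mu|` and the
#' pair sum is conserved. An exchange counts as successful only if it
#' changes at least one opinion at floating-point precision; a gate-passing
#' interaction between already-identical opinions is a no-op (this is what
#' lets the stopping rule recognise a converged population).
#'
#' @param opinions numeric opinion vector.
#' @param i,j distinct node ids (1-based indices into `opinions`).
#' @param d confidence level in (0,1\].
#' @param mu influence parameter in \[0,1\].
#' @return List with `opinions` (updated vector) and `success` (logical).
#' @examples
#' attempt_exchange(c(0.2, 0.3), 1, 2, d = 0.2, mu = 0.5)
#' @export
attempt_exchange <- function(opinions, i, j, d, mu = 0.5) {
  if (i == j) stop("i and j must be distinct nodes")
  xi <- opinions[i]
  xj <- opinions[j]
  if (abs(xi - xj) >= d) return(list(opinions = opinions, success = FALSE))
  ni <- xi + mu * (xj - xi)
  nj <- xj + mu * (xi - xj)
  if (ni == xi && nj == xj) return(list(opinions = opinions, success = FALSE))
  opinions[i] <- ni
  opinions[j] <- nj
  list(opinions = opinions, success = TRUE)
}

make_deffuant_result <- function(res, d, mu, stop_window, time_unit) {
  out <- list(opinions = res$opinions, t_f = res$t_f, events = res$events,
              successes = res$successes,
              events_to_stable = res$events_to_stable,
              termination = res$termination,
              d = d, mu = mu, stop_window = stop_window,
              time_unit = time_unit)
  if (!is.null(res$trajectory_times)) {
    out$trajectory_times <- res$trajectory_times
    out$trajectory <- res$trajectory
  }
  class(out) <- "deffuant_result"
  out
}

#' @export
print.deffuant_result <- function(x, ...) {
  cat(sprintf(paste0("deffuant_result: %d nodes, %g events (%g successful), ",
                     "T_f = %.6g %s, termination: %s\n"),
              length(x$opinions), x$events, x$successes, x$t_f, x$time_unit,
              x$termination))
  invisible(x)
}

#' Run the temporal Deffuant model
#'
#' Processes link activations from the schedule in chronological order,
#' applying [attempt_exchange()] at every activation. The run stops when a
#' quiet window with no successful exchange closes (termination
#' `"converged"`); when the simulation horizon `max_time` is reached, i.e.
#' the next activation would fall more than `max_time` time units after
#' the dynamics attached (`"horizon"`); when `max_events` activations have
#' been processed (`"max_events"`); or when every link has gone dormant
#' (`"exhausted"`, dormant cap mode only). With `stop_unit = "events"`
#' (default) the window counts consecutive failed activations -- the
#' natural reading of a dynamics driven one activation per time step; with
#' `stop_unit = "time"` it is a duration without success. The finite
#' horizon is what terminates heavy-tailed (overflow-regime) runs, whose
#' quiet window would otherwise never close; it freezes the dynamics while
#' many locally converged opinion clusters remain, which is the mechanism
#' by which burstiness raises the final cluster count. The stabilisation
#' time `T_f` is the continuous time of the last successful exchange (0 if
#' none); `events_to_stable` is the corresponding event count, so either
#' convention can be reported.
#'
#' Apply [burn_in()] to the schedule first if a stationary event stream is
#' wanted. The schedule is consumed (mutated) by the run.
#'
#' @param network the [static_network()] the schedule was built from.
#' @param schedule an [build_schedule()] object sharing `network`'s link
#'   set.
#' @param d confidence level in (0,1\].
#' @param mu influence parameter in \[0,1\] (default 0.5, which collapses a
#'   gate-passing pair onto its midpoint).
#' @param opinions initial opinion vector (see [init_opinions()]).
#' @param stop_window quiet-window length (activation count or time units,
#'   per `stop_unit`); defaults to the number of nodes.
#' @param stop_unit `"events"` (default) or `"time"`; see Details.
#' @param max_events hard cap on processed activations.
#' @param max_time simulation horizon in time units, measured from the
#'   point the dynamics attach to the schedule (default `Inf`).
#' @param record_every if positive, snapshot the opinion vector every this
#'   many events into `trajectory` / `trajectory_times`.
#' @return An object of class `deffuant_result`: final `opinions`, `t_f`,
#'   `events`, `successes`, `events_to_stable`, `termination`, and the
#'   config echo.
#' @examples
#' net <- generate_er(50, 6, seed = 1)
#' sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
#'                       seed = 2)
#' burn_in(sch, 10 * nrow(net$edges))
#' run_temporal(net, sch, d = 0.5, opinions = init_opinions(50, seed = 3))
#' @export
run_temporal <- function(network, schedule, d, mu = 0.5, opinions,
                         stop_window = network$n_nodes,
                         stop_unit = c("events", "time"), max_events = 1e8,
                         max_time = Inf, record_every = 0) {
  stopifnot(inherits(network, "static_network"),
            inherits(schedule, "activation_schedule"))
  stop_unit <- match.arg(stop_unit)
  if (!identical(schedule$edges, network$edges) ||
      schedule$n_nodes != network$n_nodes)
    stop("schedule and network do not share the same link set")
  check_dynamics_params(d, mu, stop_window, length(opinions),
                        network$n_nodes)
  if (!(max_time > 0)) stop("max_time must be positive")
  res <- run_temporal_cpp(schedule$ptr, as.double(opinions), d, mu,
                          as.double(stop_window),
                          if (stop_unit == "time") 1L else 0L,
                          as.double(max_events), as.double(max_time),
                          as.double(record_every))
  out <- make_deffuant_result(res, d, mu, stop_window, "continuous time")
  out$stop_unit <- stop_unit
  out
}

check_dynamics_params <- function(d, mu, stop_window, n_opinions, n_nodes) {
  if (!is.finite(d) || d <= 0 || d > 1) stop("d must lie in (0,1]")
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mu must lie in [0,1]")
  if (stop_window < 1) stop("stop_window must be at least 1")
  if (n_opinions != n_nodes)
    stop("opinions must have one entry per node")
  invisible(TRUE)
}

#' Run the static Deffuant baseline
#'
#' Classical discrete-time dynamics on a static network: at every step one
#' edge is chosen uniformly at random and [attempt_exchange()] applied. The
#' stopping rule is the same as [run_temporal()]'s with steps in place of
#' activations; `t_f` is reported in steps. With exponential inter-event
#' times the temporal engine is statistically equivalent to this baseline,
#' which makes it the natural cross-check.
#'
#' @param network a [static_network()] with at least one edge.
#' @param d,mu,opinions,stop_window,record_every as in [run_temporal()].
#' @param max_steps hard cap on steps.
#' @param seed integer seed for the edge-selection stream.
#' @return An object of class `deffuant_result` with `time_unit = "steps"`.
#' @examples
#' net <- generate_er(50, 6, seed = 1)
#' run_static_baseline(net, d = 0.5, opinions = init_opinions(50, seed = 3),
#'                     seed = 4)
#' @export
run_static_baseline <- function(network, d, mu = 0.5, opinions,
                                stop_window = network$n_nodes,
                                max_steps = 1e8, seed, record_every = 0) {
  stopifnot(inherits(network, "static_network"))
  if (nrow(network$edges) < 1) stop("network has no edges")
  check_dynamics_params(d, mu, stop_window, length(opinions),
                        network$n_nodes)
  res <- run_static_cpp(network$edges, as.double(opinions), d, mu,
                        as.double(stop_window), as.double(max_steps),
                        as.double(seed), as.double(record_every))
  make_deffuant_result(res, d, mu, stop_window, "steps")
}

#' Replay a recorded activation stream
#'
#' Drives the opinion dynamics with a fixed, chronologically ordered event
#' stream (e.g. from [collect_events()] or [read_event_log()]), applying
#' the same update and stopping rule as [run_temporal()]. Replaying the
#' stream a schedule produced reproduces the run bit-exactly.
#'
#' @param events data frame with columns `time`, `u`, `v`.
#' @param d,mu,opinions,stop_window as in [run_temporal()].
#' @return An object of class `deffuant_result`; termination is
#'   `"stream_end"` if the stream ran out before the stopping window
#'   closed.
#' @export
run_replay <- function(events, d, mu = 0.5, opinions,
                       stop_window = length(opinions)) {
  stopifnot(all(c("time", "u", "v") %in% names(events)))
  check_dynamics_params(d, mu, stop_window, length(opinions),
                        length(opinions))
  if (nrow(events) > 0 &&
      (min(events$u, events$v) < 1 ||
       max(events$u, events$v) > length(opinions)))
    stop("event stream references node ids outside 1..length(opinions)")
  res <- run_replay_cpp(as.double(events$time), as.integer(events$u),
                        as.integer(events$v), as.double(opinions), d, mu,
                        as.double(stop_window))
  make_deffuant_result(res, d, mu, stop_window, "continuous time")
}
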
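#' Build a per-link activation schedule
#'
#' Attaches one renewal clock to every social tie. Each link gets an initial
#' activation time drawn from a normal distribution truncated to positive
#' values; thereafter, whenever a link activates at time `t` it is re-armed
#' at `t + dt` with `dt` a fresh draw from the inter-event model. Events are
#' delivered in global chronological order (ties broken by link id). A link
#' whose next activation would fall beyond the event horizon `t_max` becomes
#' dormant and never fires again -- the mechanism that keeps heavy-tailed
#' (overflow-regime) dynamics finite.
#'
#' Two horizon semantics are available. `cap_mode = "truncate"` (default)
#' draws waiting times from the inter-event law conditioned on
#' `dt <= t_max` (exact inverse-CDF sampling of the truncated
#' distribution): every link remains a proper renewal clock with the
#' finite truncated mean, which is what makes heavy-tailed activity
#' simulable at all. `cap_mode = "dormant"` draws from the unmodified law
#' and permanently silences a link whose next activation falls beyond
#' `t_max`; the stream is then finite and can exhaust.
#'
#' Default start: `init_mean` is the mean inter-event time (truncated, in
#' the overflow regime) and `init_sd = init_mean / 4`; the particular
#' choice is washed out by [burn_in()] whenever a stationary regime
#' exists.
#'
#' Randomness uses per-link sub-streams derived by stable hashing of
#' `(seed, link id)`, so the same seed reproduces the identical event
#' sequence bit for bit, independently of how the queue is consumed.
#'
#' The schedule is a stateful object backed by external storage: popping
#' events mutates it in place. Rebuild with the same seed to restart.
#'
#' @param network a [static_network()] with at least one edge.
#' @param model an [make_interevent_model()] object.
#' @param init_mean mean of the truncated-normal initial activation times.
#' @param init_sd standard deviation of the initial times (>= 0).
#' @param t_max event horizon (time units) for the waiting-time cap.
#' @param cap_mode `"truncate"` (default) or `"dormant"`; see Details.
#' @param seed integer master seed.
#' @return An object of class `activation_schedule`.
#' @examples
#' net <- generate_er(50, 6, seed = 1)
#' sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
#'                       seed = 2)
#' next_activation(sch)
#' @export
build_schedule <- function(network, model, init_mean = NULL, init_sd = NULL,
                           t_max = 1e6, cap_mode = c("truncate", "dormant"),
                           seed) {
  stopifnot(inherits(network, "static_network"),
            inherits(model, "interevent_model"))
  cap_mode <- match.arg(cap_mode)
  if (nrow(network$edges) < 1) stop("network must have at least one edge")
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be positive")
  if (is.null(init_mean)) {
    init_mean <- if (model$mean_overflow) {
      if (cap_mode == "truncate")
        interevent_mean(model, horizon = t_max, conditional = TRUE)
      else t_max / 10
    } else {
      model$analytic_mean
    }
  }
  if (is.null(init_sd)) init_sd <- init_mean / 4
  if (init_sd < 0) stop("init_sd must be non-negative")
  if (init_mean <= 0) stop("init_mean must be positive")
  fam <- if (model$family == "exponential") 0L else 1L
  p1 <- if (fam == 0L) model$rate else model$meanlog
  p2 <- if (fam == 0L) 0 else model$sdlog
  ptr <- sched_create(network$edges, network$n_nodes, fam,
                      if (cap_mode == "truncate") 1L else 0L, p1, p2,
                      init_mean, init_sd, t_max, as.double(seed))
  structure(list(ptr = ptr, n_nodes = network$n_nodes,
                 edges = network$edges, model = model, t_max = t_max,
                 cap_mode = cap_mode, init_mean = init_mean,
                 init_sd = init_sd, seed = seed),
            class = "activation_schedule")
}

#' @export
print.activation_schedule <- function(x, ...) {
  st <- sched_state(x$ptr)
  cat(sprintf(paste0("activation_schedule: %d links (%s), %d pending, ",
                     "%g events delivered, t = %.6g, horizon %g\n"),
              nrow(x$edges), x$model$family, st$pending, st$delivered,
              st$current_time, x$t_max))
  invisible(x)
}

exhausted_condition <- function(msg) {
  stop(errorCondition(msg, class = c("schedule_exhausted", "error",
                                     "condition")))
}

#' Pop the next link activation
#'
#' Returns the earliest pending activation and re-arms that link with a
#' fresh inter-event draw (dormant if the new time exceeds the horizon).
#' Mutates the schedule in place.
#'
#' @param schedule an [build_schedule()] object.
#' @return List with `time` and `link` (the two node ids).
#' @export
next_activation <- function(schedule) {
  stopifnot(inherits(schedule, "activation_schedule"))
  ev <- sched_pop(schedule$ptr, 1L)
  if (length(ev$time) == 0)
    exhausted_condition("activation schedule exhausted (all links dormant)")
  list(time = ev$time[1], link = c(ev$u[1], ev$v[1]))
}

#' Pop a batch of link activations
#'
#' @param schedule an [build_schedule()] object.
#' @param n maximum number of events to pop.
#' @return Data frame with columns `time`, `u`, `v`, in chronological
#'   order; fewer than `n` rows if the schedule exhausts, with attribute
#'   `"exhausted"` set accordingly.
#' @export
collect_events <- function(schedule, n) {
  stopifnot(inherits(schedule, "activation_schedule"))
  ev <- sched_pop(schedule$ptr, as.integer(n))
  out <- data.frame(time = ev$time, u = ev$u, v = ev$v)
  attr(out, "exhausted") <- nrow(out) < n
  out
}

#' Discard the transient of an activation schedule
#'
#' Advances the schedule by `n_events` activations and discards them, so
#' that opinion dynamics attach to a stationary event stream. The default
#' used by the experiment runner is `10 * |E|` events (about ten renewals
#' per link), and zero in the heavy-tail overflow regime where no
#' stationary regime exists.
#'
#' @param schedule an [build_schedule()] object (mutated in place).
#' @param n_events number of activations to discard.
#' @return The schedule, invisibly.
#' @export
burn_in <- function(schedule, n_events) {
  stopifnot(inherits(schedule, "activation_schedule"))
  if (n_events < 0) stop("n_events must be non-negative")
  if (n_events == 0) return(invisible(schedule))
  done <- sched_discard(schedule$ptr, as.double(n_events))
  if (done < n_events)
    exhausted_condition(sprintf(
      "schedule exhausted during burn-in after %g of %g events",
      done, n_events))
  invisible(schedule)
}

#' Schedule bookkeeping
#'
#' `schedule_pending()` gives the number of links with a pending (non-
#' dormant) activation; `schedule_time()` the time of the last delivered
#' event; `schedule_events_delivered()` the running event count (including
#' burn-in).
#'
#' @param schedule an [build_schedule()] object.
#' @return A single number.
#' @export
schedule_pending <- function(schedule) sched_state(schedule$ptr)$pending

#' @rdname schedule_pending
#' @export
schedule_time <- function(schedule) sched_state(schedule$ptr)$current_time

#' @rdname schedule_pending
#' @export
schedule_events_delivered <- function(schedule)
  sched_state(schedule$ptr)$delivered

#' Write / read an activation event log
#'
#' CSV with header `time,u,v`, one link activation per row in chronological
#' order, at full double precision so that a written stream replays
#' bit-exactly through [run_replay()]. Node ids are the in-memory ids
#' `1..N`.
#'
#' @param events data frame with columns `time`, `u`, `v` (as produced by
#'   [collect_events()]).
#' @param path file path.
#' @return `write_event_log()` returns `path` invisibly; `read_event_log()`
#'   returns the events data frame.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(c("time", "u", "v") %in% names(events)))
  lines <- c("time,u,v",
             sprintf("%.17g,%d,%d", events$time, as.integer(events$u),
                     as.integer(events$v)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- read.csv(path, colClasses = c("numeric", "integer", "integer"))
  if (!identical(names(df), c("time", "u", "v")))
    stop("event log must have columns time,u,v")
  df
}
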
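#' Inter-event time model
#'
#' Distribution of waiting times between consecutive activations of the same
#' social tie. Two families are supported: exponential
#' `P(dt) = b exp(-b dt)` with mean `1/b` (memoryless Poisson baseline), and
#' log-normal with density
#' `P(dt) = exp(-(log(dt) - nu)^2 / (2 sigma^2)) / (sqrt(2 pi) sigma dt)`
#' and mean `exp(nu + sigma^2/2)`. The log-normal scale `sigma` sweeps the
#' activity from near-regular (`sigma << 1`, approaching a point mass at
#' `exp(nu)`) to heavily bursty (`sigma >> 1`, with nearly linear log
#' density like a power law).
#'
#' For very large `sigma` the distribution becomes so heavy-tailed that its
#' second moment `exp(2 nu + 2 sigma^2)` is not representable in double
#' precision; no finite-sample mean converges on any feasible horizon. Such
#' models carry `mean_overflow = TRUE` and report `NA` as analytic mean;
#' simulations then rely on the event-horizon cap of [build_schedule()], and
#' [interevent_mean()] can report the horizon-truncated moment instead.
#'
#' @param family `"exponential"` or `"lognormal"`.
#' @param rate exponential rate `b` (> 0).
#' @param meanlog log-normal location `nu`.
#' @param sdlog log-normal scale `sigma` (> 0).
#' @return An object of class `interevent_model`: list with `family`, the
#'   parameters, `analytic_mean` (`NA` in the overflow regime) and
#'   `mean_overflow`.
#' @examples
#' make_interevent_model("exponential", rate = 1)
#' make_interevent_model("lognormal", meanlog = 0, sdlog = 2.7)
#' @export
make_interevent_model <- function(family = c("exponential", "lognormal"),
                                  rate = NULL, meanlog = 0, sdlog = NULL) {
  family <- match.arg(family)
  if (family == "exponential") {
    if (is.null(rate) || !is.finite(rate) || rate <= 0)
      stop("exponential model requires a positive rate b")
    m <- list(family = family, rate = rate, analytic_mean = 1 / rate,
              mean_overflow = FALSE)
  } else {
    if (is.null(sdlog) || !is.finite(sdlog) || sdlog <= 0)
      stop("lognormal model requires a positive sdlog (sigma)")
    if (!is.finite(meanlog)) stop("meanlog (nu) must be finite")
    # overflow regime: second moment exp(2 nu + 2 sigma^2) beyond double range
    overflow <- (2 * meanlog + 2 * sdlog^2) > log(.Machine$double.xmax)
    m <- list(family = family, meanlog = meanlog, sdlog = sdlog,
              analytic_mean = if (overflow) NA_real_
                              else exp(meanlog + sdlog^2 / 2),
              mean_overflow = overflow)
  }
  structure(m, class = "interevent_model")
}

#' @export
print.interevent_model <- function(x, ...) {
  if (x$family == "exponential") {
    cat(sprintf("interevent_model: exponential, b = %.4g, <dt> = %.4g\n",
                x$rate, x$analytic_mean))
  } else {
    cat(sprintf("interevent_model: lognormal, nu = %.4g, sigma = %.4g, <dt> = %s\n",
                x$meanlog, x$sdlog,
                if (x$mean_overflow) "overflow (heavy-tail regime)"
                else sprintf("%.4g", x$analytic_mean)))
  }
  invisible(x)
}

#' Mean inter-event time, analytic or horizon-truncated
#'
#' Returns the analytic mean `<dt>` of an inter-event model. In the
#' heavy-tail overflow regime the analytic mean is unusable; if `horizon`
#' is supplied, a horizon-truncated moment is returned instead: by default
#' the lower partial moment `E[dt * 1{dt <= horizon}]` (computed in log
#' space as `exp(nu + sigma^2/2) * Phi((log(horizon) - nu - sigma^2) /
#' sigma)` for the log-normal), or with `conditional = TRUE` the mean of
#' the law conditioned on `dt <= horizon` -- the actual mean waiting time
#' of a renewal clock sampling the truncated distribution (see
#' [build_schedule()]'s `cap_mode = "truncate"`).
#'
#' @param model an [make_interevent_model()] object.
#' @param horizon optional positive cap used for the truncated moment.
#' @param conditional if `TRUE`, divide by `P(dt <= horizon)`.
#' @return A positive number, or `NA` for an overflowed mean with no horizon.
#' @examples
#' m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 20)
#' interevent_mean(m, horizon = 1e6)
#' @export
interevent_mean <- function(model, horizon = NULL, conditional = FALSE) {
  stopifnot(inherits(model, "interevent_model"))
  if (is.null(horizon)) {
    if (model$mean_overflow) return(NA_real_)
    return(model$analytic_mean)
  }
  if (model$family == "exponential") {
    b <- model$rate
    m <- (1 - exp(-b * horizon) * (1 + b * horizon)) / b
    if (conditional) m <- m / (1 - exp(-b * horizon))
    return(m)
  }
  nu <- model$meanlog
  s <- model$sdlog
  lm <- nu + s^2 / 2 + pnorm((log(horizon) - nu - s^2) / s, log.p = TRUE)
  if (conditional)
    lm <- lm - pnorm((log(horizon) - nu) / s, log.p = TRUE)
  exp(lm)
}

#' Sample inter-event times
#'
#' Draws waiting times from an inter-event model using R's global RNG
#' (seed with [set.seed()] for reproducibility). The activation schedule
#' uses its own per-link sub-streams; this sampler is the user-facing one
#' for inspection and fitting.
#'
#' @param model an [make_interevent_model()] object.
#' @param n number of draws.
#' @return Numeric vector of `n` strictly positive waiting times.
#' @examples
#' set.seed(1)
#' mean(sample_interevent(make_interevent_model("exponential", rate = 2), 1e4))
#' @export
sample_interevent <- function(model, n = 1) {
  stopifnot(inherits(model, "interevent_model"))
  if (model$family == "exponential") rexp(n, rate = model$rate)
  else rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog)
}
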
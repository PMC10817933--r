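make_sched <- function(net, model = make_interevent_model("exponential",
                                                          rate = 1),
                       seed = 2, ...) {
  build_schedule(net, model, seed = seed, ...)
}

test_that("every link starts with one pending activation", {
  net <- generate_er(60, 8, seed = 1)
  sch <- make_sched(net)
  expect_equal(schedule_pending(sch), nrow(net$edges))
  expect_equal(schedule_events_delivered(sch), 0)
})

test_that("events are delivered in chronological order", {
  net <- generate_er(100, 10, seed = 3)
  sch <- make_sched(net, seed = 4)
  ev <- collect_events(sch, 1e4)
  expect_equal(nrow(ev), 1e4)
  expect_true(all(diff(ev$time) >= 0))
  # every event references a link of the network
  keys <- paste0(pmin(ev$u, ev$v), ":", pmax(ev$u, ev$v))
  expect_true(all(keys %in% paste0(net$edges[, 1], ":", net$edges[, 2])))
})

test_that("the same master seed reproduces the event stream bit for bit", {
  net <- generate_er(50, 6, seed = 1)
  m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 2.7)
  e1 <- collect_events(build_schedule(net, m, seed = 11), 5000)
  e2 <- collect_events(build_schedule(net, m, seed = 11), 5000)
  expect_identical(e1, e2)
  e3 <- collect_events(build_schedule(net, m, seed = 12), 5000)
  expect_false(identical(e1$time, e3$time))
})

test_that("simultaneous initial activations break ties by link id", {
  net <- static_network(3, rbind(c(1, 2), c(1, 3)))
  sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                        init_mean = 1, init_sd = 0, seed = 5)
  a <- next_activation(sch)
  b <- next_activation(sch)
  expect_equal(a$time, 1)
  expect_equal(b$time, 1)
  expect_equal(a$link, c(1, 2))
  expect_equal(b$link, c(1, 3))
})

test_that("near-deterministic clocks tick at their period", {
  net <- static_network(2, rbind(c(1, 2)))
  m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 1e-12)
  sch <- build_schedule(net, m, init_mean = 1, init_sd = 0, seed = 6)
  ev <- collect_events(sch, 50)
  expect_equal(ev$time, 1:50, tolerance = 1e-9)
})

test_that("single-link gaps follow the renewal law (KS)", {
  net <- static_network(2, rbind(c(1, 2)))
  for (m in list(make_interevent_model("exponential", rate = 1),
                 make_interevent_model("lognormal", meanlog = 0, sdlog = 1))) {
    sch <- build_schedule(net, m, seed = 7)
    ev <- collect_events(sch, 10001)
    gaps <- diff(ev$time)
    p <- if (m$family == "exponential") {
      stats::ks.test(gaps, "pexp", m$rate)$p.value
    } else {
      stats::ks.test(gaps, "plnorm", m$meanlog, m$sdlog)$p.value
    }
    expect_gt(p, 0.01)
  }
})

test_that("burn-in discards the requested number of events", {
  net <- generate_er(40, 6, seed = 2)
  sch <- make_sched(net, seed = 8)
  burn_in(sch, 0)
  expect_equal(schedule_events_delivered(sch), 0)
  burn_in(sch, 500)
  expect_equal(schedule_events_delivered(sch), 500)
  t_mark <- schedule_time(sch)
  ev <- collect_events(sch, 1)
  expect_gte(ev$time[1], t_mark)
})

test_that("post-burn-in event rate matches the stationary renewal rate", {
  # ~100 links with unit-mean exponential clocks: rate 1 per link
  net <- generate_ws(100, 2, 0, seed = 1)
  sch <- make_sched(net, seed = 9)
  burn_in(sch, 10 * nrow(net$edges))
  t0 <- schedule_time(sch)
  ev <- collect_events(sch, 20000)
  window <- ev$time[nrow(ev)] - t0
  rate <- nrow(ev) / (window * nrow(net$edges))
  expect_lt(abs(rate - 1), 0.05)
})

test_that("stationary mean inter-event time matches exp(nu + sigma^2/2)", {
  net <- static_network(2, rbind(c(1, 2)))
  m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 1.5)
  sch <- build_schedule(net, m, seed = 10)
  gaps <- diff(collect_events(sch, 1e5)$time)
  expect_lt(abs(mean(gaps) - m$analytic_mean) / m$analytic_mean, 0.05)
})

test_that("dormant cap silences links and exhausts the schedule", {
  net <- static_network(2, rbind(c(1, 2)))
  m <- make_interevent_model("exponential", rate = 1)
  sch <- build_schedule(net, m, init_mean = 1, init_sd = 0.1, t_max = 30,
                        cap_mode = "dormant", seed = 11)
  ev <- collect_events(sch, 1e6)
  expect_true(attr(ev, "exhausted"))
  expect_true(all(ev$time <= 30))
  expect_equal(schedule_pending(sch), 0)
  expect_error(next_activation(sch), class = "schedule_exhausted")
  sch2 <- build_schedule(net, m, init_mean = 1, init_sd = 0.1, t_max = 30,
                         cap_mode = "dormant", seed = 11)
  expect_error(burn_in(sch2, 1e6), class = "schedule_exhausted")
})

test_that("truncated cap keeps waiting times within the horizon", {
  net <- static_network(2, rbind(c(1, 2)))
  m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 20)
  sch <- build_schedule(net, m, t_max = 1e6, cap_mode = "truncate", seed = 12)
  ev <- collect_events(sch, 5000)
  expect_equal(nrow(ev), 5000)  # never exhausts
  expect_true(all(diff(ev$time) <= 1e6))
  # empirical truncated mean agrees with the closed form
  m_hat <- mean(diff(ev$time))
  m_th <- interevent_mean(m, horizon = 1e6, conditional = TRUE)
  expect_lt(abs(m_hat - m_th) / m_th, 0.25)
})

test_that("event logs round-trip at full precision", {
  net <- generate_er(30, 4, seed = 3)
  sch <- make_sched(net, seed = 13)
  ev <- collect_events(sch, 500)
  f <- withr::local_tempfile()
  write_event_log(ev, f)
  back <- read_event_log(f)
  expect_identical(back$time, ev$time)
  expect_identical(back$u, as.integer(ev$u))
  expect_identical(back$v, as.integer(ev$v))
})
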
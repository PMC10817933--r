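test_that("opinion initialisation is uniform and seed-reproducible", {
  x <- init_opinions(1e5, seed = 1)
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.5), 0.01)
  expect_identical(init_opinions(100, seed = 9), init_opinions(100, seed = 9))
})

test_that("attempt_exchange follows the gated symmetric update", {
  r <- attempt_exchange(c(0.2, 0.3), 1, 2, d = 0.2, mu = 0.5)
  expect_true(r$success)
  expect_equal(r$opinions, c(0.25, 0.25))

  r <- attempt_exchange(c(0.4, 0.9), 1, 2, d = 0.2, mu = 0.5)
  expect_false(r$success)
  expect_equal(r$opinions, c(0.4, 0.9))

  r <- attempt_exchange(c(0.0, 0.1), 1, 2, d = 0.2, mu = 0.3)
  expect_true(r$success)
  expect_equal(r$opinions, c(0.03, 0.07))

  # strict inequality: a gap exactly at d fails
  r <- attempt_exchange(c(0.3, 0.5), 1, 2, d = 0.2, mu = 0.5)
  expect_false(r$success)

  # identical opinions: gate passes but nothing changes, so not a success
  r <- attempt_exchange(c(0.4, 0.4), 1, 2, d = 0.2, mu = 0.5)
  expect_false(r$success)

  expect_error(attempt_exchange(c(0.1, 0.2), 2, 2, d = 0.5), "distinct")
})

test_that("pair sum is conserved and the gap contracts by |1 - 2 mu|", {
  # dyadic opinions make the arithmetic exact in binary floating point
  set.seed(3)
  for (mu in c(0.25, 0.5, 0.75)) {
    for (rep in 1:50) {
      x <- sample.int(2^20, 2) / 2^22  # opinions in (0, 0.25]
      r <- attempt_exchange(x, 1, 2, d = 1, mu = mu)
      expect_true(r$success || x[1] == x[2])
      expect_identical(sum(r$opinions), sum(x))
      expect_identical(abs(diff(r$opinions)), abs(1 - 2 * mu) * abs(diff(x)))
    }
  }
})

er_setup <- function(n = 200, k = 10, seed = 1) {
  net <- generate_er(n, k, seed = seed)
  list(net = net,
       sch = function(s, model = make_interevent_model("exponential",
                                                       rate = 1), ...)
         build_schedule(net, model, seed = s, ...))
}

test_that("population opinion sum is conserved across a long run", {
  s <- er_setup()
  sch <- s$sch(2)
  x0 <- init_opinions(200, seed = 3)
  res <- run_temporal(s$net, sch, d = 1, mu = 0.3, opinions = x0,
                      stop_window = 1e9, max_events = 1e6)
  expect_equal(res$events, 1e6)
  expect_lt(abs(sum(res$opinions) - sum(x0)), 1e-6)
  expect_true(all(res$opinions >= 0 & res$opinions <= 1))
})

test_that("opinions stay within [0,1] along the whole trajectory", {
  s <- er_setup(100, 8, seed = 5)
  sch <- s$sch(6)
  res <- run_temporal(s$net, sch, d = 0.4, opinions = init_opinions(100, seed = 7),
                      record_every = 1000, max_events = 3e5)
  expect_true(all(res$trajectory >= 0 & res$trajectory <= 1))
  expect_true(!is.unsorted(res$trajectory_times))
})

test_that("full-confidence dynamics on a complete graph reach the mean", {
  net <- static_network(10, t(utils::combn(10, 2)))
  sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                        seed = 8)
  x0 <- init_opinions(10, seed = 9)
  res <- run_temporal(net, sch, d = 1, mu = 0.5, opinions = x0)
  expect_equal(res$termination, "converged")
  expect_true(all(abs(res$opinions - mean(x0)) < 1e-9))
  # conservation pins the consensus value at the initial mean
  expect_equal(mean(res$opinions), mean(x0), tolerance = 1e-12)
})

test_that("a pair beyond the confidence gate never exchanges", {
  net <- static_network(2, rbind(c(1, 2)))
  sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                        seed = 10)
  res <- run_temporal(net, sch, d = 0.5, opinions = c(0, 1), stop_window = 50)
  expect_equal(res$successes, 0)
  expect_equal(res$t_f, 0)
  expect_equal(res$events, 50)
  expect_equal(res$termination, "converged")
  expect_equal(res$opinions, c(0, 1))
})

test_that("isolated nodes keep their initial opinion exactly", {
  net <- static_network(5, rbind(c(1, 2), c(2, 3), c(3, 4)))
  sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                        seed = 11)
  x0 <- init_opinions(5, seed = 12)
  res <- run_temporal(net, sch, d = 1, opinions = x0)
  expect_identical(res$opinions[5], x0[5])
})

test_that("temporal runs are deterministic given seeds and flag the horizon", {
  s <- er_setup(150, 8, seed = 13)
  x0 <- init_opinions(150, seed = 14)
  r1 <- run_temporal(s$net, s$sch(15), d = 0.2, opinions = x0)
  r2 <- run_temporal(s$net, s$sch(15), d = 0.2, opinions = x0)
  expect_identical(r1$opinions, r2$opinions)
  expect_identical(r1$t_f, r2$t_f)

  rh <- run_temporal(s$net, s$sch(15), d = 0.2, opinions = x0, max_time = 0.5)
  expect_equal(rh$termination, "horizon")
})

test_that("run_temporal validates schedule-network consistency", {
  s <- er_setup(50, 6, seed = 16)
  other <- generate_er(50, 6, seed = 99)
  sch <- s$sch(17)
  expect_error(run_temporal(other, sch, d = 0.5,
                            opinions = init_opinions(50, seed = 1)),
               "link set")
})

test_that("static baseline is deterministic and converges like the model", {
  net <- generate_er(200, 10, seed = 18)
  x0 <- init_opinions(200, seed = 19)
  r1 <- run_static_baseline(net, d = 0.5, opinions = x0, seed = 20)
  r2 <- run_static_baseline(net, d = 0.5, opinions = x0, seed = 20)
  expect_identical(r1$opinions, r2$opinions)
  expect_equal(r1$termination, "converged")
  expect_equal(summarize_clusters(r1)$n_clusters, 1)
  expect_error(run_static_baseline(static_network(3, matrix(0L, 0, 2)),
                                   d = 0.5, opinions = runif(3), seed = 1),
               "no edges")
})

test_that("a stopped run is quiescent up to residual straggler absorption", {
  # after full consensus the frozen state is exactly quiet
  net <- static_network(12, t(utils::combn(12, 2)))
  sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                        seed = 29)
  res <- run_temporal(net, sch, d = 1, opinions = init_opinions(12, seed = 28))
  expect_equal(res$termination, "converged")
  more <- collect_events(sch, 2000)
  expect_equal(run_replay(more, d = 1, opinions = res$opinions,
                          stop_window = 1e9)$successes, 0)

  # in the multi-cluster regime the only remaining activity is the rare
  # absorption of stragglers: the residual success rate is tiny compared
  # with the active phase (where most activations succeed)
  for (i in 1:4) {
    net <- generate_er(200, 10, seed = 30 + i)
    sch <- build_schedule(net, make_interevent_model("exponential", rate = 1),
                          seed = 40 + i)
    res <- run_temporal(net, sch, d = 0.15,
                        opinions = init_opinions(200, seed = 50 + i))
    expect_equal(res$termination, "converged")
    more <- collect_events(sch, 10 * 200)
    rep2 <- run_replay(more, d = 0.15, opinions = res$opinions,
                       stop_window = 1e9)
    active_rate <- res$successes / res$events
    expect_lt(rep2$successes / nrow(more), min(0.05, active_rate / 3))
  }
})

test_that("replaying a recorded stream reproduces a run bit-exactly", {
  net <- generate_er(80, 8, seed = 21)
  m <- make_interevent_model("lognormal", meanlog = 0, sdlog = 1)
  x0 <- init_opinions(80, seed = 22)
  direct <- run_temporal(net, build_schedule(net, m, seed = 23), d = 0.3,
                         opinions = x0)
  stream <- collect_events(build_schedule(net, m, seed = 23),
                           direct$events)
  replay <- run_replay(stream, d = 0.3, opinions = x0, stop_window = 80)
  expect_identical(replay$opinions, direct$opinions)
  expect_identical(replay$t_f, direct$t_f)
  expect_identical(replay$successes, direct$successes)
})
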
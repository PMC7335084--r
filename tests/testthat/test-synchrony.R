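test_that("the SPIKE distance obeys its axioms on random pairs", {
  set.seed(61)
  for (r in 1:100) {
    T_s <- 60
    x <- poisson_train(runif(1, 0.5, 3), T_s)
    y <- poisson_train(runif(1, 0.5, 3), T_s)
    d_xy <- spike_distance(x, y, T_s)
    expect_gte(d_xy, 0)
    expect_identical(spike_distance(x, x, T_s), 0)
    expect_equal(spike_distance(y, x, T_s), d_xy, tolerance = 1e-14)
    k <- exp(runif(1, log(0.1), log(10)))
    expect_lt(abs(spike_distance(k * x, k * y, k * T_s) - d_xy), 1e-12)
  }
})

test_that("closed-form integration matches dense-grid quadrature", {
  set.seed(62)
  for (r in 1:10) {
    T_s <- 60
    x <- poisson_train(runif(1, 1, 2), T_s)
    y <- poisson_train(runif(1, 1, 2), T_s)
    expect_lt(abs(spike_distance(x, y, T_s) -
                    grid_spike_distance(x, y, T_s, dt = 1e-4)), 1e-3)
  }
})

test_that("degenerate and invalid inputs are rejected or handled", {
  expect_error(spike_distance(numeric(0), 1:3 / 10, 1), "at least one spike")
  expect_error(spike_distance(c(0.5, 0.2), c(0.1), 1), "sorted")
  expect_error(spike_distance(c(0.5, 1.2), c(0.1), 1), "within")
  # single-spike trains are fine
  expect_gte(spike_distance(0.3, 0.7, 1), 0)
  # spikes exactly at the interval edges do not break augmentation
  expect_identical(spike_distance(c(0, 0.5, 1), c(0, 0.5, 1), 1), 0)
})

test_that("identical trains give synchrony exactly 1 under every convention", {
  x <- poisson_train(1, 60)
  for (conv in c("ratio_of_means", "mean_of_ratios", "unnormalized")) {
    r <- pair_synchrony(x, x, synchrony_params(n_random = 20, timeline_s = 60,
                                               convention = conv), seed = 5)
    expect_identical(r$synchrony, 1)
  }
})

test_that("the surrogate null is reproducible and scales like 1/sqrt(n)", {
  x <- poisson_train(0.5, 60)
  y <- poisson_train(0.5, 60)
  p <- synchrony_params(n_random = 50, timeline_s = 60)
  r1 <- pair_synchrony(x, y, p, seed = 9)
  r2 <- pair_synchrony(x, y, p, seed = 9)
  expect_identical(r1, r2)
  r3 <- pair_synchrony(x, y, p, seed = 10)
  expect_false(identical(r1$null_mean, r3$null_mean))
  # SE of the null mean drops like 1/sqrt(n_random)
  se <- vapply(c(50, 200, 800), function(n) {
    mus <- vapply(1:15, function(s) {
      pair_synchrony(x, y, synchrony_params(n_random = n, timeline_s = 60),
                     seed = s)$null_mean
    }, 1.0)
    sd(mus)
  }, 1.0)
  expect_lt(se[2] / se[1], 1)
  expect_lt(se[3] / se[2], 1)
  expect_lt(abs(log(se[1] / se[3]) / log(4) - 1), 0.6)
})

test_that("device synchrony is 1 for identical channels, symmetric in order", {
  tt <- poisson_train(1, 60)
  sp <- make_spike_tbl(list(a = tt, b = tt, c = tt), duration_s = 60)
  p <- synchrony_params(n_random = 20, timeline_s = 60)
  sy <- device_synchrony(sp, p, seed = 2)
  expect_identical(sy$device_synchrony, 1)
  expect_identical(nrow(sy$pairs), 3L)
  # permuting channel names leaves the device value unchanged
  sp2 <- make_spike_tbl(list(c = tt, a = tt, b = tt), duration_s = 60)
  sy2 <- device_synchrony(sp2, p, seed = 2)
  expect_identical(sy2$device_synchrony, sy$device_synchrony)
  # fewer than two channels: flagged missing
  sy1 <- device_synchrony(make_spike_tbl(list(a = tt), duration_s = 60), p)
  expect_true(is.na(sy1$device_synchrony))
})

test_that("coordinated tight bursting outranks sparse jittered bursting", {
  p <- synchrony_params(n_random = 30, timeline_s = 120)
  vals <- vapply(1:5, function(s) {
    tight <- simulate_spike_trains(sim_config(
      n_channels = 4, duration_s = 120, participation_prob = 1,
      burst_jitter_s = 0.001, background_rate_hz = 0.1, seed = 600 + s
    ))
    loose <- simulate_spike_trains(sim_config(
      n_channels = 4, duration_s = 120, participation_prob = 0.2,
      burst_jitter_s = 0.05, background_rate_hz = 0.1, seed = 700 + s
    ))
    c(device_synchrony(tight$spikes, p, seed = s)$device_synchrony,
      device_synchrony(loose$spikes, p, seed = s)$device_synchrony)
  }, c(1.0, 1.0))
  expect_gt(mean(vals[1, ]), mean(vals[2, ]) + 0.1)
})

test_that("tidy and glance expose the pair table and device summary", {
  tt <- poisson_train(1, 60)
  sp <- make_spike_tbl(list(a = tt, b = sort(c(tt[-1], 0.123))),
                       duration_s = 60)
  sy <- device_synchrony(sp, synchrony_params(n_random = 10, timeline_s = 60))
  td <- tidy(sy)
  expect_true(all(c("channel_x", "channel_y", "d_obs", "null_mean",
                    "synchrony", "sync_mean_of_ratios") %in% names(td)))
  g <- glance(sy)
  expect_identical(g$n_pairs, 1L)
  expect_equal(g$device_synchrony, td$synchrony[1])
})
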
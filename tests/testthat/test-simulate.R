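test_that("zero rates give empty trains; huge rates are refused", {
  cfg <- sim_config(n_channels = 3, duration_s = 60, background_rate_hz = 0,
                    network_burst_rate_hz = 0)
  expect_identical(n_spikes(simulate_spike_trains(cfg)$spikes), 0L)
  expect_error(
    simulate_spike_trains(sim_config(n_channels = 60, duration_s = 600,
                                     background_rate_hz = 1000)),
    "10\\^7"
  )
})

test_that("background spike counts follow the Poisson rate law", {
  # Poisson-only at 2 Hz for 600 s: mean count over seeds within 3 SE of 1200
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(n_channels = 1, duration_s = 600,
                      background_rate_hz = 2, network_burst_rate_hz = 0,
                      refractory_s = 0, seed = s)
    n_spikes(simulate_spike_trains(cfg)$spikes)
  }, 1L)
  expect_lt(abs(mean(counts) - 1200), 3 * sqrt(1200) / sqrt(100))
  # dispersion consistent with Poisson (chi-square index of dispersion)
  disp <- (100 - 1) * var(counts) / 1200
  expect_gt(disp, qchisq(0.005, 99))
  expect_lt(disp, qchisq(0.995, 99))
})

test_that("degenerate burst parameters give identical bursts on all channels", {
  cfg <- sim_config(n_channels = 5, duration_s = 60, background_rate_hz = 0,
                    network_burst_rate_hz = 1 / 60, participation_prob = 1,
                    burst_jitter_s = 0, spikes_per_burst_mean = 6,
                    spikes_per_burst_dispersion = Inf,
                    intra_burst_isi_s = 0.05, seed = 5)
  # force exactly one event with exactly 6 spikes by retrying seeds
  for (s in 1:50) {
    cfg$seed <- s
    sim <- simulate_spike_trains(cfg)
    sz <- dplyr::count(sim$truth$spikes[sim$truth$spikes$source == "burst", ],
                       .data$channel_id, .data$event_id)
    if (nrow(sim$truth$events) == 1 && nrow(sz) && all(sz$n == 6)) break
  }
  expect_identical(nrow(sim$truth$events), 1L)
  trains <- lapply(spike_channels(sim$spikes),
                   function(ch) spike_times(sim$spikes, ch))
  for (tr in trains) expect_identical(tr, trains[[1]])
  expect_length(trains[[1]], 6)
})

test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  cfg <- sim_config(n_channels = 4, duration_s = 60, seed = 42)
  a <- simulate_spike_trains(cfg)
  set.seed(777)
  before <- runif(1)
  set.seed(777)
  b <- simulate_spike_trains(cfg)
  after <- runif(1)
  expect_identical(a$spikes$time_s, b$spikes$time_s)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(before, after)
})

test_that("every emitted spike has exactly one ground-truth record", {
  sim <- simulate_spike_trains(sim_config(n_channels = 6, duration_s = 120,
                                          seed = 9))
  expect_identical(n_spikes(sim$spikes), nrow(sim$truth$spikes))
  expect_identical(sim$spikes$time_s, sim$truth$spikes$time_s)
  expect_true(all(sim$truth$spikes$source %in% c("background", "burst")))
  # refractory respected per channel
  for (ch in spike_channels(sim$spikes)) {
    expect_true(all(diff(spike_times(sim$spikes, ch)) >= 0.002))
  }
})

test_that("challenge pairs scale the ground-truth burst-event rate", {
  ratios <- vapply(1:30, function(s) {
    pair <- simulate_challenge_pair(
      sim_config(n_channels = 2, duration_s = 600, seed = s),
      burst_rate_multiplier = 3
    )
    nrow(pair$truth$challenged$events) / nrow(pair$truth$baseline$events)
  }, 1.0)
  # baseline events ~ Poisson(60), challenge ~ Poisson(180)
  expect_lt(abs(mean(ratios) - 3), 3 * sd(ratios) / sqrt(30))
  expect_error(
    simulate_challenge_pair(sim_config(), participation_delta = 0.5),
    "participation"
  )
})

test_that("rendered noise floor has the configured SD", {
  # spike-free channels: the trace is pure Gaussian noise
  sp <- make_spike_tbl(list(), duration_s = 10)
  rr <- render_raw(sp, render_config(noise_sd_uV = 5, seed = 2),
                   channel_ids = c("ch1", "ch2"))
  sds <- apply(rr$recording$samples, 1, sd)
  expect_true(all(abs(sds - 5) / 5 < 0.02))
})

test_that("a rendered spike puts its trough at the spike time", {
  sp <- make_spike_tbl(list(ch1 = 1.0), duration_s = 2, trough_uV = -50)
  rr <- render_raw(sp, render_config(noise_sd_uV = 1, seed = 3))
  v <- rr$recording$samples[1, ]
  fs <- rr$recording$sampling_rate_hz
  win <- v[round(0.999 * fs):round(1.001 * fs)]
  expect_lt(abs(min(win) - (-50)), 5)  # within the noise envelope
  t_min <- (which.min(v) - 1) / fs
  expect_lt(abs(t_min - 1.0), 0.001)
})

test_that("heater events hit ceiling(fraction x channels) channels", {
  trains <- stats::setNames(
    lapply(1:60, function(i) sort(runif(5, 0, 10))),
    sprintf("ch%02d", 1:60)
  )
  sp <- make_spike_tbl(trains, duration_s = 10)
  rr <- render_raw(sp, render_config(heater_rate_hz = 0.1,
                                     heater_channel_fraction = 0.85,
                                     seed = 6))
  ev <- rr$truth$heater_events
  expect_gt(nrow(ev), 0)
  expect_true(all(lengths(ev$channels) == 51))  # ceiling(0.85 * 60)
  # the deflection is below -200 uV on the hit channels at the event time
  fs <- rr$recording$sampling_rate_hz
  for (k in seq_len(nrow(ev))) {
    at <- round(ev$time_s[k] * fs) + 1
    hit <- match(ev$channels[[k]], rr$recording$channel_ids)
    expect_true(all(rr$recording$samples[hit, at] < -200))
  }
})
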
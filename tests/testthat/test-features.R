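test_that("channel features match hand arithmetic", {
  # 600 spikes in 600 s -> 1 Hz, no bursts (1 s ISIs)
  sp <- make_spike_tbl(list(ch01 = seq(0.5, 599.5, by = 1)), duration_s = 600)
  cf <- channel_features(sp)
  expect_equal(cf$firing_rate_hz, 1.0)
  expect_identical(cf$n_bursts, 0L)
  expect_true(is.na(cf$mean_burst_duration_s))
  expect_true(is.na(cf$mean_intra_burst_isi_s))
  expect_equal(cf$pct_spikes_in_bursts, 0)
  expect_equal(cf$pct_spikes_outside_bursts, 100)

  # a single 6-spike burst at ISI 0.05 and nothing else
  sp2 <- make_spike_tbl(list(ch01 = seq(10, by = 0.05, length.out = 6)),
                        duration_s = 600)
  cf2 <- channel_features(sp2)
  expect_equal(cf2$pct_spikes_in_bursts, 100)
  expect_equal(cf2$mean_burst_duration_s, 0.25)
  expect_equal(cf2$mean_intra_burst_isi_s, 0.05)
  expect_equal(cf2$bursts_per_min, 1 / 10)
})

test_that("percentages in and out of bursts are exact complements", {
  set.seed(51)
  for (r in 1:20) {
    sim <- simulate_spike_trains(sim_config(n_channels = 4, duration_s = 60,
                                            seed = 500 + r))
    if (!n_spikes(sim$spikes)) next
    cf <- channel_features(sim$spikes)
    expect_equal(cf$pct_spikes_in_bursts + cf$pct_spikes_outside_bursts,
                 rep(100, nrow(cf)))
    expect_true(all(cf$pct_spikes_in_bursts >= 0 &
                      cf$pct_spikes_in_bursts <= 100))
  }
})

test_that("features are invariant to time translation of the recording", {
  sim <- simulate_spike_trains(sim_config(n_channels = 4, duration_s = 60,
                                          seed = 52))
  shifted <- tibble::as_tibble(sim$spikes)
  shifted$time_s <- shifted$time_s + 30
  sp2 <- mea_spikes(shifted, duration_s = 60 + 30, n_device_channels = 60)
  cf1 <- channel_features(sim$spikes, duration_s = 60)
  cf2 <- channel_features(sp2, detect_bursts(sp2), duration_s = 60)
  for (col in c("firing_rate_hz", "n_bursts", "mean_burst_duration_s",
                "mean_intra_burst_isi_s", "pct_spikes_in_bursts")) {
    expect_equal(cf2[[col]], cf1[[col]], tolerance = 1e-9)
  }
})

test_that("device means average defined channels only and respect bounds", {
  cf <- channel_features(
    make_spike_tbl(list(ch01 = seq(1, 60, by = 1),          # 1 Hz, no bursts
                        ch02 = c(seq(10, by = 0.05, length.out = 12),
                                 seq(40, 60, by = 0.2))),   # bursting
                   duration_s = 60)
  )
  df <- device_features(cf, n_device_channels = 60, device = "d")
  dev <- df[df$level == "device", ]
  expect_equal(dev$firing_rate_hz, mean(cf$firing_rate_hz))
  # the non-bursting channel does not dilute burst features
  expect_equal(dev$mean_burst_duration_s,
               cf$mean_burst_duration_s[cf$channel_id == "ch02"])
  # bounded by channel min/max
  for (f in c("firing_rate_hz", "pct_spikes_in_bursts")) {
    expect_gte(dev[[f]], min(cf[[f]], na.rm = TRUE))
    expect_lte(dev[[f]], max(cf[[f]], na.rm = TRUE))
  }
  # two channels + device row
  expect_identical(nrow(df), 3L)
})

test_that("device means are invariant to channel order", {
  sim <- simulate_spike_trains(sim_config(n_channels = 5, duration_s = 60,
                                          seed = 53))
  cf <- channel_features(sim$spikes)
  perm <- cf[sample(nrow(cf)), ]
  d1 <- device_features(cf)
  d2 <- device_features(perm)
  expect_equal(d1[d1$level == "device", -(1:3)],
               d2[d2$level == "device", -(1:3)], ignore_attr = TRUE)
})

test_that("fold change is 1 for identical epochs and tracks the multiplier", {
  sim <- simulate_spike_trains(sim_config(n_channels = 6, duration_s = 120,
                                          seed = 54))
  f <- compute_features(sim$spikes)
  fc <- fold_change(f, f)
  expect_true(all(fc$fold_change[fc$defined] == 1))
  # doubled burst-event rate doubles bursts/min within Poisson error
  ratios <- vapply(1:30, function(s) {
    pair <- simulate_challenge_pair(sim_config(n_channels = 8,
                                               duration_s = 300, seed = s),
                                    burst_rate_multiplier = 2)
    fb <- compute_features(pair$baseline)
    fc_ <- compute_features(pair$challenged)
    x <- fold_change(fb, fc_)
    x$fold_change[x$feature == "bursts_per_min"]
  }, 1.0)
  expect_lt(abs(mean(ratios) - 2), 3 * sd(ratios) / sqrt(30) + 0.2)
})

test_that("undefined baselines are flagged, config mismatches refused", {
  quiet <- make_spike_tbl(list(ch01 = seq(1, 590, by = 1)), duration_s = 600)
  busy <- make_spike_tbl(list(ch01 = c(seq(10, by = 0.05, length.out = 12),
                                       seq(30, 580, by = 1))),
                         duration_s = 600)
  fq <- compute_features(quiet)
  fb <- compute_features(busy)
  fc <- fold_change(fq, fb)
  expect_false(fc$defined[fc$feature == "bursts_per_min"])
  expect_true(is.na(fc$fold_change[fc$feature == "bursts_per_min"]))
  f_other <- compute_features(busy, params = burst_params(min_spikes = 4))
  expect_error(fold_change(fq, f_other), "different burst parameters")
})
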
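test_that("the 80%-of-channels rule is boundary inclusive", {
  # 50/60 = 83% -> one event; 48/60 = exactly 80% -> one event;
  # 47/60 and 40/60 -> none
  expect_identical(nrow(detect_heater_events(simultaneous_event(50))), 1L)
  expect_identical(nrow(detect_heater_events(simultaneous_event(48))), 1L)
  expect_identical(nrow(detect_heater_events(simultaneous_event(47))), 0L)
  expect_identical(nrow(detect_heater_events(simultaneous_event(40))), 0L)
})

test_that("only sub--200 uV troughs are heater candidates", {
  sp <- simultaneous_event(50, amp = -150)
  expect_identical(nrow(detect_heater_events(sp)), 0L)
  # exactly -200 is not below -200
  sp2 <- simultaneous_event(50, amp = -200)
  expect_identical(nrow(detect_heater_events(sp2)), 0L)
})

test_that("candidates within the 1 ms window coalesce into one timed event", {
  trains <- stats::setNames(
    lapply(1:50, function(i) 5 + (i %% 5) * 2e-4),  # spread over 0.8 ms
    sprintf("ch%02d", 1:50)
  )
  sp <- make_spike_tbl(trains, duration_s = 10, trough_uV = -300)
  ev <- detect_heater_events(sp)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$time_s, 5)  # earliest candidate
  expect_identical(ev$n_channels, 50L)
})

test_that("the purge window is symmetric, inclusive at 6 ms", {
  base <- simultaneous_event(50, t = 5)
  extra <- tibble::tibble(channel_id = "ch01",
                          time_s = c(4.993, 4.995, 5.004, 5.006, 5.007),
                          trough_uV = -50)
  sp <- mea_spikes(dplyr::bind_rows(tibble::as_tibble(base), extra),
                   duration_s = 10, n_device_channels = 60)
  ev <- detect_heater_events(sp)
  out <- purge_heater_spikes(sp, ev)
  kept <- out$time_s[out$channel_id == "ch01"]
  # |dt| = 7 ms survives; |dt| <= 6 ms (and the artifacts themselves) do not
  expect_identical(kept, c(4.993, 5.007))
  # 50 artifact spikes + the extras at 4.995, 5.004 and 5.006 s
  expect_identical(attr(out, "n_purged"), 53L)
})

test_that("purging with no events is the identity", {
  sim <- simulate_spike_trains(sim_config(n_channels = 5, duration_s = 60,
                                          seed = 31))
  ev <- detect_heater_events(sim$spikes)
  expect_identical(nrow(ev), 0L)
  out <- purge_heater_spikes(sim$spikes, ev)
  expect_equal(tibble::as_tibble(out), tibble::as_tibble(sim$spikes),
               ignore_attr = TRUE)
})

test_that("injected heater events are fully removed, clean spikes retained", {
  # a device whose recordable electrodes all carry units, so the injected
  # events can reach the 80%-of-all-channels bar
  sim <- simulate_spike_trains(sim_config(seed = 32, n_device_channels = 12L))
  ev_times <- seq(30, 570, length.out = 10)
  contam <- inject_heater_artifacts(sim$spikes, ev_times, seed = 33)
  ev <- detect_heater_events(contam$spikes)
  expect_identical(nrow(ev), 10L)
  expect_equal(ev$time_s, ev_times, tolerance = 1e-9)
  out <- purge_heater_spikes(contam$spikes, ev)
  # no artifact-derived spike survives
  art <- contam$spikes[contam$truth$is_artifact, ]
  expect_identical(nrow(dplyr::semi_join(
    tibble::as_tibble(out), tibble::as_tibble(art),
    by = c("channel_id", "time_s")
  )), 0L)
  # and nothing within the purge window of any true event
  for (t in ev_times) expect_true(all(abs(out$time_s - t) > 0.006))
  # >= 95% of clean spikes retained
  clean <- contam$spikes[!contam$truth$is_artifact, ]
  expect_gt(n_spikes(out) / nrow(clean), 0.95)
})

test_that("channel QC keeps 10-spike channels and drops 9-spike channels", {
  sp <- make_spike_tbl(list(ch01 = seq_len(9) / 10,
                            ch02 = seq_len(10) / 10,
                            ch03 = seq_len(25) / 30),
                       duration_s = 600)
  res <- filter_low_count_channels(sp, min_spikes = 10)
  expect_identical(sort(spike_channels(res$spikes)), c("ch02", "ch03"))
  expect_identical(res$active$active, c(FALSE, TRUE, TRUE))
  expect_equal(percent_active(res$active, 60), 100 * 2 / 60)
})

test_that("percent_active handles the edge cases", {
  expect_identical(percent_active(logical(0), 60), 0)
  expect_identical(percent_active(rep(TRUE, 60), 60), 100)
  expect_identical(percent_active(c(rep(TRUE, 9), rep(FALSE, 3)), 60), 15)
  expect_error(percent_active(TRUE, 0), "positive")
})

test_that("cleaning order is detect -> purge -> filter and conserves spikes", {
  sim <- simulate_spike_trains(sim_config(n_channels = 8, duration_s = 120,
                                          n_device_channels = 8L, seed = 34))
  # one channel made sparse so the QC drops it after purging
  sparse <- tibble::as_tibble(sim$spikes)
  sparse <- sparse[sparse$channel_id != "ch08" |
                     seq_len(nrow(sparse)) %% 37 == 0, ]
  sp <- mea_spikes(sparse, duration_s = 120, n_device_channels = 8)
  contam <- inject_heater_artifacts(sp, c(40, 80), seed = 35)
  res <- clean_spikes(contam$spikes)
  expect_identical(res$qc$n_heater_events, 2L)
  dropped_spikes <- {
    counts <- dplyr::count(tibble::as_tibble(
      purge_heater_spikes(contam$spikes, res$events)
    ), channel_id)
    sum(counts$n[!counts$channel_id %in% spike_channels(res$spikes)])
  }
  expect_identical(res$qc$n_spikes_in,
                   res$qc$n_spikes_out + res$qc$n_spikes_purged +
                     dropped_spikes)
})

test_that("purge monotonicity: output is a subset of the input", {
  set.seed(36)
  for (r in 1:10) {
    sim <- simulate_spike_trains(sim_config(n_channels = 6, duration_s = 60,
                                            n_device_channels = 6L,
                                            seed = 100 + r))
    contam <- inject_heater_artifacts(sim$spikes, runif(3, 5, 55),
                                      seed = 200 + r)
    ev <- detect_heater_events(contam$spikes)
    out <- purge_heater_spikes(contam$spikes, ev)
    joined <- dplyr::semi_join(tibble::as_tibble(out),
                               tibble::as_tibble(contam$spikes),
                               by = c("channel_id", "time_s"))
    expect_identical(nrow(joined), n_spikes(out))
    for (t in ev$time_s) expect_true(all(abs(out$time_s - t) > 0.006))
  }
})
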
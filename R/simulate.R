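#' Simulation configuration
#'
#' Parameters of the synthetic MEA spike-train generator. Each channel fires
#' homogeneous Poisson background spikes; on top of that a device-level
#' Poisson process of *network-burst events* coordinates the channels: each
#' channel joins each event with probability `participation_prob` and emits
#' the event's spike pattern starting at its own onset, jittered around the
#' event time by a zero-mean Gaussian of SD `burst_jitter_s`. Each event's
#' pattern is drawn once and shared by its participating channels (that is
#' what makes the bursting *coordinated*; with zero jitter, participating
#' channels are exact replicas): its spike count is negative-binomial
#' (mean `spikes_per_burst_mean`, dispersion `spikes_per_burst_dispersion`;
#' `Inf` gives Poisson) and its intra-burst ISIs are exponential with mean
#' `intra_burst_isi_s`, truncated to `[refractory_s, 0.1 s]` so that
#' ground-truth bursts stay compact enough to satisfy the burst definition
#' used downstream. A refractory period is enforced by thinning (any spike
#' closer than `refractory_s` to its predecessor is deleted).
#'
#' Defaults describe a moderately active bursting culture on a 60-electrode
#' device of which 12 electrodes pick up units: 0.2 Hz background per
#' channel, 0.1 network bursts per second device-wide, 80% participation,
#' 10 ms onset jitter, ~12 spikes per burst at ~20 ms intra-burst ISI, 2 ms
#' refractory period, 10-minute epochs. Simulated troughs are drawn from a
#' Gaussian (`trough_mean_uV`, `trough_sd_uV`) so artifact rules that look at
#' amplitudes can be exercised.
#'
#' @param n_channels Number of spike-bearing channels.
#' @param duration_s Epoch length (s).
#' @param background_rate_hz Poisson background rate per channel (Hz).
#' @param network_burst_rate_hz Device-level rate of network-burst events (Hz).
#' @param participation_prob Probability a channel joins a given event.
#' @param burst_jitter_s SD of the per-channel onset jitter (s).
#' @param spikes_per_burst_mean,spikes_per_burst_dispersion Mean and
#'   negative-binomial size of the per-burst spike count (`Inf` = Poisson).
#' @param intra_burst_isi_s Mean of the truncated-exponential intra-burst ISI.
#' @param refractory_s Refractory period enforced by thinning (s).
#' @param trough_mean_uV,trough_sd_uV Gaussian trough amplitudes (microvolts).
#' @param n_device_channels Total recordable electrodes on the device.
#' @param seed Seed for this generator.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_channels = 12L, duration_s = 600,
                       background_rate_hz = 0.2,
                       network_burst_rate_hz = 0.1,
                       participation_prob = 0.8,
                       burst_jitter_s = 0.010,
                       spikes_per_burst_mean = 12,
                       spikes_per_burst_dispersion = Inf,
                       intra_burst_isi_s = 0.020,
                       refractory_s = 0.002,
                       trough_mean_uV = -60, trough_sd_uV = 8,
                       n_device_channels = 60L, seed = 1L) {
  stopifnot(n_channels >= 1, duration_s > 0,
            background_rate_hz >= 0, is.finite(background_rate_hz),
            network_burst_rate_hz >= 0, is.finite(network_burst_rate_hz),
            participation_prob >= 0, participation_prob <= 1,
            burst_jitter_s >= 0, spikes_per_burst_mean >= 0,
            intra_burst_isi_s > 0, refractory_s >= 0,
            n_device_channels >= n_channels)
  structure(list(n_channels = as.integer(n_channels), duration_s = duration_s,
                 background_rate_hz = background_rate_hz,
                 network_burst_rate_hz = network_burst_rate_hz,
                 participation_prob = participation_prob,
                 burst_jitter_s = burst_jitter_s,
                 spikes_per_burst_mean = spikes_per_burst_mean,
                 spikes_per_burst_dispersion = spikes_per_burst_dispersion,
                 intra_burst_isi_s = intra_burst_isi_s,
                 refractory_s = refractory_s,
                 trough_mean_uV = trough_mean_uV, trough_sd_uV = trough_sd_uV,
                 n_device_channels = as.integer(n_device_channels),
                 seed = as.integer(seed)),
            class = c("sim_config", "mea_params"))
}

#' Simulate coordinated bursting spike trains
#'
#' Draws one synthetic device recording from [sim_config()] together with its
#' ground truth. Deterministic for a fixed config (including its seed): the
#' caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @param device Device label for the output table.
#' @return A list with elements
#'   * `spikes` — an [mea_spikes()] table,
#'   * `truth` — a list with `spikes` (per-spike provenance: `source` is
#'     `"background"` or `"burst"`, `event_id` links burst spikes to their
#'     network event), `events` (device-level event times) and
#'     `participation` (which channel joined which event, with its jittered
#'     onset).
#' @examples
#' sim <- simulate_spike_trains(sim_config(n_channels = 4, duration_s = 60))
#' sim$spikes
#' @export
simulate_spike_trains <- function(config, device = "sim") {
  stopifnot(inherits(config, "sim_config"))
  expected <- config$n_channels * config$duration_s * config$background_rate_hz +
    config$network_burst_rate_hz * config$duration_s *
    config$n_channels * config$participation_prob * config$spikes_per_burst_mean
  if (expected > 1e7) {
    stop("configuration implies > 10^7 expected spikes; refusing to simulate",
         call. = FALSE)
  }
  withr::with_seed(config$seed, simulate_spike_trains_impl(config, device))
}

simulate_spike_trains_impl <- function(config, device) {
  T_s <- config$duration_s
  ch_ids <- sprintf("ch%02d", seq_len(config$n_channels))

  n_ev <- stats::rpois(1, config$network_burst_rate_hz * T_s)
  ev_times <- sort(stats::runif(n_ev, 0, T_s))
  events <- tibble::tibble(event_id = seq_len(n_ev), time_s = ev_times)

  # one spike pattern per network event, shared by every participating
  # channel: the device-wide coordination the synchrony stage measures.
  # With zero onset jitter, coordinated channels are exact replicas.
  ev_sizes <- draw_burst_size(n_ev, config)
  ev_patterns <- lapply(seq_len(n_ev), function(e) {
    if (ev_sizes[e] < 1) return(double())
    cumsum(c(0, rtrunc_exp(ev_sizes[e] - 1, config$intra_burst_isi_s, 0.1,
                           lower = config$refractory_s)))
  })

  part_rows <- list()
  spike_rows <- list()
  for (ci in seq_along(ch_ids)) {
    ch <- ch_ids[ci]
    # background: homogeneous Poisson
    nb <- stats::rpois(1, config$background_rate_hz * T_s)
    bg <- stats::runif(nb, 0, T_s)
    tt <- bg
    src <- rep("background", nb)
    eid <- rep(NA_integer_, nb)
    if (n_ev > 0 && config$participation_prob > 0) {
      joins <- which(stats::runif(n_ev) < config$participation_prob)
      for (e in joins) {
        nspk <- ev_sizes[e]
        if (nspk < 1) next
        onset <- ev_times[e] + stats::rnorm(1, 0, config$burst_jitter_s)
        bt <- onset + ev_patterns[[e]]
        part_rows[[length(part_rows) + 1]] <-
          tibble::tibble(event_id = e, channel_id = ch, onset_s = onset)
        tt <- c(tt, bt)
        src <- c(src, rep("burst", nspk))
        eid <- c(eid, rep(e, nspk))
      }
    }
    keep <- tt >= 0 & tt <= T_s
    tt <- tt[keep]; src <- src[keep]; eid <- eid[keep]
    o <- order(tt)
    tt <- tt[o]; src <- src[o]; eid <- eid[o]
    keep <- thin_refractory(tt, config$refractory_s)
    tt <- tt[keep]; src <- src[keep]; eid <- eid[keep]
    # break exact ties across sources (measure-zero but possible in replay)
    dup <- duplicated(tt)
    tt <- tt[!dup]; src <- src[!dup]; eid <- eid[!dup]
    spike_rows[[ci]] <- tibble::tibble(channel_id = ch, time_s = tt,
                                       source = src, event_id = eid)
  }

  per_spike <- dplyr::bind_rows(spike_rows)
  per_spike$trough_uV <- pmin(
    stats::rnorm(nrow(per_spike), config$trough_mean_uV, config$trough_sd_uV),
    -1
  )
  spikes <- mea_spikes(per_spike[c("channel_id", "time_s", "trough_uV")],
                       device_id = device, duration_s = T_s,
                       n_device_channels = config$n_device_channels)
  truth <- list(
    spikes = per_spike,
    events = events,
    participation = if (length(part_rows)) dplyr::bind_rows(part_rows)
                    else tibble::tibble(event_id = integer(),
                                        channel_id = character(),
                                        onset_s = double())
  )
  list(spikes = spikes, truth = truth)
}

draw_burst_size <- function(n, config) {
  mu <- config$spikes_per_burst_mean
  size <- config$spikes_per_burst_dispersion
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

# Exponential with mean `mu` truncated to [lower, upper], by inverse CDF.
# The lower bound keeps intra-burst ISIs clear of the refractory period, so
# the realized per-burst spike count follows the configured distribution
# instead of being deflated by thinning.
rtrunc_exp <- function(n, mu, upper, lower = 0) {
  if (n <= 0) return(double())
  u <- stats::runif(n)
  p_lo <- 1 - exp(-lower / mu)
  p_hi <- 1 - exp(-upper / mu)
  -mu * log(1 - (p_lo + u * (p_hi - p_lo)))
}

# Keep-first thinning: drop any spike closer than `refractory` to the last
# *kept* spike. Preserves sortedness.
thin_refractory <- function(times, refractory) {
  n <- length(times)
  keep <- logical(n)
  if (n == 0) return(keep)
  last <- -Inf
  for (i in seq_len(n)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}

#' Raw-voltage rendering configuration
#'
#' Parameters for turning a spike table into a synthetic raw recording:
#' Gaussian noise plus one biphasic template per spike (trough aligned to the
#' spike time at the nearest sample), and optional device-wide heater
#' artifacts — large negative deflections injected simultaneously on
#' `ceiling(heater_channel_fraction * n_channels)` randomly chosen channels,
#' followed by a damped oscillation ("afterwaves") spanning
#' `heater_afterwave_span_s`. The afterwaves are deliberately large enough to
#' masquerade as spikes under naive threshold detection, which is what makes
#' artifact removal testable.
#'
#' @param sampling_rate_hz Sampling rate of the rendered trace (default
#'   5 kHz for desk-scale runs; the acquisition-grade 22.3 kHz also works).
#' @param noise_sd_uV SD of the Gaussian noise floor (microvolts).
#' @param spike_trough_uV Template trough amplitude used when the spike table
#'   has no amplitudes (`NA` troughs); negative microvolts.
#' @param spike_width_ms Full template width in milliseconds.
#' @param heater_rate_hz Poisson rate of heater events (0 disables them).
#' @param heater_amplitude_uV Main deflection of a heater event; must be
#'   below -200 so the events qualify under the artifact rule.
#' @param heater_channel_fraction Fraction of channels hit by each event.
#' @param heater_afterwave_span_s Span of the decaying afterwaves (s).
#' @param seed Seed for noise, heater placement and channel choice.
#' @return A `render_config` object.
#' @export
render_config <- function(sampling_rate_hz = 5000, noise_sd_uV = 5,
                          spike_trough_uV = -60, spike_width_ms = 1.2,
                          heater_rate_hz = 0, heater_amplitude_uV = -350,
                          heater_channel_fraction = 0.85,
                          heater_afterwave_span_s = 0.006, seed = 1L) {
  stopifnot(sampling_rate_hz > 0, noise_sd_uV > 0, spike_trough_uV < 0,
            spike_width_ms > 0, heater_rate_hz >= 0,
            heater_channel_fraction > 0, heater_channel_fraction <= 1,
            heater_afterwave_span_s > 0)
  if (heater_amplitude_uV >= -200) {
    stop("`heater_amplitude_uV` must be below -200", call. = FALSE)
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 noise_sd_uV = noise_sd_uV,
                 spike_trough_uV = spike_trough_uV,
                 spike_width_ms = spike_width_ms,
                 heater_rate_hz = heater_rate_hz,
                 heater_amplitude_uV = heater_amplitude_uV,
                 heater_channel_fraction = heater_channel_fraction,
                 heater_afterwave_span_s = heater_afterwave_span_s,
                 seed = as.integer(seed)),
            class = c("render_config", "mea_params"))
}

#' Render a spike table into a raw voltage recording
#'
#' @param spikes An [mea_spikes()] table (its spike-bearing channels define
#'   the rendered channels).
#' @param config A [render_config()].
#' @param channel_ids Channels to render; defaults to the spike-bearing
#'   channels of `spikes` (spike-free channels can be rendered by listing
#'   them here).
#' @return A list with `recording` (an [mea_recording()]) and `truth`
#'   (`spikes`: the rendered spike times/channels; `heater_events`: event
#'   times and the channel set of each event).
#' @export
render_raw <- function(spikes, config = render_config(), channel_ids = NULL) {
  stopifnot(is_mea_spikes(spikes), inherits(config, "render_config"))
  withr::with_seed(config$seed, render_raw_impl(spikes, config, channel_ids))
}

render_raw_impl <- function(spikes, config, channel_ids = NULL) {
  fs <- config$sampling_rate_hz
  T_s <- spike_duration(spikes)
  n_samp <- max(1L, as.integer(round(T_s * fs)))
  ch_ids <- channel_ids %||% sort(spike_channels(spikes))
  if (!length(ch_ids)) ch_ids <- "ch01"
  n_ch <- length(ch_ids)

  v <- matrix(stats::rnorm(n_ch * n_samp, 0, config$noise_sd_uV),
              nrow = n_ch)

  tpl <- spike_template(fs, config$spike_width_ms)
  for (ci in seq_len(n_ch)) {
    rows <- spikes[spikes$channel_id == ch_ids[ci], ]
    if (!nrow(rows)) next
    amp <- ifelse(is.na(rows$trough_uV), config$spike_trough_uV,
                  rows$trough_uV)
    for (k in seq_len(nrow(rows))) {
      v[ci, ] <- add_waveform(v[ci, ], tpl$shape * abs(amp[k]),
                              round(rows$time_s[k] * fs) + 1L - tpl$trough_at + 1L)
    }
  }

  n_he <- stats::rpois(1, config$heater_rate_hz * T_s)
  he_times <- sort(stats::runif(n_he, 0, T_s))
  he_channels <- vector("list", n_he)
  if (n_he > 0) {
    hw <- heater_waveform(fs, config$heater_amplitude_uV,
                          config$heater_afterwave_span_s)
    n_hit <- ceiling(config$heater_channel_fraction * n_ch)
    for (e in seq_len(n_he)) {
      hit <- sort(sample.int(n_ch, n_hit))
      he_channels[[e]] <- ch_ids[hit]
      at <- round(he_times[e] * fs) + 1L
      for (ci in hit) v[ci, ] <- add_waveform(v[ci, ], hw, at)
    }
  }

  rec <- mea_recording(v, sampling_rate_hz = fs, channel_ids = ch_ids,
                       device_id = device_id(spikes))
  list(recording = rec,
       truth = list(
         spikes = tibble::as_tibble(spikes),
         heater_events = tibble::tibble(
           event_id = seq_len(n_he), time_s = he_times,
           channels = he_channels
         )
       ))
}

# Biphasic extracellular template: sharp negative trough with a shallow
# positive overshoot; normalized so min(shape) == -1 at index `trough_at`.
spike_template <- function(fs, width_ms) {
  width_s <- width_ms / 1000
  tt <- seq(0, width_s, by = 1 / fs)
  s1 <- width_s / 6
  t0 <- 2.2 * s1
  shape <- -exp(-((tt - t0)^2) / (2 * s1^2)) +
    0.35 * exp(-((tt - t0 - 2.4 * s1)^2) / (2 * (1.8 * s1)^2))
  shape <- shape / abs(min(shape))
  list(shape = shape, trough_at = which.min(shape))
}

# Main deflection plus damped-oscillation afterwaves over `span_s`; the
# oscillation's later negative lobes stay large enough to cross spike
# detection thresholds, mimicking the "subsequent waves" of real heater
# events.
heater_waveform <- function(fs, amplitude_uV, span_s) {
  tt <- seq(0, span_s, by = 1 / fs)
  tau <- span_s / 3
  w <- amplitude_uV * exp(-tt / tau) * cos(2 * pi * tt / (span_s / 2.5))
  w
}

# Add `wave` into `trace` starting at sample index `at` (may be off the ends).
add_waveform <- function(trace, wave, at) {
  i1 <- max(1L, at)
  i2 <- min(length(trace), at + length(wave) - 1L)
  if (i1 > i2) return(trace)
  trace[i1:i2] <- trace[i1:i2] + wave[(i1 - at + 1L):(i2 - at + 1L)]
  trace
}

#' Simulate a baseline / drug-challenge recording pair
#'
#' Models a disinhibition-type challenge (e.g. a GABA-A antagonist) as
#' parameter modulation: the challenged epoch is regenerated with the
#' network-burst rate multiplied by `burst_rate_multiplier` and the
#' participation probability shifted by `participation_delta`, on the same
#' channel layout. Seeds for the two epochs are derived deterministically
#' from `config$seed`, so the pair is reproducible and baseline/challenge are
#' statistically independent draws.
#'
#' @param config A [sim_config()] describing the baseline epoch.
#' @param burst_rate_multiplier Positive factor on the network-burst rate.
#' @param participation_delta Additive shift of the participation probability.
#' @param device Device label (shared by both epochs).
#' @return A list with `baseline`, `challenged` (both [mea_spikes()]) and
#'   `truth` (the two generators' ground truths plus the modulation applied).
#' @export
simulate_challenge_pair <- function(config, burst_rate_multiplier = 3,
                                    participation_delta = 0,
                                    device = "sim") {
  stopifnot(inherits(config, "sim_config"), burst_rate_multiplier > 0)
  p2 <- config$participation_prob + participation_delta
  if (p2 < 0 || p2 > 1) {
    stop("`participation_prob + participation_delta` must be in [0, 1]",
         call. = FALSE)
  }
  cfg_base <- config
  cfg_base$seed <- derive_seed(config$seed, "baseline")
  cfg_chal <- config
  cfg_chal$network_burst_rate_hz <-
    config$network_burst_rate_hz * burst_rate_multiplier
  cfg_chal$participation_prob <- p2
  cfg_chal$seed <- derive_seed(config$seed, "challenge")
  base <- simulate_spike_trains(cfg_base, device = device)
  chal <- simulate_spike_trains(cfg_chal, device = device)
  list(baseline = base$spikes, challenged = chal$spikes,
       truth = list(baseline = base$truth, challenged = chal$truth,
                    burst_rate_multiplier = burst_rate_multiplier,
                    participation_delta = participation_delta))
}

#' Inject heater-artifact spikes into a spike table
#'
#' Spike-table-level counterpart of the raw-level heater artifacts: at each
#' event time, a sub--200 uV "spike" is added on a random subset of channels
#' (fraction `channel_fraction` of the device's spike-bearing channels), and
#' each affected channel additionally gains `n_afterwave` ordinary-amplitude
#' spurious spikes within `afterwave_span_s` after the event — the detections
#' the trailing afterwaves would produce. Useful for exercising artifact
#' detection and purging without rendering raw voltage.
#'
#' @param spikes An [mea_spikes()] table.
#' @param event_times Numeric vector of artifact times (s).
#' @param channel_fraction Fraction of spike-bearing channels hit per event.
#' @param amplitude_uV Trough of the injected artifact spikes (< -200).
#' @param n_afterwave Spurious afterwave spikes per affected channel.
#' @param afterwave_span_s Afterwave spikes fall in
#'   `(event, event + afterwave_span_s]`.
#' @param seed Seed for channel choice and afterwave placement.
#' @return A list with `spikes` (contaminated table) and `truth` (logical
#'   vector marking the artifact-derived rows of the returned table, plus the
#'   event times and channels).
#' @export
inject_heater_artifacts <- function(spikes, event_times,
                                    channel_fraction = 0.85,
                                    amplitude_uV = -320,
                                    n_afterwave = 2L,
                                    afterwave_span_s = 0.006,
                                    seed = 1L) {
  stopifnot(is_mea_spikes(spikes), all(event_times >= 0),
            all(event_times <= spike_duration(spikes)), amplitude_uV < -200)
  ch_ids <- sort(spike_channels(spikes))
  n_hit <- ceiling(channel_fraction * length(ch_ids))
  withr::with_seed(seed, {
    rows <- list()
    hit_sets <- list()
    for (e in seq_along(event_times)) {
      hit <- sort(sample(ch_ids, n_hit))
      hit_sets[[e]] <- hit
      t_e <- event_times[e]
      for (ch in hit) {
        after <- t_e + sort(stats::runif(n_afterwave, 1e-4, afterwave_span_s))
        rows[[length(rows) + 1]] <- tibble::tibble(
          channel_id = ch,
          time_s = c(t_e, after),
          trough_uV = c(amplitude_uV,
                        stats::rnorm(n_afterwave, -45, 5))
        )
      }
    }
  })
  extra <- dplyr::bind_rows(rows)
  extra <- extra[extra$time_s <= spike_duration(spikes), ]
  combined <- dplyr::bind_rows(
    tibble::as_tibble(spikes)[c("channel_id", "time_s", "trough_uV")],
    extra
  )
  is_artifact <- c(rep(FALSE, n_spikes(spikes)), rep(TRUE, nrow(extra)))
  dup <- duplicated(combined[c("channel_id", "time_s")])
  combined <- combined[!dup, ]
  is_artifact <- is_artifact[!dup]
  o <- order(combined$channel_id, combined$time_s)
  out <- mea_spikes(combined[o, ], device_id = device_id(spikes),
                    duration_s = spike_duration(spikes),
                    n_device_channels = n_device_channels(spikes))
  list(spikes = out,
       truth = list(is_artifact = is_artifact[o],
                    event_times = event_times,
                    channels = hit_sets))
}
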
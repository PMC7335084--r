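#' Estimate the noise SD of a single voltage trace
#'
#' Raw extracellular traces are noise plus spikes, so a plain sample SD is
#' biased upward by the spikes themselves. The default estimator is the
#' median absolute deviation scaled to the Gaussian SD,
#' `median(|v - median(v)|) / 0.6745`, the field-standard spike-robust noise
#' estimate; `"global_sd"` is the plain sample SD, kept for sensitivity
#' analysis.
#'
#' @param trace Numeric vector of voltage samples (microvolts), at least
#'   1000 samples.
#' @param params A [detection_params()] (only `noise_estimator` is used), or
#'   an estimator name.
#' @return The estimated noise SD in microvolts (positive scalar).
#' @examples
#' estimate_noise_sd(rnorm(5000, sd = 5))
#' @export
estimate_noise_sd <- function(trace, params = detection_params()) {
  if (is.character(params)) params <- detection_params(noise_estimator = params)
  if (length(trace) < 1000) {
    stop("need at least 1000 samples to estimate the noise SD", call. = FALSE)
  }
  sigma <- switch(params$noise_estimator,
                  mad = stats::mad(trace, constant = 1 / 0.6745),
                  global_sd = stats::sd(trace))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate signal: noise SD is zero (constant trace?)",
         call. = FALSE)
  }
  sigma
}

#' Detect spikes by negative noise-scaled thresholding
#'
#' Per channel, the threshold is `-threshold_multiplier` times the channel's
#' estimated noise SD (default -4.5 sigma). Each excursion of the trace below
#' threshold yields one spike at the time of its local minimum (the trough),
#' with the trough voltage as amplitude; troughs closer than `dead_time_s` to
#' the previously accepted trough are merged, keeping the deeper one.
#' Positive excursions are ignored. Spike time = trough time: unambiguous and
#' stable under jitter, unlike the threshold-crossing time.
#'
#' Because the threshold scales with the noise estimate, detection is
#' equivariant under rescaling of the trace: multiplying a channel by `k > 0`
#' leaves the detected spike times unchanged.
#'
#' @param recording An [mea_recording()].
#' @param params A [detection_params()]. If `params$bandpass` is set, a
#'   zero-phase Butterworth band-pass is applied before detection (requires
#'   the `signal` package).
#' @param n_device_channels Total electrodes on the device for the output
#'   spike table; defaults to the number of recorded channels.
#' @return An [mea_spikes()] table with one row per detected spike. The
#'   per-channel noise SDs are attached as attribute `"noise_sd_uV"` (named
#'   numeric vector).
#' @export
detect_spikes <- function(recording, params = detection_params(),
                          n_device_channels = NULL) {
  stopifnot(is_mea_recording(recording),
            inherits(params, "detection_params"))
  fs <- recording$sampling_rate_hz
  if (params$dead_time_s > 0 && params$dead_time_s * fs < 2) {
    stop("sampling rate too low: `dead_time_s` spans fewer than 2 samples",
         call. = FALSE)
  }
  n_device_channels <- n_device_channels %||% nrow(recording$samples)

  rows <- vector("list", nrow(recording$samples))
  sig <- stats::setNames(numeric(nrow(recording$samples)),
                         recording$channel_ids)
  for (ci in seq_len(nrow(recording$samples))) {
    v <- recording$samples[ci, ]
    if (!is.null(params$bandpass)) v <- apply_bandpass(v, fs, params$bandpass)
    sigma <- estimate_noise_sd(v, params)
    sig[ci] <- sigma
    det <- detect_channel(v, fs, -params$threshold_multiplier * sigma,
                          params$dead_time_s)
    rows[[ci]] <- tibble::tibble(channel_id = recording$channel_ids[ci],
                                 time_s = det$time_s + recording$t0_s,
                                 trough_uV = det$trough_uV)
  }
  out <- mea_spikes(dplyr::bind_rows(rows),
                    device_id = recording$device_id,
                    duration_s = recording_duration(recording),
                    n_device_channels = n_device_channels)
  attr(out, "noise_sd_uV") <- sig
  out
}

# One channel: excursions below `threshold`, trough per excursion, dead-time
# merge keeping the deeper trough.
detect_channel <- function(v, fs, threshold, dead_time_s) {
  below <- v < threshold
  empty <- list(time_s = double(), trough_uV = double())
  if (!any(below)) return(empty)
  d <- diff(c(FALSE, below, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  idx <- integer(length(starts))
  for (k in seq_along(starts)) {
    seg <- starts[k]:ends[k]
    idx[k] <- seg[which.min(v[seg])]
  }
  tt <- (idx - 1L) / fs
  amp <- v[idx]
  # sequential merge: a trough within dead_time of the last accepted trough
  # replaces it if deeper, otherwise is dropped
  keep_t <- double(length(tt))
  keep_a <- double(length(tt))
  m <- 0L
  for (k in seq_along(tt)) {
    if (m > 0L && tt[k] - keep_t[m] <= dead_time_s) {
      if (amp[k] < keep_a[m]) {
        keep_t[m] <- tt[k]
        keep_a[m] <- amp[k]
      }
    } else {
      m <- m + 1L
      keep_t[m] <- tt[k]
      keep_a[m] <- amp[k]
    }
  }
  list(time_s = keep_t[seq_len(m)], trough_uV = keep_a[seq_len(m)])
}

apply_bandpass <- function(v, fs, bandpass) {
  if (!requireNamespace("signal", quietly = TRUE)) {
    stop("band-pass filtering needs the `signal` package", call. = FALSE)
  }
  ny <- fs / 2
  if (bandpass$high_hz >= ny) {
    stop("band-pass `high_hz` must be below the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(bandpass$order, c(bandpass$low_hz, bandpass$high_hz) / ny,
                       type = "pass")
  as.numeric(signal::filtfilt(bf, v))
}
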
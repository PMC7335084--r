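#' Analysis parameter blocks
#'
#' Constructors for the parameter blocks of the pipeline, each validated on
#' construction. The defaults are the published analysis settings:
#' spikes at -4.5 x the per-channel noise SD; heater artifacts as sub -200 uV
#' troughs hitting at least 80% of the device's channels inside a 1 ms window,
#' with a 6 ms purge around each event; channels with fewer than 10 spikes
#' dropped; bursts by the five-parameter maximum-interval rule (begin ISI
#' <= 0.1 s, end ISI <= 0.2 s, inter-burst interval >= 0.5 s, duration
#' >= 0.05 s, >= 6 spikes); synchrony normalized against 1000 random
#' surrogates on a 600 s timeline.
#'
#' @param threshold_multiplier Positive multiple of the noise SD; the
#'   detection threshold is `-threshold_multiplier * sigma` (negative
#'   excursions only).
#' @param dead_time_s Minimum separation between accepted troughs; closer
#'   troughs are merged keeping the deeper one. Guards against double-counting
#'   multiphasic waveforms.
#' @param noise_estimator `"mad"` (median absolute deviation scaled to the
#'   Gaussian SD, robust to spikes riding on the noise) or `"global_sd"`
#'   (plain sample SD, biased upward by spikes; kept for sensitivity
#'   analysis).
#' @param bandpass `NULL`, or `list(low_hz=, high_hz=, order=)` for an
#'   optional zero-phase Butterworth band-pass before detection. Recordings
#'   band-passed at acquisition need none.
#' @return A validated parameter list of class `mea_params`.
#' @name parameters
NULL

#' @rdname parameters
#' @export
detection_params <- function(threshold_multiplier = 4.5, dead_time_s = 0.001,
                             noise_estimator = c("mad", "global_sd"),
                             bandpass = NULL) {
  noise_estimator <- match.arg(noise_estimator)
  stopifnot(threshold_multiplier > 0, dead_time_s >= 0)
  if (!is.null(bandpass)) {
    stopifnot(is.list(bandpass),
              all(c("low_hz", "high_hz") %in% names(bandpass)),
              bandpass$low_hz > 0, bandpass$high_hz > bandpass$low_hz)
    bandpass$order <- bandpass$order %||% 2L
  }
  structure(list(threshold_multiplier = threshold_multiplier,
                 dead_time_s = dead_time_s,
                 noise_estimator = noise_estimator,
                 bandpass = bandpass),
            class = c("detection_params", "mea_params"))
}

#' @rdname parameters
#' @param window_s Width of the sliding coincidence window (s).
#' @param amplitude_uV Candidate spikes must have troughs strictly below this
#'   voltage (microvolts, negative).
#' @param channel_fraction Minimum fraction of channels that must carry a
#'   candidate inside one window ("at least", boundary inclusive).
#' @param purge_s Half-width of the symmetric purge window around each heater
#'   event; every spike within it (inclusive) is removed.
#' @param fraction_denominator What "all channels" means: every recordable
#'   electrode on the device (`"all_device_channels"`, the literal device-wide
#'   reading, default) or only channels carrying at least one spike
#'   (`"channels_with_spikes"`).
#' @export
artifact_params <- function(window_s = 0.001, amplitude_uV = -200,
                            channel_fraction = 0.80, purge_s = 0.006,
                            fraction_denominator = c("all_device_channels",
                                                     "channels_with_spikes")) {
  fraction_denominator <- match.arg(fraction_denominator)
  stopifnot(window_s > 0, amplitude_uV < 0,
            channel_fraction > 0, channel_fraction <= 1,
            purge_s >= window_s)
  structure(list(window_s = window_s, amplitude_uV = amplitude_uV,
                 channel_fraction = channel_fraction, purge_s = purge_s,
                 fraction_denominator = fraction_denominator),
            class = c("artifact_params", "mea_params"))
}

#' @rdname parameters
#' @param max_begin_isi_s Maximum ISI that can open a burst.
#' @param max_end_isi_s Maximum ISI that can extend a burst.
#' @param min_ibi_s Candidate bursts separated by less than this are merged.
#' @param min_duration_s Minimum burst duration (last minus first spike).
#' @param min_spikes Minimum spikes per burst.
#' @export
burst_params <- function(max_begin_isi_s = 0.1, max_end_isi_s = 0.2,
                         min_ibi_s = 0.5, min_duration_s = 0.05,
                         min_spikes = 6L) {
  stopifnot(max_begin_isi_s > 0, max_end_isi_s > 0, min_ibi_s > 0,
            min_duration_s > 0, min_spikes >= 1)
  if (max_begin_isi_s > max_end_isi_s) {
    stop("`max_begin_isi_s` must not exceed `max_end_isi_s`", call. = FALSE)
  }
  structure(list(max_begin_isi_s = max_begin_isi_s,
                 max_end_isi_s = max_end_isi_s,
                 min_ibi_s = min_ibi_s,
                 min_duration_s = min_duration_s,
                 min_spikes = as.integer(min_spikes)),
            class = c("burst_params", "mea_params"))
}

#' @rdname parameters
#' @param n_random Number of Monte-Carlo surrogate pairs for the null.
#' @param timeline_s Timeline on which both the observed distance and the
#'   uniform surrogates are evaluated (600 s = the 10-minute epoch,
#'   independent of the actual recording length unless overridden).
#' @param convention Normalization arithmetic: `"ratio_of_means"`
#'   (`1 - D_obs / mean(D_rand)`; chance ~ 0, identity = 1, default),
#'   `"mean_of_ratios"` (`1 - mean(D_obs / D_rand)`), or `"unnormalized"`
#'   (`1 - D_obs`).
#' @param clip Clip synchrony values into `[0, 1]`? Default `FALSE`: slightly
#'   negative values (trains farther apart than the random null) are
#'   information worth keeping.
#' @export
synchrony_params <- function(n_random = 1000L, timeline_s = 600,
                             convention = c("ratio_of_means", "mean_of_ratios",
                                            "unnormalized"),
                             clip = FALSE) {
  convention <- match.arg(convention)
  stopifnot(n_random >= 1, timeline_s > 0)
  structure(list(n_random = as.integer(n_random), timeline_s = timeline_s,
                 convention = convention, clip = isTRUE(clip)),
            class = c("synchrony_params", "mea_params"))
}

#' @export
print.mea_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Full analysis configuration
#'
#' Bundles all stage parameters, the channel QC threshold and the master seed
#' into one object that serializes losslessly to YAML, so a whole run is
#' reproducible from a single config file.
#'
#' @param detection,artifacts,bursts,synchrony Stage parameter blocks; see
#'   [parameters].
#' @param qc_min_spikes Channels with fewer spikes than this (after artifact
#'   purge) are dropped; such channels are not "active electrodes".
#' @param seed Master seed; per-stage seeds are derived from it (see
#'   [derive_seed()]).
#' @return An `analysis_config` object.
#' @seealso [read_config()], [write_config()]
#' @export
analysis_config <- function(detection = detection_params(),
                            artifacts = artifact_params(),
                            bursts = burst_params(),
                            synchrony = synchrony_params(),
                            qc_min_spikes = 10L, seed = 1L) {
  stopifnot(inherits(detection, "detection_params"),
            inherits(artifacts, "artifact_params"),
            inherits(bursts, "burst_params"),
            inherits(synchrony, "synchrony_params"),
            qc_min_spikes >= 0)
  structure(list(detection = detection, artifacts = artifacts,
                 bursts = bursts, synchrony = synchrony,
                 qc_min_spikes = as.integer(qc_min_spikes),
                 seed = as.integer(seed)),
            class = c("analysis_config", "mea_params"))
}

#' Write / read an analysis configuration as YAML
#'
#' The YAML file mirrors [analysis_config()] field for field; reading a
#' written file reproduces the configuration exactly.
#'
#' @param config An `analysis_config`.
#' @param path File path.
#' @return `read_config()` returns an `analysis_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- lapply(unclass(config), function(el) {
    if (inherits(el, "mea_params")) unclass(el) else el
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("detection", "artifacts", "bursts", "synchrony")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("config file is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  analysis_config(
    detection = do.call(detection_params, x$detection),
    artifacts = do.call(artifact_params, x$artifacts),
    bursts = do.call(burst_params, x$bursts),
    synchrony = do.call(synchrony_params, x$synchrony),
    qc_min_spikes = x$qc_min_spikes %||% 10L,
    seed = x$seed %||% 1L
  )
}

#' Derive a stage seed from the master seed
#'
#' One master seed fans out to independent, reproducible per-stage seeds by
#' hashing the stage name into an offset, so any stage can be re-run on its
#' own with the same random stream it had inside the full pipeline.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name, e.g. `"simulate"`, `"synchrony"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 1000003
  as.integer((as.double(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}
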
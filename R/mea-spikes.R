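#' Spike table: the pipeline's central object
#'
#' An `mea_spikes` object is a tibble with one row per detected (or simulated)
#' spike and columns `channel_id` (character), `time_s` (seconds from epoch
#' start) and `trough_uV` (trough voltage, microvolts, negative for
#' extracellular spikes). Three attributes travel with it:
#'
#' * `device_id` — identifier of the MEA device,
#' * `duration_s` — length of the recording epoch (default 600 s, i.e. the
#'   10-minute epochs used for baseline and challenge recordings),
#' * `n_device_channels` — total recordable electrodes on the device
#'   (default 60). Grounded or broken electrodes make the number of
#'   spike-bearing channels smaller, so this is stored explicitly; it is the
#'   denominator for "% active electrodes" and for the device-wide artifact
#'   rule.
#'
#' Rows are kept sorted by channel then time; times are strictly increasing
#' within a channel.
#'
#' @param x A data frame with columns `channel_id`, `time_s` and (optionally)
#'   `trough_uV`. A missing `trough_uV` column is filled with `NA`.
#' @param device_id Device identifier.
#' @param duration_s Recording duration in seconds.
#' @param n_device_channels Total electrodes on the device.
#' @return An `mea_spikes` tibble.
#' @examples
#' sp <- mea_spikes(
#'   data.frame(channel_id = "ch01", time_s = c(0.2, 0.5), trough_uV = -40),
#'   device_id = "dev1", duration_s = 10
#' )
#' n_spikes(sp)
#' @export
mea_spikes <- function(x, device_id = "device", duration_s = 600,
                       n_device_channels = 60L) {
  x <- tibble::as_tibble(x)
  if (!all(c("channel_id", "time_s") %in% names(x))) {
    stop("spike table needs columns `channel_id` and `time_s`", call. = FALSE)
  }
  if (!"trough_uV" %in% names(x)) x$trough_uV <- NA_real_
  x <- dplyr::select(x, "channel_id", "time_s", "trough_uV")
  x$channel_id <- as.character(x$channel_id)
  x$time_s <- as.double(x$time_s)
  x$trough_uV <- as.double(x$trough_uV)
  x <- dplyr::arrange(x, .data$channel_id, .data$time_s)
  out <- new_mea_spikes(x, device_id = device_id, duration_s = duration_s,
                        n_device_channels = n_device_channels)
  validate_mea_spikes(out)
}

new_mea_spikes <- function(x, device_id, duration_s, n_device_channels) {
  structure(
    x,
    device_id = as.character(device_id),
    duration_s = as.double(duration_s),
    n_device_channels = as.integer(n_device_channels),
    class = c("mea_spikes", class(tibble::tibble()))
  )
}

validate_mea_spikes <- function(x) {
  dur <- spike_duration(x)
  if (!is.finite(dur) || dur <= 0) {
    stop("`duration_s` must be a positive number", call. = FALSE)
  }
  if (anyNA(x$time_s) || any(x$time_s < 0) || any(x$time_s > dur)) {
    stop("spike times must lie in [0, duration_s]", call. = FALSE)
  }
  dup <- duplicated(x[c("channel_id", "time_s")])
  if (any(dup)) {
    stop("duplicate (channel, time) spikes at e.g. t = ",
         format(x$time_s[which(dup)[1]]), " s", call. = FALSE)
  }
  nch <- dplyr::n_distinct(x$channel_id)
  if (attr(x, "n_device_channels") < nch) {
    stop("`n_device_channels` (", attr(x, "n_device_channels"),
         ") is smaller than the number of spike-bearing channels (", nch, ")",
         call. = FALSE)
  }
  x
}

#' @rdname mea_spikes
#' @export
is_mea_spikes <- function(x) inherits(x, "mea_spikes")

# Re-attach spike-table metadata after dplyr verbs (which strip attributes).
restore_spike_attrs <- function(x, template) {
  new_mea_spikes(tibble::as_tibble(x),
                 device_id = attr(template, "device_id"),
                 duration_s = attr(template, "duration_s"),
                 n_device_channels = attr(template, "n_device_channels"))
}

#' Spike-table metadata accessors
#'
#' @param x An `mea_spikes` object.
#' @return `spike_duration()` the epoch length in seconds, `device_id()` the
#'   device label, `n_device_channels()` the total electrode count,
#'   `n_spikes()` the number of spikes, `spike_channels()` the ids of
#'   spike-bearing channels, and `spike_times()` the sorted spike times of one
#'   channel as a numeric vector.
#' @export
spike_duration <- function(x) attr(x, "duration_s")

#' @rdname spike_duration
#' @export
device_id <- function(x) attr(x, "device_id")

#' @rdname spike_duration
#' @export
n_device_channels <- function(x) attr(x, "n_device_channels")

#' @rdname spike_duration
#' @export
n_spikes <- function(x) nrow(x)

#' @rdname spike_duration
#' @export
spike_channels <- function(x) unique(x$channel_id)

#' @rdname spike_duration
#' @param channel A channel id.
#' @export
spike_times <- function(x, channel) {
  sort(x$time_s[x$channel_id == channel])
}

#' @export
print.mea_spikes <- function(x, ...) {
  cat(sprintf(
    "<mea_spikes> device %s: %d spikes on %d/%d channels over %.6g s\n",
    device_id(x), nrow(x), dplyr::n_distinct(x$channel_id),
    n_device_channels(x), spike_duration(x)
  ))
  NextMethod()
}

#' Raw multichannel voltage recording
#'
#' Container for a raw extracellular recording: a channels-by-samples voltage
#' matrix in microvolts plus the sampling rate and channel identities. All
#' channels share one sample clock. The acquisition convention is 22.3 kHz
#' sampling, band-passed 268-8036 Hz, 10-minute epochs; the simulator defaults
#' to 5 kHz for desk-scale work since the detection logic is rate-agnostic.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`, microvolts.
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param channel_ids Character vector of channel labels (default `"ch01"`...).
#' @param device_id Device identifier.
#' @param t0_s Epoch start time in seconds (times are reported relative to it).
#' @return An `mea_recording` object.
#' @examples
#' rec <- mea_recording(matrix(rnorm(2000), nrow = 2), sampling_rate_hz = 1000)
#' rec
#' @export
mea_recording <- function(samples, sampling_rate_hz = 22300,
                          channel_ids = NULL, device_id = "device",
                          t0_s = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1 || ncol(samples) < 1) {
    stop("`samples` must have at least one channel and one sample",
         call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` contains non-finite voltages", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number", call. = FALSE)
  }
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  if (length(channel_ids) != nrow(samples)) {
    stop("`channel_ids` length must equal the number of rows of `samples`",
         call. = FALSE)
  }
  structure(
    list(device_id = as.character(device_id),
         channel_ids = as.character(channel_ids),
         samples = samples,
         sampling_rate_hz = as.double(sampling_rate_hz),
         t0_s = as.double(t0_s)),
    class = "mea_recording"
  )
}

#' @rdname mea_recording
#' @param x An object.
#' @export
is_mea_recording <- function(x) inherits(x, "mea_recording")

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> device %s: %d channels x %d samples @ %.4g kHz (%.6g s)\n",
    x$device_id, nrow(x$samples), ncol(x$samples),
    x$sampling_rate_hz / 1000, ncol(x$samples) / x$sampling_rate_hz
  ))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate_hz
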
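#' Detect device-wide heater artifacts in a spike table
#'
#' The stage heater of a recording rig produces near-simultaneous large
#' negative deflections on most electrodes at once — unmistakably non-neural.
#' The rule: among detected spikes, candidates are those with troughs
#' strictly below `amplitude_uV` (default -200 uV); sliding a window of
#' `window_s` (default 1 ms) over the candidate times, any window in which at
#' least `channel_fraction` (default 80%, boundary inclusive) of the
#' channels carry a candidate marks one heater event, timed at the earliest
#' candidate in the window. Overlapping qualifying windows coalesce into a
#' single event, so one physical artifact is never counted twice.
#'
#' The window is anchored at candidate spikes rather than stepped sample by
#' sample — equivalent coverage at a fraction of the cost. The denominator
#' for the channel fraction is, by default, every recordable electrode on the
#' device (`n_device_channels`); set
#' `fraction_denominator = "channels_with_spikes"` to count only
#' spike-bearing channels.
#'
#' @param spikes An [mea_spikes()] table with trough amplitudes.
#' @param params An [artifact_params()].
#' @return A tibble of class `heater_events` with one row per event:
#'   `time_s`, `n_channels` (distinct channels in the qualifying window) and
#'   `channels` (list column of their ids).
#' @export
detect_heater_events <- function(spikes, params = artifact_params()) {
  stopifnot(is_mea_spikes(spikes), inherits(params, "artifact_params"))
  denom <- switch(params$fraction_denominator,
                  all_device_channels = n_device_channels(spikes),
                  channels_with_spikes = length(spike_channels(spikes)))
  if (is.na(denom) || denom < 1) {
    stop("`n_device_channels` must be set when `fraction_denominator` is ",
         "\"all_device_channels\"", call. = FALSE)
  }
  need <- ceiling(params$channel_fraction * denom)

  cand <- spikes[!is.na(spikes$trough_uV) &
                   spikes$trough_uV < params$amplitude_uV, ]
  out <- tibble::tibble(time_s = double(), n_channels = integer(),
                        channels = list())
  if (nrow(cand)) {
    o <- order(cand$time_s)
    ct <- cand$time_s[o]
    cc <- cand$channel_id[o]
    n <- length(ct)
    k <- 1L
    while (k <= n) {
      in_win <- which(ct >= ct[k] & ct <= ct[k] + params$window_s)
      chs <- unique(cc[in_win])
      if (length(chs) >= need) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          time_s = ct[k], n_channels = length(chs), channels = list(sort(chs))
        ))
        # later anchors inside this window would overlap it: coalesce
        k <- in_win[length(in_win)] + 1L
      } else {
        k <- k + 1L
      }
    }
  }
  class(out) <- c("heater_events", class(out))
  out
}

#' Purge spikes around heater events
#'
#' Removes, on every channel, every spike within `purge_s` (default 6 ms,
#' inclusive, symmetric) of any heater event — the events themselves plus the
#' spurious detections of their trailing afterwaves.
#'
#' @param spikes An [mea_spikes()] table.
#' @param events A `heater_events` tibble from [detect_heater_events()].
#' @param params An [artifact_params()].
#' @return The cleaned [mea_spikes()] table; the number of spikes removed is
#'   attached as attribute `"n_purged"`.
#' @export
purge_heater_spikes <- function(spikes, events, params = artifact_params()) {
  stopifnot(is_mea_spikes(spikes), inherits(params, "artifact_params"))
  if (!nrow(events)) {
    attr(spikes, "n_purged") <- 0L
    return(spikes)
  }
  et <- sort(events$time_s)
  # distance from each spike to the nearest event
  i <- findInterval(spikes$time_s, et)
  d_lo <- ifelse(i >= 1, spikes$time_s - et[pmax(i, 1L)], Inf)
  d_hi <- ifelse(i < length(et), et[pmin(i + 1L, length(et))] - spikes$time_s,
                 Inf)
  # inclusive boundary, with a 1 ns guard so decimal timestamps exactly
  # purge_s away are not saved by floating-point representation
  near <- pmin(d_lo, d_hi) <= params$purge_s + 1e-9
  out <- restore_spike_attrs(tibble::as_tibble(spikes)[!near, ], spikes)
  attr(out, "n_purged") <- sum(near)
  out
}

#' Drop channels with too few spikes
#'
#' Applied after heater-spike removal: channels with fewer than `min_spikes`
#' spikes (default 10) are dropped from analysis. The surviving channels are
#' the device's *active electrodes*.
#'
#' @param spikes An [mea_spikes()] table (already artifact-purged).
#' @param min_spikes Minimum spike count to keep a channel.
#' @return A list with `spikes` (filtered table) and `active` (tibble with
#'   one row per spike-bearing input channel: `channel_id`, `n_spikes`,
#'   `active`).
#' @export
filter_low_count_channels <- function(spikes, min_spikes = 10L) {
  stopifnot(is_mea_spikes(spikes), min_spikes >= 0)
  counts <- dplyr::count(tibble::as_tibble(spikes), .data$channel_id,
                         name = "n_spikes")
  counts$active <- counts$n_spikes >= min_spikes
  keep <- counts$channel_id[counts$active]
  out <- restore_spike_attrs(
    tibble::as_tibble(spikes)[spikes$channel_id %in% keep, ], spikes
  )
  list(spikes = out, active = tibble::as_tibble(counts))
}

#' Percentage of active electrodes
#'
#' @param active The `active` tibble from [filter_low_count_channels()] (or a
#'   logical vector).
#' @param n_device_channels Total recordable electrodes on the device.
#' @return `100 * n_active / n_device_channels`.
#' @examples
#' percent_active(c(TRUE, TRUE, FALSE), n_device_channels = 60)
#' @export
percent_active <- function(active, n_device_channels) {
  if (is.data.frame(active)) active <- active$active
  if (is.na(n_device_channels) || n_device_channels <= 0) {
    stop("`n_device_channels` must be positive", call. = FALSE)
  }
  100 * sum(active) / n_device_channels
}

#' Run the full cleaning sequence
#'
#' Fixed order, matching the published procedure: detect heater events, purge
#' spikes around them, then drop low-count channels.
#'
#' @param spikes An [mea_spikes()] table.
#' @param params An [artifact_params()].
#' @param min_spikes Channel QC threshold.
#' @return A list with `spikes` (cleaned), `events`, `active`, and a `qc`
#'   summary (events found, spikes removed, channels dropped, percent active).
#' @export
clean_spikes <- function(spikes, params = artifact_params(),
                         min_spikes = 10L) {
  events <- detect_heater_events(spikes, params)
  purged <- purge_heater_spikes(spikes, events, params)
  filt <- filter_low_count_channels(purged, min_spikes)
  list(
    spikes = filt$spikes,
    events = events,
    active = filt$active,
    qc = tibble::tibble(
      n_heater_events = nrow(events),
      n_spikes_in = n_spikes(spikes),
      n_spikes_purged = attr(purged, "n_purged"),
      n_spikes_out = n_spikes(filt$spikes),
      n_channels_dropped = sum(!filt$active$active),
      percent_active = percent_active(filt$active,
                                      n_device_channels(spikes))
    )
  )
}
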
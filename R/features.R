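feature_cols <- c("firing_rate_hz", "n_bursts", "bursts_per_min",
                  "mean_burst_duration_s", "mean_intra_burst_isi_s",
                  "pct_spikes_in_bursts", "pct_spikes_outside_bursts")

#' Per-channel firing and bursting features
#'
#' For each spike-bearing channel: overall firing rate (spikes / duration),
#' burst count and rate, mean burst duration, mean intra-burst ISI (each
#' burst's mean ISI, averaged across bursts), and the complementary percent
#' of spikes inside / outside bursts. On a channel with no bursts the
#' burst-derived features are missing (`NA`, not zero — inactivity is not the
#' same as short bursts) while `pct_spikes_in_bursts` is 0.
#'
#' @param spikes An [mea_spikes()] table (typically the cleaned, QC-filtered
#'   output of [clean_spikes()]).
#' @param bursts Burst tibble from [detect_bursts()] on the same table.
#' @param duration_s Recording duration; defaults to the spike table's.
#' @return A tibble with one row per channel: `channel_id`, `n_spikes` and
#'   the feature columns.
#' @export
channel_features <- function(spikes, bursts = detect_bursts(spikes),
                             duration_s = NULL) {
  stopifnot(is_mea_spikes(spikes))
  duration_s <- duration_s %||% spike_duration(spikes)
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  chans <- sort(spike_channels(spikes))
  rows <- lapply(chans, function(ch) {
    tt <- spike_times(spikes, ch)
    bb <- bursts[bursts$channel_id == ch, , drop = FALSE]
    nb <- nrow(bb)
    in_burst <- 0L
    if (nb) in_burst <- sum(bb$n_spikes)
    pct_in <- if (length(tt)) 100 * in_burst / length(tt) else NA_real_
    tibble::tibble(
      channel_id = ch,
      n_spikes = length(tt),
      firing_rate_hz = length(tt) / duration_s,
      n_bursts = nb,
      bursts_per_min = nb / (duration_s / 60),
      mean_burst_duration_s = if (nb) mean(bb$end_s - bb$start_s) else NA_real_,
      # burst spikes are consecutive, so a burst's mean ISI is its
      # duration over (n_spikes - 1)
      mean_intra_burst_isi_s =
        if (nb) mean((bb$end_s - bb$start_s) / (bb$n_spikes - 1L))
        else NA_real_,
      pct_spikes_in_bursts = pct_in,
      pct_spikes_outside_bursts = if (is.na(pct_in)) NA_real_ else 100 - pct_in
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(channel_id = character(), n_spikes = integer(),
                          !!!stats::setNames(rep(list(double()),
                                                 length(feature_cols)),
                                             feature_cols))
  }
  out
}

#' Device-level feature table
#'
#' Builds the tidy per-device feature table: one row per channel plus one
#' device-mean row. Device means are arithmetic means over channels with a
#' defined value only — a channel with no bursts contributes its firing rate
#' but not a burst duration. The device row also carries
#' `percent_active_electrodes`.
#'
#' @param channel_feats Output of [channel_features()] (on active channels).
#' @param active The `active` tibble from [filter_low_count_channels()], or a
#'   percent-active value; `NULL` derives percent-active from the number of
#'   channels in `channel_feats`.
#' @param n_device_channels Total recordable electrodes.
#' @param device Device label.
#' @param burst_parameters The [burst_params()] the features were computed
#'   under; carried as an attribute so fold-change comparison can refuse
#'   mismatched configurations.
#' @return A `device_features` tibble with columns `device_id`, `level`
#'   (`"channel"` / `"device"`), `channel_id` (empty on the device row),
#'   `percent_active_electrodes` (device row only) and the feature columns.
#' @export
device_features <- function(channel_feats, active = NULL,
                            n_device_channels = 60L, device = "device",
                            burst_parameters = burst_params()) {
  pct_active <- if (is.null(active)) {
    100 * nrow(channel_feats) / n_device_channels
  } else if (is.data.frame(active) || is.logical(active)) {
    percent_active(active, n_device_channels)
  } else {
    as.double(active)
  }
  ch_rows <- tibble::tibble(device_id = device, level = "channel",
                            channel_id = channel_feats$channel_id,
                            percent_active_electrodes = NA_real_)
  for (f in feature_cols) ch_rows[[f]] <- as.double(channel_feats[[f]])
  dev_row <- tibble::tibble(device_id = device, level = "device",
                            channel_id = "",
                            percent_active_electrodes = pct_active)
  for (f in feature_cols) {
    v <- channel_feats[[f]]
    dev_row[[f]] <- if (is.null(v) || !length(v) || all(is.na(v))) NA_real_
                    else mean(v, na.rm = TRUE)
  }
  out <- dplyr::bind_rows(ch_rows, dev_row)
  attr(out, "burst_params") <- burst_parameters
  class(out) <- c("device_features", class(out))
  out
}

#' Compute device features straight from a cleaned spike table
#'
#' Convenience wrapper: bursts, channel features and device aggregation in
#' one call.
#'
#' @param spikes Cleaned, QC-filtered [mea_spikes()] table.
#' @param active Optional `active` tibble from [filter_low_count_channels()].
#' @param params A [burst_params()].
#' @return A `device_features` tibble (see [device_features()]).
#' @export
compute_features <- function(spikes, active = NULL, params = burst_params()) {
  bursts <- detect_bursts(spikes, params)
  cf <- channel_features(spikes, bursts)
  device_features(cf, active = active,
                  n_device_channels = n_device_channels(spikes),
                  device = device_id(spikes), burst_parameters = params)
}

#' Fold change of device features after a drug challenge
#'
#' The change in activity from a baseline epoch to a challenge epoch on the
#' same device, reported per device-level feature as the ratio
#' challenge / baseline (the conventional reading of "fold change"); an
#' additive `challenge - baseline` mode is available behind `mode`. Features
#' whose baseline is zero or missing are flagged undefined rather than
#' reported as infinite.
#'
#' @param baseline,challenge `device_features` tibbles from
#'   [device_features()], computed under identical burst parameters (a
#'   mismatch is an error, not a warning).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return A tibble with one row per feature: `feature`, `baseline`,
#'   `challenge`, `fold_change`, `defined`.
#' @export
fold_change <- function(baseline, challenge, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  bp1 <- attr(baseline, "burst_params")
  bp2 <- attr(challenge, "burst_params")
  if (!is.null(bp1) && !is.null(bp2) && !identical(unclass(bp1), unclass(bp2))) {
    stop("baseline and challenge were computed under different burst ",
         "parameters; refusing to compare", call. = FALSE)
  }
  b <- baseline[baseline$level == "device", , drop = FALSE]
  c_ <- challenge[challenge$level == "device", , drop = FALSE]
  if (nrow(b) != 1 || nrow(c_) != 1) {
    stop("need exactly one device row in each feature table", call. = FALSE)
  }
  feats <- c("percent_active_electrodes", feature_cols)
  bv <- vapply(feats, function(f) as.double(b[[f]]), 1.0)
  cv <- vapply(feats, function(f) as.double(c_[[f]]), 1.0)
  if (mode == "ratio") {
    defined <- is.finite(bv) & is.finite(cv) & bv > 0
    fc <- ifelse(defined, cv / bv, NA_real_)
  } else {
    defined <- is.finite(bv) & is.finite(cv)
    fc <- ifelse(defined, cv - bv, NA_real_)
  }
  tibble::tibble(feature = feats, baseline = bv, challenge = cv,
                 fold_change = fc, defined = defined)
}
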
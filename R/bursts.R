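#' Detect bursts with the five-parameter maximum-interval rule
#'
#' A burst is a compact run of spikes on one channel. Detection proceeds in
#' four passes over the sorted spike train:
#'
#' 1. **Seed** — a candidate burst opens at spike *i* when the interval to
#'    the next spike is at most `max_begin_isi_s` (0.1 s). A channel's last
#'    spike can never seed.
#' 2. **Extend** — following spikes are absorbed while each successive ISI is
#'    at most `max_end_isi_s` (0.2 s).
#' 3. **Merge** — consecutive candidates whose gap (first spike of the next
#'    minus last spike of the previous) is less than `min_ibi_s` (0.5 s) are
#'    fused. Merging precedes filtering, the convention associated with this
#'    parameter set.
#' 4. **Filter** — candidates with fewer than `min_spikes` (6) spikes or
#'    duration (last minus first spike) under `min_duration_s` (0.05 s) are
#'    discarded.
#'
#' Burst extent is defined by its member spikes: `start_s` is the first and
#' `end_s` the last member spike time, duration their difference. Surviving
#' bursts on a channel are disjoint, sorted, and separated by at least
#' `min_ibi_s`.
#'
#' @param spikes An [mea_spikes()] table, or a sorted numeric vector of spike
#'   times for a single train.
#' @param params A [burst_params()].
#' @return A tibble with one row per burst: `channel_id`, `burst_id` (1-based
#'   within channel), `start_s`, `end_s`, `n_spikes`, and `first_idx` /
#'   `last_idx` (indices of the member spikes into the channel's sorted
#'   train). For a numeric-vector input `channel_id` is `"train"`. The
#'   `device_id` of a spike-table input is carried as an attribute.
#' @examples
#' detect_bursts(seq(0, by = 0.05, length.out = 6), burst_params())
#' @export
detect_bursts <- function(spikes, params = burst_params()) {
  stopifnot(inherits(params, "burst_params"))
  if (is.numeric(spikes)) {
    out <- burst_one_channel(spikes, params)
    out$channel_id <- rep("train", nrow(out))
    return(dplyr::relocate(out, "channel_id"))
  }
  stopifnot(is_mea_spikes(spikes))
  pieces <- lapply(sort(spike_channels(spikes)), function(ch) {
    b <- burst_one_channel(spike_times(spikes, ch), params)
    b$channel_id <- rep(ch, nrow(b))
    dplyr::relocate(b, "channel_id")
  })
  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) {
    out <- tibble::tibble(channel_id = character(), burst_id = integer(),
                          start_s = double(), end_s = double(),
                          n_spikes = integer(), first_idx = integer(),
                          last_idx = integer())
  }
  attr(out, "device_id") <- device_id(spikes)
  attr(out, "burst_params") <- params
  out
}

burst_one_channel <- function(times, params) {
  empty <- tibble::tibble(burst_id = integer(), start_s = double(),
                          end_s = double(), n_spikes = integer(),
                          first_idx = integer(), last_idx = integer())
  n <- length(times)
  if (n < 2) return(empty)
  if (is.unsorted(times, strictly = FALSE)) {
    stop("spike times must be sorted", call. = FALSE)
  }
  isi <- diff(times)

  # seed + extend
  first <- integer(0)
  last <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= params$max_begin_isi_s) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= params$max_end_isi_s) j <- j + 1L
      first <- c(first, i)
      last <- c(last, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(first)) return(empty)

  # merge candidates separated by less than min_ibi_s
  mf <- first[1]
  ml <- last[1]
  if (length(first) > 1) {
    for (k in 2:length(first)) {
      gap <- times[first[k]] - times[ml[length(ml)]]
      if (gap < params$min_ibi_s) {
        ml[length(ml)] <- last[k]
      } else {
        mf <- c(mf, first[k])
        ml <- c(ml, last[k])
      }
    }
  }

  # filter on spike count and duration
  nsp <- ml - mf + 1L
  dur <- times[ml] - times[mf]
  ok <- nsp >= params$min_spikes & dur >= params$min_duration_s
  mf <- mf[ok]; ml <- ml[ok]
  if (!length(mf)) return(empty)
  tibble::tibble(burst_id = seq_along(mf),
                 start_s = times[mf], end_s = times[ml],
                 n_spikes = ml - mf + 1L,
                 first_idx = mf, last_idx = ml)
}
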
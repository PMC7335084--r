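# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the SPIKE distance is integrated on a dense
# grid instead of segment-wise in closed form, and the burst reference is a
# run-length formulation instead of the package's scan loop.

# Dense-grid quadrature of the SPIKE dissimilarity profile (midpoint rule).
grid_spike_distance <- function(x, y, t_end, dt = 1e-4) {
  xa <- x
  ya <- y
  if (xa[1] > 0) xa <- c(0, xa)
  if (xa[length(xa)] < t_end) xa <- c(xa, t_end)
  if (ya[1] > 0) ya <- c(0, ya)
  if (ya[length(ya)] < t_end) ya <- c(ya, t_end)

  tm <- seq(dt / 2, t_end - dt / 2, by = dt)

  nearest <- function(v, w) {
    i <- findInterval(v, w)
    lo <- ifelse(i >= 1, v - w[pmax(i, 1)], Inf)
    hi <- ifelse(i < length(w), w[pmin(i + 1, length(w))] - v, Inf)
    pmin(lo, hi)
  }
  side <- function(train, other, tt) {
    i <- findInterval(tt, train)
    tP <- train[pmax(i, 1)]
    tF <- train[pmin(i + 1, length(train))]
    nu <- tF - tP
    dP <- nearest(tP, other)
    dF <- nearest(tF, other)
    list(S = (dP * (tF - tt) + dF * (tt - tP)) / nu, nu = nu)
  }
  sx <- side(xa, ya, tm)
  sy <- side(ya, xa, tm)
  m <- (sx$nu + sy$nu) / 2
  S <- (sx$S * sy$nu + sy$S * sx$nu) / (2 * m^2)
  sum(S) * dt / t_end
}

# Run-length burst reference: end-linked runs of spikes, candidate = first
# begin-qualifying spike of a run to the run's end; repeat-merge; filter.
brute_force_bursts <- function(times, p = burst_params()) {
  n <- length(times)
  none <- data.frame(first_idx = integer(), last_idx = integer())
  if (n < 2) return(none)
  isi <- diff(times)
  linked <- isi <= p$max_end_isi_s
  r <- rle(linked)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  cand <- none
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    # run of spikes starts[k] .. stops[k] + 1 linked by end-ISIs
    s_candidates <- starts[k]:stops[k]
    seeds <- s_candidates[isi[s_candidates] <= p$max_begin_isi_s]
    if (!length(seeds)) next
    cand <- rbind(cand,
                  data.frame(first_idx = min(seeds), last_idx = stops[k] + 1))
  }
  if (!nrow(cand)) return(none)
  repeat {
    if (nrow(cand) < 2) break
    gaps <- times[cand$first_idx[-1]] - times[cand$last_idx[-nrow(cand)]]
    hit <- which(gaps < p$min_ibi_s)
    if (!length(hit)) break
    i <- hit[1]
    cand$last_idx[i] <- cand$last_idx[i + 1]
    cand <- cand[-(i + 1), , drop = FALSE]
  }
  nsp <- cand$last_idx - cand$first_idx + 1
  dur <- times[cand$last_idx] - times[cand$first_idx]
  out <- cand[nsp >= p$min_spikes & dur >= p$min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out$first_idx <- as.integer(out$first_idx)
  out$last_idx <- as.integer(out$last_idx)
  out
}

# Random spike train whose ISIs straddle all five burst-rule thresholds.
random_threshold_train <- function(n_isi) {
  pool <- list(
    function(k) runif(k, 0.05, 0.15),   # around max_begin 0.1
    function(k) runif(k, 0.15, 0.25),   # around max_end 0.2
    function(k) runif(k, 0.35, 0.65),   # around min_ibi 0.5
    function(k) rexp(k, rate = 1 / 0.05),
    function(k) rexp(k, rate = 1 / 1.0),
    function(k) sample(c(0.1, 0.2, 0.5), k, replace = TRUE)  # exact bounds
  )
  which_pool <- sample(seq_along(pool), n_isi, replace = TRUE)
  isis <- vapply(which_pool, function(w) pool[[w]](1), 1.0)
  cumsum(c(runif(1, 0, 0.5), isis))
}

# Quick construction of a spike table from a named list of time vectors.
make_spike_tbl <- function(trains, duration_s = 600, n_device_channels = 60,
                           trough_uV = -60, device = "dev") {
  df <- dplyr::bind_rows(
    tibble::tibble(channel_id = character(), time_s = double(),
                   trough_uV = double()),
    lapply(names(trains), function(ch) {
      tibble::tibble(channel_id = ch, time_s = trains[[ch]],
                     trough_uV = rep_len(trough_uV, length(trains[[ch]])))
    })
  )
  mea_spikes(df, device_id = device, duration_s = duration_s,
             n_device_channels = n_device_channels)
}

# Poisson spike train on [0, T] (at least one spike).
poisson_train <- function(rate, t_end) {
  n <- max(1L, rpois(1, rate * t_end))
  sort(runif(n, 0, t_end))
}

# A device with one simultaneous sub--200 uV deflection on `n_hit` of
# `n_dev` channels at time `t`.
simultaneous_event <- function(n_hit, t = 5, n_dev = 60, amp = -300) {
  trains <- stats::setNames(
    lapply(seq_len(n_hit), function(i) t),
    sprintf("ch%02d", seq_len(n_hit))
  )
  make_spike_tbl(trains, duration_s = 10, n_device_channels = n_dev,
                 trough_uV = amp)
}
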
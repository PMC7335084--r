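#' Read and write raw voltage recordings (HDF5)
#'
#' Raw recordings are stored in an HDF5 container with a single 2-D dataset
#' `voltage_uV` (channels x samples) carrying the attributes
#' `sampling_rate_hz`, `channel_ids`, `device_id` and `units`. Voltages are
#' converted to microvolts on read (`units` of `"uV"`, `"mV"` or `"V"` are
#' understood); in-memory objects are always microvolts and seconds.
#'
#' Requires the `rhdf5` package.
#'
#' @param path Path to an HDF5 file.
#' @return `read_raw()` returns an [mea_recording()]; `write_raw()` returns
#'   `path` invisibly.
#' @export
read_raw <- function(path) {
  require_rhdf5()
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)
  if (!"voltage_uV" %in% contents$name) {
    stop("raw container is missing the `voltage_uV` dataset", call. = FALSE)
  }
  x <- rhdf5::h5read(path, "voltage_uV", read.attributes = TRUE)
  att <- attributes(x)
  for (need in c("sampling_rate_hz", "channel_ids", "units")) {
    if (is.null(att[[need]])) {
      stop("raw container is missing the `", need, "` attribute",
           call. = FALSE)
    }
  }
  scale <- switch(tolower(as.character(att$units)[1]),
                  "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6,
                  stop("unknown voltage units: ", att$units, call. = FALSE))
  samples <- matrix(as.double(x), nrow = nrow(x)) * scale
  if (!all(is.finite(samples))) {
    stop("raw recording contains non-finite samples", call. = FALSE)
  }
  mea_recording(samples,
                sampling_rate_hz = as.double(att$sampling_rate_hz),
                channel_ids = as.character(att$channel_ids),
                device_id = if (is.null(att$device_id)) "device"
                            else as.character(att$device_id),
                t0_s = if (is.null(att$t0_s)) 0 else as.double(att$t0_s))
}

#' @rdname read_raw
#' @param recording An [mea_recording()].
#' @export
write_raw <- function(recording, path) {
  require_rhdf5()
  stopifnot(is_mea_recording(recording))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(recording$samples, path, "voltage_uV")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, "voltage_uV")
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(recording$sampling_rate_hz, did, "sampling_rate_hz")
  rhdf5::h5writeAttribute(recording$channel_ids, did, "channel_ids")
  rhdf5::h5writeAttribute(recording$device_id, did, "device_id")
  rhdf5::h5writeAttribute("uV", did, "units")
  rhdf5::h5writeAttribute(recording$t0_s, did, "t0_s")
  invisible(path)
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("raw-recording I/O needs the `rhdf5` package", call. = FALSE)
  }
}

#' Read and write spike tables (CSV)
#'
#' The CSV schema is `device_id,channel_id,spike_time_s,trough_uV`, one row
#' per spike. Unsorted rows are sorted silently; duplicate (channel, time)
#' rows and negative times are validation errors. When `duration_s` is not
#' given it is taken from the file if written by [write_spikes()], otherwise
#' the maximum spike time rounded up to a whole second.
#'
#' @param path CSV file path.
#' @param duration_s Recording duration; `NULL` to infer.
#' @param n_device_channels Total electrodes on the device; `NULL` to take it
#'   from the file (falling back to 60).
#' @return `read_spikes()` returns an [mea_spikes()] table.
#' @export
read_spikes <- function(path, duration_s = NULL, n_device_channels = NULL) {
  df <- utils::read.csv(path, colClasses = c(
    device_id = "character", channel_id = "character",
    spike_time_s = "numeric", trough_uV = "numeric"
  ), comment.char = "#")
  need <- c("device_id", "channel_id", "spike_time_s", "trough_uV")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("spike CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) && any(df$spike_time_s < 0)) {
    stop("spike CSV contains negative times", call. = FALSE)
  }
  meta <- read_meta_comments(path)
  dev <- if (nrow(df)) df$device_id[1] else (meta$device_id %||% "device")
  if (is.null(duration_s)) {
    duration_s <- meta$duration_s %||%
      (if (nrow(df)) ceiling(max(df$spike_time_s)) else 600)
  }
  if (is.null(n_device_channels)) {
    n_device_channels <- meta$n_device_channels %||% 60L
  }
  mea_spikes(
    data.frame(channel_id = df$channel_id, time_s = df$spike_time_s,
               trough_uV = df$trough_uV),
    device_id = dev, duration_s = as.double(duration_s),
    n_device_channels = as.integer(n_device_channels)
  )
}

#' @rdname read_spikes
#' @param spikes An [mea_spikes()] table.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(is_mea_spikes(spikes))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# device_id=%s duration_s=%.9f n_device_channels=%d",
                     device_id(spikes), spike_duration(spikes),
                     n_device_channels(spikes)), con)
  df <- data.frame(device_id = device_id(spikes),
                   channel_id = spikes$channel_id,
                   spike_time_s = sprintf("%.9f", spikes$time_s),
                   trough_uV = sprintf("%.6f", spikes$trough_uV))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Metadata line written by write_spikes/write_bursts:
# "# key=value key=value ..."
read_meta_comments <- function(path) {
  first <- readLines(path, n = 1L)
  out <- list()
  if (length(first) && startsWith(first, "#")) {
    for (kv in strsplit(trimws(sub("^#", "", first)), " +")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) {
        val <- suppressWarnings(as.numeric(parts[2]))
        out[[parts[1]]] <- if (is.na(val)) parts[2] else val
      }
    }
  }
  out
}

#' Read and write burst tables (CSV)
#'
#' Schema: `device_id,channel_id,burst_id,burst_start_s,burst_end_s,n_spikes`.
#'
#' @param bursts A burst tibble from [detect_bursts()].
#' @param path CSV file path.
#' @export
write_bursts <- function(bursts, path) {
  df <- data.frame(device_id = attr(bursts, "device_id") %||% "device",
                   channel_id = bursts$channel_id,
                   burst_id = bursts$burst_id,
                   burst_start_s = sprintf("%.9f", bursts$start_s),
                   burst_end_s = sprintf("%.9f", bursts$end_s),
                   n_spikes = bursts$n_spikes)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bursts
#' @export
read_bursts <- function(path) {
  df <- utils::read.csv(path, colClasses = c(channel_id = "character",
                                             device_id = "character"))
  out <- tibble::tibble(channel_id = df$channel_id,
                        burst_id = as.integer(df$burst_id),
                        start_s = as.double(df$burst_start_s),
                        end_s = as.double(df$burst_end_s),
                        n_spikes = as.integer(df$n_spikes))
  attr(out, "device_id") <- if (nrow(df)) df$device_id[1] else "device"
  out
}

#' Read and write feature tables (CSV)
#'
#' Tidy layout: one row per (device, channel) plus one device-mean row per
#' device (`level == "device"`), one feature per column. Features that are
#' undefined for a channel (e.g. burst duration on a channel with no bursts)
#' are written as empty fields and read back as `NA`.
#'
#' @param features A feature tibble from [device_features()].
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, colClasses = c(channel_id = "character",
                                             device_id = "character",
                                             level = "character"))
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
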
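#' Run the full analysis pipeline on one recording
#'
#' Executes the stages in the fixed published order — spike detection (when
#' the input is raw voltage), heater-artifact detection and purge, channel
#' QC, burst detection, feature extraction, synchrony — writing each stage's
#' table as CSV into `out_dir` together with a JSON run manifest (config
#' hash, seed, per-stage counts, file paths). Every stage output is reusable
#' as standalone input to the corresponding function, and a rerun with the
#' same config and seed reproduces the outputs byte for byte.
#'
#' @param input An [mea_recording()], an [mea_spikes()] table, or a path to a
#'   raw HDF5 container / spike CSV.
#' @param config An [analysis_config()] or a path to its YAML form.
#' @param out_dir Output directory (created if missing).
#' @param synchrony Compute the synchrony stage? (It dominates runtime; set
#'   `FALSE` for feature-only runs.)
#' @return Invisibly, a list with `spikes` (cleaned), `bursts`, `features`,
#'   `synchrony` (or `NULL`), `qc` and `manifest`.
#' @export
run_pipeline <- function(input, config = analysis_config(),
                         out_dir = ".", synchrony = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "analysis_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_files <- list()
  counts <- list()
  t_started <- Sys.time()

  if (is.character(input)) {
    input <- if (grepl("\\.(h5|hdf5)$", input, ignore.case = TRUE)) {
      read_raw(input)
    } else {
      read_spikes(input)
    }
  }

  if (is_mea_recording(input)) {
    spikes_raw <- detect_spikes(input, config$detection)
    stage_files$spikes_detected <- file.path(out_dir, "spikes_detected.csv")
    write_spikes(spikes_raw, stage_files$spikes_detected)
  } else if (is_mea_spikes(input)) {
    spikes_raw <- input
  } else {
    stop("`input` must be a recording, a spike table, or a path",
         call. = FALSE)
  }
  counts$spikes_detected <- n_spikes(spikes_raw)

  cleaned <- clean_spikes(spikes_raw, config$artifacts, config$qc_min_spikes)
  counts$heater_events <- cleaned$qc$n_heater_events
  counts$spikes_purged <- cleaned$qc$n_spikes_purged
  counts$channels_dropped <- cleaned$qc$n_channels_dropped
  counts$spikes_clean <- n_spikes(cleaned$spikes)
  counts$percent_active <- cleaned$qc$percent_active
  stage_files$spikes_clean <- file.path(out_dir, "spikes_clean.csv")
  write_spikes(cleaned$spikes, stage_files$spikes_clean)
  stage_files$heater_events <- file.path(out_dir, "heater_events.csv")
  utils::write.csv(
    data.frame(event_id = seq_len(nrow(cleaned$events)),
               time_s = if (nrow(cleaned$events)) {
                 sprintf("%.9f", cleaned$events$time_s)
               } else character(),
               n_channels = cleaned$events$n_channels),
    stage_files$heater_events, row.names = FALSE, quote = FALSE
  )

  bursts <- detect_bursts(cleaned$spikes, config$bursts)
  counts$bursts <- nrow(bursts)
  stage_files$bursts <- file.path(out_dir, "bursts.csv")
  write_bursts(bursts, stage_files$bursts)

  cf <- channel_features(cleaned$spikes, bursts)
  feats <- device_features(cf, active = cleaned$active,
                           n_device_channels = n_device_channels(spikes_raw),
                           device = device_id(spikes_raw),
                           burst_parameters = config$bursts)
  stage_files$features <- file.path(out_dir, "features.csv")
  write_features(feats, stage_files$features)

  sync <- NULL
  if (synchrony && length(spike_channels(cleaned$spikes)) >= 2) {
    sync <- device_synchrony(cleaned$spikes, config$synchrony,
                             seed = derive_seed(config$seed, "synchrony"))
    stage_files$synchrony <- file.path(out_dir, "synchrony.csv")
    utils::write.csv(as.data.frame(tidy(sync)), stage_files$synchrony,
                     row.names = FALSE, quote = FALSE)
    counts$device_synchrony <- sync$device_synchrony
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("meaflow")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    device_id = device_id(spikes_raw),
    started = format(t_started, "%Y-%m-%dT%H:%M:%S"),
    counts = counts,
    files = stage_files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(spikes = cleaned$spikes, bursts = bursts, features = feats,
                 synchrony = sync, qc = cleaned$qc, manifest = manifest))
}

#' Compare a baseline and a challenge run as fold changes
#'
#' Runs [run_pipeline()] (feature stages) on both epochs with one shared
#' configuration and reports device-level fold changes.
#'
#' @param baseline,challenge Inputs accepted by [run_pipeline()].
#' @param config An [analysis_config()].
#' @param out_dir Output directory; fold changes are written to
#'   `fold_change.csv`.
#' @param synchrony Include the synchrony stage in both runs?
#' @return Invisibly, a list with both run results and the `fold_change`
#'   tibble.
#' @export
run_challenge <- function(baseline, challenge, config = analysis_config(),
                          out_dir = ".", synchrony = FALSE) {
  res_b <- run_pipeline(baseline, config,
                        out_dir = file.path(out_dir, "baseline"),
                        synchrony = synchrony)
  res_c <- run_pipeline(challenge, config,
                        out_dir = file.path(out_dir, "challenge"),
                        synchrony = synchrony)
  fc <- fold_change(res_b$features, res_c$features)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(as.data.frame(fc), file.path(out_dir, "fold_change.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(baseline = res_b, challenge = res_c, fold_change = fc))
}
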
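#' End-to-end run configuration
#'
#' Bundles the sub-configurations of a full simulate-analyze-classify run.
#'
#' @param cohort a [cohort_config()]
#' @param window_len,hop spectrogram settings in samples
#' @param band_halfwidth moving-band half-width in Hz
#' @param n_rounds,learning_rate,max_splits RUSBoost settings
#' @param k number of cross-validation folds
#' @param cv_seed seed for fold assignment and ensemble fits
#' @param output_dir where [run_pipeline()] writes its artifacts
#' @return an object of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(), window_len = 256,
                       hop = 512, band_halfwidth = 20, n_rounds = 30,
                       learning_rate = 0.1, max_splits = 20, k = 5,
                       cv_seed = 42, output_dir = "chirpscope_run") {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(
    list(cohort = cohort, window_len = window_len, hop = hop,
         band_halfwidth = band_halfwidth, n_rounds = n_rounds,
         learning_rate = learning_rate, max_splits = max_splits, k = k,
         cv_seed = cv_seed, output_dir = output_dir),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `cohort` key
#' holds [cohort_config()] fields (its `chirp` sub-key holds
#' [chirp_spec()] fields). Missing keys fall back to the defaults.
#'
#' @param path YAML file path
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  cohort_args$chirp <- do.call(chirp_spec, cohort_args$chirp %||% list())
  cohort <- do.call(cohort_config, cohort_args)
  top <- y[setdiff(names(y), "cohort")]
  do.call(run_config, c(list(cohort = cohort), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of a configuration, for provenance stamping of artifacts.
# The output directory is excluded so identical analyses written to
# different places produce identical artifacts.
config_hash <- function(config) {
  config$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Simulate a cohort, analyze it, extract features, cross-validate the
#' classifier, and write every artifact to `config$output_dir`: WAVs and
#' `metadata.csv`, per-recording intensity-profile CSVs (under
#' `profiles/`), per-label group-curve CSVs and a comparison plot, the
#' feature table, a `results.json` with the pooled cross-validation
#' metrics, and a human-readable `report.txt`. All seeds and the
#' configuration hash are embedded in `results.json`.
#'
#' @param config a [run_config()]
#' @param write_wavs also write one WAV per recording (default TRUE)
#' @return invisibly, the report list (group difference, confusion matrix,
#'   accuracy, ppv, tpr, fpr, auc, paths)
#' @export
run_pipeline <- function(config = run_config(), write_wavs = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out, 2) != 0) {
    stop("output directory is not writable: ", out, call. = FALSE)
  }

  message("Simulating cohort (", config$cohort$n_healthy, " healthy + ",
          config$cohort$n_acs, " ACS observations)...")
  cohort <- generate_cohort(config$cohort)
  if (write_wavs) write_cohort(cohort, out) else {
    utils::write.csv(cohort$metadata, file.path(out, "metadata.csv"),
                     row.names = FALSE)
  }

  message("Computing intensity profiles...")
  chirp <- config$cohort$chirp
  profiles <- lapply(cohort$recordings, intensity_profile, chirp = chirp,
                     window_len = config$window_len, hop = config$hop,
                     band_halfwidth = config$band_halfwidth)
  prof_dir <- file.path(out, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (i in seq_along(profiles)) {
    write_curve_csv(profiles[[i]], file.path(
      prof_dir, sprintf("%s_%s.csv", cohort$recordings[[i]]$subject_id,
                        cohort$recordings[[i]]$location)))
  }

  labels <- cohort$metadata$true_label
  curves <- lapply(split(seq_along(profiles), labels), function(idx) {
    group_average_curve(profiles[idx])
  })
  for (lab in names(curves)) {
    write_curve_csv(curves[[lab]], file.path(out, paste0("group_", lab, ".csv")))
  }
  diff <- NULL
  if (all(c("healthy", "acs") %in% names(curves))) {
    diff <- group_difference(curves$healthy, curves$acs)
    grDevices::png(file.path(out, "group_curves.png"), 900, 600)
    plot_group_curves(curves)
    grDevices::dev.off()
  }

  message("Extracting features...")
  feats <- build_feature_table(cohort$recordings, profiles, labels)
  utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)

  message("Cross-validating the RUSBoost ensemble...")
  cv <- stratified_cv(feats[, FEATURE_NAMES], feats$label, k = config$k,
                      seed = config$cv_seed, n_rounds = config$n_rounds,
                      learning_rate = config$learning_rate,
                      max_splits = config$max_splits)
  grDevices::png(file.path(out, "roc.png"), 700, 700)
  plot_roc(cv)
  grDevices::dev.off()

  results <- list(
    config_hash = config_hash(config),
    cohort_seed = config$cohort$seed, cv_seed = config$cv_seed,
    n_observations = nrow(feats),
    class_counts = as.list(table(labels)),
    group_difference_mean_db = if (!is.null(diff)) diff$mean_db else NULL,
    group_difference_min_db = if (!is.null(diff)) diff$min_db else NULL,
    fold_assignments = cv$fold_assignments,
    confusion_matrix = unclass(cv$confusion_matrix),
    accuracy = cv$accuracy, ppv = cv$ppv, tpr_acs = cv$tpr_acs,
    fpr = cv$fpr, auc = cv$auc, roc_points = cv$roc_points)
  jsonlite::write_json(results, file.path(out, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- c(
    sprintf("chirpscope pipeline run (config %s)", results$config_hash),
    sprintf("observations: %d (%s)", nrow(feats),
            paste(sprintf("%s=%d", names(table(labels)), table(labels)),
                  collapse = ", ")),
    if (!is.null(diff)) sprintf(
      "healthy - ACS group intensity difference: mean %.1f dB, min %.1f dB",
      diff$mean_db, diff$min_db),
    "pooled out-of-fold confusion matrix (rows = truth):",
    utils::capture.output(print(cv$confusion_matrix)),
    sprintf("accuracy %.3f | PPV %.3f | TPR(acs) %.3f | FPR %.3f | AUC %.3f",
            cv$accuracy, cv$ppv, cv$tpr_acs, cv$fpr, cv$auc))
  writeLines(report, file.path(out, "report.txt"))
  message(paste(report, collapse = "\n"))

  invisible(list(group_difference = diff, cv = cv, features = feats,
                 results = results, output_dir = out))
}

#' Analyze externally supplied recordings
#'
#' Applies the spectral pipeline to a directory of WAV files with a
#' metadata CSV (as written by [write_cohort()], or produced by any
#' compatible recorder). Sample rates that do not match the configured
#' chirp are refused, not resampled.
#'
#' @param wav_dir directory of `{subject_id}_{location}.wav` files
#' @param metadata_csv CSV with at least subject_id, location and a label
#'   column (`true_label`)
#' @param config a [run_config()]
#' @return list with `profiles` (per recording) and `curves` (per label
#'   with at least 2 members)
#' @export
analyze_recordings <- function(wav_dir, metadata_csv,
                               config = run_config()) {
  metadata <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  chirp <- config$cohort$chirp
  profiles <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    path <- file.path(wav_dir, sprintf("%s_%s.wav", metadata$subject_id[i],
                                       metadata$location[i]))
    if (!file.exists(path)) {
      stop("metadata row without a matching WAV: ", path, call. = FALSE)
    }
    rec <- read_wav(path)
    if (rec$sample_rate != chirp$sample_rate) {
      stop(sprintf("%s: sample rate %d Hz does not match the configured %d Hz (resampling is refused)",
                   path, rec$sample_rate, chirp$sample_rate), call. = FALSE)
    }
    profiles[[i]] <- intensity_profile(
      rec, chirp = chirp, window_len = config$window_len, hop = config$hop,
      band_halfwidth = config$band_halfwidth)
  }
  groups <- split(seq_len(nrow(metadata)), metadata$true_label)
  curves <- lapply(groups[lengths(groups) >= 2], function(idx) {
    group_average_curve(profiles[idx])
  })
  list(profiles = profiles, curves = curves, metadata = metadata)
}
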
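#' Cohort generation configuration
#'
#' Study conditions for the synthetic cohort: class sizes, noise floor,
#' between-subject variability and the pathological attenuation model. The
#' defaults reproduce the reference study structure: 133 healthy and 12 ACS
#' observations (145 total), pathology at the posterior basal pair, ACS
#' extra attenuation averaging 12-16 dB and never dropping below 5 dB
#' across the band.
#'
#' @param n_healthy number of healthy-labeled observations
#' @param n_acs number of ACS-labeled observations
#' @param noise_db measurement-noise floor in dB relative to the chirp
#'   amplitude (`-Inf` disables noise)
#' @param subject_gain_sd_db SD of the flat between-subject gain offset, dB
#' @param subject_wiggle_sd_db SD of the smooth per-subject frequency
#'   wiggle, dB
#' @param acs_extra_range the per-recording mean extra attenuation for ACS
#'   observations is drawn uniformly from this range, dB
#' @param acs_wiggle_sd_db SD of the smooth variation of the extra
#'   attenuation, dB
#' @param acs_min_extra_db floor on the extra attenuation at every
#'   frequency, dB
#' @param base_attenuation_db healthy baseline chest-wall attenuation, dB
#' @param affected_locations posterior sites at which pathology manifests
#'   (ACS observations are generated at these sites)
#' @param seed master seed; a fixed seed gives byte-identical output
#' @param chirp the [chirp_spec()] of the percussive input
#' @param attenuating_findings,non_attenuating_findings,mixed_findings
#'   finding-name lists used when synthesizing EMR metadata (see
#'   [finding_attenuation_class()])
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_healthy = 133, n_acs = 12, noise_db = -40,
                          subject_gain_sd_db = 2, subject_wiggle_sd_db = 1,
                          acs_extra_range = c(12, 16),
                          acs_wiggle_sd_db = 1.5, acs_min_extra_db = 5,
                          base_attenuation_db = 10,
                          affected_locations = c("PBL", "PBR"),
                          seed = 42, chirp = chirp_spec(),
                          attenuating_findings = ATTENUATING_FINDINGS,
                          non_attenuating_findings = NON_ATTENUATING_FINDINGS,
                          mixed_findings = MIXED_FINDINGS) {
  check_that(n_healthy >= 0 && n_acs >= 0, "n_healthy/n_acs",
             "must be >= 0")
  check_that(length(acs_extra_range) == 2 && diff(acs_extra_range) >= 0,
             "acs_extra_range", "must be an increasing pair")
  check_that(all(affected_locations %in% POSTERIOR_LOCATIONS),
             "affected_locations", "must be posterior sites")
  structure(
    list(n_healthy = n_healthy, n_acs = n_acs, noise_db = noise_db,
         subject_gain_sd_db = subject_gain_sd_db,
         subject_wiggle_sd_db = subject_wiggle_sd_db,
         acs_extra_range = acs_extra_range,
         acs_wiggle_sd_db = acs_wiggle_sd_db,
         acs_min_extra_db = acs_min_extra_db,
         base_attenuation_db = base_attenuation_db,
         affected_locations = affected_locations,
         seed = seed, chirp = chirp,
         attenuating_findings = attenuating_findings,
         non_attenuating_findings = non_attenuating_findings,
         mixed_findings = mixed_findings),
    class = "cohort_config"
  )
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_healthy` healthy and `n_acs` ACS chirp-response recordings.
#' Each subject contributes recordings at the six posterior sites (healthy
#' subjects) or at the configured affected sites (ACS subjects, posterior
#' basal pair by default), cycling until the requested observation counts
#' are reached. Every subject receives a flat gain offset and a smooth
#' frequency wiggle; ACS recordings additionally pass through an
#' [acs_profile()] whose mean extra attenuation is drawn uniformly from
#' `acs_extra_range` and floored at `acs_min_extra_db`. Measurement noise
#' is added last, relative to the chirp amplitude. The whole procedure is
#' deterministic given `config$seed`.
#'
#' @param config a [cohort_config()]
#' @return a list with `recordings` (list of [recording()]) and `metadata`
#'   (data.frame, one row per recording: subject_id, location, true_label,
#'   bmi, stethoscope, findings, fever, respiratory_symptoms, voc, seed,
#'   mean_extra_db)
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_healthy = 6, n_acs = 2))
#' table(coh$metadata$true_label)
#' }
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- config$n_healthy + config$n_acs
  if (n_total == 0) stop("empty cohort: n_healthy + n_acs must be > 0",
                         call. = FALSE)
  chirp <- config$chirp
  clean <- generate_chirp(chirp)

  with_local_seed(config$seed, {
    recordings <- vector("list", n_total)
    meta <- vector("list", n_total)
    idx <- 0

    emit <- function(rec, extra_db, bmi, findings, fever, resp, voc) {
      idx <<- idx + 1
      recordings[[idx]] <<- rec
      meta[[idx]] <<- data.frame(
        subject_id = rec$subject_id, location = rec$location,
        true_label = rec$true_label, bmi = round(bmi, 1),
        stethoscope = "eko", findings = findings, fever = fever,
        respiratory_symptoms = resp, voc = voc, seed = config$seed,
        mean_extra_db = extra_db, stringsAsFactors = FALSE)
    }

    synth_subject <- function(subject_id, label, locations, n_rec) {
      base <- healthy_profile(chirp, config$base_attenuation_db,
                              stats::rnorm(1, 0, config$subject_gain_sd_db),
                              config$subject_wiggle_sd_db)
      is_acs <- label == "acs"
      bmi <- min(stats::rnorm(1, 25, 2.5), 30)
      for (j in seq_len(n_rec)) {
        loc <- locations[(j - 1) %% length(locations) + 1]
        extra <- NA_real_
        prof <- base
        if (is_acs) {
          extra <- stats::runif(1, config$acs_extra_range[1],
                                config$acs_extra_range[2])
          prof <- acs_profile(base, extra, config$acs_wiggle_sd_db,
                              config$acs_min_extra_db)
        }
        rec <- clean
        rec$subject_id <- subject_id
        rec$location <- loc
        rec$true_label <- label
        rec <- apply_transmission(rec, prof, chirp)
        rec <- add_noise(rec, config$noise_db,
                         ref_amplitude = chirp$amplitude)
        emit(rec, extra, bmi,
             findings = if (is_acs) "infiltrate" else "",
             fever = is_acs, resp = is_acs, voc = FALSE)
      }
    }

    remaining <- config$n_healthy
    s <- 0
    while (remaining > 0) {
      s <- s + 1
      take <- min(6, remaining)
      synth_subject(sprintf("H%03d", s), "healthy", POSTERIOR_LOCATIONS, take)
      remaining <- remaining - take
    }
    remaining <- config$n_acs
    s <- 0
    n_loc <- length(config$affected_locations)
    while (remaining > 0) {
      s <- s + 1
      take <- min(n_loc, remaining)
      synth_subject(sprintf("A%03d", s), "acs",
                    config$affected_locations, take)
      remaining <- remaining - take
    }

    list(recordings = recordings, metadata = do.call(rbind, meta))
  })
}

#' Write a cohort to disk
#'
#' One 16-bit PCM mono WAV per recording, named
#' `{subject_id}_{location}.wav`, plus a `metadata.csv`.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the metadata file path
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_wav(rec, file.path(dir, sprintf("%s_%s.wav",
                                          rec$subject_id, rec$location)))
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE)
  invisible(meta_path)
}

#' Read a cohort back from disk
#'
#' Reads `metadata.csv` and the WAVs written by [write_cohort()].
#'
#' @param dir directory containing `metadata.csv` and the WAV files
#' @return a list with `recordings` and `metadata`, as [generate_cohort()]
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv in ", dir, call. = FALSE)
  }
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(metadata)), function(i) {
    path <- file.path(dir, sprintf("%s_%s.wav", metadata$subject_id[i],
                                   metadata$location[i]))
    if (!file.exists(path)) {
      stop("metadata row without a matching WAV: ", path, call. = FALSE)
    }
    rec <- read_wav(path)
    rec$subject_id <- metadata$subject_id[i]
    rec$location <- metadata$location[i]
    rec$true_label <- metadata$true_label[i]
    rec
  })
  list(recordings = recordings, metadata = metadata)
}
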
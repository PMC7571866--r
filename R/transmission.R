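#' Frequency-dependent transmission profile
#'
#' Describes how much sound intensity is lost between the percussive input
#' at the sternum and a posterior recording site, as a per-frequency
#' attenuation in dB. Consolidated or fluid-filled lung transmits the chirp
#' at markedly lower intensity than aerated lung, which is the physical
#' premise of the whole analysis.
#'
#' @param frequencies grid of Hz values spanning the chirp band
#' @param attenuation_db per-frequency attenuation in dB (finite, >= 0,
#'   applied as a loss)
#' @param class_tag one of `HEALTHY_BASELINE`, `ACS_LIKE`,
#'   `UNCOMPLICATED_VOC`, `COMPLICATED_VOC`
#' @return an object of class `transmission_profile`
#' @export
transmission_profile <- function(frequencies, attenuation_db,
                                 class_tag = "HEALTHY_BASELINE") {
  check_that(length(frequencies) == length(attenuation_db), "attenuation_db",
             "must have one value per frequency")
  check_that(all(is.finite(attenuation_db)), "attenuation_db",
             "must be finite")
  check_that(all(attenuation_db >= 0), "attenuation_db",
             "must be >= 0 (attenuation is a loss)")
  check_that(!is.unsorted(frequencies), "frequencies",
             "must be non-decreasing")
  check_that(class_tag %in% c("HEALTHY_BASELINE", "ACS_LIKE",
                              "UNCOMPLICATED_VOC", "COMPLICATED_VOC"),
             "class_tag", "unknown class tag")
  structure(
    list(frequencies = as.numeric(frequencies),
         attenuation_db = as.numeric(attenuation_db),
         class_tag = class_tag),
    class = "transmission_profile"
  )
}

#' Flat transmission profile
#'
#' Convenience constructor for a constant attenuation across the chirp band,
#' used mainly in parameter-recovery experiments.
#'
#' @param attenuation_db constant attenuation in dB (>= 0)
#' @param chirp a [chirp_spec()] fixing the frequency span
#' @param class_tag passed to [transmission_profile()]
#' @export
flat_profile <- function(attenuation_db, chirp = chirp_spec(),
                         class_tag = "HEALTHY_BASELINE") {
  f <- c(chirp$f_start, chirp$f_end)
  transmission_profile(f, rep(attenuation_db, 2), class_tag)
}

# Smooth per-subject frequency wiggle: natural cubic spline through
# `n_knots` Gaussian knot values, centered so it contributes zero mean
# attenuation over the band.
smooth_wiggle <- function(frequencies, sd_db, n_knots = 8) {
  if (sd_db <= 0) return(rep(0, length(frequencies)))
  knots_x <- seq(min(frequencies), max(frequencies), length.out = n_knots)
  knots_y <- stats::rnorm(n_knots, 0, sd_db)
  w <- stats::spline(knots_x, knots_y, xout = frequencies,
                     method = "natural")$y
  w - mean(w)
}

#' Healthy-baseline transmission profile
#'
#' Baseline chest-wall attenuation plus a flat per-subject gain offset and a
#' smooth per-subject frequency wiggle (natural cubic spline through 8
#' knots). The offset and wiggle emulate between-subject variability in
#' chest geometry and stethoscope coupling; they give the healthy group a
#' non-degenerate standard-error band.
#'
#' @param chirp a [chirp_spec()] fixing the frequency span
#' @param base_db baseline attenuation level in dB
#' @param gain_offset_db flat per-subject gain offset in dB (positive =
#'   quieter subject)
#' @param wiggle_sd_db standard deviation of the spline wiggle in dB
#' @param n_grid number of grid points across the band
#' @return a `HEALTHY_BASELINE` [transmission_profile()]
#' @export
healthy_profile <- function(chirp = chirp_spec(), base_db = 10,
                            gain_offset_db = 0, wiggle_sd_db = 1,
                            n_grid = 64) {
  f <- seq(chirp$f_start, chirp$f_end, length.out = n_grid)
  att <- base_db + gain_offset_db + smooth_wiggle(f, wiggle_sd_db)
  transmission_profile(f, pmax(att, 0), "HEALTHY_BASELINE")
}

#' ACS-like transmission profile
#'
#' Takes a subject's healthy baseline and adds the extra attenuation caused
#' by an infiltrate: a mean level `extra_db` with smooth frequency
#' variation, floored so the loss relative to baseline is never less than
#' `min_extra_db` at any frequency. The wiggle is mean-centered before
#' flooring so the band-average extra attenuation equals `extra_db`.
#'
#' @param baseline a `HEALTHY_BASELINE` [transmission_profile()]
#' @param extra_db mean extra attenuation in dB
#' @param wiggle_sd_db standard deviation of the smooth variation in dB
#' @param min_extra_db hard floor on the extra attenuation in dB
#' @return an `ACS_LIKE` [transmission_profile()] on the baseline's grid
#' @export
acs_profile <- function(baseline, extra_db, wiggle_sd_db = 1.5,
                        min_extra_db = 5) {
  stopifnot(inherits(baseline, "transmission_profile"))
  f <- baseline$frequencies
  extra <- pmax(extra_db + smooth_wiggle(f, wiggle_sd_db), min_extra_db)
  transmission_profile(f, baseline$attenuation_db + extra, "ACS_LIKE")
}

#' Apply a transmission profile to a recording
#'
#' Filters the waveform so that its spectral magnitude at frequency f is
#' scaled by `10^(-attenuation_db(f) / 20)`. Implemented as a zero-phase
#' frequency-domain multiply: the full-length FFT of the waveform is scaled
#' bin-by-bin by the attenuation interpolated at the bin frequency
#' (constant extrapolation beyond the profile grid) and inverted. A flat
#' 0 dB profile reproduces the input to within numerical round-off.
#'
#' @param rec a [recording()]
#' @param profile a [transmission_profile()]; its grid must cover the chirp
#'   frequency span
#' @param chirp the [chirp_spec()] whose span the profile must cover
#' @return a [recording()] of the same length, with `true_label` preserved
#' @export
apply_transmission <- function(rec, profile, chirp = chirp_spec()) {
  stopifnot(inherits(rec, "recording"),
            inherits(profile, "transmission_profile"))
  fr <- range(profile$frequencies)
  if (fr[1] > chirp$f_start || fr[2] < chirp$f_end) {
    stop(sprintf(
      "transmission profile grid [%g, %g] Hz does not cover the chirp span [%g, %g] Hz",
      fr[1], fr[2], chirp$f_start, chirp$f_end), call. = FALSE)
  }
  n <- length(rec$samples)
  bin_f <- (seq_len(n) - 1) / n * rec$sample_rate
  bin_f <- pmin(bin_f, rec$sample_rate - bin_f)  # fold to [0, Nyquist]
  att <- stats::approx(profile$frequencies, profile$attenuation_db,
                       xout = bin_f, rule = 2)$y
  spec <- stats::fft(rec$samples) * db_to_amp(-att)
  out <- Re(stats::fft(spec, inverse = TRUE)) / n
  recording(pmin(pmax(out, -1), 1), rec$sample_rate,
            subject_id = rec$subject_id, location = rec$location,
            true_label = rec$true_label)
}

#' Add Gaussian measurement noise to a recording
#'
#' Adds zero-mean white Gaussian noise with RMS equal to
#' `ref_amplitude * 10^(noise_db / 20)`, i.e. a noise floor specified in dB
#' relative to the chirp input amplitude (so the same absolute noise level
#' applies whether or not the signal was attenuated). `noise_db = -Inf`
#' switches the noise off. Samples are clipped to \[-1, 1\] with a warning
#' if clipping occurs.
#'
#' @param rec a [recording()]
#' @param noise_db noise floor in dB relative to `ref_amplitude` (<= 0)
#' @param seed optional integer; given the same seed the output is
#'   bit-identical
#' @param ref_amplitude reference amplitude; defaults to the chirp default
#' @return a [recording()]
#' @export
add_noise <- function(rec, noise_db, seed = NULL, ref_amplitude = 0.5) {
  stopifnot(inherits(rec, "recording"))
  check_that(noise_db <= 0, "noise_db",
             "must be <= 0 (relative to the chirp amplitude)")
  if (identical(noise_db, -Inf)) return(rec)
  sd_noise <- ref_amplitude * db_to_amp(noise_db)
  noise <- with_local_seed(seed, stats::rnorm(length(rec$samples), 0, sd_noise))
  out <- rec$samples + noise
  if (any(out < -1 | out > 1)) {
    warning(sprintf("%d samples clipped to [-1, 1] after noise addition",
                    sum(out < -1 | out > 1)))
    out <- pmin(pmax(out, -1), 1)
  }
  recording(out, rec$sample_rate, subject_id = rec$subject_id,
            location = rec$location, true_label = rec$true_label)
}
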
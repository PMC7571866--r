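#' Short-time Fourier spectrogram of a recording
#'
#' Divides the waveform into Hamming-windowed `window_len`-point blocks
#' whose start indices advance by `hop` samples, and takes the magnitude of
#' the one-sided FFT of each block. With the defaults (256-point window,
#' hop 512) a 14-s recording at 4 kHz yields exactly 109 evenly spaced
#' frames of 129 one-sided bins spaced 15.625 Hz apart. The hop exceeds the
#' window, i.e. blocks are non-overlapping with a gap; this is the only
#' integer hop that places 109 evenly spaced 256-point frames across 56,000
#' samples.
#'
#' @param rec a [recording()]
#' @param window_len analysis window length in samples
#' @param hop advance between block start indices in samples
#' @return an object of class `spectrogram`: list with `magnitudes`
#'   (frames x bins), `frame_times` (s, window centers), `bin_freqs` (Hz)
#' @examples
#' sg <- compute_spectrogram(generate_chirp(chirp_spec()))
#' dim(sg$magnitudes)  # 109 x 129
#' @export
compute_spectrogram <- function(rec, window_len = 256, hop = 512) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  if (n < window_len) {
    stop(sprintf("recording of %d samples is shorter than one %d-sample window",
                 n, window_len), call. = FALSE)
  }
  win <- signal::hamming(window_len)
  starts <- seq(1, n - window_len + 1, by = hop)
  frames <- vapply(starts, function(s) {
    rec$samples[s:(s + window_len - 1)] * win
  }, numeric(window_len))
  spec <- stats::mvfft(frames)                       # window_len x n_frames
  n_bins <- window_len %/% 2 + 1
  magnitudes <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(
    list(magnitudes = magnitudes,
         frame_times = (starts - 1 + (window_len - 1) / 2) / rec$sample_rate,
         bin_freqs = (seq_len(n_bins) - 1) * rec$sample_rate / window_len),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d frames x %d bins (%.3f Hz spacing)\n",
              nrow(x$magnitudes), ncol(x$magnitudes), diff(x$bin_freqs[1:2])))
  invisible(x)
}

#' Chirp-tracking band-average intensity profile
#'
#' The core measurement of the analysis: a moving frequency-band average of
#' the spectrogram whose center tracks the instantaneous chirp frequency.
#' For each frame, the magnitudes of all bins whose center frequency lies
#' within `band_halfwidth` Hz (closed interval) of the chirp frequency at
#' the frame's center time are averaged and converted to dB. The +/-20 Hz
#' default captures spectral leakage of the nonstationary chirp into
#' adjacent bins; at 15.625 Hz bin spacing it admits 2-3 bins per frame.
#'
#' @param spec_gram a [compute_spectrogram()] result
#' @param chirp the [chirp_spec()] describing the input sweep
#' @param band_halfwidth half-width of the moving band in Hz
#' @param db_floor magnitudes are clamped to this before the log, so silent
#'   frames give a finite dB value
#' @return an object of class `intensity_profile`: `chirp_freqs` (Hz, one
#'   per frame), `intensity_db`, `band_halfwidth`; the attribute
#'   `n_floored` counts frames where the floor was applied
#' @export
chirp_band_intensity <- function(spec_gram, chirp = chirp_spec(),
                                 band_halfwidth = 20, db_floor = DB_FLOOR) {
  stopifnot(inherits(spec_gram, "spectrogram"))
  if (chirp$f_start < min(spec_gram$bin_freqs) ||
      chirp$f_end > max(spec_gram$bin_freqs)) {
    stop("chirp frequency span exceeds the spectrogram's bin range",
         call. = FALSE)
  }
  fc <- chirp_frequency(chirp, spec_gram$frame_times)
  band_mean <- vapply(seq_along(fc), function(i) {
    in_band <- abs(spec_gram$bin_freqs - fc[i]) <= band_halfwidth
    if (!any(in_band)) {
      stop(sprintf("no spectrogram bins within +/-%g Hz of %g Hz",
                   band_halfwidth, fc[i]), call. = FALSE)
    }
    mean(spec_gram$magnitudes[i, in_band])
  }, numeric(1))
  structure(
    list(chirp_freqs = fc,
         intensity_db = amp_to_db(band_mean, db_floor),
         band_halfwidth = band_halfwidth),
    class = "intensity_profile",
    n_floored = sum(band_mean < db_floor)
  )
}

#' Intensity profile of a recording in one call
#'
#' Convenience wrapper: spectrogram then band tracking.
#'
#' @inheritParams compute_spectrogram
#' @inheritParams chirp_band_intensity
#' @export
intensity_profile <- function(rec, chirp = chirp_spec(), window_len = 256,
                              hop = 512, band_halfwidth = 20) {
  chirp_band_intensity(compute_spectrogram(rec, window_len, hop),
                       chirp, band_halfwidth)
}

#' Group mean and standard-error intensity curve
#'
#' Averages intensity profiles across a group of recordings. By default
#' each profile is first converted to dB and the mean and standard error of
#' the mean (sample SD / sqrt(n)) are taken per frequency in the dB domain,
#' which yields symmetric error bands; averaging of the linear band
#' magnitudes before the dB conversion is available via `domain =
#' "linear"` (SEM then mapped to dB by the delta method).
#'
#' @param profiles list of [chirp_band_intensity()] results sharing one
#'   frequency grid
#' @param domain `"db"` (default) or `"linear"`
#' @return an object of class `group_curve`: `chirp_freqs`, `mean_db`,
#'   `sem_db`, `n`
#' @export
group_average_curve <- function(profiles, domain = c("db", "linear")) {
  domain <- match.arg(domain)
  n <- length(profiles)
  if (n < 2) stop("a group curve needs at least 2 profiles", call. = FALSE)
  grid <- profiles[[1]]$chirp_freqs
  for (p in profiles) {
    if (length(p$chirp_freqs) != length(grid) ||
        max(abs(p$chirp_freqs - grid)) > 1e-9) {
      stop("profiles do not share a common frequency grid", call. = FALSE)
    }
  }
  db_mat <- do.call(rbind, lapply(profiles, `[[`, "intensity_db"))
  if (domain == "db") {
    mean_db <- colMeans(db_mat)
    sem_db <- apply(db_mat, 2, stats::sd) / sqrt(n)
  } else {
    lin <- db_to_amp(db_mat)
    m <- colMeans(lin)
    sem_lin <- apply(lin, 2, stats::sd) / sqrt(n)
    mean_db <- amp_to_db(m)
    sem_db <- 20 / log(10) * sem_lin / m
  }
  structure(
    list(chirp_freqs = grid, mean_db = mean_db, sem_db = sem_db, n = n),
    class = "group_curve"
  )
}

#' Healthy-minus-pathological group difference in dB
#'
#' The per-frequency difference between two group curves, plus its mean and
#' minimum over the chirp span. A large, strictly positive difference
#' (healthy minus ACS) is the acoustic signature of consolidation.
#'
#' @param healthy,acs [group_average_curve()] results on the same grid
#' @return list with `chirp_freqs`, `difference_db` (per frequency),
#'   `mean_db`, `min_db`
#' @export
group_difference <- function(healthy, acs) {
  stopifnot(inherits(healthy, "group_curve"), inherits(acs, "group_curve"))
  if (length(healthy$chirp_freqs) != length(acs$chirp_freqs) ||
      max(abs(healthy$chirp_freqs - acs$chirp_freqs)) > 1e-9) {
    stop("group curves are on different frequency grids", call. = FALSE)
  }
  d <- healthy$mean_db - acs$mean_db
  list(chirp_freqs = healthy$chirp_freqs, difference_db = d,
       mean_db = mean(d), min_db = min(d))
}

#' Plot group intensity curves
#'
#' Mean +/- 1 SEM per group against chirp frequency, in the style used for
#' comparing healthy and pathological transmission.
#'
#' @param curves named list of [group_average_curve()] results
#' @param main plot title
#' @export
plot_group_curves <- function(curves, main = "Sound transmission intensity") {
  stopifnot(length(curves) >= 1)
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 2")
  ylim <- range(unlist(lapply(curves, function(g)
    c(g$mean_db - g$sem_db, g$mean_db + g$sem_db))))
  graphics::plot(NULL, xlim = range(curves[[1]]$chirp_freqs), ylim = ylim,
                 xlab = "Chirp frequency (Hz)", ylab = "Intensity (dB)",
                 main = main)
  for (i in seq_along(curves)) {
    g <- curves[[i]]
    graphics::polygon(c(g$chirp_freqs, rev(g$chirp_freqs)),
                      c(g$mean_db - g$sem_db, rev(g$mean_db + g$sem_db)),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(g$chirp_freqs, g$mean_db, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(curves), col = cols,
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Write an intensity profile or group curve as CSV
#'
#' @param x an `intensity_profile` or `group_curve`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_curve_csv <- function(x, path) {
  df <- if (inherits(x, "intensity_profile")) {
    data.frame(chirp_freq_hz = x$chirp_freqs, intensity_db = x$intensity_db)
  } else if (inherits(x, "group_curve")) {
    data.frame(chirp_freq_hz = x$chirp_freqs, mean_db = x$mean_db,
               sem_db = x$sem_db, n = x$n)
  } else {
    stop("x must be an intensity_profile or group_curve", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
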
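# 20-dimensional acoustic feature set: 8 distributional statistics of the
# dB intensity profile + 12 MFCCs of the raw waveform. The split follows
# the natural reading of the protocol: moments and quantiles summarize the
# transmission curve, MFCCs the audio spectral envelope.

#' Names of the 20 features, in canonical column order
#' @export
FEATURE_NAMES <- c("mean", "median", "std", "q25", "q50", "q75",
                   "skewness", "kurtosis", paste0("mfcc_", 1:12))

#' Distributional statistics of an intensity profile
#'
#' Eight statistics of the dB intensity values: mean, median, sample
#' standard deviation (n-1), the 25/50/75% quantiles (linear-interpolation
#' convention), Fisher skewness and excess kurtosis (no small-sample bias
#' correction; both defined as 0 for a constant profile). `q50` duplicates
#' the median by construction and is retained so the feature count is
#' exactly 20.
#'
#' @param profile a [chirp_band_intensity()] result
#' @return named numeric vector of length 8
#' @export
extract_statistical_features <- function(profile) {
  x <- profile$intensity_db
  if (length(x) == 0 || !all(is.finite(x))) {
    stop("intensity profile must be non-empty and finite", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (stats::sd(x) == 0) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- e1071::skewness(x, type = 1)
    kurt <- e1071::kurtosis(x, type = 1)
  }
  c(mean = mean(x), median = stats::median(x), std = stats::sd(x),
    q25 = q[1], q50 = q[2], q75 = q[3], skewness = skew, kurtosis = kurt)
}

# mel <-> Hz (HTK convention)
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank evaluated at the FFT bin frequencies.
# Returns an n_filters x n_bins weight matrix.
mel_filterbank <- function(n_filters, n_bins, sample_rate, nfft,
                           f_min, f_max) {
  edges <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max),
                         length.out = n_filters + 2))
  bin_f <- (seq_len(n_bins) - 1) * sample_rate / nfft
  fb <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; mid <- edges[m + 1]; hi <- edges[m + 2]
    up <- (bin_f - lo) / (mid - lo)
    down <- (hi - bin_f) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in)
dct2_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  j <- seq_len(n_in) - 1
  m <- sqrt(2 / n_in) * cos(pi * outer(k, j + 0.5) / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Mel-frequency cepstral coefficients of a recording
#'
#' Standard MFCC pipeline: the waveform is framed (25 ms Hamming windows,
#' 10 ms hop), each frame's one-sided power spectrum is pooled by a
#' 26-filter triangular mel filterbank spanning 0-2000 Hz, log-compressed
#' (floored so silence stays finite), and decorrelated by an orthonormal
#' DCT-II. Coefficients 1-12 are kept (the 0th, which carries overall gain,
#' is excluded) and averaged across frames, so a global gain change leaves
#' all returned coefficients untouched.
#'
#' @param rec a [recording()]
#' @param n_coeffs number of coefficients to keep (excluding the 0th)
#' @param frame_ms,hop_ms frame length and hop in milliseconds
#' @param n_filters number of mel filters
#' @param f_min,f_max filterbank span in Hz (`f_max = NULL` means Nyquist)
#' @return named numeric vector `mfcc_1` ... `mfcc_<n_coeffs>`
#' @export
extract_mfcc <- function(rec, n_coeffs = 12, frame_ms = 25, hop_ms = 10,
                         n_filters = 26, f_min = 0, f_max = NULL) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate
  if (is.null(f_max)) f_max <- fs / 2
  frame_len <- round(frame_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  n <- length(rec$samples)
  if (n < frame_len) {
    stop(sprintf("recording of %d samples is shorter than one %d-sample MFCC frame",
                 n, frame_len), call. = FALSE)
  }
  nfft <- 2^ceiling(log2(frame_len))
  n_bins <- nfft %/% 2 + 1
  win <- signal::hamming(frame_len)
  starts <- seq(1, n - frame_len + 1, by = hop)
  frames <- vapply(starts, function(s) {
    c(rec$samples[s:(s + frame_len - 1)] * win, numeric(nfft - frame_len))
  }, numeric(nfft))
  power <- Mod(stats::mvfft(frames)[seq_len(n_bins), , drop = FALSE])^2
  fb <- mel_filterbank(n_filters, n_bins, fs, nfft, f_min, f_max)
  log_energy <- log(pmax(fb %*% power, 1e-20))   # n_filters x n_frames
  dct <- dct2_matrix(n_coeffs + 1, n_filters)
  cep <- dct %*% log_energy
  out <- rowMeans(cep)[-1]                        # drop the gain-carrying c0
  stats::setNames(out, paste0("mfcc_", seq_len(n_coeffs)))
}

#' Assemble the feature table
#'
#' One row per observation: identifiers, label, then the 20 features in the
#' canonical order of [FEATURE_NAMES] (8 intensity-profile statistics
#' followed by 12 MFCCs). Row order follows input order.
#'
#' @param recordings list of [recording()]s (MFCC source)
#' @param profiles list of matching [chirp_band_intensity()] results
#'   (statistics source)
#' @param labels character vector of observation labels
#' @return data.frame with columns observation_id, subject_id, location,
#'   label, then the 20 features
#' @export
build_feature_table <- function(recordings, profiles, labels) {
  n <- length(recordings)
  if (length(profiles) != n || length(labels) != n) {
    stop(sprintf("length mismatch: %d recordings, %d profiles, %d labels",
                 n, length(profiles), length(labels)), call. = FALSE)
  }
  empty <- data.frame(observation_id = character(), subject_id = character(),
                      location = character(), label = character(),
                      stringsAsFactors = FALSE)
  for (f in FEATURE_NAMES) empty[[f]] <- numeric()
  if (n == 0) return(empty)
  rows <- lapply(seq_len(n), function(i) {
    feats <- c(extract_statistical_features(profiles[[i]]),
               extract_mfcc(recordings[[i]]))
    stopifnot(identical(names(feats), FEATURE_NAMES))
    cbind(
      data.frame(observation_id = sprintf("obs%03d", i),
                 subject_id = recordings[[i]]$subject_id,
                 location = recordings[[i]]$location,
                 label = labels[i], stringsAsFactors = FALSE),
      as.data.frame(as.list(feats))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature table for a whole cohort
#'
#' Runs the spectral pipeline on every recording and assembles the feature
#' table, using the metadata's `true_label` column as the label.
#'
#' @param cohort result of [generate_cohort()] or [read_cohort()]
#' @param chirp the [chirp_spec()] of the percussive input
#' @inheritParams chirp_band_intensity
#' @return data.frame as [build_feature_table()]
#' @export
cohort_feature_table <- function(cohort, chirp = chirp_spec(),
                                 band_halfwidth = 20) {
  profiles <- lapply(cohort$recordings, intensity_profile, chirp = chirp,
                     band_halfwidth = band_halfwidth)
  build_feature_table(cohort$recordings, profiles,
                      cohort$metadata$true_label)
}
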
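#' Chirp specification
#'
#' Parameters of the percussive input: a sinusoid whose instantaneous
#' frequency increases linearly with time, introduced at the sternum and
#' recorded at the posterior chest. The defaults describe the standard
#' protocol: 100 to 1000 Hz over 14 s, sampled at 4 kHz.
#'
#' @param f_start start frequency in Hz (> 0)
#' @param f_end end frequency in Hz (> f_start, at most Nyquist)
#' @param duration sweep duration in seconds (> 0)
#' @param sample_rate sampling rate in samples/second
#' @param amplitude peak amplitude as a full-scale fraction in (0, 1]
#' @return an object of class `chirp_spec`
#' @examples
#' spec <- chirp_spec()
#' chirp_frequency(spec, t = 7)  # 550 Hz, the linear midpoint
#' @export
chirp_spec <- function(f_start = 100, f_end = 1000, duration = 14,
                       sample_rate = 4000, amplitude = 0.5) {
  check_that(is.numeric(f_start) && f_start > 0, "f_start", "must be > 0")
  check_that(is.numeric(f_end) && f_end > f_start, "f_end",
             "must exceed f_start")
  check_that(f_end <= sample_rate / 2, "f_end",
             sprintf("must not exceed the Nyquist frequency %g Hz",
                     sample_rate / 2))
  check_that(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  check_that(is.numeric(sample_rate) && sample_rate > 0, "sample_rate",
             "must be > 0")
  check_that(is.numeric(amplitude) && amplitude > 0 && amplitude <= 1,
             "amplitude", "must be in (0, 1]")
  structure(
    list(f_start = f_start, f_end = f_end, duration = duration,
         sample_rate = sample_rate, amplitude = amplitude),
    class = "chirp_spec"
  )
}

#' @export
print.chirp_spec <- function(x, ...) {
  cat(sprintf("Linear chirp: %g -> %g Hz over %g s at %g Hz (amplitude %g)\n",
              x$f_start, x$f_end, x$duration, x$sample_rate, x$amplitude))
  invisible(x)
}

#' Instantaneous chirp frequency
#'
#' @param spec a [chirp_spec()]
#' @param t time(s) in seconds from the start of the sweep
#' @return `f_start + (f_end - f_start) * t / duration`, in Hz
#' @export
chirp_frequency <- function(spec, t) {
  spec$f_start + (spec$f_end - spec$f_start) * t / spec$duration
}

#' Generate a chirp waveform
#'
#' Synthesizes the percussive input as `amplitude * sin(2 * pi * phi(t))`
#' where the phase `phi` is the exact integral of the linear frequency ramp
#' (quadratic in time), not a stepped approximation.
#'
#' @param spec a [chirp_spec()]
#' @param subject_id,location,true_label provenance fields attached to the
#'   returned [recording()]
#' @return a [recording()] of length `round(duration * sample_rate)` samples
#' @examples
#' rec <- generate_chirp(chirp_spec())
#' length(rec$samples)  # 56000
#' @export
generate_chirp <- function(spec, subject_id = "chirp", location = "PBR",
                           true_label = "unknown") {
  stopifnot(inherits(spec, "chirp_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  k <- (spec$f_end - spec$f_start) / spec$duration   # sweep rate, Hz/s
  phase <- spec$f_start * t + 0.5 * k * t^2          # integral of f(t)
  samples <- spec$amplitude * sin(2 * pi * phase)
  recording(samples, spec$sample_rate, subject_id = subject_id,
            location = location, true_label = true_label)
}

#' Recording container
#'
#' One subject-by-location waveform plus provenance metadata.
#'
#' @param samples mono waveform as full-scale fractions in \[-1, 1\]
#' @param sample_rate samples per second
#' @param subject_id subject identifier
#' @param location one of the six posterior sites `PAL`, `PAR`, `PML`,
#'   `PMR`, `PBL`, `PBR` (posterior apex / middle / basal, left / right)
#' @param true_label one of `healthy`, `acs`, `voc_uncomplicated`,
#'   `voc_complicated`, or `unknown`
#' @return an object of class `recording`
#' @export
recording <- function(samples, sample_rate, subject_id = "unknown",
                      location = "PBR", true_label = "unknown") {
  check_that(is.numeric(samples) && length(samples) > 0, "samples",
             "must be a non-empty numeric vector")
  check_that(all(is.finite(samples)), "samples", "must be finite")
  check_that(max(abs(samples)) <= 1 + 1e-9, "samples",
             "must lie in [-1, 1]")
  check_that(location %in% POSTERIOR_LOCATIONS, "location",
             paste("must be one of", paste(POSTERIOR_LOCATIONS, collapse = ", ")))
  check_that(true_label %in% c(STUDY_LABELS, "unknown"), "true_label",
             paste("must be one of", paste(c(STUDY_LABELS, "unknown"), collapse = ", ")))
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         subject_id = subject_id, location = location,
         true_label = true_label),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording %s @ %s: %d samples at %g Hz (%.2f s), label %s\n",
              x$subject_id, x$location, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$true_label))
  invisible(x)
}

#' The six posterior recording sites
#'
#' Posterior apex, middle and basal lobes, left and right.
#' @export
POSTERIOR_LOCATIONS <- c("PAL", "PAR", "PML", "PMR", "PBL", "PBR")

#' Observation labels used throughout the package
#' @export
STUDY_LABELS <- c("healthy", "acs", "voc_uncomplicated", "voc_complicated")
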
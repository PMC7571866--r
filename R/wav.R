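# Minimal canonical RIFF/WAVE I/O, PCM 16-bit mono. Covers exactly the
# interchange format this package emits; not a general WAV library.

#' Write a recording as a 16-bit PCM mono WAV file
#'
#' @param rec a [recording()]; samples are quantized from \[-1, 1\] to
#'   signed 16-bit integers
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  pcm <- as.integer(round(pmin(pmax(rec$samples, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  sr <- as.integer(rec$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path; must be PCM, 16-bit, mono
#' @return a [recording()] with samples rescaled to \[-1, 1\]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop(path, ": not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop(path, ": not a WAVE file", call. = FALSE)

  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop(path, ": only PCM WAV is supported", call. = FALSE)
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop(path, ": data chunk before fmt", call. = FALSE)
      if (bits != 16L) stop(path, ": only 16-bit WAV is supported", call. = FALSE)
      if (n_channels != 1L) stop(path, ": only mono WAV is supported", call. = FALSE)
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (padded)
    }
  }
  if (is.null(samples)) stop(path, ": no data chunk found", call. = FALSE)
  recording(samples / 32767, sample_rate)
}
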
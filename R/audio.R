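#' Write a mono waveform as 16-bit PCM RIFF/WAVE
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped. Quantization
#' rounds to the nearest 16-bit integer, so writing and re-reading a quantized
#' waveform is lossless.
#'
#' @param wave numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param fs sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs = 16000L) {
  if (!is.numeric(wave) || length(wave) < 1L) stop("`wave` must be a non-empty numeric vector")
  pcm <- as.integer(round(pmax(pmin(wave, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM RIFF/WAVE file (mono)
#'
#' @param path file path.
#' @return list with `wave` (numeric in `[-1, 1]`) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave_id <- readChar(con, 4)
  if (!identical(wave_id, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (sz > 16L) invisible(readBin(con, raw(), sz - 16L))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), sz / 2L, size = 2, endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!identical(bits, 16L)) stop("only 16-bit PCM supported")
  if (!identical(channels, 1L)) stop("only mono supported")
  list(wave = samples / 32767, fs = fs)
}

#' Write a phonetic transcript in .PHN format
#'
#' One line per interval: `start_sample end_sample label`, half-open sample
#' intervals `[start, end)`, 0-based.
#'
#' @param transcript data frame with columns `start`, `end`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phn <- function(transcript, path) {
  stopifnot(all(c("start", "end", "label") %in% names(transcript)))
  writeLines(sprintf("%d %d %s", transcript$start, transcript$end, transcript$label), path)
  invisible(path)
}

#' Read a .PHN phonetic transcript
#'
#' @param path file path.
#' @return data frame with columns `start`, `end`, `label`.
#' @export
read_phn <- function(path) {
  x <- read.table(path, header = FALSE, col.names = c("start", "end", "label"),
                  colClasses = c("integer", "integer", "character"))
  validate_transcript(x)
  x
}

# check the transcript invariants: sorted, non-overlapping, tiling
validate_transcript <- function(transcript, n_samples = NULL) {
  stopifnot(all(c("start", "end", "label") %in% names(transcript)))
  if (any(transcript$end <= transcript$start)) stop("transcript has empty or inverted intervals")
  if (is.unsorted(transcript$start, strictly = TRUE)) stop("transcript intervals not sorted")
  if (nrow(transcript) > 1L &&
      any(transcript$start[-1L] != transcript$end[-nrow(transcript)])) {
    stop("transcript intervals do not tile the waveform")
  }
  if (!is.null(n_samples) && transcript$end[nrow(transcript)] != n_samples) {
    stop("transcript does not cover the waveform")
  }
  invisible(transcript)
}
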
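# Cochlear front end: gammatone filterbank and cochleogram extraction.
#
# The default configuration mirrors the modelling convention for speech:
# 194 channels with center frequencies from 73 to 7630 Hz on an ERB-rate
# scale, envelopes sampled every 1 ms.

# ERB-rate scale (Glasberg & Moore): number of ERBs below frequency f (Hz)
hz_to_erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_rate_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth  <- function(f) 24.7 * (1 + 0.00437 * f)

#' Build a gammatone filterbank
#'
#' Center frequencies are spaced uniformly on the ERB-rate scale between
#' `f_lo` and `f_hi` (both included). Filters are 4th-order gammatones with
#' bandwidths proportional to the equivalent rectangular bandwidth (ERB) at
#' each center frequency.
#'
#' @param n_channels number of filters (default 194).
#' @param f_lo,f_hi lowest and highest center frequency in Hz (defaults 73 and
#'   7630).
#' @param fs sample rate in Hz (default 16000).
#' @return an object of class `"filterbank"`: list with `n_channels`,
#'   `center_freqs`, `bandwidths`, `fs`.
#' @export
#' @examples
#' fb <- build_filterbank(194, 73, 7630, 16000)
#' range(fb$center_freqs)
build_filterbank <- function(n_channels = 194L, f_lo = 73, f_hi = 7630, fs = 16000L) {
  stopifnot_scalar_int(n_channels, "n_channels", min = 2L)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= fs / 2) stop("f_hi must be below the Nyquist frequency fs/2", call. = FALSE)
  cf <- erb_rate_to_hz(seq(hz_to_erb_rate(f_lo), hz_to_erb_rate(f_hi),
                           length.out = n_channels))
  cf[1L] <- f_lo; cf[n_channels] <- f_hi  # pin endpoints against rounding
  structure(
    list(n_channels = as.integer(n_channels), center_freqs = cf,
         bandwidths = erb_bandwidth(cf), fs = as.integer(fs)),
    class = "filterbank"
  )
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("gammatone filterbank: %d channels, %.0f-%.0f Hz, fs = %d Hz\n",
              x$n_channels, x$center_freqs[1], x$center_freqs[x$n_channels], x$fs))
  invisible(x)
}

# 4th-order gammatone impulse response for one channel, truncated FIR
gammatone_ir <- function(cf, bw, fs, n_taps = 2048L) {
  t <- (seq_len(n_taps) - 1) / fs
  b <- 1.019 * bw
  ir <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  ir / sqrt(sum(ir^2))  # unit-energy normalization
}

# filter a waveform with every channel of the bank (FFT overlap-free: one
# big FFT per signal, one inverse per channel)
apply_filterbank <- function(wave, fb, n_taps = 2048L) {
  n <- length(wave)
  nfft <- 2^ceiling(log2(n + n_taps - 1L))
  wf <- fft(c(wave, numeric(nfft - n)))
  out <- matrix(0, fb$n_channels, n)
  for (c in seq_len(fb$n_channels)) {
    ir <- gammatone_ir(fb$center_freqs[c], fb$bandwidths[c], fb$fs, n_taps)
    irf <- fft(c(ir, numeric(nfft - n_taps)))
    y <- Re(fft(wf * irf, inverse = TRUE)) / nfft
    out[c, ] <- y[seq_len(n)]
  }
  out
}

#' Compute a cochleogram
#'
#' Converts a waveform into a channels-by-frames matrix of filterbank
#' envelope energies. Per channel the signal is bandpass filtered
#' (gammatone), half-wave rectified, smoothed with a 2nd-order Butterworth
#' lowpass (100 Hz), and sampled every `frame_step` milliseconds.
#'
#' @param wave numeric waveform.
#' @param filterbank a [build_filterbank()] object.
#' @param frame_step frame step in ms (default 1).
#' @param compress apply `log1p` compression to the energies (default FALSE;
#'   raw envelopes are the default because the downstream model is agnostic to
#'   the front-end's output scale).
#' @return object of class `"cochleogram"`: list with `energy`
#'   (channels x frames, non-negative), `frame_step` (ms), `center_freqs`,
#'   `fs`.
#' @export
cochleogram <- function(wave, filterbank, frame_step = 1, compress = FALSE) {
  if (length(wave) == 0L) stop("empty waveform", call. = FALSE)
  fb <- filterbank
  stopifnot(inherits(fb, "filterbank"))
  duration_ms <- length(wave) / fb$fs * 1000
  n_frames <- floor(duration_ms / frame_step)
  if (n_frames < 1L) stop("waveform shorter than one frame", call. = FALSE)
  bp <- apply_filterbank(wave, fb)
  bp[bp < 0] <- 0  # half-wave rectification
  lp <- signal::butter(2, 100 / (fb$fs / 2), type = "low")
  step_samples <- fb$fs * frame_step / 1000
  idx <- floor((seq_len(n_frames) - 1) * step_samples) + 1L
  energy <- matrix(0, fb$n_channels, n_frames)
  for (c in seq_len(fb$n_channels)) {
    env <- signal::filter(lp, bp[c, ])
    energy[c, ] <- env[idx]
  }
  energy[energy < 0] <- 0  # Butterworth undershoot guard: energies stay >= 0
  if (compress) energy <- log1p(energy)
  structure(
    list(energy = energy, frame_step = frame_step,
         center_freqs = fb$center_freqs, fs = fb$fs),
    class = "cochleogram"
  )
}

#' @export
print.cochleogram <- function(x, ...) {
  cat(sprintf("cochleogram: %d channels x %d frames (%.3g ms step)\n",
              nrow(x$energy), ncol(x$energy), x$frame_step))
  invisible(x)
}

#' @export
plot.cochleogram <- function(x, ...) {
  graphics::image(t(x$energy), xlab = "time (frames)", ylab = "channel",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Write / read a cochleogram as TSV
#'
#' The matrix is stored channels-by-frames with a header of metadata lines
#' (`# frame_step`, `# fs`, `# center_freqs`).
#'
#' @param x a cochleogram.
#' @param path file path.
#' @return `path` (write) or a cochleogram (read).
#' @export
write_cochleogram <- function(x, path) {
  stopifnot(inherits(x, "cochleogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_step\t%.17g", x$frame_step),
               sprintf("# fs\t%d", x$fs),
               paste0("# center_freqs\t",
                      paste(sprintf("%.17g", x$center_freqs), collapse = "\t"))), con)
  write.table(x$energy, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cochleogram
#' @export
read_cochleogram <- function(path) {
  hdr <- readLines(path, n = 3L)
  frame_step <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  fs <- as.integer(strsplit(hdr[2], "\t")[[1]][2])
  cf <- as.numeric(strsplit(hdr[3], "\t")[[1]][-1])
  energy <- as.matrix(read.table(path, skip = 3L, sep = "\t"))
  dimnames(energy) <- NULL
  structure(list(energy = energy, frame_step = frame_step,
                 center_freqs = cf, fs = fs),
            class = "cochleogram")
}
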
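# Seeded generator of formant-synthesized labelled speech with ground-truth
# acoustic parameters. Stands in for a licensed phonetically transcribed
# corpus: continuous speech as a sequence of labelled phoneme tokens drawn
# from an inventory with class-specific acoustic structure.

#' Build a phoneme inventory
#'
#' Draws `n_phonemes` phoneme specifications split over four classes
#' (`vowel`, `plosive`, `fricative`, `nasal`). Voiced classes get a
#' fundamental frequency and F1/F2 formant contours (linear trajectories with
#' class-typical ranges, slopes varied across phonemes so that contour
#' dynamics differ between phonemes); plosives get a voice-onset time and a
#' burst spectral peak; fricatives get a noise spectral peak.
#'
#' @param n_phonemes inventory size (default 33); at least one per requested
#'   class.
#' @param class_mix named proportions over the four classes, summing to 1.
#' @param seed integer seed; the inventory is deterministic given the seed.
#' @return list of `"phoneme_spec"` lists with fields `label`, `class`, `f0`,
#'   `f1_contour`, `f2_contour` (Hz, over normalized token time), `vot` (s),
#'   `spectral_peak` (Hz), `duration_range` (s); class `"phoneme_inventory"`.
#' @export
#' @examples
#' inv <- make_inventory(12, seed = 1)
#' table(vapply(inv, `[[`, "", "class"))
make_inventory <- function(n_phonemes = 33L,
                           class_mix = c(vowel = 0.4, plosive = 0.2,
                                         fricative = 0.2, nasal = 0.2),
                           seed = 1L) {
  classes <- c("vowel", "plosive", "fricative", "nasal")
  if (!all(names(class_mix) %in% classes)) stop("unknown class in `class_mix`")
  class_mix <- class_mix[class_mix > 0]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("`class_mix` proportions must sum to 1")
  if (n_phonemes < length(class_mix)) {
    stop("`n_phonemes` smaller than the number of requested classes", call. = FALSE)
  }
  # largest-remainder allocation with at least one per class
  raw <- class_mix * n_phonemes
  counts <- pmax(floor(raw), 1)
  while (sum(counts) < n_phonemes) {
    i <- which.max(raw - counts); counts[i] <- counts[i] + 1
  }
  while (sum(counts) > n_phonemes) {
    i <- which.max(counts - raw); counts[i] <- counts[i] - 1
  }
  with_seed(seed, {
    inv <- list()
    for (cl in names(counts)) {
      for (i in seq_len(counts[[cl]])) {
        inv[[length(inv) + 1L]] <- draw_phoneme_spec(cl, i)
      }
    }
    inv
  }) -> inv
  structure(inv, class = "phoneme_inventory")
}

# one random phoneme specification of a given class
draw_phoneme_spec <- function(class, index) {
  tpts <- seq(0, 1, length.out = 21L)
  spec <- switch(class,
    vowel = {
      f0 <- runif(1, 90, 220)
      f1a <- runif(1, 300, 850); f1b <- f1a + runif(1, -250, 250)
      f1b <- min(max(f1b, 280), 900)
      f2a <- runif(1, max(1000, f1a + 400), 2400)
      f2b <- f2a + runif(1, -500, 500)
      f2b <- min(max(f2b, f1b + 350), 2600)
      list(f0 = f0,
           f1_contour = f1a + (f1b - f1a) * tpts,
           f2_contour = f2a + (f2b - f2a) * tpts,
           vot = NA_real_, spectral_peak = NA_real_,
           duration_range = c(0.08, 0.16))
    },
    nasal = {
      f0 <- runif(1, 90, 220)
      f1 <- runif(1, 230, 350)
      f2 <- runif(1, 900, 1300)
      list(f0 = f0,
           f1_contour = rep(f1, length(tpts)) + runif(1, -15, 15) * tpts,
           f2_contour = rep(f2, length(tpts)) + runif(1, -40, 40) * tpts,
           vot = NA_real_, spectral_peak = NA_real_,
           duration_range = c(0.06, 0.12))
    },
    plosive = {
      vot <- runif(1, 0.01, 0.07)
      list(f0 = NA_real_, f1_contour = NULL, f2_contour = NULL,
           vot = vot, spectral_peak = runif(1, 500, 4000),
           duration_range = c(vot + 0.03, vot + 0.08))
    },
    fricative = {
      list(f0 = NA_real_, f1_contour = NULL, f2_contour = NULL,
           vot = NA_real_, spectral_peak = runif(1, 2000, 6000),
           duration_range = c(0.08, 0.15))
    },
    stop("unknown phoneme class: ", class)
  )
  spec$label <- sprintf("%s%02d", substr(class, 1, 1), index)
  spec$class <- class
  structure(spec, class = "phoneme_spec")
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "class")
  cat(sprintf("phoneme inventory: %d phonemes (%s)\n", length(x),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)), collapse = ", ")))
  invisible(x)
}

# second-order resonator impulse response (damped sinusoid), ~40 ms
resonator_ir <- function(f, bw, fs, dur = 0.04) {
  t <- seq(0, dur, by = 1 / fs)
  exp(-pi * bw * t) * sin(2 * pi * f * t)
}

# synthesize one voiced token: impulse train at f0 through F1/F2 resonators
# with per-pulse instantaneous formant values taken from the contour
synth_voiced <- function(n, f0, f1c, f2c, fs, amp2 = 0.6, gain = 1) {
  wave <- numeric(n + fs %/% 20)  # head room for the resonator tails
  period <- max(round(fs / f0), 8L)
  pulses <- seq(1L, n, by = period)
  tpos <- (pulses - 1) / max(n - 1, 1)
  grid <- seq(0, 1, length.out = length(f1c))
  f1 <- approx(grid, f1c, xout = tpos, rule = 2)$y
  f2 <- approx(grid, f2c, xout = tpos, rule = 2)$y
  for (i in seq_along(pulses)) {
    ir <- gain * (resonator_ir(f1[i], 70, fs) + amp2 * resonator_ir(f2[i], 110, fs))
    j <- pulses[i]
    wave[j:(j + length(ir) - 1L)] <- wave[j:(j + length(ir) - 1L)] + ir
  }
  wave[seq_len(n)]
}

# noise shaped by a resonator around a spectral peak
synth_noise_band <- function(n, peak, bw, fs) {
  noise <- rnorm(n + fs %/% 50)
  ir <- resonator_ir(peak, bw, fs, dur = 0.01)
  y <- signal::filter(ir, 1, noise)
  y <- y[seq_len(n)]
  y / (max(abs(y)) + 1e-12)
}

#' Synthesize a labelled speech corpus
#'
#' Produces one continuous 16 kHz waveform of phoneme tokens drawn (balanced,
#' shuffled) from the inventory, with inter-token silences of 20-80 ms and
#' longer sentence pauses (150-250 ms) every ~12 tokens, plus leading and
#' trailing silence. Per token, F0/F1/F2/spectral peak (and VOT) are jittered
#' multiplicatively (lognormal, `jitter_sd` on the log scale); the ground
#' truth records the jittered values actually synthesized.
#'
#' Voiced tokens (vowels, nasals) are impulse trains through second-order
#' resonators at the jittered formants; plosives are a silence of length VOT
#' followed by a band-shaped burst; fricatives are noise shaped around the
#' spectral peak.
#'
#' @param inventory a [make_inventory()] object.
#' @param n_tokens number of phoneme tokens (>= 1).
#' @param jitter_sd lognormal sd of the per-token multiplicative jitter
#'   (default 0.05; 0 disables jitter).
#' @param seed integer seed; the corpus is byte-identical given the seed.
#' @param fs sample rate (Hz), default 16000.
#' @param sentence_len number of tokens between long pauses.
#' @return object of class `"speech_corpus"`: list with
#'   \describe{
#'     \item{wave}{numeric waveform in `[-1, 1]`, quantized to 16-bit steps}
#'     \item{fs}{sample rate}
#'     \item{transcript}{data frame `start`, `end`, `label` (0-based half-open
#'       sample intervals, tiling the waveform; silence labelled `"sil"`)}
#'     \item{frame_truth}{data frame with per-1-ms-frame `f0`, `f1`, `f2`
#'       (Hz; `NaN` outside voiced spans)}
#'     \item{tokens}{data frame of per-token ground truth: `label`, `class`,
#'       `start`, `end`, `f0`, `f1`, `f2` (token means), `vot`,
#'       `spectral_peak`}
#'   }
#' @export
synthesize <- function(inventory, n_tokens, jitter_sd = 0.05, seed = 1L,
                       fs = 16000L, sentence_len = 12L) {
  stopifnot(inherits(inventory, "phoneme_inventory"))
  stopifnot_scalar_int(n_tokens, "n_tokens")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  with_seed(seed, synthesize_impl(inventory, n_tokens, jitter_sd, fs, sentence_len))
}

synthesize_impl <- function(inventory, n_tokens, jitter_sd, fs, sentence_len) {
  order_idx <- sample(rep_len(seq_along(inventory), n_tokens))
  jit <- function(x) if (is.na(x)) NA_real_ else x * exp(rnorm(1, 0, jitter_sd))

  pieces <- list(); labels <- character(0)
  tokens <- list()
  lead <- round(0.2 * fs)
  pieces[[1]] <- numeric(lead); labels[1] <- "sil"
  for (k in seq_along(order_idx)) {
    sp <- inventory[[order_idx[k]]]
    dur <- runif(1, sp$duration_range[1], sp$duration_range[2])
    n <- round(dur * fs)
    f0 <- jit(sp$f0)
    peak <- jit(sp$spectral_peak)
    vot <- if (is.na(sp$vot)) NA_real_ else min(sp$vot * exp(rnorm(1, 0, jitter_sd)),
                                                0.8 * dur)
    fj <- if (!is.null(sp$f1_contour)) exp(rnorm(1, 0, jitter_sd)) else NA_real_
    f1c <- if (!is.null(sp$f1_contour)) sp$f1_contour * fj else NULL
    f2c <- if (!is.null(sp$f2_contour)) sp$f2_contour * fj else NULL
    tok_wave <- switch(sp$class,
      vowel = synth_voiced(n, f0, f1c, f2c, fs),
      nasal = 0.6 * synth_voiced(n, f0, f1c, f2c, fs, amp2 = 0.25),
      plosive = {
        n_vot <- round(vot * fs)
        burst <- synth_noise_band(n - n_vot, peak, 600, fs)
        env <- exp(-seq(0, by = 1 / fs, length.out = n - n_vot) / 0.015)
        c(numeric(n_vot), burst * env)
      },
      fricative = 0.7 * synth_noise_band(n, peak, 500, fs)
    )
    m <- max(abs(tok_wave))
    if (m > 0) tok_wave <- tok_wave / m * 0.5 * switch(sp$class, nasal = 0.6,
                                                       plosive = 0.9, 1)
    pieces[[length(pieces) + 1L]] <- tok_wave
    labels[length(labels) + 1L] <- sp$label
    tokens[[length(tokens) + 1L]] <- data.frame(
      label = sp$label, class = sp$class, n = n,
      f0 = f0, f1 = if (is.null(f1c)) NA_real_ else mean(f1c),
      f2 = if (is.null(f2c)) NA_real_ else mean(f2c),
      vot = vot, spectral_peak = peak, stringsAsFactors = FALSE)
    # inter-token silence; longer pause at sentence boundaries
    gap <- if (k %% sentence_len == 0L) runif(1, 0.15, 0.25) else runif(1, 0.02, 0.08)
    pieces[[length(pieces) + 1L]] <- numeric(round(gap * fs))
    labels[length(labels) + 1L] <- "sil"
    # stash contours for the frame truth
    tokens[[length(tokens)]]$.f1c <- I(list(f1c))
    tokens[[length(tokens)]]$.f2c <- I(list(f2c))
  }
  pieces[[length(pieces) + 1L]] <- numeric(round(0.2 * fs))
  labels[length(labels) + 1L] <- "sil"

  lens <- vapply(pieces, length, 0L)
  keep <- lens > 0L
  pieces <- pieces[keep]; labels <- labels[keep]; lens <- lens[keep]
  # merge adjacent silence intervals
  wave <- unlist(pieces, use.names = FALSE)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  ends <- cumsum(lens)
  transcript <- data.frame(start = starts, end = ends, label = labels,
                           stringsAsFactors = FALSE)
  transcript <- merge_silences(transcript)
  validate_transcript(transcript, length(wave))

  # global scaling + 16-bit quantization (byte-identical reproducibility)
  wave <- wave / max(abs(wave)) * 0.9
  wave <- round(wave * 32767) / 32767

  tok_df <- do.call(rbind, tokens)
  tok_starts <- transcript$start[transcript$label != "sil"]
  tok_ends <- transcript$end[transcript$label != "sil"]
  tok_df$start <- tok_starts; tok_df$end <- tok_ends

  frame_truth <- build_frame_truth(tok_df, length(wave), fs)
  tok_df$.f1c <- NULL; tok_df$.f2c <- NULL; tok_df$n <- NULL

  structure(list(wave = wave, fs = fs, transcript = transcript,
                 frame_truth = frame_truth, tokens = tok_df),
            class = "speech_corpus")
}

merge_silences <- function(tr) {
  keep <- rep(TRUE, nrow(tr))
  for (i in seq_len(nrow(tr))[-1]) {
    if (tr$label[i] == "sil" && tr$label[i - 1] == "sil" && keep[i - 1]) {
      j <- max(which(keep[seq_len(i - 1)]))
      tr$end[j] <- tr$end[i]; keep[i] <- FALSE
    }
  }
  tr[keep, , drop = FALSE][, c("start", "end", "label")] -> out
  rownames(out) <- NULL
  out
}

# per-1-ms-frame f0/f1/f2 tracks; NaN outside voiced spans
build_frame_truth <- function(tok_df, n_samples, fs) {
  n_frames <- floor(n_samples / fs * 1000)
  f0 <- rep(NaN, n_frames); f1 <- rep(NaN, n_frames); f2 <- rep(NaN, n_frames)
  spf <- fs / 1000  # samples per frame
  for (i in seq_len(nrow(tok_df))) {
    f1c <- tok_df$.f1c[[i]]
    if (is.null(f1c)) next
    f2c <- tok_df$.f2c[[i]]
    fr0 <- floor(tok_df$start[i] / spf) + 1L
    fr1 <- min(ceiling(tok_df$end[i] / spf), n_frames)
    if (fr1 < fr0) next
    tpos <- seq(0, 1, length.out = fr1 - fr0 + 1L)
    grid <- seq(0, 1, length.out = length(f1c))
    f1[fr0:fr1] <- approx(grid, f1c, xout = tpos, rule = 2)$y
    f2[fr0:fr1] <- approx(grid, f2c, xout = tpos, rule = 2)$y
    f0[fr0:fr1] <- tok_df$f0[i]
  }
  data.frame(frame = seq_len(n_frames), f0 = f0, f1 = f1, f2 = f2)
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat(sprintf("speech corpus: %.2f s at %d Hz, %d tokens, %d phoneme labels\n",
              length(x$wave) / x$fs, x$fs, nrow(x$tokens),
              length(unique(x$tokens$label))))
  invisible(x)
}

#' All instances of a phoneme in a transcript
#'
#' @param transcript data frame `start`, `end`, `label`.
#' @param label phoneme label.
#' @return data frame of the matching intervals, onset-sorted; zero rows if
#'   the label does not occur.
#' @export
phoneme_instances <- function(transcript, label) {
  out <- transcript[transcript$label == label, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a corpus to disk (WAV + .PHN + ground-truth TSVs)
#'
#' @param corpus a [synthesize()] result.
#' @param dir output directory (created if missing).
#' @param stem file stem (default `"corpus"`).
#' @return named vector of the written paths, invisibly.
#' @export
write_corpus <- function(corpus, dir, stem = "corpus") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    wav = file.path(dir, paste0(stem, ".wav")),
    phn = file.path(dir, paste0(stem, ".phn")),
    frames = file.path(dir, paste0(stem, "_frames.tsv")),
    tokens = file.path(dir, paste0(stem, "_tokens.tsv"))
  )
  write_wav(corpus$wave, paths["wav"], corpus$fs)
  write_phn(corpus$transcript, paths["phn"])
  write.table(corpus$frame_truth, paths["frames"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(corpus$tokens, paths["tokens"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(paths)
}
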
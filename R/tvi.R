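# Temporal variation index (TVI) of phoneme formant contours: each
# phoneme's averaged F1 (or F2) contour is projected onto the first
# principal component of all phonemes' contours; units whose responses
# correlate with the TVIs encode formant dynamics.

#' Build per-phoneme formant contours
#'
#' Each voiced instance's per-frame F1/F2 track is resampled to `T` points
#' (linear interpolation over normalized token time) and the instance
#' contours are averaged per phoneme. Phonemes without any voiced frames
#' (no defined formants) are excluded.
#'
#' @param frame_truth data frame with per-1-ms-frame `f1`, `f2` (a
#'   [synthesize()] `frame_truth`, or a tracker's output in the same shape).
#' @param transcript corpus transcript.
#' @param T_points common contour length (default 50).
#' @param fs,frame_step timing of the frame grid.
#' @return `"contour_set"`: list with `f1`, `f2` (phonemes x T matrices,
#'   rownames = labels), `counts` (instances per phoneme).
#' @export
build_contours <- function(frame_truth, transcript, T_points = 50L,
                           fs = 16000L, frame_step = 1) {
  spf <- fs * frame_step / 1000
  n_frames <- nrow(frame_truth)
  inst <- transcript[transcript$label != "sil", , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(inst))) {
    fr0 <- max(floor(inst$start[i] / spf) + 1L, 1L)
    fr1 <- min(ceiling(inst$end[i] / spf), n_frames)
    if (fr1 <= fr0) next
    t1 <- frame_truth$f1[fr0:fr1]; t2 <- frame_truth$f2[fr0:fr1]
    ok <- !is.na(t1)
    if (sum(ok) < 2L) next
    grid <- seq(0, 1, length.out = sum(ok))
    xout <- seq(0, 1, length.out = T_points)
    lab <- inst$label[i]
    entry <- list(f1 = approx(grid, t1[ok], xout = xout)$y,
                  f2 = approx(grid, t2[ok], xout = xout)$y)
    acc[[lab]] <- c(acc[[lab]], list(entry))
  }
  if (length(acc) == 0L) stop("no voiced instances with defined formants", call. = FALSE)
  labs <- sort(names(acc))
  f1 <- t(vapply(labs, function(l) colMeans(do.call(rbind, lapply(acc[[l]], `[[`, "f1"))),
                 numeric(T_points)))
  f2 <- t(vapply(labs, function(l) colMeans(do.call(rbind, lapply(acc[[l]], `[[`, "f2"))),
                 numeric(T_points)))
  structure(list(f1 = f1, f2 = f2,
                 counts = setNames(lengths(acc[labs]), labs)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour set: %d phonemes, %d time points\n",
              nrow(x$f1), ncol(x$f1)))
  invisible(x)
}

#' Temporal variation index of each phoneme's formant contour
#'
#' PCA over the phoneme contours (column-centered across phonemes); the TVI
#' of a phoneme is the signed projection of its (centered) contour onto the
#' first principal component. The PC1 sign is fixed so its
#' largest-magnitude element is positive.
#'
#' @param contours a [build_contours()] set.
#' @param formant `"f1"` or `"f2"`.
#' @param center center the contours before projecting (default TRUE; the
#'   standard PCA convention).
#' @return named numeric vector of TVIs, with attributes `pc1` (the first
#'   principal component) and `eigenvalue` (its sample variance share).
#' @export
tvi <- function(contours, formant = c("f1", "f2"), center = TRUE) {
  formant <- match.arg(formant)
  X <- contours[[formant]]
  if (nrow(X) < 2L) stop("need at least 2 phonemes")
  Xc <- sweep(X, 2, colMeans(X))
  if (all(Xc == 0)) stop("zero-variance contours: TVI undefined", call. = FALSE)
  sv <- svd(Xc, nu = 0L, nv = 1L)
  pc1 <- sv$v[, 1]
  s <- sign(pc1[which.max(abs(pc1))]); if (s == 0) s <- 1
  pc1 <- pc1 * s
  proj <- as.numeric((if (center) Xc else X) %*% pc1)
  structure(setNames(proj, rownames(X)), pc1 = pc1,
            eigenvalue = sv$d[1]^2 / (nrow(X) - 1))
}

#' Correlation between unit responses and phoneme TVIs
#'
#' A unit's response to a phoneme is its mean response amplitude over the
#' phoneme's instances; the encoding of formant dynamics is the Pearson
#' correlation between those per-phoneme responses and the TVIs.
#'
#' @param responses units x phonemes matrix of mean responses (colnames =
#'   labels), or a single named vector.
#' @param tvis named TVI vector from [tvi()].
#' @return data frame `unit`, `correlation` (NA with a warning for
#'   zero-variance responses).
#' @export
tvi_correlation <- function(responses, tvis) {
  if (is.vector(responses)) responses <- matrix(responses, 1,
                                                dimnames = list(NULL, names(responses)))
  labs <- intersect(colnames(responses), names(tvis))
  if (length(labs) < 3L) stop("need at least 3 phonemes in common", call. = FALSE)
  r <- vapply(seq_len(nrow(responses)), function(i) {
    x <- responses[i, labs]
    if (sd(x) == 0 || sd(tvis[labs]) == 0) {
      warning("zero-variance responses: correlation undefined")
      return(NA_real_)
    }
    cor(x, tvis[labs])
  }, 0)
  data.frame(unit = seq_len(nrow(responses)), correlation = r)
}

#' Mean response of each unit to each phoneme
#'
#' @param table a [response_amplitudes()] table.
#' @param units unit subset (default all).
#' @return units x phonemes matrix of mean amplitudes.
#' @export
mean_phoneme_responses <- function(table, units = NULL) {
  units <- units %||% seq_len(table$n_units)
  a <- table$amplitudes[table$amplitudes$unit %in% units, ]
  m <- tapply(a$amplitude, list(a$unit, a$label), mean)
  m[match(units, as.integer(rownames(m))), , drop = FALSE]
}
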
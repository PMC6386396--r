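# Linear decoding of acoustic parameters (F0, F1, F2, VOT, spectral peak)
# from unit response amplitudes: per-instance parameter estimation, 20-fold
# cross-validated least squares with the training-RMSE correctness
# criterion, a uniform random decoder as the chance baseline, and the
# accompanying significance test.

#' Estimate per-instance acoustic parameters
#'
#' For every non-silence instance: F0/F1/F2 are the medians of the per-frame
#' tracks over the instance (ground-truth tracks for synthetic corpora); the
#' spectral peak is the center frequency of the maximum-energy cochleogram
#' cell within the instance; VOT comes from the per-token ground truth.
#' Parameters are `NA` where class-inapplicable (e.g. F0 of a fricative).
#'
#' @param cochleogram a [cochleogram()] of the corpus waveform.
#' @param transcript the corpus transcript.
#' @param ground_truth optional list with `frame_truth` (data frame `f0`,
#'   `f1`, `f2` per 1-ms frame) and `tokens` (per-token `vot`); a
#'   [synthesize()] corpus works directly.
#' @return data frame with one row per instance: `instance`, `label`,
#'   `start`, `end`, `f0`, `f1`, `f2`, `vot`, `spectral_peak`.
#' @export
estimate_params <- function(cochleogram, transcript, ground_truth = NULL) {
  stopifnot(inherits(cochleogram, "cochleogram"))
  fs <- cochleogram$fs
  spf <- fs * cochleogram$frame_step / 1000
  n_frames <- ncol(cochleogram$energy)
  inst <- transcript[transcript$label != "sil", , drop = FALSE]
  ft <- ground_truth$frame_truth
  toks <- ground_truth$tokens

  med_track <- function(track, f0r, f1r) {
    v <- track[f0r:f1r]
    if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
  }
  out <- data.frame(instance = seq_len(nrow(inst)), label = inst$label,
                    start = inst$start, end = inst$end,
                    f0 = NA_real_, f1 = NA_real_, f2 = NA_real_,
                    vot = NA_real_, spectral_peak = NA_real_)
  for (i in seq_len(nrow(inst))) {
    fr0 <- max(floor(inst$start[i] / spf) + 1L, 1L)
    fr1 <- min(ceiling(inst$end[i] / spf), n_frames)
    if (fr1 < fr0) next
    if (!is.null(ft)) {
      out$f0[i] <- med_track(ft$f0, fr0, fr1)
      out$f1[i] <- med_track(ft$f1, fr0, fr1)
      out$f2[i] <- med_track(ft$f2, fr0, fr1)
    }
    block <- cochleogram$energy[, fr0:fr1, drop = FALSE]
    peak_channel <- arrayInd(which.max(block), dim(block))[1]
    out$spectral_peak[i] <- cochleogram$center_freqs[peak_channel]
    if (!is.null(toks)) {
      j <- which(toks$start == inst$start[i])
      if (length(j) == 1L) out$vot[i] <- toks$vot[j]
    }
  }
  out
}

# least squares with intercept; falls back to the minimum-norm solution for
# rank-deficient designs (SVD pseudoinverse)
fit_linear <- function(X, y) {
  Xa <- cbind(1, X)
  qr_fit <- qr(Xa)
  if (qr_fit$rank == ncol(Xa)) {
    as.numeric(qr.coef(qr_fit, y))
  } else {
    sv <- svd(Xa)
    keep <- sv$d > max(sv$d) * 1e-10
    as.numeric(sv$v[, keep, drop = FALSE] %*%
                 ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep]))
  }
}

predict_linear <- function(coefs, X) as.numeric(cbind(1, X) %*% coefs)

# seeded shuffle, then contiguous blocks
make_folds <- function(n, folds, seed) {
  ord <- with_seed(seed, sample.int(n))
  split(ord, cut(seq_len(n), folds, labels = FALSE))
}

#' Cross-validated linear decoding with the training-RMSE criterion
#'
#' Per fold: fit `y = w x + b` by least squares on the training split,
#' compute the root-mean-squared error on that training split, and score a
#' test prediction as correct when its absolute error is below the training
#' RMSE. Accuracy is the fraction of correct test predictions.
#'
#' @param X instances x units response matrix.
#' @param y instance parameter values (`NA` rows are dropped).
#' @param folds number of folds (default 20).
#' @param seed integer seed for the fold assignment.
#' @return `"decoding_result"`: list with `accuracy` (per fold), `rmse`,
#'   `y_min`, `y_max` (per fold, from the training split), `folds`, `n`.
#' @export
linear_decode_cv <- function(X, y, folds = 20L, seed = 1L) {
  X <- as.matrix(X)
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < folds) stop("fewer instances with defined values than folds", call. = FALSE)
  fold_idx <- make_folds(n, folds, seed)
  acc <- rmse <- ymin <- ymax <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_idx[[f]]
    train <- setdiff(seq_len(n), test)
    coefs <- fit_linear(X[train, , drop = FALSE], y[train])
    train_err <- y[train] - predict_linear(coefs, X[train, , drop = FALSE])
    rmse[f] <- sqrt(mean(train_err^2))
    pred <- predict_linear(coefs, X[test, , drop = FALSE])
    acc[f] <- mean(abs(pred - y[test]) < rmse[f])
    ymin[f] <- min(y[train]); ymax[f] <- max(y[train])
  }
  structure(list(accuracy = acc, rmse = rmse, y_min = ymin, y_max = ymax,
                 folds = folds, n = n, fold_idx = fold_idx, y = y),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("linear decoding: %d folds over %d instances, accuracy %.3f +/- %.3f\n",
              x$folds, x$n, mean(x$accuracy), sd(x$accuracy)))
  invisible(x)
}

#' Chance-level accuracies from a uniform random decoder
#'
#' For each test sample the decoder outputs a uniform draw between the
#' minimum and maximum of the training-split ground truth, scored with the
#' same correctness threshold as the linear decoder (its training RMSE).
#'
#' @param y parameter values (`NA` dropped; must match the decoding run).
#' @param folds number of folds.
#' @param seed integer seed for the draws.
#' @param linear_result the matching [linear_decode_cv()] result supplying
#'   the per-fold RMSE thresholds, fold assignment, and training ranges.
#' @return numeric vector of per-fold accuracies.
#' @export
random_decoder_cv <- function(y, folds = 20L, seed = 1L, linear_result) {
  stopifnot(inherits(linear_result, "decoding_result"))
  y <- y[!is.na(y)]
  stopifnot(length(y) == linear_result$n)
  if (any(linear_result$y_max == linear_result$y_min)) {
    warning("constant training targets: random decoder accuracy is 1 by construction")
  }
  with_seed(seed, {
    vapply(seq_len(folds), function(f) {
      test <- linear_result$fold_idx[[f]]
      draws <- runif(length(test), linear_result$y_min[f], linear_result$y_max[f])
      mean(abs(draws - y[test]) < linear_result$rmse[f])
    }, 0)
  })
}

#' Compare decoder accuracies (two-sample Student's t-test)
#'
#' @param linear_acc,random_acc per-fold accuracy vectors of equal length.
#' @return the p-value. Degenerate zero-variance inputs: `1` for equal
#'   means, `0` otherwise.
#' @export
significance <- function(linear_acc, random_acc) {
  stopifnot(length(linear_acc) == length(random_acc))
  if (var(linear_acc) == 0 && var(random_acc) == 0) {
    return(if (mean(linear_acc) == mean(random_acc)) 1 else 0)
  }
  t.test(linear_acc, random_acc, var.equal = TRUE)$p.value
}

#' Decode one parameter with linear and random decoders
#'
#' @inheritParams linear_decode_cv
#' @param param_name label carried into the result.
#' @return list with `linear` (decoding result), `random` (per-fold
#'   accuracies), `p_value`, `param`.
#' @export
decode_param <- function(X, y, folds = 20L, seed = 1L, param_name = "param") {
  lin <- linear_decode_cv(X, y, folds = folds, seed = seed)
  rnd <- random_decoder_cv(y, folds = folds, seed = seed + 1L, linear_result = lin)
  list(linear = lin, random = rnd,
       p_value = significance(lin$accuracy, rnd),
       param = param_name)
}

#' Response-amplitude design matrix
#'
#' Instances x units matrix of response amplitudes, the decoder's feature
#' matrix.
#'
#' @param table a [response_amplitudes()] table.
#' @param units unit subset (default all).
#' @return numeric matrix with instance ids as rownames.
#' @export
amplitude_matrix <- function(table, units = NULL) {
  units <- units %||% seq_len(table$n_units)
  a <- table$amplitudes
  insts <- sort(unique(a$instance))
  X <- matrix(NA_real_, length(insts), length(units))
  for (k in seq_along(units)) {
    sub <- a[a$unit == units[k], ]
    X[match(sub$instance, insts), k] <- sub$amplitude
  }
  rownames(X) <- insts
  X
}

#' Decoding accuracies per unit group and layer
#'
#' Restricts the linear decoder to each group's units. Parameters are
#' decoded over the instances where they are defined (vowel parameters over
#' vowels, VOT/spectral peak over consonants).
#'
#' @param tables named list (per layer) of [response_amplitudes()] tables.
#' @param groups named list (per layer) of integer group labels over that
#'   layer's active units (names of the vector = unit indices).
#' @param params an [estimate_params()] data frame.
#' @param param_names parameters to decode.
#' @param folds,seed cross-validation controls.
#' @return data frame: `layer`, `group`, `param`, `mean_accuracy`,
#'   `mean_random`, `p_value`, `n_units`, `n_instances`.
#' @export
group_decoding <- function(tables, groups, params,
                           param_names = c("f0", "f1", "f2", "vot", "spectral_peak"),
                           folds = 20L, seed = 1L) {
  rows <- list()
  for (layer in names(tables)) {
    tab <- tables[[layer]]
    gl <- groups[[layer]]
    unit_ids <- as.integer(names(gl))
    for (g in sort(unique(gl))) {
      units <- unit_ids[gl == g]
      if (length(units) == 0L) { warning("empty group skipped"); next }
      X_all <- amplitude_matrix(tab, units)
      for (p in param_names) {
        y <- params[[p]][match(as.integer(rownames(X_all)), params$instance)]
        if (sum(!is.na(y)) < folds) next
        res <- decode_param(X_all, y, folds = folds, seed = seed, param_name = p)
        rows[[length(rows) + 1L]] <- data.frame(
          layer = layer, group = g, param = p,
          mean_accuracy = mean(res$linear$accuracy),
          mean_random = mean(res$random), p_value = res$p_value,
          n_units = length(units), n_instances = res$linear$n)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cochleogram decoding baseline
#'
#' Uses a fixed-length onset-aligned cochleogram window (default 170 ms at
#' the 1-ms frame step), flattened, as the feature vector of each instance;
#' instances too close to the end are zero-padded.
#'
#' @param cochleogram corpus cochleogram.
#' @param transcript corpus transcript.
#' @param params an [estimate_params()] data frame.
#' @param param_names parameters to decode.
#' @param window_ms window length in ms (default 170).
#' @param folds,seed cross-validation controls.
#' @return data frame: `param`, `mean_accuracy`, `mean_random`, `p_value`,
#'   `n_instances`.
#' @export
cochleogram_baseline <- function(cochleogram, transcript, params,
                                 param_names = c("f0", "f1", "f2", "vot",
                                                 "spectral_peak"),
                                 window_ms = 170L, folds = 20L, seed = 1L) {
  fs <- cochleogram$fs
  spf <- fs * cochleogram$frame_step / 1000
  E <- cochleogram$energy
  n_frames <- ncol(E)
  win <- round(window_ms / cochleogram$frame_step)
  inst <- transcript[transcript$label != "sil", , drop = FALSE]
  n_padded <- 0L
  X <- t(vapply(seq_len(nrow(inst)), function(i) {
    fr0 <- floor(inst$start[i] / spf) + 1L
    fr1 <- fr0 + win - 1L
    if (fr1 > n_frames) {
      block <- cbind(E[, fr0:n_frames, drop = FALSE],
                     matrix(0, nrow(E), fr1 - n_frames))
      n_padded <<- n_padded + 1L
    } else {
      block <- E[, fr0:fr1, drop = FALSE]
    }
    as.vector(block)
  }, numeric(nrow(E) * win)))
  if (n_padded > 0L) message(n_padded, " instance(s) zero-padded at the corpus end")
  rows <- lapply(param_names, function(p) {
    y <- params[[p]][match(seq_len(nrow(inst)), params$instance)]
    if (sum(!is.na(y)) < folds) return(NULL)
    res <- decode_param(X, y, folds = folds, seed = seed, param_name = p)
    data.frame(param = p, mean_accuracy = mean(res$linear$accuracy),
               mean_random = mean(res$random), p_value = res$p_value,
               n_instances = res$linear$n)
  })
  do.call(rbind, rows)
}
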
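# Phoneme-selectivity statistics. A "unit" for these analyses is one
# feature map at the analysis layer; the map's column at each output frame
# is max-reduced over the frequency axis before amplitude extraction (top
# layers are nearly global in frequency, and selectivity is reported per
# map).

#' Per-instance response amplitudes and silence responses of a layer
#'
#' Aligns a layer's responses to the transcript. Each unit's response
#' amplitude for a phoneme instance is the maximum absolute response over
#' the output frames whose receptive fields overlap the instance (phoneme
#' length is not normalized). Output frames whose receptive fields lie
#' entirely inside silence intervals are collected as the unit's silence
#' responses; frames overlapping any phoneme are the speech frames.
#'
#' @param stack the layer's feature stack (h x t x m).
#' @param transcript corpus transcript (`start`, `end`, `label`; samples).
#' @param rf,jump temporal receptive-field extent and output-grid spacing of
#'   the layer in input frames (see [layer_geometry()]).
#' @param fs waveform sample rate (Hz).
#' @param frame_step cochleogram frame step (ms).
#' @return `"response_table"`: list with `resp` (units x frames matrix of
#'   frequency-max-reduced responses), `amplitudes` (data frame `unit`,
#'   `label`, `instance`, `amplitude`), `silence_frames`, `speech_frames`
#'   (output-frame indices), `labels`, `n_units`, `rf`, `jump`.
#' @export
response_amplitudes <- function(stack, transcript, rf, jump, fs = 16000L,
                                frame_step = 1) {
  x <- as_stack(stack)
  n_units <- dim(x)[3]
  T_out <- dim(x)[2]
  # frequency-axis max-reduction: one response stream per map
  resp <- t(apply(x, c(2, 3), max))   # m x T
  spf <- fs * frame_step / 1000  # samples per input frame

  inst <- transcript[transcript$label != "sil", , drop = FALSE]
  amps <- vector("list", nrow(inst))
  skipped <- 0L
  for (i in seq_len(nrow(inst))) {
    fr <- input_to_output_frames(inst$start[i], inst$end[i], spf, rf, jump,
                                 T_out, overlap = TRUE)
    if (length(fr) == 0L) { skipped <- skipped + 1L; next }
    a <- apply(abs(resp[, fr, drop = FALSE]), 1, max)
    amps[[i]] <- data.frame(unit = seq_len(n_units), label = inst$label[i],
                            instance = i, amplitude = a)
  }
  if (skipped > 0L) {
    warning(sprintf("%d instance(s) outside the encoded range were skipped", skipped))
  }
  amplitudes <- do.call(rbind, amps)

  sil <- transcript[transcript$label == "sil", , drop = FALSE]
  silence_frames <- integer(0)
  for (i in seq_len(nrow(sil))) {
    silence_frames <- c(silence_frames,
                        input_to_output_frames(sil$start[i], sil$end[i], spf,
                                               rf, jump, T_out, overlap = FALSE))
  }
  # speech frames: overlap at least one phoneme instance
  speech_frames <- sort(unique(unlist(lapply(seq_len(nrow(inst)), function(i) {
    input_to_output_frames(inst$start[i], inst$end[i], spf, rf, jump, T_out,
                           overlap = TRUE)
  }))))

  structure(list(resp = resp, amplitudes = amplitudes,
                 silence_frames = sort(unique(silence_frames)),
                 speech_frames = speech_frames,
                 labels = sort(unique(inst$label)),
                 n_units = n_units, rf = rf, jump = jump),
            class = "response_table")
}

# map a sample interval [s0, s1) to output-frame indices. Output frame t
# covers input frames [(t-1)*jump + 1, (t-1)*jump + rf].
# overlap = TRUE: frames whose receptive field overlaps the interval;
# overlap = FALSE: frames entirely inside it.
input_to_output_frames <- function(s0, s1, spf, rf, jump, T_out, overlap = TRUE) {
  f0 <- floor(s0 / spf) + 1L          # first input frame touched
  f1 <- ceiling(s1 / spf)             # last input frame touched
  if (overlap) {
    t_lo <- ceiling((f0 - rf) / jump) + 1L
    t_hi <- floor((f1 - 1) / jump) + 1L
  } else {
    t_lo <- ceiling((f0 - 1) / jump) + 1L
    t_hi <- floor((f1 - rf) / jump) + 1L
  }
  t_lo <- max(t_lo, 1L); t_hi <- min(t_hi, T_out)
  if (t_hi < t_lo) integer(0) else t_lo:t_hi
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("response table: %d units, %d instances of %d phonemes, %d silence frames\n",
              x$n_units, length(unique(x$amplitudes$instance)), length(x$labels),
              length(x$silence_frames)))
  invisible(x)
}

# one-sided rank-sum p-value P(median(x) > median(y)), guarded for
# degenerate inputs
ranksum_greater_p <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  if (max(c(x, y)) == min(c(x, y))) return(1)
  suppressWarnings(wilcox.test(x, y, alternative = "greater", exact = NULL)$p.value)
}

#' Units responding more to speech than to silence
#'
#' One-sided rank-sum test per unit comparing responses at randomly selected
#' speech frames against the unit's silence-frame responses.
#'
#' @param table a [response_amplitudes()] table.
#' @param alpha significance level (default 0.001).
#' @param n_frames number of speech frames sampled (default 1000).
#' @param seed integer seed for the frame sample.
#' @return integer vector of active unit indices.
#' @export
active_units <- function(table, alpha = 0.001, n_frames = 1000L, seed = 1L) {
  if (length(table$silence_frames) < 2L) {
    stop("fewer than 2 silence frames at this layer; regenerate the corpus ",
         "with longer silence intervals", call. = FALSE)
  }
  if (length(table$speech_frames) < 2L) stop("fewer than 2 speech frames")
  fr <- with_seed(seed, {
    if (length(table$speech_frames) > n_frames) {
      sample(table$speech_frames, n_frames)
    } else table$speech_frames
  })
  p <- vapply(seq_len(table$n_units), function(i) {
    ranksum_greater_p(table$resp[i, fr], table$resp[i, table$silence_frames])
  }, 0)
  which(!is.na(p) & p < alpha)
}

#' Phoneme selectivity index vector of one unit
#'
#' The PSI for phoneme `phi` is the number of other phonemes whose response
#' amplitude distribution is statistically smaller than `phi`'s (one-sided
#' rank-sum, `p < alpha`). With `P` phonemes each PSI lies in `[0, P - 1]`.
#'
#' @param table a [response_amplitudes()] table.
#' @param unit unit index.
#' @param alpha per-comparison significance level (default 0.01; no
#'   multiple-testing correction, matching the convention this statistic is
#'   defined with).
#' @param min_instances phonemes with fewer instances are excluded from both
#'   sides of the comparison (default 2).
#' @return named integer vector of PSIs over the retained phonemes.
#' @export
psi_vector <- function(table, unit, alpha = 0.01, min_instances = 2L) {
  a <- table$amplitudes[table$amplitudes$unit == unit, , drop = FALSE]
  by_label <- split(a$amplitude, a$label)
  counts <- lengths(by_label)
  if (any(counts < min_instances)) {
    dropped <- names(by_label)[counts < min_instances]
    message("excluding phoneme(s) with too few instances: ",
            paste(dropped, collapse = ", "))
    by_label <- by_label[counts >= min_instances]
  }
  labs <- names(by_label)
  P <- length(labs)
  psi <- setNames(integer(P), labs)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i == j) next
      p <- ranksum_greater_p(by_label[[i]], by_label[[j]])
      if (!is.na(p) && p < alpha) psi[i] <- psi[i] + 1L
    }
  }
  psi
}

#' PSI matrix of a set of units
#'
#' @param table a [response_amplitudes()] table.
#' @param units unit indices (default: all units).
#' @inheritParams psi_vector
#' @return integer matrix units x phonemes (rownames = unit ids, colnames =
#'   phoneme labels), class `"psi_matrix"`.
#' @export
psi_matrix <- function(table, units = NULL, alpha = 0.01, min_instances = 2L) {
  units <- units %||% seq_len(table$n_units)
  rows <- lapply(units, function(u) {
    suppressMessages(psi_vector(table, u, alpha, min_instances))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- units
  class(out) <- c("psi_matrix", "matrix", "array")
  out
}

#' Cluster units and phonemes by their PSI patterns
#'
#' Hierarchical agglomerative clustering (Euclidean distance) applied along
#' both axes: units are cut into `n_groups` groups, and both axes are
#' reordered by their dendrograms for heatmap display.
#'
#' @param psi a [psi_matrix()] (units x phonemes).
#' @param n_groups number of unit groups (default 6).
#' @param method linkage (default `"ward.D2"`).
#' @return list with `unit_groups` (named integer vector), `unit_order`,
#'   `phoneme_order`, `unit_tree`, `phoneme_tree`.
#' @export
cluster_psi <- function(psi, n_groups = 6L, method = "ward.D2") {
  if (nrow(psi) < n_groups) {
    stop("fewer units than requested groups", call. = FALSE)
  }
  ut <- hclust(dist(psi), method = method)
  pt <- hclust(dist(t(psi)), method = method)
  list(unit_groups = cutree(ut, k = n_groups),
       unit_order = ut$order, phoneme_order = pt$order,
       unit_tree = ut, phoneme_tree = pt)
}

#' F-ratio of a layer's PSI vectors
#'
#' Ratio of between-group to within-group variability of the PSI vectors:
#' \deqn{F = \frac{\sum_j m_j \|\bar p_j - \bar p\|^2 / (n-1)}
#'            {\sum_j \sum_{i \in \Omega_j} \|p_i - \bar p_j\|^2 / (m-n)}}
#' with `m` units in `n` groups, group memberships `Omega_j` of sizes `m_j`.
#'
#' @param psi units x phonemes PSI matrix.
#' @param groups integer group label per unit (e.g. from [cluster_psi()]).
#' @return the F-ratio; `Inf` (with a warning) when the within-group
#'   variability is zero.
#' @export
f_ratio <- function(psi, groups) {
  psi <- unclass(psi)
  stopifnot(nrow(psi) == length(groups))
  gs <- unique(groups)
  n <- length(gs); m <- nrow(psi)
  if (n < 2L) stop("need at least 2 groups")
  if (m <= n) stop("need more units than groups")
  grand <- colMeans(psi)
  between <- 0; within <- 0
  for (g in gs) {
    idx <- which(groups == g)
    mu <- colMeans(psi[idx, , drop = FALSE])
    between <- between + length(idx) * sum((mu - grand)^2)
    within <- within + sum(sweep(psi[idx, , drop = FALSE], 2, mu)^2)
  }
  if (within == 0) {
    warning("zero within-group variability; F-ratio is infinite")
    return(Inf)
  }
  (between / (n - 1)) / (within / (m - n))
}

#' Average PSI vectors over phonemes sharing a phonetic feature
#'
#' @param psi units x phonemes PSI matrix (colnames = phoneme labels).
#' @param phoneme_to_feature named character vector mapping every phoneme to
#'   exactly one feature.
#' @return features x units matrix of feature-averaged PSIs.
#' @export
feature_psi <- function(psi, phoneme_to_feature) {
  labs <- colnames(psi)
  if (is.null(labs)) stop("`psi` must have phoneme column names")
  unmapped <- setdiff(labs, names(phoneme_to_feature))
  if (length(unmapped) > 0L) {
    stop("unmapped phoneme(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  feats <- phoneme_to_feature[labs]
  out <- t(apply(psi, 1, function(row) tapply(row, feats, mean)))
  t(out)  # features x units
}

#' Phonetic-feature map for a synthetic inventory
#'
#' Maps each phoneme to one of six features: `plosive`, `fricative`,
#' `nasal`, and -- for vowels, by F1/F2 centroid relative to the vowel
#' medians -- `low back`, `low front`, `high front` (high back vowels are
#' folded into `low back`: backness dominates the grouping).
#'
#' @param inventory a [make_inventory()] object.
#' @return named character vector phoneme label -> feature.
#' @export
phoneme_feature_map <- function(inventory) {
  labs <- vapply(inventory, `[[`, "", "label")
  cls <- vapply(inventory, `[[`, "", "class")
  feat <- cls
  vi <- which(cls == "vowel")
  if (length(vi) > 0L) {
    f1 <- vapply(inventory[vi], function(s) mean(s$f1_contour), 0)
    f2 <- vapply(inventory[vi], function(s) mean(s$f2_contour), 0)
    low <- f1 >= median(f1)
    front <- f2 >= median(f2)
    feat[vi] <- ifelse(front & !low, "high front",
                       ifelse(front & low, "low front", "low back"))
  }
  setNames(feat, labs)
}

#' Lifetime sparseness of a response sequence
#'
#' \deqn{S = 1 - (E[r])^2 / E[r^2]}
#' A constant response gives 0; a one-hot response over `N` frames gives
#' `1 - 1/N`. All-zero responses are undefined: `NA` with a warning.
#'
#' @param responses numeric vector of per-frame responses.
#' @return sparseness in `[0, 1)`.
#' @export
lifetime_sparseness <- function(responses) {
  if (length(responses) < 1L) stop("empty response sequence")
  m2 <- mean(responses^2)
  if (m2 == 0) {
    warning("all-zero responses: lifetime sparseness undefined")
    return(NA_real_)
  }
  1 - mean(responses)^2 / m2
}

# mean lifetime sparseness of a layer's units, computed on absolute
# responses (code magnitudes); all-zero units are skipped
mean_lifetime_sparseness <- function(resp, units = NULL) {
  units <- units %||% seq_len(nrow(resp))
  s <- suppressWarnings(
    vapply(units, function(i) lifetime_sparseness(abs(resp[i, ])), 0)
  )
  mean(s, na.rm = TRUE)
}

#' Full selectivity analysis of one layer
#'
#' Convenience wrapper: response table, active-unit screen, PSI matrix of
#' the active units, clustering into groups, F-ratio, and mean lifetime
#' sparseness. The group count is reduced when fewer active units are
#' available; with fewer than 3 active units the PSI statistics are
#' skipped (with a warning).
#'
#' @param stack the layer's feature stack.
#' @param transcript corpus transcript.
#' @param rf,jump the layer's temporal receptive-field extent and
#'   output-grid spacing in input frames (see [layer_geometry()]).
#' @param fs sample rate (Hz).
#' @param n_groups unit group count for clustering/F-ratio.
#' @param alpha_active,alpha_psi significance levels.
#' @param seed seed for the active-unit frame sample.
#' @param use_active screen units first (default TRUE).
#' @return list with `table`, `active`, `psi`, `groups`, `f_ratio`,
#'   `sparseness`.
#' @export
layer_selectivity <- function(stack, transcript, rf, jump, fs = 16000L,
                              n_groups = 6L, alpha_active = 0.001,
                              alpha_psi = 0.01, seed = 1L,
                              use_active = TRUE) {
  tab <- response_amplitudes(stack, transcript, rf, jump, fs)
  act <- if (use_active) active_units(tab, alpha = alpha_active, seed = seed)
         else seq_len(tab$n_units)
  if (length(act) < 3L) {
    warning("fewer than 3 active units; selectivity statistics skipped")
    return(list(table = tab, active = act, psi = NULL, groups = NULL,
                f_ratio = NA_real_,
                sparseness = mean_lifetime_sparseness(tab$resp, act)))
  }
  psi <- psi_matrix(tab, units = act, alpha = alpha_psi)
  k <- min(n_groups, length(act) - 1L)
  cl <- cluster_psi(psi, n_groups = k)
  list(table = tab, active = act, psi = psi, groups = cl,
       f_ratio = f_ratio(psi, cl$unit_groups),
       sparseness = mean_lifetime_sparseness(tab$resp, act))
}

#' Sparseness penalty sweep of one S layer
#'
#' Retrains the target S layer's dictionary (lower layers fixed at their
#' trained state) for each penalty value, re-encodes the layer, and
#' measures the analysis layer's mean lifetime sparseness and F-ratio. The
#' analysis layer is the C layer following the target when it pools,
#' otherwise the target itself.
#'
#' With the default `encoder = "optimize"` the swept layer's responses are
#' the lasso codes at the swept penalty, so the penalty controls response
#' sparseness directly at inference; `encoder = "conv"` uses the
#' convolutional encoder, where the penalty acts only through the learned
#' atoms.
#'
#' @param model a trained model with kept activations.
#' @param cochleograms the training corpus (list of cochleograms).
#' @param transcript the corpus transcript.
#' @param layer_id S layer to sweep.
#' @param lambdas penalty values (default: 16 values log-spaced in
#'   `[0.001, 100]`).
#' @param n_patches,seed,epochs retraining controls.
#' @param n_groups unit group count for the F-ratio.
#' @param fs sample rate.
#' @param encoder `"optimize"` (default) or `"conv"`.
#' @return data frame with one row per lambda: `lambda`, `sparseness`,
#'   `f_ratio`, `n_active` (`NA` statistics when too few units are active).
#' @export
lambda_sweep <- function(model, cochleograms, transcript, layer_id,
                         lambdas = 10^seq(-3, 2, length.out = 16),
                         n_patches = 2000L, seed = 1L, epochs = 3L,
                         n_groups = 6L, fs = 16000L,
                         encoder = c("optimize", "conv")) {
  encoder <- match.arg(encoder)
  if (any(lambdas <= 0)) stop("lambda values must be > 0")
  arch <- model$arch
  lspec <- arch[[layer_id]]
  if (is.null(lspec) || lspec$kind != "S") {
    stop("`layer_id` must name an S layer")
  }
  i <- match(layer_id, names(arch))
  # inputs to the swept layer: previous layer's activations (or cochleogram)
  inputs <- if (i == 1L) lapply(cochleograms, as_stack)
            else model$activations[[names(arch)[i - 1L]]]
  analysis_is_c <- i < length(arch) && arch[[i + 1L]]$kind == "C" &&
    arch[[i + 1L]]$pool_mode != "none"
  analysis_layer <- if (analysis_is_c) names(arch)[i + 1L] else layer_id
  geo <- model$geometry
  gi <- match(analysis_layer, geo$layer)

  per_item <- diff(round(seq(0, n_patches, length.out = length(inputs) + 1L)))
  plist <- lapply(seq_along(inputs), function(k) {
    if (per_item[k] == 0L) return(NULL)
    sample_patches(inputs[[k]], per_item[k], kernel = lspec$kernel,
                   seed = seed + 7000L + k)
  })
  patches <- do.call(rbind, plist)

  rows <- lapply(lambdas, function(lam) {
    bank <- learn_dictionary(patches, m = lspec$n_maps, lambda = lam,
                             epochs = epochs, seed = seed,
                             regularizer = lspec$regularizer,
                             kernel = lspec$kernel, u = dim(inputs[[1]])[3])
    stack <- if (encoder == "optimize") {
      encode_optimize(inputs[[1]], bank, lambda = lam,
                      s_conv = lspec$conv_stride, max_sweeps = 30L, tol = 1e-4)
    } else {
      encode_conv(inputs[[1]], bank, s_conv = lspec$conv_stride)
    }
    if (analysis_is_c) {
      cl <- arch[[i + 1L]]
      stack <- pool(stack, mode = cl$pool_mode, size = cl$pool_size,
                    stride = cl$pool_stride)
    }
    sel <- tryCatch(
      layer_selectivity(stack, transcript, rf = geo$rf[gi],
                        jump = geo$jump[gi], fs = fs, n_groups = n_groups,
                        seed = seed),
      error = function(e) NULL)
    if (is.null(sel) || is.na(sel$f_ratio)) {
      return(data.frame(lambda = lam, sparseness = NA_real_,
                        f_ratio = NA_real_,
                        n_active = if (is.null(sel)) 0L else length(sel$active)))
    }
    data.frame(lambda = lam, sparseness = sel$sparseness,
               f_ratio = sel$f_ratio, n_active = length(sel$active))
  })
  do.call(rbind, rows)
}
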
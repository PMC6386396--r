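# Spectro-temporal receptive fields: composed top-down from the learned
# dictionaries by linear combination across layers, then parameterized by a
# rank-1 SVD into spectral and temporal profiles.

#' Compose the STRF of a unit by linear combination of lower-layer bases
#'
#' The STRF of an S1 unit is its basis. For a unit in a higher S layer the
#' basis weights are placed on the input grid at the spacing of the layer's
#' input (the cumulative product of convolution strides below it), padded by
#' the pooling offset of the intervening C layer, and convolved ("full"
#' mode) with the STRFs of the lower layer's units, summing over input maps.
#'
#' Two placement conventions are available: `"dilate"` (default) spaces the
#' weights exactly, so STRF dimensions equal [rf_extent()] for every layer;
#' `"nearest"` duplicates each weight into a `d x d` block
#' (nearest-neighbor expansion), the visualization convention -- sizes then
#' exceed the exact extent by `d - 1` at layers whose input spacing `d`
#' exceeds 1.
#'
#' C-layer units share the STRF of the preceding S layer's units (pooling
#' only shifts and enlarges the region slightly), so `layer_id` must name an
#' S layer; ask for the preceding S layer to inspect C units.
#'
#' @param model a trained model (needs `banks` and `arch`).
#' @param layer_id S-layer name.
#' @param unit_index feature-map index within the layer.
#' @param expansion `"dilate"` or `"nearest"`.
#' @return `"strf"` object: the channels x frames matrix with attributes
#'   `layer_id` and `unit_index`.
#' @export
compose_strf <- function(model, layer_id, unit_index,
                         expansion = c("dilate", "nearest")) {
  expansion <- match.arg(expansion)
  all_strfs <- compose_strf_layer(model, layer_id, expansion)
  if (unit_index < 1L || unit_index > length(all_strfs)) {
    stop("unit_index out of range", call. = FALSE)
  }
  structure(all_strfs[[unit_index]], layer_id = layer_id,
            unit_index = unit_index, class = c("strf", "matrix"))
}

#' @rdname compose_strf
#' @details `compose_strf_layer()` returns the STRFs of all units of the
#'   layer (a list of matrices); the recursion computes every lower layer's
#'   STRFs once.
#' @export
compose_strf_layer <- function(model, layer_id, expansion = c("dilate", "nearest")) {
  expansion <- match.arg(expansion)
  arch <- model$arch
  s_layers <- names(arch)[vapply(arch, function(l) l$kind == "S", TRUE)]
  target <- match(layer_id, s_layers)
  if (is.na(target)) stop("`layer_id` must name an S layer", call. = FALSE)

  bank1 <- model$banks[[s_layers[1]]]
  k1 <- bank1$kernel
  strfs <- lapply(seq_len(bank1$m), function(j) matrix(bank1$B[, j], k1, k1))
  if (target == 1L) return(strfs)

  jump <- arch[[s_layers[1]]]$conv_stride
  for (li in 2:target) {
    nm <- s_layers[li]
    bank <- model$banks[[nm]]
    k <- bank$kernel; u <- bank$u
    # pooling offset of the C layer between s_layers[li-1] and s_layers[li]
    c_nm <- sub("^S", "C", s_layers[li - 1L])
    cl <- arch[[c_nm]]
    pad <- if (!is.null(cl) && cl$pool_mode != "none") (cl$pool_size - 1L) * jump else 0L
    new_strfs <- vector("list", bank$m)
    for (j in seq_len(bank$m)) {
      W <- array(bank$B[, j], c(k, k, u))
      acc <- NULL
      for (uu in seq_len(u)) {
        M <- place_weights(W[, , uu], jump, pad, expansion)
        contrib <- conv2_full(strfs[[uu]], M)
        acc <- if (is.null(acc)) contrib else acc + contrib
      }
      new_strfs[[j]] <- acc
    }
    strfs <- new_strfs
    jump <- jump * arch[[nm]]$conv_stride
  }
  strfs
}

# place a k x k weight slice on the input grid: spacing `d`, pooling pad.
# dilate: exact placement (extent (k-1)*d + 1); nearest: d x d duplication
# (extent k*d). Pad is split as evenly as the parity allows.
place_weights <- function(W, d, pad, expansion) {
  k <- nrow(W)
  if (expansion == "nearest") {
    M <- W[rep(seq_len(k), each = d), rep(seq_len(k), each = d), drop = FALSE]
  } else {
    side <- (k - 1L) * d + 1L
    M <- matrix(0, side, side)
    idx <- (seq_len(k) - 1L) * d + 1L
    M[idx, idx] <- W
  }
  if (pad > 0L) {
    lo <- pad %/% 2L; hi <- pad - lo
    side <- nrow(M)
    out <- matrix(0, side + pad, side + pad)
    out[(lo + 1L):(lo + side), (lo + 1L):(lo + side)] <- M
    M <- out
  }
  M
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("STRF of unit %s in layer %s: %d x %d\n",
              attr(x, "unit_index"), attr(x, "layer_id"), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
plot.strf <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "time", ylab = "frequency", useRaster = TRUE, ...)
  invisible(x)
}

#' Spectral and temporal profiles of an STRF (rank-1 SVD)
#'
#' The first left and right singular vectors of the STRF matrix. Signs are
#' fixed so that each profile's largest-magnitude element is positive; the
#' returned `sigma` carries the compensating sign so that
#' `sigma * spectral %*% t(temporal)` is the best rank-1 approximation.
#'
#' @param strf an STRF matrix.
#' @return list with `spectral` (length = channels, unit norm), `temporal`
#'   (length = frames, unit norm), `sigma` (signed first singular value).
#' @export
strf_profiles <- function(strf) {
  m <- unclass(strf)
  if (all(m == 0)) stop("all-zero STRF has no profiles", call. = FALSE)
  sv <- svd(m, nu = 1L, nv = 1L)
  u <- sv$u[, 1]; v <- sv$v[, 1]
  su <- sign(u[which.max(abs(u))]); if (su == 0) su <- 1
  sp <- sign(v[which.max(abs(v))]); if (sp == 0) sp <- 1
  list(spectral = u * su, temporal = v * sp, sigma = sv$d[1] * su * sp)
}

# smallest contiguous window around the peak holding >= `frac` of the
# squared-profile energy; ties expand toward symmetry
energy_window <- function(profile, frac = 0.9) {
  e <- profile^2
  total <- sum(e)
  peak <- which.max(e)
  lo <- hi <- peak
  acc <- e[peak]
  while (acc < frac * total - 1e-12) {
    left <- if (lo > 1L) e[lo - 1L] else -Inf
    right <- if (hi < length(e)) e[hi + 1L] else -Inf
    take_left <- if (left == right) (peak - lo) <= (hi - peak) else left > right
    if (take_left && is.finite(left)) { lo <- lo - 1L; acc <- acc + e[lo] }
    else { hi <- hi + 1L; acc <- acc + e[hi] }
  }
  c(lo = lo, hi = hi, peak = peak)
}

# per-channel width on a (generally non-uniform) center-frequency grid
channel_widths <- function(center_freqs) {
  n <- length(center_freqs)
  if (n == 1L) return(1)
  d <- diff(center_freqs)
  c(d[1], (d[-1] + d[-(n - 1)]) / 2, d[n - 1])
}

#' STRF parameters from the rank-1 profiles
#'
#' Center frequency = center frequency of the spectral profile's energy
#' peak; bandwidth = summed channel widths of the smallest contiguous window
#' around the peak holding 90% of the spectral energy. Best T = location of
#' the temporal profile's energy peak (ms); duration = length of the 90%
#' temporal energy window (frames times `frame_step`, ms). The spectral
#' modulation (cycles per channel span) is the peak of the spectral
#' profile's magnitude spectrum (DC excluded); a Fourier-peak Best T variant
#' (temporal modulation, Hz) is reported alongside.
#'
#' @param profiles result of [strf_profiles()].
#' @param center_freqs channel center frequencies (Hz) covering the STRF's
#'   frequency extent.
#' @param frame_step frame step in ms.
#' @param energy_frac energy fraction defining bandwidth/duration windows
#'   (default 0.9).
#' @return one-row data frame: `center_f`, `bandwidth` (Hz), `best_t`,
#'   `duration` (ms), `spectral_modulation` (cycles/span),
#'   `temporal_modulation` (Hz).
#' @export
strf_parameters <- function(profiles, center_freqs, frame_step = 1,
                            energy_frac = 0.9) {
  sp <- profiles$spectral; tp <- profiles$temporal
  if (length(center_freqs) != length(sp)) {
    stop("`center_freqs` length must match the spectral profile", call. = FALSE)
  }
  ws <- energy_window(sp, energy_frac)
  wt <- energy_window(tp, energy_frac)
  widths <- channel_widths(center_freqs)
  data.frame(
    center_f = center_freqs[ws["peak"]],
    bandwidth = sum(widths[ws["lo"]:ws["hi"]]),
    best_t = (wt[["peak"]] - 1) * frame_step,
    duration = (wt[["hi"]] - wt[["lo"]] + 1) * frame_step,
    spectral_modulation = fft_peak_frequency(sp),
    temporal_modulation = fft_peak_frequency(tp, frame_step / 1000)
  )
}

# peak of the magnitude spectrum, DC excluded. With `dt = NULL` the result
# is in cycles over the profile's whole extent (bin index k = k cycles per
# span); with a sample spacing `dt` (seconds) it is in Hz.
fft_peak_frequency <- function(x, dt = NULL) {
  n <- length(x)
  mag <- Mod(fft(x - mean(x)))[seq_len(n %/% 2 + 1L)]
  if (length(mag) < 2L) return(0)
  k <- which.max(mag[-1L])  # skip DC
  if (is.null(dt)) k else k / (n * dt)
}

#' Population summary of STRF parameters
#'
#' Per parameter, a normalized histogram with the axis scaled to `[0, 1]` by
#' the maximum value, plus the (Best T, spectral modulation) scatter table
#' for the temporal/spectral modulation tradeoff.
#'
#' @param params data frame of [strf_parameters()] rows (one per unit).
#' @param breaks histogram bin count (default 10).
#' @return list with `histograms` (named list of data frames `mid`, `mass`;
#'   masses sum to 1, axis in units of the parameter maximum) and `scatter`
#'   (data frame `best_t`, `spectral_modulation`).
#' @export
strf_population_summary <- function(params, breaks = 10L) {
  stopifnot(nrow(params) >= 1L)
  four <- c("best_t", "duration", "center_f", "bandwidth")
  hists <- lapply(four, function(p) {
    v <- params[[p]]
    mx <- max(v)
    if (mx == 0) mx <- 1
    v <- v / mx
    h <- graphics::hist(v, breaks = seq(0, 1, length.out = breaks + 1L),
                        plot = FALSE, include.lowest = TRUE)
    data.frame(mid = h$mids, mass = h$counts / sum(h$counts))
  })
  names(hists) <- four
  list(histograms = hists,
       scatter = params[, c("best_t", "spectral_modulation")])
}
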
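# The hierarchical sparse-coding network: alternating S layers (sparse
# coding, implemented as convolution with learned dictionary atoms) and C
# layers (max pooling). Dictionaries are learned layer-wise, bottom-up, by
# online dictionary learning with an L1-penalized coding step:
#
#   minimize_{B, r^k}  sum_k ||x^k - B r^k||_2^2 + lambda ||r^k||_1
#   subject to         ||b_j||_2 <= 1
#
# where x^k are k x k x u patches of the layer input, B the dictionary, and
# r^k the sparse codes.

#' Construct one layer specification
#'
#' @param kind `"S"` (sparse coding) or `"C"` (pooling).
#' @param kernel patch side length for S layers (default 10).
#' @param n_maps number of dictionary atoms / feature maps (S layers).
#' @param conv_stride convolution stride (S layers; 1 or 2).
#' @param pool_size,pool_stride pooling window and stride (C layers; defaults
#'   2 and 1).
#' @param pool_mode `"max"`, `"average"`, or `"none"` (pass-through).
#' @param lambda sparseness penalty for the coding step (default 1).
#' @param regularizer `"L1"` (sparse coding) or `"L2"` (ridge control).
#' @return a `"layer_spec"` list.
#' @export
layer_spec <- function(kind = c("S", "C"), kernel = 10L, n_maps = NULL,
                       conv_stride = 1L, pool_size = 2L, pool_stride = 1L,
                       pool_mode = c("max", "average", "none"),
                       lambda = 1, regularizer = c("L1", "L2")) {
  kind <- match.arg(kind)
  pool_mode <- match.arg(pool_mode)
  regularizer <- match.arg(regularizer)
  if (kind == "S") {
    if (is.null(n_maps)) stop("S layers need `n_maps`")
    if (!conv_stride %in% c(1L, 2L)) stop("`conv_stride` must be 1 or 2")
    if (lambda <= 0) stop("`lambda` must be > 0")
  } else {
    if (pool_size < 1L) stop("`pool_size` must be >= 1")
  }
  structure(list(kind = kind, kernel = as.integer(kernel),
                 n_maps = if (is.null(n_maps)) NULL else as.integer(n_maps),
                 conv_stride = as.integer(conv_stride),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 pool_mode = pool_mode, lambda = lambda,
                 regularizer = regularizer),
            class = "layer_spec")
}

#' Build an alternating S/C architecture
#'
#' One S layer per entry of `n_maps`, each followed by a C layer. Layers are
#' named `S1, C1, S2, C2, ...`.
#'
#' @param n_maps atoms per S layer.
#' @param kernels kernel per S layer (recycled; default 10).
#' @param strides convolution stride per S layer (recycled; default 1).
#' @param lambda sparseness penalty (recycled over S layers).
#' @param pool_mode,pool_size,pool_stride pooling configuration shared by the
#'   C layers.
#' @param regularizer `"L1"` or `"L2"` coding penalty.
#' @return a `"shmax_arch"` object (named list of [layer_spec()]s).
#' @export
#' @examples
#' arch <- default_architecture()
#' rf_extent(arch, "C6")
shmax_architecture <- function(n_maps, kernels = 10L, strides = 1L, lambda = 1,
                               pool_mode = "max", pool_size = 2L,
                               pool_stride = 1L, regularizer = "L1") {
  n_s <- length(n_maps)
  kernels <- rep_len(as.integer(kernels), n_s)
  strides <- rep_len(as.integer(strides), n_s)
  lambda <- rep_len(lambda, n_s)
  layers <- list()
  for (i in seq_len(n_s)) {
    layers[[paste0("S", i)]] <- layer_spec("S", kernel = kernels[i],
                                           n_maps = n_maps[i],
                                           conv_stride = strides[i],
                                           lambda = lambda[i],
                                           regularizer = regularizer)
    layers[[paste0("C", i)]] <- layer_spec("C", pool_size = pool_size,
                                           pool_stride = pool_stride,
                                           pool_mode = pool_mode)
  }
  structure(layers, class = "shmax_arch")
}

#' @rdname shmax_architecture
#' @details `default_architecture()` is the 12-layer configuration used at
#'   full scale: six S layers (kernels 10x10, convolution strides 2, 2, 1, 1,
#'   1, 1, feature-map counts 100, 200, 300, 400, 500, 500), each followed by
#'   max pooling with window 2 and stride 1.
#' @export
default_architecture <- function(lambda = 1, pool_mode = "max") {
  shmax_architecture(n_maps = c(100L, 200L, 300L, 400L, 500L, 500L),
                     kernels = 10L, strides = c(2L, 2L, 1L, 1L, 1L, 1L),
                     lambda = lambda, pool_mode = pool_mode)
}

#' @export
print.shmax_arch <- function(x, ...) {
  for (nm in names(x)) {
    l <- x[[nm]]
    if (l$kind == "S") {
      cat(sprintf("%-3s sparse coding: kernel %dx%d, %d maps, stride %d, lambda %g (%s)\n",
                  nm, l$kernel, l$kernel, l$n_maps, l$conv_stride, l$lambda,
                  l$regularizer))
    } else {
      cat(sprintf("%-3s pooling: %s, window %d, stride %d\n",
                  nm, l$pool_mode, l$pool_size, l$pool_stride))
    }
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# receptive-field arithmetic

#' Receptive-field extent and output-grid spacing of every layer
#'
#' Standard receptive-field composition: an S layer with kernel `k` adds
#' `(k - 1) * jump` to the extent and multiplies the output-grid spacing
#' (`jump`, in input frames per output step) by its stride; a pooling layer
#' with window `w` adds `(w - 1) * jump`.
#'
#' @param arch a [shmax_architecture()] object.
#' @return data frame with one row per layer: `layer`, `rf` (extent, frames
#'   or channels -- receptive fields are square), `jump`.
#' @export
layer_geometry <- function(arch) {
  rf <- 1L; jump <- 1L
  out <- data.frame(layer = character(0), rf = integer(0), jump = integer(0))
  for (nm in names(arch)) {
    l <- arch[[nm]]
    if (l$kind == "S") {
      rf <- rf + (l$kernel - 1L) * jump
      jump <- jump * l$conv_stride
    } else if (l$pool_mode != "none") {
      rf <- rf + (l$pool_size - 1L) * jump
      jump <- jump * l$pool_stride
    }
    out <- rbind(out, data.frame(layer = nm, rf = rf, jump = jump))
  }
  out
}

#' Receptive-field extent of a layer's units
#'
#' @param arch architecture.
#' @param layer_id layer name, e.g. `"S2"` or `"C6"`.
#' @return named integer vector `c(freq = ..., time = ...)` -- receptive
#'   fields are square, so the two entries are equal; in frames at the input
#'   frame step (1 ms by default, so the time entry doubles as ms).
#' @export
rf_extent <- function(arch, layer_id) {
  geo <- layer_geometry(arch)
  i <- match(layer_id, geo$layer)
  if (is.na(i)) stop("unknown layer: ", layer_id, call. = FALSE)
  c(freq = geo$rf[i], time = geo$rf[i])
}

# ---------------------------------------------------------------------------
# feature stacks and patches

# coerce inputs (cochleogram / matrix / 3-D array) to an h x t x u stack
as_stack <- function(x) {
  if (inherits(x, "cochleogram")) x <- x$energy
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Sample random patches from a feature stack or cochleogram
#'
#' Draws `n_patches` square `kernel x kernel x u` patches uniformly over all
#' valid positions, flattened row-major over (height, time, map) in R's
#' native array order.
#'
#' @param stack a cochleogram, matrix, or h x t x u array.
#' @param n_patches number of patches.
#' @param kernel patch side length.
#' @param seed integer seed (deterministic sampling).
#' @return matrix `n_patches x (kernel^2 * u)`, with attribute `positions`
#'   (matrix of 1-based top-left corners) and `kernel`, `u`.
#' @export
sample_patches <- function(stack, n_patches, kernel = 10L, seed = 1L) {
  x <- as_stack(stack)
  h <- dim(x)[1]; t <- dim(x)[2]; u <- dim(x)[3]
  if (h < kernel || t < kernel) stop("stack smaller than the kernel", call. = FALSE)
  stopifnot_scalar_int(n_patches, "n_patches")
  nh <- h - kernel + 1L; nt <- t - kernel + 1L
  pos <- with_seed(seed, cbind(sample.int(nh, n_patches, replace = TRUE),
                               sample.int(nt, n_patches, replace = TRUE)))
  out <- matrix(0, n_patches, kernel * kernel * u)
  for (i in seq_len(n_patches)) {
    out[i, ] <- as.vector(x[pos[i, 1]:(pos[i, 1] + kernel - 1L),
                            pos[i, 2]:(pos[i, 2] + kernel - 1L), , drop = FALSE])
  }
  structure(out, positions = pos, kernel = as.integer(kernel), u = u)
}

# im2col: all valid patches at the given stride, as rows of a matrix.
# Output position (i, j) maps to input top-left ((i-1)*stride+1, (j-1)*stride+1).
im2col <- function(x, kernel, stride, t_range = NULL) {
  h <- dim(x)[1]; t <- dim(x)[2]; u <- dim(x)[3]
  oh <- (h - kernel) %/% stride + 1L
  ot_all <- (t - kernel) %/% stride + 1L
  ot_idx <- t_range %||% seq_len(ot_all)
  n_pos <- oh * length(ot_idx)
  out <- matrix(0, n_pos, kernel * kernel * u)
  hi <- (seq_len(oh) - 1L) * stride
  ti <- (ot_idx - 1L) * stride
  col <- 0L
  for (uu in seq_len(u)) {
    for (q in seq_len(kernel)) {
      for (p in seq_len(kernel)) {
        col <- col + 1L
        out[, col] <- x[hi + p, ti + q, uu]  # oh x ot block, column-major
      }
    }
  }
  structure(out, oh = oh, ot = length(ot_idx))
}

# ---------------------------------------------------------------------------
# coding

# batch lasso coding by coordinate descent, vectorized over patches.
# X: n x N (columns are patches), B: n x m. Minimizes, per column,
# ||x - B r||_2^2 + lambda ||r||_1.
code_lasso <- function(X, B, lambda, max_sweeps = 100L, tol = 1e-7) {
  G <- crossprod(B)                 # m x m
  C <- crossprod(B, X)              # m x N
  m <- ncol(B); N <- ncol(X)
  R <- matrix(0, m, N)
  d <- diag(G)
  active <- d > 1e-12
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(m)) {
      if (!active[j]) next
      cj <- C[j, ] - G[j, ] %*% R + d[j] * R[j, ]
      new <- soft_threshold(as.numeric(cj), lambda / 2) / d[j]
      delta <- max(delta, max(abs(new - R[j, ])))
      R[j, ] <- new
    }
    if (delta < tol) break
  }
  R
}

# ridge coding (L2-regularized control): r = (G + lambda I)^-1 B'x
code_ridge <- function(X, B, lambda) {
  G <- crossprod(B)
  solve(G + diag(lambda, ncol(B)), crossprod(B, X))
}

code_patches <- function(X, B, lambda, regularizer = "L1", ...) {
  if (regularizer == "L2") code_ridge(X, B, lambda) else code_lasso(X, B, lambda, ...)
}

# Eq-style objective, averaged over patches
sc_objective <- function(patches, B, lambda, regularizer = "L1", ...) {
  X <- t(patches)
  R <- code_patches(X, B, lambda, regularizer, ...)
  resid <- X - B %*% R
  pen <- if (regularizer == "L2") lambda * colSums(R^2) else lambda * colSums(abs(R))
  mean(colSums(resid^2) + pen)
}

#' Learn a sparse-coding dictionary from patches
#'
#' Online dictionary learning: minibatch coordinate-descent lasso coding
#' followed by a block coordinate-descent dictionary update on running
#' second-moment accumulators, with atoms projected to the unit L2 ball.
#' After the final epoch atoms are renormalized to unit norm (atoms that were
#' never activated keep their normalized initialization).
#'
#' @param patches matrix with one flattened patch per row (e.g. from
#'   [sample_patches()]).
#' @param m number of atoms.
#' @param lambda sparseness penalty (> 0).
#' @param epochs passes over the patch set (default 5).
#' @param batch_size minibatch size (default 256).
#' @param seed integer seed (initialization and patch order).
#' @param regularizer `"L1"` (default) or `"L2"`.
#' @param kernel,u patch geometry; taken from `patches` attributes when
#'   present.
#' @param forget per-minibatch forgetting factor on the second-moment
#'   accumulators (default 0.9), so that codes computed against stale
#'   dictionaries are progressively down-weighted.
#' @param init `"kmeans"` (default; k-means centers of the normalized
#'   patches, a standard dictionary initialization that avoids
#'   mixed-atom local minima) or `"patches"` (random normalized patches).
#' @return `"dictionary_bank"`: list with `B` (n x m atom matrix, columns
#'   unit-norm), `m`, `n`, `kernel`, `u`, `lambda`, `regularizer`,
#'   `objective_trace` (mean minibatch objective per epoch).
#' @export
learn_dictionary <- function(patches, m, lambda = 1, epochs = 5L,
                             batch_size = 256L, seed = 1L,
                             regularizer = c("L1", "L2"),
                             kernel = NULL, u = NULL, forget = 0.9,
                             init = c("kmeans", "patches")) {
  init <- match.arg(init)
  regularizer <- match.arg(regularizer)
  stopifnot_scalar_int(m, "m")
  if (lambda <= 0) stop("`lambda` must be > 0")
  kernel <- kernel %||% attr(patches, "kernel")
  u <- u %||% attr(patches, "u")
  X_all <- t(as.matrix(patches))  # n x N
  n <- nrow(X_all); N <- ncol(X_all)

  norms <- sqrt(colSums(X_all^2))
  if (all(norms == 0)) {
    warning("all patches are zero; dictionary left at (zero) initialization")
    return(new_bank(matrix(0, n, m), kernel, u, lambda, regularizer, numeric(0)))
  }

  with_seed(seed, {
    B <- init_dictionary(X_all, m, norms, init)
    B_init <- B
    A <- matrix(0, m, m); Bm <- matrix(0, n, m)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      obj <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        Xb <- X_all[, batches[[bi]], drop = FALSE]
        R <- code_patches(Xb, B, lambda, regularizer, max_sweeps = 50L)
        resid <- Xb - B %*% R
        pen <- if (regularizer == "L2") lambda * colSums(R^2)
               else lambda * colSums(abs(R))
        obj[bi] <- mean(colSums(resid^2) + pen)
        # forgetting factor: down-weight codes computed with older
        # dictionaries so the accumulators track the current dictionary
        A <- forget * A + tcrossprod(R)
        Bm <- forget * Bm + tcrossprod(Xb, R)
        # block coordinate descent on the atoms
        for (pass in 1:2) {
          for (j in seq_len(m)) {
            if (A[j, j] < 1e-10) next
            v <- (Bm[, j] - B %*% A[, j]) / A[j, j] + B[, j]
            B[, j] <- v / max(1, sqrt(sum(v^2)))
          }
        }
      }
      trace[ep] <- mean(obj)
      # replace unused or duplicated atoms with poorly reconstructed
      # patches (standard dead-atom maintenance); skip after the last
      # epoch so returned atoms are the converged ones
      if (ep < epochs) {
        sub <- if (N > 1000L) sample.int(N, 1000L) else seq_len(N)
        Xs <- X_all[, sub, drop = FALSE]
        Rs <- code_patches(Xs, B, lambda, regularizer, max_sweeps = 50L)
        err <- colSums((Xs - B %*% Rs)^2)
        usage <- rowSums(abs(Rs) > 1e-8)
        Gb <- abs(crossprod(B))
        diag(Gb) <- 0
        dup <- vapply(seq_len(m), function(j) any(Gb[j, seq_len(j - 1L)] > 0.9),
                      TRUE)
        bad <- which(usage < max(1, 0.002 * length(sub)) | dup)
        if (length(bad) > 0L) {
          worst <- sub[order(err, decreasing = TRUE)]
          for (bj in seq_along(bad)) {
            j <- bad[bj]
            v <- X_all[, worst[min(bj, length(worst))]]
            nv <- sqrt(sum(v^2))
            if (nv == 0) next
            B[, j] <- v / nv
            A[j, ] <- 0; A[, j] <- 0; Bm[, j] <- 0
          }
        }
      }
    }
    # final renormalization: unit-norm atoms (zero atoms stay zero)
    nb <- sqrt(colSums(B^2))
    B <- sweep(B, 2, pmax(nb, 1e-12), "/")
    bank <- new_bank(B, kernel, u, lambda, regularizer, trace)
    bank$B_init <- B_init
    bank
  })
}

# dictionary initialization (runs inside the caller's seeded RNG scope)
init_dictionary <- function(X_all, m, norms, init) {
  nz <- which(norms > 0)
  if (init == "kmeans" && length(nz) > 2L * m) {
    sub <- if (length(nz) > 2000L) sample(nz, 2000L) else nz
    Xn <- t(X_all[, sub, drop = FALSE]) / norms[sub]
    nstart <- if (m <= 16L) 8L else 3L
    km <- tryCatch(
      suppressWarnings(kmeans(Xn, centers = m, nstart = nstart, iter.max = 30L)),
      error = function(e) NULL)
    if (!is.null(km) && nrow(km$centers) == m) {
      B <- t(km$centers)
      cn <- sqrt(colSums(B^2))
      ok <- cn > 1e-10
      B[, ok] <- sweep(B[, ok, drop = FALSE], 2, cn[ok], "/")
      if (any(!ok)) {
        idx <- sample(nz, sum(!ok), replace = sum(!ok) > length(nz))
        B[, !ok] <- sweep(X_all[, idx, drop = FALSE], 2, norms[idx], "/")
      }
      return(B)
    }
  }
  idx <- sample(nz, m, replace = m > length(nz))
  sweep(X_all[, idx, drop = FALSE], 2, norms[idx], "/")
}

new_bank <- function(B, kernel, u, lambda, regularizer, trace) {
  dimnames(B) <- NULL
  structure(list(B = B, m = ncol(B), n = nrow(B),
                 kernel = kernel, u = u, lambda = lambda,
                 regularizer = regularizer, objective_trace = trace),
            class = "dictionary_bank")
}

#' @export
print.dictionary_bank <- function(x, ...) {
  cat(sprintf("dictionary bank: %d atoms of dim %d (kernel %s, u %s, lambda %g, %s)\n",
              x$m, x$n, x$kernel %||% "?", x$u %||% "?", x$lambda, x$regularizer))
  invisible(x)
}

# ---------------------------------------------------------------------------
# encoding and pooling

new_stack <- function(values, layer_id = NULL) {
  structure(values, layer_id = layer_id, class = c("feature_stack", "array"))
}

#' Convolutional encoding with a dictionary bank
#'
#' Each atom is cross-correlated with the input stack ("valid" region, no
#' padding): map `j` at output position `(h, t)` is the inner product of atom
#' `j` with the `k x k x u` patch whose top-left corner is at input position
#' `((h-1)*s + 1, (t-1)*s + 1)`.
#'
#' @param stack cochleogram / matrix / h x t x u array.
#' @param bank a [learn_dictionary()] bank whose `u` matches the stack.
#' @param s_conv convolution stride.
#' @param chunk number of output time columns processed per block (memory
#'   control).
#' @return `"feature_stack"`: oh x ot x m array.
#' @export
encode_conv <- function(stack, bank, s_conv = 1L, chunk = 1024L) {
  x <- as_stack(stack)
  k <- bank$kernel
  if (dim(x)[3] != bank$u) stop("stack channel count does not match bank `u`", call. = FALSE)
  if (dim(x)[1] < k || dim(x)[2] < k) stop("stack smaller than the kernel", call. = FALSE)
  oh <- (dim(x)[1] - k) %/% s_conv + 1L
  ot <- (dim(x)[2] - k) %/% s_conv + 1L
  out <- array(0, c(oh, ot, bank$m))
  for (t0 in seq(1L, ot, by = chunk)) {
    t_idx <- t0:min(t0 + chunk - 1L, ot)
    P <- im2col(x, k, s_conv, t_range = t_idx)
    R <- P %*% bank$B      # (oh*|t_idx|) x m
    out[, t_idx, ] <- array(R, c(oh, length(t_idx), bank$m))
  }
  new_stack(out)
}

#' Sparse-coding encoding (per-patch lasso optimization)
#'
#' Reference encoder: at every valid position the code vector minimizes
#' `||x - B r||^2 + lambda ||r||_1` for the learned dictionary (coordinate
#' descent). Slower than [encode_conv()]; used for comparing the two
#' encoders' response statistics.
#'
#' @inheritParams encode_conv
#' @param lambda penalty (defaults to the bank's).
#' @param max_sweeps,tol coordinate-descent controls.
#' @return `"feature_stack"`: oh x ot x m array of codes.
#' @export
encode_optimize <- function(stack, bank, lambda = NULL, s_conv = 1L,
                            chunk = 512L, max_sweeps = 200L, tol = 1e-8) {
  x <- as_stack(stack)
  k <- bank$kernel
  lambda <- lambda %||% bank$lambda
  if (dim(x)[3] != bank$u) stop("stack channel count does not match bank `u`", call. = FALSE)
  oh <- (dim(x)[1] - k) %/% s_conv + 1L
  ot <- (dim(x)[2] - k) %/% s_conv + 1L
  out <- array(0, c(oh, ot, bank$m))
  for (t0 in seq(1L, ot, by = chunk)) {
    t_idx <- t0:min(t0 + chunk - 1L, ot)
    P <- im2col(x, k, s_conv, t_range = t_idx)
    R <- code_patches(t(P), bank$B, lambda, bank$regularizer,
                      max_sweeps = max_sweeps, tol = tol)
    out[, t_idx, ] <- array(t(R), c(oh, length(t_idx), bank$m))
  }
  new_stack(out)
}

#' Spatial pooling over feature maps
#'
#' Slides a `size x size` window with the given stride over each map and
#' takes the maximum (or average). With the default window 2 / stride 1 the
#' output has one fewer row and one fewer column than the input.
#'
#' @param stack feature stack (h x t x m array).
#' @param mode `"max"` or `"average"`.
#' @param size pooling window side.
#' @param stride pooling stride.
#' @return pooled `"feature_stack"`.
#' @export
pool <- function(stack, mode = c("max", "average"), size = 2L, stride = 1L) {
  mode <- match.arg(mode)
  x <- as_stack(stack)
  h <- dim(x)[1]; t <- dim(x)[2]
  if (size > h || size > t) stop("pooling window larger than the stack", call. = FALSE)
  oh <- (h - size) %/% stride + 1L
  ot <- (t - size) %/% stride + 1L
  hi <- (seq_len(oh) - 1L) * stride
  ti <- (ot_seq <- seq_len(ot) - 1L) * stride
  out <- NULL
  for (a in seq_len(size)) {
    for (b in seq_len(size)) {
      block <- x[hi + a, ti + b, , drop = FALSE]
      out <- if (is.null(out)) block
             else if (mode == "max") pmax(out, block)
             else out + block
    }
  }
  if (mode == "average") out <- out / (size * size)
  new_stack(array(out, c(oh, ot, dim(x)[3])))
}

# ---------------------------------------------------------------------------
# layer-wise training

#' Train the network layer-wise
#'
#' Bottom-up: for each S layer, sample patches from the current corpus
#' representation, learn the dictionary, encode the corpus by convolution,
#' then apply the following C layer's pooling (or pass through for
#' `pool_mode = "none"`). Training is deterministic given `seed`.
#'
#' @param cochleograms list of cochleograms (or stacks); the training corpus.
#' @param arch a [shmax_architecture()].
#' @param n_patches patches sampled per S layer (default 2000; split across
#'   corpus items).
#' @param seed integer seed.
#' @param epochs,batch_size dictionary-learning controls.
#' @param keep_activations keep the per-layer encoded corpus in the model
#'   (default TRUE; needed by the selectivity/decoding analyses).
#' @param start_from optional partially trained model: its banks and
#'   activations for layers below `start_layer` are reused (used by the
#'   lambda sweep and kernel-variant experiments).
#' @param start_layer first S-layer name to (re)train when `start_from` is
#'   given.
#' @param verbose print per-layer progress.
#' @return `"shmax_model"`: list with `arch`, `banks` (per S layer),
#'   `activations` (per layer per corpus item, if kept), `geometry`.
#' @export
train_network <- function(cochleograms, arch, n_patches = 2000L, seed = 1L,
                          epochs = 3L, batch_size = 256L,
                          keep_activations = TRUE, start_from = NULL,
                          start_layer = NULL, verbose = FALSE) {
  if (length(cochleograms) == 0L) stop("empty corpus", call. = FALSE)
  stacks <- lapply(cochleograms, as_stack)
  banks <- list()
  activations <- list()
  layer_names <- names(arch)
  skip_until <- 0L
  if (!is.null(start_from)) {
    stopifnot(!is.null(start_layer))
    i_start <- match(start_layer, layer_names)
    if (is.na(i_start)) stop("unknown `start_layer`")
    below <- layer_names[seq_len(i_start - 1L)]
    banks <- start_from$banks[intersect(names(start_from$banks), below)]
    prev <- if (i_start == 1L) NULL else below[length(below)]
    if (!is.null(prev)) stacks <- start_from$activations[[prev]]
    activations <- start_from$activations[intersect(names(start_from$activations), below)]
    skip_until <- i_start - 1L
  }
  li <- 0L
  for (nm in layer_names) {
    li <- li + 1L
    if (li <= skip_until) next
    l <- arch[[nm]]
    if (l$kind == "S") {
      # split the patch budget over corpus items
      per_item <- diff(round(seq(0, n_patches, length.out = length(stacks) + 1L)))
      plist <- list()
      for (i in seq_along(stacks)) {
        if (per_item[i] == 0L) next
        plist[[length(plist) + 1L]] <-
          sample_patches(stacks[[i]], per_item[i], kernel = l$kernel,
                         seed = seed + 1000L * li + i)
      }
      patches <- do.call(rbind, plist)
      bank <- learn_dictionary(patches, m = l$n_maps, lambda = l$lambda,
                               epochs = epochs, batch_size = batch_size,
                               seed = seed + li, regularizer = l$regularizer,
                               kernel = l$kernel, u = dim(stacks[[1]])[3])
      banks[[nm]] <- bank
      stacks <- lapply(stacks, encode_conv, bank = bank, s_conv = l$conv_stride)
    } else if (l$pool_mode != "none") {
      stacks <- lapply(stacks, pool, mode = l$pool_mode,
                       size = l$pool_size, stride = l$pool_stride)
    }
    if (keep_activations) activations[[nm]] <- stacks
    if (verbose) {
      d <- dim(stacks[[1]])
      message(sprintf("%s: %d x %d x %d", nm, d[1], d[2], d[3]))
    }
  }
  structure(list(arch = arch, banks = banks,
                 activations = if (keep_activations) activations else NULL,
                 geometry = layer_geometry(arch)),
            class = "shmax_model")
}

#' @export
print.shmax_model <- function(x, ...) {
  cat(sprintf("hierarchical sparse-coding model: %d layers (%s)\n",
              length(x$arch), paste(names(x$arch), collapse = " ")))
  if (!is.null(x$activations)) {
    cat(sprintf("activations kept for %d layers, %d corpus item(s)\n",
                length(x$activations), length(x$activations[[1]])))
  }
  invisible(x)
}

#' Encode a new input through a trained model
#'
#' @param model a [train_network()] model.
#' @param x cochleogram or stack.
#' @param up_to last layer to compute (default: the whole network).
#' @return named list of feature stacks, one per layer up to `up_to`.
#' @export
encode_network <- function(model, x, up_to = NULL) {
  stack <- as_stack(x)
  out <- list()
  for (nm in names(model$arch)) {
    l <- model$arch[[nm]]
    stack <- if (l$kind == "S") {
      encode_conv(stack, model$banks[[nm]], s_conv = l$conv_stride)
    } else if (l$pool_mode != "none") {
      pool(stack, mode = l$pool_mode, size = l$pool_size, stride = l$pool_stride)
    } else stack
    out[[nm]] <- stack
    if (!is.null(up_to) && nm == up_to) break
  }
  out
}
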
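# Shared fixtures, memoized across test files. Three seeded corpus/model
# replicates (fixture seeds 1:3) at the desk-scale test profile:
# 12-phoneme inventory, 96 tokens, 96 cochlear channels, 6-layer network
# (S1/C1/S2/C2/S3/C3 with 16/24/32 maps, strides 2/2/1), 2000 patches per
# layer.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

fx_inventory <- function() fx_memo("inventory", make_inventory(12, seed = 7))

fx_filterbank <- function() fx_memo("fb", build_filterbank(96, 73, 7630, 16000))

fx_arch <- function() {
  fx_memo("arch", shmax_architecture(n_maps = c(16L, 24L, 32L), kernels = 10L,
                                     strides = c(2L, 2L, 1L)))
}

fx_corpus <- function(i) {
  fx_memo(paste0("corpus", i),
          synthesize(fx_inventory(), 96, jitter_sd = 0.05, seed = 100L + i))
}

fx_cochleogram <- function(i) {
  fx_memo(paste0("coch", i), cochleogram(fx_corpus(i)$wave, fx_filterbank()))
}

fx_model <- function(i) {
  fx_memo(paste0("model", i),
          train_network(list(fx_cochleogram(i)), fx_arch(),
                        n_patches = 2000L, seed = 200L + i, epochs = 3L))
}

# selectivity analysis of one layer of fixture model i
fx_selectivity <- function(i, layer) {
  fx_memo(paste0("sel", i, "_", layer), {
    model <- fx_model(i)
    geo <- model$geometry
    gi <- match(layer, geo$layer)
    layer_selectivity(model$activations[[layer]][[1]],
                      fx_corpus(i)$transcript,
                      rf = geo$rf[gi], jump = geo$jump[gi],
                      n_groups = 6L, seed = 5L)
  })
}

# planted-dictionary recovery problem: 8 orthogonal atoms in R^16, patches
# are sparse non-negative combinations (1-2 active atoms, amplitudes in
# [1, 2]) plus small Gaussian noise
make_planted <- function(seed, n_patches = 2000L) {
  withr::with_seed(seed, {
    atoms <- qr.Q(qr(matrix(rnorm(16 * 16), 16)))[, 1:8]
    codes <- matrix(0, 8, n_patches)
    for (i in seq_len(n_patches)) {
      k <- sample(1:2, 1, prob = c(0.7, 0.3))
      codes[sample(1:8, k), i] <- runif(k, 1, 2)
    }
    list(atoms = atoms,
         patches = t(atoms %*% codes + 0.005 * matrix(rnorm(16 * n_patches), 16)))
  })
}

# greedy 1-1 matching of learned to true atoms; counts matches with
# |cosine| above the threshold
greedy_atom_matches <- function(true_atoms, learned, threshold = 0.9) {
  cs <- abs(crossprod(true_atoms, learned))
  used <- integer(0)
  n <- 0L
  for (r in seq_len(nrow(cs))) {
    j <- which.max(replace(cs[r, ], used, -1))
    used <- c(used, j)
    if (cs[r, j] > threshold) n <- n + 1L
  }
  n
}

# literal triple-sum convolutional encoder (oracle for the conv encoding)
oracle_encode <- function(x, B, k, s) {
  u <- dim(x)[3]
  oh <- (dim(x)[1] - k) %/% s + 1L
  ot <- (dim(x)[2] - k) %/% s + 1L
  m <- ncol(B)
  out <- array(0, c(oh, ot, m))
  for (j in seq_len(m)) {
    b <- array(B[, j], c(k, k, u))
    for (hh in seq_len(oh)) for (tt in seq_len(ot)) {
      acc <- 0
      for (p in 0:(k - 1)) for (q in 0:(k - 1)) for (uu in seq_len(u)) {
        acc <- acc + x[s * (hh - 1) + p + 1, s * (tt - 1) + q + 1, uu] *
          b[p + 1, q + 1, uu]
      }
      out[hh, tt, j] <- acc
    }
  }
  out
}

# literal two-loop F-ratio oracle
oracle_f_ratio <- function(psi, groups) {
  gs <- unique(groups)
  n <- length(gs); m <- nrow(psi)
  grand <- colMeans(psi)
  num <- 0
  for (g in gs) {
    idx <- which(groups == g)
    mu <- colMeans(psi[idx, , drop = FALSE])
    num <- num + length(idx) * sum((mu - grand)^2)
  }
  den <- 0
  for (g in gs) {
    for (i in which(groups == g)) {
      mu <- colMeans(psi[groups == g, , drop = FALSE])
      den <- den + sum((psi[i, ] - mu)^2)
    }
  }
  (num / (n - 1)) / (den / (m - n))
}

# exact one-sided rank-sum p-value by enumeration (small n, no ties)
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  combos <- utils::combn(nx + ny, nx)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)])
  w_all <- apply(combos, 2, function(idx) sum(rank(c(x, y))[idx]))
  mean(w_all >= w_obs)
}

# a hand-built response table (for direct PSI / active-unit constructions)
fake_response_table <- function(amplitudes, resp = NULL,
                                silence_frames = integer(0),
                                speech_frames = integer(0)) {
  structure(list(resp = resp, amplitudes = amplitudes,
                 silence_frames = silence_frames,
                 speech_frames = speech_frames,
                 labels = sort(unique(amplitudes$label)),
                 n_units = max(amplitudes$unit), rf = 1L, jump = 1L),
            class = "response_table")
}
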
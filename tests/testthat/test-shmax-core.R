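# independent per-patch coordinate-descent lasso oracle (scalar loops,
# run to tight tolerance)
oracle_lasso <- function(x, B, lambda, iters = 5000L, tol = 1e-10) {
  m <- ncol(B)
  r <- numeric(m)
  for (it in seq_len(iters)) {
    r_old <- r
    for (j in seq_len(m)) {
      resid <- x - B %*% r + B[, j] * r[j]
      cj <- sum(B[, j] * resid)
      r[j] <- sign(cj) * max(abs(cj) - lambda / 2, 0) / sum(B[, j]^2)
    }
    if (max(abs(r - r_old)) < tol) break
  }
  r
}

lasso_objective <- function(x, B, r, lambda) {
  sum((x - B %*% r)^2) + lambda * sum(abs(r))
}

test_that("patch sampling is seeded, in-bounds, and matches positional lookup", {
  x <- array(rnorm(12 * 15 * 2), c(12, 15, 2))
  p1 <- sample_patches(x, 20, kernel = 4, seed = 5)
  p2 <- sample_patches(x, 20, kernel = 4, seed = 5)
  expect_identical(p1, p2)
  pos <- attr(p1, "positions")
  for (i in seq_len(nrow(pos))) {
    expect_equal(p1[i, ],
                 as.vector(x[pos[i, 1]:(pos[i, 1] + 3), pos[i, 2]:(pos[i, 2] + 3), ]))
  }
  # a stack exactly one kernel wide has a single valid patch
  y <- array(rnorm(100), c(10, 10, 1))
  pu <- sample_patches(y, 7, kernel = 10, seed = 1)
  expect_true(all(apply(pu, 1, function(r) identical(r, as.vector(y)))))
  expect_error(sample_patches(y, 5, kernel = 11), "smaller than the kernel")
})

test_that("dictionary learning enforces the unit-norm constraint and reduces the objective", {
  d <- make_planted(11, n_patches = 2300L)
  train <- d$patches[1:2000, ]
  held <- d$patches[2001:2300, ]   # held out from the same process
  bank <- learn_dictionary(train, m = 8, lambda = 0.1, epochs = 4, seed = 11)
  norms <- sqrt(colSums(bank$B^2))
  expect_true(all(norms >= 1 - 1e-6 & norms <= 1 + 1e-12))
  # objective on the held-out patch set not worse than at initialization
  expect_lte(shmax:::sc_objective(held, bank$B, 0.1),
             shmax:::sc_objective(held, bank$B_init, 0.1))
  # minibatch objective trace decreases in the median across epochs
  expect_lte(median(diff(bank$objective_trace)), 0)
})

test_that("a huge penalty drives codes to zero; all-zero patches warn", {
  d <- make_planted(4)
  bank <- learn_dictionary(d$patches, m = 8, lambda = 0.1, epochs = 2, seed = 4)
  codes <- shmax:::code_lasso(t(d$patches[1:100, ]), bank$B, lambda = 100)
  expect_lt(mean(abs(codes)), 1e-3)
  expect_warning(learn_dictionary(matrix(0, 50, 16), m = 4, lambda = 1),
                 "all patches are zero")
})

test_that("convolutional encoding equals the literal triple-sum evaluation", {
  withr::with_seed(21, {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    B <- matrix(rnorm(3 * 3 * 2 * 2), 18, 2)
  })
  bank <- shmax:::new_bank(B, kernel = 3L, u = 2L, lambda = 1, "L1", numeric(0))
  for (s in 1:2) {
    enc <- encode_conv(x, bank, s_conv = s)
    expect_equal(unclass(enc), oracle_encode(x, B, 3L, s), tolerance = 1e-12)
  }
})

test_that("a delta-kernel basis reproduces the input channel over the valid region", {
  x <- array(rnorm(8 * 9 * 2), c(8, 9, 2))
  B <- matrix(0, 3 * 3 * 2, 1)
  B[1, 1] <- 1  # 1 at patch position (0, 0, channel 1)
  bank <- shmax:::new_bank(B, kernel = 3L, u = 2L, lambda = 1, "L1", numeric(0))
  enc <- encode_conv(x, bank, s_conv = 1L)
  expect_equal(enc[, , 1], x[1:6, 1:7, 1], tolerance = 1e-14)
})

test_that("encoding output dimensions follow the stride formula", {
  x <- array(rnorm(12 * 12), c(12, 12, 1))
  bank <- shmax:::new_bank(matrix(rnorm(100), 100, 3), 10L, 1L, 1, "L1", numeric(0))
  enc <- encode_conv(x, bank, s_conv = 2L)
  expect_equal(dim(enc), c(2L, 2L, 3L))
  expect_error(encode_conv(array(rnorm(36), c(6, 6, 1)), bank), "smaller than")
  bank2 <- shmax:::new_bank(matrix(rnorm(32), 32, 2), 4L, 2L, 1, "L1", numeric(0))
  expect_error(encode_conv(x, bank2), "does not match")
})

test_that("optimization encoding solves the per-patch lasso", {
  # lambda = 0 with an orthonormal complete dictionary: codes are the
  # basis inner products
  withr::with_seed(31, {
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
    x <- array(rnorm(2 * 5), c(2, 5, 1))
  })
  bank <- shmax:::new_bank(Q, kernel = 2L, u = 1L, lambda = 1, "L1", numeric(0))
  enc0 <- encode_optimize(x, bank, lambda = 0)
  for (hh in 1:1) for (tt in 1:4) {
    patch <- as.vector(x[hh:(hh + 1), tt:(tt + 1), 1])
    expect_equal(enc0[hh, tt, ], as.numeric(crossprod(Q, patch)), tolerance = 1e-6)
  }
  # agreement with an independent coordinate-descent oracle at tol 1e-8,
  # and feasibility: never worse than the zero code
  withr::with_seed(32, {
    B <- matrix(rnorm(8 * 5), 8, 5)
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    y <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  })
  bank2 <- shmax:::new_bank(B, kernel = 2L, u = 2L, lambda = 0.3, "L1", numeric(0))
  enc <- encode_optimize(y, bank2, lambda = 0.3, max_sweeps = 500L, tol = 1e-10)
  for (hh in 1:3) for (tt in 1:5) {
    patch <- as.vector(y[hh:(hh + 1), tt:(tt + 1), ])
    r_pkg <- enc[hh, tt, ]
    r_orc <- oracle_lasso(patch, B, 0.3)
    expect_equal(lasso_objective(patch, B, r_pkg, 0.3),
                 lasso_objective(patch, B, r_orc, 0.3), tolerance = 1e-6)
    expect_lte(lasso_objective(patch, B, r_pkg, 0.3),
               lasso_objective(patch, B, numeric(5), 0.3) + 1e-12)
  }
})

test_that("pooling matches brute-force window reduction and shrinks by one", {
  x <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  pm <- pool(x, "max")
  pa <- pool(x, "average")
  expect_equal(dim(pm), c(4L, 6L, 2L))   # one fewer row and column
  brute_max <- array(0, c(4, 6, 2)); brute_avg <- brute_max
  for (a in 1:4) for (b in 1:6) for (j in 1:2) {
    w <- x[a:(a + 1), b:(b + 1), j]
    brute_max[a, b, j] <- max(w); brute_avg[a, b, j] <- mean(w)
  }
  expect_equal(unclass(pm), brute_max, tolerance = 1e-14)
  expect_equal(unclass(pa), brute_avg, tolerance = 1e-14)
  expect_true(all(pm >= pa))
  # constant input is invariant under both modes
  k <- array(2.5, c(3, 4, 1))
  expect_true(all(pool(k, "max") == 2.5))
  expect_true(all(pool(k, "average") == 2.5))
  # stride > 1 and window > 2 against brute force
  y <- array(rnorm(9 * 9), c(9, 9, 1))
  p3 <- pool(y, "max", size = 3, stride = 2)
  expect_equal(dim(p3), c(4L, 4L, 1L))
  for (a in 1:4) for (b in 1:4) {
    expect_equal(p3[a, b, 1],
                 max(y[(2 * a - 1):(2 * a + 1), (2 * b - 1):(2 * b + 1), 1]))
  }
  expect_error(pool(array(0, c(2, 2, 1)), size = 3), "larger than")
})

test_that("receptive-field extents reproduce the reference architecture size table", {
  arch <- default_architecture()
  geo <- layer_geometry(arch)
  expect_equal(geo$rf,
               c(10L, 12L, 30L, 34L, 70L, 74L, 110L, 114L, 150L, 154L, 190L, 194L))
  expect_equal(unname(rf_extent(arch, "S2")["time"]), 30L)
  expect_error(rf_extent(arch, "S9"), "unknown layer")
  # single S layer, kernel k, stride 1 -> extent k
  a1 <- shmax_architecture(n_maps = 4L, kernels = 7L, strides = 1L)
  expect_equal(unname(rf_extent(a1, "S1")["time"]), 7L)
})

test_that("a kernel-20 fifth S layer matches the default sixth layer's extent", {
  arch <- default_architecture()
  variant <- arch
  variant[["S5"]]$kernel <- 20L
  expect_equal(rf_extent(variant, "S5"), rf_extent(arch, "S6"))
})

test_that("layer-wise training is deterministic and yields the composed dimensions", {
  corp <- synthesize(fx_inventory(), 16, seed = 41)
  fb <- build_filterbank(48, 73, 7630, 16000)
  coch <- cochleogram(corp$wave, fb)
  arch <- shmax_architecture(n_maps = c(6L, 8L), kernels = 10L, strides = c(2L, 2L))
  m1 <- train_network(list(coch), arch, n_patches = 400L, seed = 17, epochs = 2L)
  m2 <- train_network(list(coch), arch, n_patches = 400L, seed = 17, epochs = 2L)
  expect_identical(m1$banks$S1$B, m2$banks$S1$B)
  expect_identical(m1$banks$S2$B, m2$banks$S2$B)
  # composed dimension arithmetic, layer by layer
  h <- 48L; t <- ncol(coch$energy)
  h1 <- (h - 10L) %/% 2L + 1L; t1 <- (t - 10L) %/% 2L + 1L
  expect_equal(dim(m1$activations$S1[[1]]), c(h1, t1, 6L))
  expect_equal(dim(m1$activations$C1[[1]]), c(h1 - 1L, t1 - 1L, 6L))
  h2 <- (h1 - 1L - 10L) %/% 2L + 1L; t2 <- (t1 - 1L - 10L) %/% 2L + 1L
  expect_equal(dim(m1$activations$S2[[1]]), c(h2, t2, 8L))
  expect_equal(dim(m1$activations$C2[[1]]), c(h2 - 1L, t2 - 1L, 8L))
  # pass-through C layers leave dimensions unchanged
  arch_np <- shmax_architecture(n_maps = c(6L, 8L), kernels = 10L,
                                strides = c(2L, 2L), pool_mode = "none")
  m3 <- train_network(list(coch), arch_np, n_patches = 400L, seed = 17, epochs = 2L)
  expect_equal(dim(m3$activations$C1[[1]]), dim(m3$activations$S1[[1]]))
})

test_that("trained atoms give sparser (more kurtotic) responses than random atoms", {
  # convolve trained deep-layer atoms on the preceding C layer's feature
  # maps, against a control basis whose elements are iid draws from the
  # trained atoms' element distribution (heavy-tailed vs Gaussian-like
  # response contrast)
  model <- fx_model(1)
  bank <- model$banks$S3
  x <- model$activations$C2[[1]][, 1:2000, , drop = FALSE]
  resp_trained <- as.numeric(encode_conv(x, bank, s_conv = 1L))
  rand_B <- withr::with_seed(9, {
    matrix(sample(as.numeric(bank$B), length(bank$B), replace = TRUE),
           nrow(bank$B))
  })
  rand_B <- sweep(rand_B, 2, sqrt(colSums(rand_B^2)), "/")
  rand_bank <- shmax:::new_bank(rand_B, bank$kernel, bank$u, 1, "L1", numeric(0))
  resp_random <- as.numeric(encode_conv(x, rand_bank, s_conv = 1L))
  k_trained <- shmax:::excess_kurtosis(resp_trained)
  k_random <- shmax:::excess_kurtosis(resp_random)
  expect_gt(k_trained, 0)
  expect_gt(k_trained, k_random)
})

test_that("models round-trip through the plain-text serialization", {
  model <- fx_model(1)
  dir <- withr::local_tempdir()
  write_model(model, dir)
  back <- read_model(dir)
  expect_equal(back$banks$S1$B, model$banks$S1$B, tolerance = 1e-15)
  expect_equal(back$banks$S3$B, model$banks$S3$B, tolerance = 1e-15)
  expect_equal(back$geometry, model$geometry)
  expect_equal(names(back$arch), names(model$arch))
})
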
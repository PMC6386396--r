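test_that("the worked two-layer geometry composes to a 7x7 receptive field", {
  # 3x3 first-layer bases, 2x2 second-layer slices, down-sampling ratio 2,
  # pooling window 2 stride 1 between the layers
  arch <- shmax_architecture(n_maps = c(4L, 2L), kernels = c(3L, 2L),
                             strides = c(2L, 1L))
  banks <- withr::with_seed(1, list(
    S1 = shmax:::new_bank(matrix(rnorm(9 * 4), 9, 4), 3L, 1L, 1, "L1", numeric(0)),
    S2 = shmax:::new_bank(matrix(rnorm(2 * 2 * 4 * 2), 16, 2), 2L, 4L, 1, "L1",
                          numeric(0))))
  model <- structure(list(arch = arch, banks = banks,
                          geometry = layer_geometry(arch)),
                     class = "shmax_model")
  s <- compose_strf(model, "S2", 1)
  expect_equal(dim(s), c(7L, 7L))
  expect_equal(unname(rf_extent(arch, "S2")), c(7L, 7L))
  expect_error(compose_strf(model, "S2", 99), "out of range")
  expect_error(compose_strf(model, "C1", 1), "S layer")
})

test_that("a one-hot second-layer weight reproduces the first-layer basis", {
  # stride 1, no pooling: the delta weight at (1, 1) in slice 3 picks out
  # basis 3, zero-padded to the composed extent
  arch <- shmax_architecture(n_maps = c(4L, 1L), kernels = c(3L, 2L),
                             strides = 1L, pool_mode = "none")
  B1 <- withr::with_seed(2, matrix(rnorm(9 * 4), 9, 4))
  W <- array(0, c(2, 2, 4)); W[1, 1, 3] <- 1
  banks <- list(
    S1 = shmax:::new_bank(B1, 3L, 1L, 1, "L1", numeric(0)),
    S2 = shmax:::new_bank(matrix(as.vector(W), ncol = 1), 2L, 4L, 1, "L1",
                          numeric(0)))
  model <- structure(list(arch = arch, banks = banks,
                          geometry = layer_geometry(arch)),
                     class = "shmax_model")
  s <- compose_strf(model, "S2", 1)
  expect_equal(dim(s), c(4L, 4L))
  expect_equal(s[1:3, 1:3], matrix(B1[, 3], 3, 3), tolerance = 1e-14)
  expect_true(all(s[4, ] == 0) && all(s[, 4] == 0))
})

test_that("composition equals the linearized network's input gradient", {
  # purely linear stack: strides 1, pooling disabled
  arch <- shmax_architecture(n_maps = c(3L, 2L), kernels = c(3L, 2L),
                             strides = 1L, pool_mode = "none")
  banks <- withr::with_seed(3, list(
    S1 = shmax:::new_bank(matrix(rnorm(9 * 3), 9, 3), 3L, 1L, 1, "L1", numeric(0)),
    S2 = shmax:::new_bank(matrix(rnorm(2 * 2 * 3 * 2), 12, 2), 2L, 3L, 1, "L1",
                          numeric(0))))
  model <- structure(list(arch = arch, banks = banks,
                          geometry = layer_geometry(arch)),
                     class = "shmax_model")
  for (unit in 1:2) {
    s <- compose_strf(model, "S2", unit)   # 4 x 4
    grad <- matrix(0, 4, 4)
    base <- encode_network(model, array(0, c(4, 4, 1)))$S2[1, 1, unit]
    for (i in 1:4) for (j in 1:4) {
      x <- array(0, c(4, 4, 1)); x[i, j, 1] <- 1
      grad[i, j] <- encode_network(model, x)$S2[1, 1, unit] - base
    }
    expect_equal(unclass(s), grad, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("composed receptive fields match rf_extent at every trained layer", {
  model <- fx_model(1)
  for (layer in c("S1", "S2", "S3")) {
    strfs <- compose_strf_layer(model, layer)
    expected <- unname(rf_extent(model$arch, layer))
    for (s in strfs[c(1, length(strfs))]) expect_equal(dim(s), expected)
  }
})

test_that("rank-1 profiles recover the SVD factors with fixed signs", {
  u <- c(0.1, -0.9, 0.4); v <- c(0.5, 0.2, -0.7, 0.1)
  strf <- outer(u, v) * 3
  pr <- strf_profiles(strf)
  expect_equal(sum(pr$spectral^2), 1, tolerance = 1e-12)
  expect_equal(sum(pr$temporal^2), 1, tolerance = 1e-12)
  # largest-magnitude elements positive
  expect_gt(pr$spectral[which.max(abs(pr$spectral))], 0)
  expect_gt(pr$temporal[which.max(abs(pr$temporal))], 0)
  # proportional to the generating factors
  expect_equal(abs(cor(pr$spectral, u)), 1, tolerance = 1e-10)
  expect_equal(abs(cor(pr$temporal, v)), 1, tolerance = 1e-10)

  # random matrix: signed sigma * outer(profiles) is the best rank-1 fit
  m <- withr::with_seed(5, matrix(rnorm(25), 5))
  pr2 <- strf_profiles(m)
  sv <- svd(m)
  best <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
  expect_equal(pr2$sigma * outer(pr2$spectral, pr2$temporal), best,
               tolerance = 1e-10)
  expect_error(strf_profiles(matrix(0, 3, 3)), "all-zero")
})

test_that("STRF parameters: point masses, Gaussian duration, flat profiles", {
  cf <- seq(100, 4000, length.out = 100)
  # one-hot spectral profile at channel 50
  sp <- numeric(100); sp[50] <- 1
  tp <- exp(-((1:61) - 31)^2 / (2 * 5^2)); tp <- tp / sqrt(sum(tp^2))
  pars <- strf_parameters(list(spectral = sp, temporal = tp), cf, frame_step = 1)
  expect_equal(pars$center_f, cf[50])
  expect_equal(pars$bandwidth, shmax:::channel_widths(cf)[50])
  # Gaussian sd = 5 frames: 90% energy window ~ 2 * 1.645 * 5 frames;
  # profile energy is the squared Gaussian (sd 5/sqrt(2)), whose 90% mass
  # spans 2 * 1.645 * 5 / sqrt(2) frames -- verify against direct
  # accumulation instead of the rule of thumb
  e <- tp^2
  width_oracle <- min(vapply(1:40, function(w) {
    if (max(vapply(seq_len(61 - w + 1), function(a) sum(e[a:(a + w - 1)]), 0)) >=
        0.9 * sum(e)) w else NA_integer_
  }, NA_integer_), na.rm = TRUE)
  expect_lte(abs(pars$duration - width_oracle), 1)
  expect_equal(pars$best_t, 30)  # peak at frame 31, 1 ms step, 0-based ms

  # flat temporal profile over 10 frames: 9 frames hold exactly 90%
  flat <- rep(1 / sqrt(10), 10)
  pars2 <- strf_parameters(list(spectral = sp, temporal = flat), cf, frame_step = 1)
  expect_equal(pars2$duration, 9)
})

test_that("STRF parameters are invariant to global sign and scale", {
  m <- withr::with_seed(6, matrix(rnorm(20 * 30), 20))
  cf <- seq(200, 5000, length.out = 20)
  p1 <- strf_parameters(strf_profiles(m), cf)
  p2 <- strf_parameters(strf_profiles(-2.7 * m), cf)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("population summaries normalize axes and masses", {
  params <- data.frame(best_t = c(5, 10, 20), duration = c(10, 30, 40),
                       center_f = c(300, 800, 1500), bandwidth = c(50, 100, 400),
                       spectral_modulation = c(1, 2, 3),
                       temporal_modulation = c(10, 20, 30))
  s <- strf_population_summary(params)
  for (h in s$histograms) {
    expect_equal(sum(h$mass), 1)
    expect_true(all(h$mid <= 1))
  }
  expect_equal(nrow(s$scatter), 3L)
  # single unit: all mass in the top bin (value scaled to exactly 1)
  s1 <- strf_population_summary(params[2, , drop = FALSE])
  for (h in s1$histograms) expect_equal(h$mass[length(h$mass)], 1)
})
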
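test_that("response amplitudes equal a brute-force scan over frames", {
  # rf = 1, jump = 1: output frame t covers input frame t (1 ms = 16 samples)
  values <- withr::with_seed(8, array(rnorm(1 * 40 * 3), c(1, 40, 3)))
  tr <- data.frame(start = c(0L, 64L, 160L, 320L, 480L),
                   end = c(64L, 160L, 320L, 480L, 640L),
                   label = c("a", "sil", "b", "a", "sil"))
  tab <- response_amplitudes(values, tr, rf = 1L, jump = 1L)
  inst_rows <- tr[tr$label != "sil", ]
  for (k in seq_len(nrow(inst_rows))) {
    fr <- (floor(inst_rows$start[k] / 16) + 1):ceiling(inst_rows$end[k] / 16)
    for (u in 1:3) {
      got <- tab$amplitudes$amplitude[tab$amplitudes$unit == u &
                                        tab$amplitudes$instance == k]
      expect_equal(got, max(abs(values[1, fr, u])))
    }
  }
  # silence frames lie inside the silence intervals
  expect_true(all(tab$silence_frames %in% c(5:10, 31:40)))
  # a single spike of -3 gives amplitude 3; constant zero gives 0
  z <- array(0, c(1, 40, 1)); z[1, 22, 1] <- -3  # frame 22: inside instance 3
  tz <- response_amplitudes(z, tr, rf = 1L, jump = 1L)
  expect_equal(tz$amplitudes$amplitude[tz$amplitudes$instance == 3], 3)
  expect_equal(tz$amplitudes$amplitude[tz$amplitudes$instance == 1], 0)
})

test_that("receptive-field overlap mapping respects rf and jump", {
  # jump 2, rf 4: output frame t covers input frames (2t-1)..(2t+2)
  out <- shmax:::input_to_output_frames(s0 = 320, s1 = 480, spf = 16,
                                        rf = 4L, jump = 2L, T_out = 100L,
                                        overlap = TRUE)
  # input frames 21..30; overlapping output frames: ceil((21-4)/2)+1 .. 15
  expect_equal(out, 10:15)
  inside <- shmax:::input_to_output_frames(320, 480, 16, 4L, 2L, 100L,
                                           overlap = FALSE)
  expect_equal(inside, 11:14)
  expect_length(shmax:::input_to_output_frames(0, 16, 16, 10L, 2L, 100L,
                                               overlap = FALSE), 0L)
})

test_that("rank-sum p-values match exhaustive enumeration at small n", {
  withr::with_seed(13, {
    for (rep in 1:8) {
      x <- round(runif(6), 3); y <- round(runif(5), 3)
      if (anyDuplicated(c(x, y))) next
      expect_equal(shmax:::ranksum_greater_p(x, y), oracle_ranksum_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("active-unit screening separates responsive from null units", {
  withr::with_seed(14, {
    resp <- rbind(runif(200),                       # unit 1: same everywhere
                  c(runif(100, 0.9, 1.1), numeric(100)))  # unit 2: speech only
  })
  tab <- fake_response_table(
    amplitudes = data.frame(unit = 1L, label = "a", instance = 1L, amplitude = 1),
    resp = resp, silence_frames = 101:200, speech_frames = 1:100)
  tab$n_units <- 2L
  act <- active_units(tab, alpha = 0.001, seed = 3)
  expect_false(1L %in% act)
  expect_true(2L %in% act)
  tab$silence_frames <- integer(0)
  expect_error(active_units(tab), "regenerate the corpus")
})

test_that("a perfectly selective unit over 33 phonemes scores 32", {
  labs <- sprintf("p%02d", 1:33)
  amp <- withr::with_seed(15, do.call(rbind, lapply(seq_along(labs), function(i) {
    data.frame(unit = 1L, label = labs[i], instance = seq_len(30) + (i - 1) * 30,
               amplitude = if (i == 1) 10 + runif(30, -0.1, 0.1)
                           else runif(30, 0, 0.2))
  })))
  tab <- fake_response_table(amp)
  psi <- psi_vector(tab, 1, alpha = 0.01)
  expect_equal(unname(psi["p01"]), 32L)
  expect_true(all(psi <= 32L))
})

test_that("identically distributed amplitudes give an all-zero PSI vector", {
  amp <- withr::with_seed(16, do.call(rbind, lapply(c("a", "b", "c"), function(l) {
    data.frame(unit = 1L, label = l, instance = seq_len(20),
               amplitude = runif(20))
  })))
  psi <- psi_vector(fake_response_table(amp), 1)
  expect_true(all(psi == 0L))
})

test_that("PSI pairwise decisions match the enumeration oracle and rank statistics", {
  withr::with_seed(17, {
    labs <- c("a", "b", "c", "d")
    amp <- do.call(rbind, lapply(seq_along(labs), function(i) {
      data.frame(unit = 1L, label = labs[i], instance = seq_len(6) + (i - 1) * 6,
                 amplitude = runif(6) + i / 2)
    }))
  })
  tab <- fake_response_table(amp)
  psi <- psi_vector(tab, 1, alpha = 0.05)
  by_lab <- split(amp$amplitude, amp$label)
  oracle <- vapply(labs, function(a) {
    sum(vapply(setdiff(labs, a), function(b) {
      oracle_ranksum_p(by_lab[[a]], by_lab[[b]]) < 0.05
    }, TRUE))
  }, 0)
  expect_equal(as.integer(psi[labs]), as.integer(oracle))

  # invariance under strictly monotone amplitude transforms
  amp2 <- amp; amp2$amplitude <- exp(3 * amp2$amplitude)
  expect_identical(psi, psi_vector(fake_response_table(amp2), 1, alpha = 0.05))
})

test_that("clustering splits separated clouds and is permutation-invariant", {
  withr::with_seed(18, {
    psi <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
                 matrix(rnorm(40, 5, 0.2), 10, 4))
  })
  colnames(psi) <- c("a", "b", "c", "d")
  cl <- cluster_psi(psi, n_groups = 2)
  expect_equal(length(unique(cl$unit_groups[1:10])), 1L)
  expect_equal(length(unique(cl$unit_groups[11:20])), 1L)
  expect_true(cl$unit_groups[1] != cl$unit_groups[11])
  expect_true(all(diff(cl$unit_tree$height) >= -1e-12))
  perm <- withr::with_seed(1, sample(20))
  cl2 <- cluster_psi(psi[perm, ], n_groups = 2)
  agree <- table(cl$unit_groups[perm], cl2$unit_groups)
  expect_equal(sum(agree > 0), 2L)  # one-to-one label correspondence
  expect_error(cluster_psi(psi[1:3, ], n_groups = 6), "fewer units")
})

test_that("the F-ratio equals its literal formula and is scale-invariant", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      psi <- matrix(rnorm(12 * 5), 12, 5)
      groups <- sample(1:3, 12, replace = TRUE)
      if (length(unique(groups)) < 2) next
      expect_equal(f_ratio(psi, groups), oracle_f_ratio(psi, groups),
                   tolerance = 1e-12)
      expect_equal(f_ratio(psi * 7.3, groups), f_ratio(psi, groups),
                   tolerance = 1e-12)
    }
  })
  # equal group means -> F = 0
  psi0 <- rbind(c(0, 2), c(2, 0), c(1, 1), c(1, 1), c(0.5, 1.5), c(1.5, 0.5))
  expect_equal(f_ratio(psi0, c(1, 1, 2, 2, 3, 3)), 0)
  # zero within-group variability -> infinite, with a warning
  psi_inf <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 1))
  expect_warning(f <- f_ratio(psi_inf, c(1, 1, 2, 2, 3)), "infinite")
  expect_identical(f, Inf)
})

test_that("feature averaging equals a group-by mean and validates the map", {
  psi <- matrix(1:12, 3, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  map <- c(a = "plosive", b = "plosive", c = "nasal", d = "nasal")
  fp <- feature_psi(psi, map)
  expect_equal(dim(fp), c(2L, 3L))
  expect_equal(fp["plosive", ], rowMeans(psi[, c("a", "b")]))
  expect_equal(fp["nasal", ], rowMeans(psi[, c("c", "d")]))
  # one phoneme per feature: output equals the input rows
  map1 <- c(a = "f1", b = "f2", c = "f3", d = "f4")
  fp1 <- feature_psi(psi, map1)
  expect_equal(unname(fp1[paste0("f", 1:4), ]), unname(t(psi)))
  expect_error(feature_psi(psi, map[1:3]), "unmapped")
})

test_that("the synthetic feature map assigns each phoneme exactly one of six features", {
  inv <- make_inventory(20, seed = 23)
  map <- phoneme_feature_map(inv)
  expect_length(map, 20L)
  expect_true(all(map %in% c("plosive", "fricative", "nasal",
                             "low back", "low front", "high front")))
  cls <- vapply(inv, `[[`, "", "class")
  expect_true(all(map[cls == "plosive"] == "plosive"))
  expect_true(all(map[cls == "vowel"] %in% c("low back", "low front", "high front")))
})

test_that("lifetime sparseness matches its closed forms and moment definition", {
  expect_equal(lifetime_sparseness(rep(3.2, 50)), 0)
  one_hot <- c(1, numeric(24))
  expect_equal(lifetime_sparseness(one_hot), 1 - 1 / 25)
  r <- withr::with_seed(20, rgamma(100, 0.5))
  expect_equal(lifetime_sparseness(r), 1 - mean(r)^2 / mean(r^2),
               tolerance = 1e-14)
  expect_warning(s <- lifetime_sparseness(numeric(10)), "all-zero")
  expect_true(is.na(s))
})
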
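#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor cutree dist fft hclust kmeans median
#'   rnorm runif sd setNames t.test var wilcox.test
#' @importFrom utils tail write.table read.table
NULL

# soft-threshold operator used by the lasso coordinate descent
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# full-mode 2-D convolution (no kernel flip is NOT convolution; this flips,
# matching conv2(..., "full") semantics used for STRF composition)
conv2_full <- function(a, b) {
  ra <- nrow(a); ca <- ncol(a)
  rb <- nrow(b); cb <- ncol(b)
  out <- matrix(0, ra + rb - 1L, ca + cb - 1L)
  # accumulate shifted copies of `a` weighted by elements of `b`
  for (i in seq_len(rb)) {
    for (j in seq_len(cb)) {
      w <- b[i, j]
      if (w == 0) next
      out[i:(i + ra - 1L), j:(j + ca - 1L)] <-
        out[i:(i + ra - 1L), j:(j + ca - 1L)] + w * a
    }
  }
  out
}

# excess kurtosis (Fisher) of a numeric vector
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NaN)
  mean(x^4) / m2^2 - 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
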
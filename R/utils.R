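# Internal numerical helpers shared across stages.

# Coefficient of variation: sd / |mean| over non-missing entries, with a
# 1e-12 floor on |mean|; below the floor the sd alone is returned (a profile
# centered exactly at zero still carries variation worth keeping).
.cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  s <- stats::sd(x)
  m <- abs(mean(x))
  if (m < 1e-12) s else s / m
}

# Row-wise coefficient of variation of a matrix with NA masking.
.rowCV <- function(m) apply(m, 1L, .cv)

# Vectorized two-sample t-test across matrix rows, groups given by a logical
# column selector (TRUE = group 1). Pooled-variance Student's t by default,
# Welch optional. Rows where either group has < 2 non-missing values get
# p = NA (degenerate: separability cannot be established). Zero pooled
# variance with a mean difference gives p = 0; with no difference p = 1.
.rowTTest <- function(m, g1, welch = FALSE) {
  m1 <- m[, g1, drop = FALSE]
  m2 <- m[, !g1, drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- .rowVar(m1, mu1, n1); v2 <- .rowVar(m2, mu2, n2)
  d <- mu1 - mu2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t <- d / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  # exact ties in a zero-variance row: no evidence either way
  zerose <- is.finite(d) & se2 <= 0
  p[zerose & abs(d) > 0] <- 0
  p[zerose & d == 0] <- 1
  p[n1 < 2L | n2 < 2L] <- NA_real_
  list(t = t, df = df, p = p, delta = d)
}

.rowVar <- function(m, mu, n) {
  v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  v
}

# Pearson correlation of two vectors over jointly observed entries.
# Returns r = NA when fewer than 3 joint observations or either side has
# zero variance (rank-based downstream steps need defined values).
.pearsonPair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, n = n))
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    return(list(r = NA_real_, n = n))
  list(r = stats::cor(xs, ys), n = n)
}

# Row-wise Pearson correlation of a matrix against one profile vector,
# pairwise-complete, with joint observation counts; r undefined (NA) below
# 3 joint observations. Vectorized via a single cor() call.
.corAgainstProfile <- function(E, profile) {
  r <- suppressWarnings(
    stats::cor(t(E), profile, use = "pairwise.complete.obs"))[, 1L]
  n <- as.integer((!is.na(E)) %*% !is.na(profile))
  r[n < 3L] <- NA_real_
  list(r = r, n = n)
}

# Two-sided p-value of a Pearson r via the t transform
# t = r * sqrt((n-2)/(1-r^2)), df = n - 2.
.corPValue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  rr <- pmin(pmax(r[ok], -1), 1)
  t <- rr * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(t), n[ok] - 2)
  p[ok][abs(rr) >= 1] <- 0
  p
}

# Squared masked Euclidean distances between sample rows X (with NA) and
# complete codebook rows C, each normalized by the count of observed
# components of the sample. Returns |X| x |C| matrix.
.maskedDist2 <- function(X, C) {
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  nobs <- rowSums(M)
  if (any(nobs == 0L)) stop("profile with all entries missing")
  cross <- X0 %*% t(C)                       # sum_j m x_j c_kj
  x2 <- rowSums(X0^2)                        # sum_j m x_j^2
  c2 <- (M * 1) %*% t(C^2)                   # sum_j m c_kj^2
  d2 <- (x2 - 2 * cross + c2) / nobs
  pmax(d2, 0)
}

# Deterministic RNG scope: evaluates expr under a local seed without
# disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Mean-impute missing entries per row (used only to feed the LDA, which
# needs complete vectors; the imputation uses train-side means).
.imputeRows <- function(m, means = NULL) {
  if (is.null(means)) means <- rowMeans(m, na.rm = TRUE)
  means[!is.finite(means)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- means[idx[, 1L]]
  m
}
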
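#' Spearman rank-order correlation
#'
#' rho is the Pearson correlation of the average ranks of the two samples;
#' the p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom
#' (adequate at the sample sizes seen in dose-response pooling; exact
#' permutation p-values are not computed).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List: rho, p (two-sided), n, and `constant_input` flag (rho NA
#'   when either input is constant).
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, constant_input = TRUE))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p, n = n, constant_input = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins: the two-sided p-value is the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table
#' (point-probability method, with a 1 + 1e-7 relative tolerance against
#' floating-point ties).
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts `rbind(c(a, b), c(c, d))`.
#' @return List: p, odds-ratio point estimate (cross-product, Inf/0 allowed),
#'   and the observed table probability.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2, 2)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("all-zero table")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  k <- lo:hi
  pk <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(pk[pk <= p_obs * (1 + 1e-7)])
  list(p = min(1, p),
       odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       p_observed_table = p_obs)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are dropped (the classical convention); ties
#' among the absolute differences receive average ranks. For n <= `exact_max`
#' remaining pairs the null distribution of the positive-rank sum W is
#' enumerated exactly by dynamic programming over the 2^n sign assignments
#' (ranks doubled to keep tie-averaged half-ranks integral); the two-sided p
#' is 2 * min(P(W <= w), P(W >= w)), capped at 1. Above `exact_max` a normal
#' approximation with tie correction is used and reported.
#'
#' @param a,b Paired numeric vectors (or set `b = NULL` and pass differences
#'   in `a`).
#' @param exact_max Largest n for exact enumeration.
#' @return List: W, p, n (non-zero pairs), method (`"exact"` or
#'   `"normal_approx"`), `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_max = 25) {
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(W = 0, p = 1, n = 0, method = "degenerate", all_zero = TRUE))
  if (length(nz) < 2) stop("need at least 2 non-zero differences")
  r <- rank(abs(nz), ties.method = "average")
  W <- sum(r[nz > 0])
  n <- length(nz)
  if (n <= exact_max) {
    # DP over doubled ranks: counts[w + 1] = number of sign assignments with
    # doubled positive-rank sum w
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(abs(nz))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = W, p = p, n = n, method = method, all_zero = FALSE)
}

#' t test with optional log transform
#'
#' Classical two-tailed t test on optionally log-transformed values:
#' log-normal populations are transformed to achieve normality before
#' comparing means. Unpaired comparisons use the Welch unequal-variance
#' form. The trunk-vs-field threshold comparison is the canonical use:
#' per-fiber NT/RF ratios, log2-transformed, unpaired.
#'
#' @param x,y The two groups (same length if `paired`).
#' @param paired Paired or independent samples.
#' @param log_transform `"none"`, `"log10"`, or `"log2"` (values must be
#'   positive when transforming).
#' @return List: t, df, p, estimate (group means on the analysis scale),
#'   transform.
#' @export
t_test_groups <- function(x, y, paired = FALSE,
                          log_transform = c("none", "log10", "log2")) {
  log_transform <- match.arg(log_transform)
  tf <- switch(log_transform, none = identity, log10 = log10, log2 = log2)
  if (log_transform != "none" && (any(x <= 0) || any(y <= 0)))
    stop("log transform requires positive values")
  tx <- tf(x); ty <- tf(y)
  if (stats::var(tx) == 0 && stats::var(ty) == 0)
    return(list(t = NA_real_, df = NA_real_,
                p = if (mean(tx) == mean(ty)) 1 else NA_real_,
                estimate = c(mean(tx), mean(ty)),
                transform = log_transform, zero_variance = TRUE))
  ht <- stats::t.test(tx, ty, paired = paired, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = c(mean(tx), mean(ty)),
       transform = log_transform, zero_variance = FALSE)
}

#' Monte-Carlo Lilliefors test of normality
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal with the
#' sample's own mean and SD; because the parameters are estimated, the
#' standard KS null is invalid, so the p-value is calibrated by a seeded
#' Monte-Carlo null: `n_mc` standard-normal samples of the same size, each
#' with parameters re-estimated. p = (1 + #{D* >= D}) / (n_mc + 1).
#'
#' @param x Sample, n >= 5.
#' @param n_mc Monte-Carlo resamples.
#' @param seed Integer seed.
#' @return List: D (KS statistic), p, n_mc, `constant_sample` flag (p = 0
#'   when the sample is constant).
#' @export
lilliefors_normality <- function(x, n_mc = 2000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("Lilliefors test requires n >= 5")
  if (stats::sd(x) == 0)
    return(list(D = 1, p = 0, n_mc = 0, constant_sample = TRUE))
  ks_stat <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    fz <- stats::pnorm(z)
    i <- seq_len(length(v))
    max(i / length(v) - fz, fz - (i - 1) / length(v))
  }
  D <- ks_stat(x)
  set.seed(seed)
  d_null <- vapply(seq_len(n_mc), function(i) ks_stat(stats::rnorm(n)),
                   numeric(1))
  list(D = D, p = (1 + sum(d_null >= D)) / (n_mc + 1), n_mc = n_mc,
       constant_sample = FALSE)
}
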
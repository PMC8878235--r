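# Statistical fitness measures used to score candidate segmentations, plus
# the normality-based cluster-merge rule.

#' Fuzzy entropy of a membership distribution
#'
#' Shannon entropy \eqn{-\sum_{i}\sum_{j} y_{ij} \log y_{ij}} (natural log)
#' of a membership/probability matrix whose entries sum to one, with
#' \eqn{0 \log 0 := 0}. Low entropy means crisp, unambiguous assignments;
#' high entropy means diffuse membership. Note the sign convention: the value
#' returned is the conventional non-negative entropy, so that "lower = tighter
#' clustering" holds when it enters [aggregate_fitness()].
#'
#' @param membership Non-negative vector or matrix. If the total mass is not
#'   1 it is renormalized with a warning.
#' @return Non-negative scalar, in nats. At most `log(M)` for `M` entries.
#' @examples
#' fuzzy_entropy(c(1, 0, 0))          # 0
#' fuzzy_entropy(rep(1 / 8, 8))       # log(8)
#' @export
fuzzy_entropy <- function(membership) {
  m <- as.numeric(membership)
  if (anyNA(m)) stop("membership contains NA")
  if (any(m < 0)) stop("membership entries must be non-negative")
  total <- sum(m)
  if (total <= 0) stop("membership has zero total mass")
  if (abs(total - 1) > 1e-8) {
    warning("membership mass ", format(total), " is not 1; renormalizing")
    m <- m / total
  }
  m <- m[m > 0]
  -sum(m * log(m))
}

#' Sample skewness
#'
#' Third standardized moment \eqn{\frac{1}{n}\sum (y - \bar y)^3 / s^3},
#' where `s` is the sample standard deviation (denominator \eqn{n - 1}).
#' Zero spread is reported as 0 with a degenerate flag (see
#' [is_degenerate()]).
#'
#' @param values Numeric vector, length >= 2.
#' @return Scalar skewness; negates exactly under `values -> -values`.
#' @export
sample_skewness <- function(values) {
  n <- length(values)
  if (n < 2) stop("skewness needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) return(degenerate_zero())
  mean((values - mean(values))^3) / s^3
}

#' Sample kurtosis (moment convention)
#'
#' Fourth standardized moment \eqn{\frac{1}{n}\sum (y - \bar y)^4 / s^4} with
#' `s` the sample standard deviation (denominator \eqn{n - 1}); approximately
#' 3 for a large normal sample (no excess-kurtosis subtraction). Zero spread
#' is reported as 0 with a degenerate flag.
#'
#' @inheritParams sample_skewness
#' @return Scalar kurtosis; invariant under shift and non-zero rescaling.
#' @export
sample_kurtosis <- function(values) {
  n <- length(values)
  if (n < 2) stop("kurtosis needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) return(degenerate_zero())
  mean((values - mean(values))^4) / s^4
}

#' Unbiased sample variance
#'
#' \eqn{\sum_i (y_i - \bar y)^2 / (N - 1)}; a thin, contract-checked wrapper
#' around [stats::var()].
#'
#' @inheritParams sample_skewness
#' @export
sample_variance <- function(values) {
  if (length(values) < 2) stop("variance needs at least 2 values")
  stats::var(as.numeric(values))
}

#' Correlation of a joint (co-occurrence) probability matrix
#'
#' The standard gray-level co-occurrence correlation
#' \eqn{\sum_{ij} (i - \mu_i)(j - \mu_j) p_{ij} / (s_i s_j)} over 0-based
#' level indices, where \eqn{\mu_i, s_i} are the mean and standard deviation
#' of the row marginal (and likewise for columns). Returns a value in
#' \eqn{[-1, 1]}; if either marginal has zero spread the statistic is
#' undefined and 0 is returned with a degenerate flag.
#'
#' @param p Non-negative matrix; renormalized with a warning if its entries
#'   do not sum to 1.
#' @export
joint_correlation <- function(p) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("joint probability matrix must be non-negative")
  total <- sum(p)
  if (total <= 0) stop("joint probability matrix has zero mass")
  if (abs(total - 1) > 1e-8) {
    warning("joint matrix mass ", format(total), " is not 1; renormalizing")
    p <- p / total
  }
  i <- seq_len(nrow(p)) - 1
  j <- seq_len(ncol(p)) - 1
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mi <- sum(i * pi_)
  mj <- sum(j * pj_)
  si <- sqrt(sum((i - mi)^2 * pi_))
  sj <- sqrt(sum((j - mj)^2 * pj_))
  if (si <= 0 || sj <= 0) return(degenerate_zero())
  sum(outer(i - mi, j - mj) * p) / (si * sj)
}

#' Bundle the five fitness measures into a named vector
#'
#' @param fuzzy_entropy,kurtosis,skewness,correlation,variance Scalars.
#' @return Named numeric vector in the canonical measure order.
#' @export
fitness_vector <- function(fuzzy_entropy, kurtosis, skewness,
                           correlation, variance) {
  c(fuzzy_entropy = as.numeric(fuzzy_entropy),
    kurtosis      = as.numeric(kurtosis),
    skewness      = as.numeric(skewness),
    correlation   = as.numeric(correlation),
    variance      = as.numeric(variance))
}

#' Aggregate a fitness vector into a single scalar (lower is better)
#'
#' Weighted sum of the five measures. The default weights `(1, 0, 0, 0, 1)`
#' combine fuzzy entropy of the soft assignments with pooled within-cluster
#' variance, both of which are minimized by tight, well-separated clusters;
#' the signed measures (skewness, kurtosis, correlation) default to weight 0
#' and are carried for reporting.
#'
#' @param fv Named vector from [fitness_vector()] (or any numeric length-5
#'   vector in the canonical order entropy, kurtosis, skewness, correlation,
#'   variance).
#' @param weights Non-negative length-5 vector, not all zero.
#' @return Scalar fitness; lower is better.
#' @export
aggregate_fitness <- function(fv, weights = c(1, 0, 0, 0, 1)) {
  stopifnot(length(weights) == 5, all(is.finite(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0)) stop("weights must not be all zero")
  nm <- c("fuzzy_entropy", "kurtosis", "skewness", "correlation", "variance")
  v <- if (!is.null(names(fv)) && all(nm %in% names(fv))) {
    as.numeric(fv[nm])
  } else {
    as.numeric(fv)
  }
  stopifnot(length(v) == 5)
  sum(weights * v)
}

#' Skewness-kurtosis omnibus normality test
#'
#' D'Agostino-Pearson omnibus test: the sample skewness and kurtosis are each
#' transformed to approximate standard normal deviates (D'Agostino 1970 for
#' skewness; Anscombe & Glynn 1983 for kurtosis) and
#' \eqn{K^2 = z_{skew}^2 + z_{kurt}^2} is referred to a \eqn{\chi^2_2}
#' distribution. This is the natural omnibus companion to a merge rule framed
#' in terms of those two statistics.
#'
#' @param values Numeric vector, n >= 8 (the approximations are not defined
#'   below that).
#' @param alpha Significance level; the sample is called normal when
#'   `p_value >= alpha`.
#' @return List with `statistic`, `p_value`, `is_normal`.
#' @export
test_normality <- function(values, alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 8) stop("normality test requires at least 8 observations")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) stop("normality test undefined for zero-variance data")
  g1 <- mean(xc^3) / m2^1.5
  b2 <- mean(xc^4) / m2^2

  # skewness: D'Agostino (1970) transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha_s <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha_s)

  # kurtosis: Anscombe & Glynn (1983) transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  tt <- (1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4)))
  z2 <- ((1 - 2 / (9 * a)) - sign(tt) * abs(tt)^(1 / 3)) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(statistic = k2, p_value = p, is_normal = p >= alpha)
}

#' Decide whether two clusters should be merged
#'
#' Two intensity populations are merged when their kurtosis and skewness agree
#' within `tol` (reason `"equal_stats"`). When either statistic disagrees, the
#' clusters are merged anyway if *both* pass the omnibus normality test at
#' `alpha` (reason `"both_normal"`) - two normal populations differing only in
#' location/scale are treated as one tissue class. Otherwise the merge is
#' rejected. Clusters with fewer than 8 members cannot be tested and are
#' rejected with `detail = "undersized"`. The decision is symmetric in its
#' two arguments.
#'
#' @param cluster_a,cluster_b Numeric vectors of member values (e.g. pixel
#'   intensities).
#' @param tol Absolute tolerance for "equal" kurtosis/skewness.
#' @param alpha Significance level passed to [test_normality()].
#' @return List with `merge` (logical), `reason` (one of `equal_stats`,
#'   `both_normal`, `rejected`), `p_values` (length 2, `NA` when the
#'   normality test was not reached), and `detail`.
#' @export
should_merge <- function(cluster_a, cluster_b, tol = 0.5, alpha = 0.05) {
  a <- as.numeric(cluster_a)
  b <- as.numeric(cluster_b)
  if (length(a) < 8 || length(b) < 8) {
    return(list(merge = FALSE, reason = "rejected",
                p_values = c(NA_real_, NA_real_), detail = "undersized"))
  }
  dk <- abs(sample_kurtosis(a) - sample_kurtosis(b))
  ds <- abs(sample_skewness(a) - sample_skewness(b))
  if (dk <= tol && ds <= tol) {
    return(list(merge = TRUE, reason = "equal_stats",
                p_values = c(NA_real_, NA_real_), detail = "stats_within_tol"))
  }
  ta <- tryCatch(test_normality(a, alpha), error = function(e) NULL)
  tb <- tryCatch(test_normality(b, alpha), error = function(e) NULL)
  if (is.null(ta) || is.null(tb)) {
    return(list(merge = FALSE, reason = "rejected",
                p_values = c(NA_real_, NA_real_), detail = "test_undefined"))
  }
  pv <- c(ta$p_value, tb$p_value)
  if (ta$is_normal && tb$is_normal) {
    list(merge = TRUE, reason = "both_normal", p_values = pv,
         detail = "normality_passed")
  } else {
    list(merge = FALSE, reason = "rejected", p_values = pv,
         detail = "normality_failed")
  }
}
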
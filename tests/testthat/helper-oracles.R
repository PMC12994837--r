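# Independent oracles used to cross-check the package's statistical
# primitives. Each is implemented from first principles, by a different
# route than the implementation it checks.

# Wilson CC interval by numerically inverting the defining score
# inequality |p_hat - p| - 1/(2n) = z * sqrt(p(1-p)/n).
oracle_wilson <- function(k, n, alpha) {
  z <- qnorm(1 - alpha / 2)
  p_hat <- k / n
  score_lo <- function(p) (p_hat - p - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n)
  score_hi <- function(p) (p - p_hat - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n)
  lower <- if (k == 0) 0 else {
    stats::uniroot(score_lo, c(1e-15, p_hat), tol = 1e-14)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(score_hi, c(p_hat, 1 - 1e-15), tol = 1e-14)$root
  }
  c(lower = max(lower, 0), upper = min(upper, 1))
}

# Two-sample CC proportion test from the textbook cell-wise chi-squared
# form (with the small-sample cap on the Yates term) and the Wald CC
# interval on the difference.
oracle_two_prop <- function(k1, n1, k2, n2, alpha) {
  p_pool <- (k1 + k2) / (n1 + n2)
  O <- c(k1, n1 - k1, k2, n2 - k2)
  E <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
  yates <- min(0.5, abs(k1 - E[1]))
  stat <- sum((abs(O - E) - yates)^2 / E)
  p_value <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  width <- qnorm(1 - alpha / 2) *
    sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) +
    yates * (1 / n1 + 1 / n2)
  c(diff = p1 - p2,
    lower = max(p1 - p2 - width, -1),
    upper = min(p1 - p2 + width, 1),
    p_value = p_value)
}

# OLS slope by the closed-form moment ratio.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Normalized discrete Gaussian pmf on a truncated support (direct
# normalization; truncation error is negligible at |x| <= 12 sigma).
oracle_dgauss_pmf <- function(sigma, half_width = ceiling(12 * sigma)) {
  x <- -half_width:half_width
  w <- exp(-x^2 / (2 * sigma^2))
  stats::setNames(w / sum(w), x)
}

# Cluster (person-level) percentile bootstrap for the difference of two
# overlapping group proportions; the oracle for delta-method intervals.
oracle_boot_shift_ci <- function(stacked, B = 400, alpha = 0.05) {
  persons <- unique(stacked$person_key)
  n <- length(persons)
  in_e <- stacked$src == 0
  e_m <- as.numeric(table(factor(stacked$person_key[in_e], persons)))
  c_m <- as.numeric(table(factor(stacked$person_key[!in_e], persons)))
  yp <- stacked$y[match(persons, stacked$person_key)]
  W <- stats::rmultinom(B, n, rep(1 / n, n))  # n x B cluster weights
  p_e <- as.vector(crossprod(W, yp * e_m)) / as.vector(crossprod(W, e_m))
  p_c <- as.vector(crossprod(W, yp * c_m)) / as.vector(crossprod(W, c_m))
  stats::quantile(p_c - p_e, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                  names = FALSE)
}

# All 2- and 3-element subsets of the single-race codes, as canonical
# race-set strings.
all_multirace_sets <- function() {
  races <- ck_single_races()
  sets <- c(utils::combn(races, 2, simplify = FALSE),
            utils::combn(races, 3, simplify = FALSE))
  vapply(sets, function(s) paste(sort(s), collapse = ";"), character(1))
}
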
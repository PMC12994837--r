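#' Noise configuration for count protection
#'
#' The published tables this package emulates apply integer-valued
#' discrete Gaussian noise to all unweighted counts and release values
#' rounded to a base (every printed count is a multiple of 10). The
#' census noise scale is unpublished; the defaults here (`sigma = 4`,
#' `rounding_base = 10`) are for fixture realism and privacy
#' demonstrations only -- this module is not certified disclosure
#' avoidance and performs no formal privacy-budget accounting.
#'
#' @param sigma Noise scale (non-negative).
#' @param rounding_base Positive integer rounding base.
#' @param seed Optional integer seed making protection reproducible.
#' @return A list of class `ck_noise_config`.
#' @export
noise_config <- function(sigma = 4, rounding_base = 10L, seed = NULL) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (rounding_base < 1) abort("`rounding_base` must be at least 1")
  structure(list(sigma = sigma, rounding_base = as.integer(rounding_base),
                 seed = seed),
            class = "ck_noise_config")
}

#' Sample from the discrete Gaussian distribution
#'
#' Exact sampler for the integer-valued distribution with
#' `P(X = x)` proportional to `exp(-x^2 / (2 sigma^2))`, by rejection
#' from a two-sided geometric (discrete Laplace) base distribution --
#' the standard exact construction, involving no floating-point normal
#' rounding. `sigma = 0` returns 0 deterministically.
#'
#' @param n Number of draws.
#' @param sigma Scale parameter (non-negative).
#' @return Integer vector of length `n`.
#' @export
sample_discrete_gaussian <- function(n, sigma) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (sigma == 0) return(integer(n))
  t <- floor(sigma) + 1
  p_geom <- 1 - exp(-1 / t)
  out <- integer(0)
  need <- n
  while (need > 0L) {
    m <- max(need * 2L, 16L)
    # discrete Laplace(t): difference of two iid geometrics on {0,1,...}
    x <- rgeom(m, p_geom) - rgeom(m, p_geom)
    acc_p <- exp(-(abs(x) - sigma^2 / t)^2 / (2 * sigma^2))
    keep <- runif(m) < acc_p
    out <- c(out, x[keep])
    need <- n - length(out)
  }
  as.integer(out[seq_len(n)])
}

# normalized pmf of the discrete Gaussian on a symmetric support,
# truncated where mass is negligible
discrete_gaussian_pmf <- function(sigma, support = -ceiling(12 * sigma):ceiling(12 * sigma)) {
  w <- exp(-support^2 / (2 * sigma^2))
  setNames(w / sum(w), support)
}

#' Protect released counts with discrete Gaussian noise and rounding
#'
#' Each count independently receives an additive discrete Gaussian draw,
#' is clamped at zero (released tables contain no negative counts), and
#' is then rounded to the nearest multiple of the rounding base.
#' Percentages derived from protected tables should be recomputed from
#' the noisy counts. Reproducible when the config carries a seed.
#'
#' @param counts Numeric vector or data frame of non-negative integer
#'   counts (for a data frame, every numeric column is protected).
#' @param config A [noise_config()].
#' @return Protected counts with the same shape as the input; always
#'   non-negative multiples of `rounding_base`.
#' @export
protect_counts <- function(counts, config = noise_config()) {
  protect_vec <- function(x) {
    if (any(x < 0 | x != round(x))) {
      abort("counts must be non-negative integers")
    }
    noisy <- x + sample_discrete_gaussian(length(x), config$sigma)
    clamped <- pmax(noisy, 0)
    config$rounding_base * round(clamped / config$rounding_base)
  }
  with_seed(config$seed, {
    if (is.data.frame(counts)) {
      mutate(tibble::as_tibble(counts), across(where(is.numeric), protect_vec))
    } else if (is.matrix(counts)) {
      out <- counts
      out[] <- protect_vec(as.vector(counts))
      out
    } else {
      protect_vec(counts)
    }
  })
}
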
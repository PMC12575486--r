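#' Highest posterior density interval
#'
#' Shortest interval containing a given fraction of the samples, the interval
#' convention used throughout the package (default mass 0.89).
#'
#' @param x numeric vector of posterior draws.
#' @param prob probability mass the interval must contain, in (0, 1).
#' @return named numeric vector `c(low, high)`.
#' @export
#' @examples
#' hpdi(rbeta(4000, 8, 2))
hpdi <- function(x, prob = 0.89) {
  stopifnot(is.numeric(x), length(x) >= 2, prob > 0, prob < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(low = x[1], high = x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(low = x[i], high = x[i + m])
}

# Split-chain potential scale reduction factor. `draws` is an iterations x
# chains matrix; each chain is split in half so within-chain trends inflate
# the statistic.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  halves <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size across chains (coda's spectral estimator, summed).
ess_multi <- function(draws) {
  draws <- as.matrix(draws)
  sum(apply(draws, 2, function(x) coda::effectiveSize(coda::mcmc(x))))
}

assert_probability <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name))
  }
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (bad) {
    abort(sprintf("`%s` must lie in the %s interval (0, 1).",
                  name, if (open) "open" else "closed"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    abort(sprintf("`%s` must contain integers >= %d.", name, min))
  }
  invisible(x)
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

# log(1 - d)^e computed stably
log_surv <- function(d, e) e * log1p(-d)
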
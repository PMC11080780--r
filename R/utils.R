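#' Percent relative standard deviation
#'
#' Computes 100 * SD/mean with the sample (n - 1) standard deviation, the
#' universal precision metric of bioanalytical validation.
#'
#' @param x numeric vector of replicate values (length >= 2).
#' @param na.rm drop missing values first.
#' @return \%RSD as a single number; `NA` if fewer than 2 finite values or the
#'   mean is zero.
#' @examples
#' pct_rsd(c(9, 10, 11))  # 10
#' @export
pct_rsd <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
# cv = 0 returns exact ones.
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Seed the RNG only when a seed is supplied; callers may instead manage
# .Random.seed themselves.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Format a fold difference the way assay reports print it
#'
#' Folds of 10 or more are shown to three significant figures, smaller folds
#' to two (so 823.06 prints as 823 and 3.588 as 3.6).
#'
#' @param fold numeric fold difference(s).
#' @return numeric vector rounded for reporting.
#' @export
format_fold <- function(fold) {
  ifelse(abs(fold) >= 10, signif(fold, 3), signif(fold, 2))
}

# trapezoidal integration on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_evmrm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "evmrm_error")))
}
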
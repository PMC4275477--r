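#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation between two vectors with the standard 95%
#' confidence interval from the Fisher z-transform (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `r`, `conf_low`, `conf_high`, `n`, `p_value`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble::tibble(
    r = unname(ct$estimate), conf_low = ct$conf.int[[1]],
    conf_high = ct$conf.int[[2]], n = length(x), p_value = ct$p.value
  )
}

#' Mann-Whitney rank-sum test
#'
#' U statistic with mid-ranks for ties. The p-value is exact — by full
#' enumeration of all `choose(n + m, n)` group assignments of the pooled
#' sample — when `n + m <= exact_limit`; otherwise the normal approximation
#' with tie correction and continuity correction is used. Two-sided by
#' default. The exact branch handles ties correctly, which is why it is
#' enumerated here rather than delegated.
#'
#' @param x,y Numeric samples.
#' @param two_sided Two-sided test (default); otherwise the one-sided
#'   alternative that `x` tends larger.
#' @param exact_limit Largest pooled size for the enumeration branch.
#' @return A one-row tibble: `u`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, two_sided = TRUE, exact_limit = 16L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u <- u_of(seq_len(n))
  mu <- n * m / 2

  if (N <= exact_limit) {
    combos <- utils::combn(N, n)
    us <- apply(combos, 2L, u_of)
    p <- if (two_sided) {
      mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    } else {
      mean(us >= u - 1e-9)
    }
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 == 0) return(tibble::tibble(u = u, p_value = 1,
                                           method = "normal approximation"))
    cc <- 0.5
    if (two_sided) {
      z <- (u - mu - sign(u - mu) * cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    } else {
      z <- (u - mu - cc) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation"
  }
  tibble::tibble(u = u, p_value = p, method = method)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value defined as the sum of hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. A zero margin makes every table equally (un)informative; p = 1 is
#' returned with a warning.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or the four
#'   counts `c(a, b, c, d)` row-wise.
#' @return A one-row tibble: `p_value`.
#' @export
fisher_exact <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]
  row1 <- sum(tab[1, ]); col1 <- sum(tab[, 1]); total <- sum(tab)
  if (row1 == 0 || col1 == 0 || row1 == total || col1 == total) {
    warning("zero margin: p = 1", call. = FALSE)
    return(tibble::tibble(p_value = 1))
  }
  support <- max(0, row1 + col1 - total):min(row1, col1)
  probs <- stats::dhyper(support, col1, total - col1, row1)
  p_obs <- stats::dhyper(a, col1, total - col1, row1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble::tibble(p_value = min(1, p))
}
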
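## One-sided Wilcoxon signed-rank test on a vector of (log2) differences.
## Exact null distribution (all 2^n sign assignments of the ranks) when the
## sample is small and tie-free; tie-corrected normal approximation with
## continuity correction otherwise — matching the behaviour of standard
## implementations, which cannot compute exact p-values in the presence of
## ties.

#' Wilcoxon signed-rank test (one-sided)
#'
#' Tests whether the differences `x` are centred above (`"greater"`) or
#' below (`"less"`) zero. Exact zeros are dropped (classic treatment).
#' With `n <= exact_max` nonzero values and no tied absolute values the
#' exact signed-rank distribution is used; otherwise a normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x Numeric vector of differences (e.g. per-region log2 fold
#'   changes).
#' @param alternative `"greater"` or `"less"`.
#' @param exact_max Largest tie-free sample size using the exact
#'   distribution (default 25).
#' @return An object of class `wsr_test`: list with `n` (nonzero
#'   differences), `statistic` (W+, the positive-rank sum), `p_value`,
#'   `exact` (logical), `alternative` and the input differences.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), "greater")$p_value # 0.125
#' @export
wilcoxon_signed_rank <- function(x, alternative = c("greater", "less"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) abort("no nonzero differences")
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  ties <- any(duplicated(abs(x)))
  if (!ties && n <= exact_max) {
    exact <- TRUE
    p <- switch(alternative,
      greater = psignrank(w - 1, n, lower.tail = FALSE),
      less = psignrank(w, n)
    )
  } else {
    exact <- FALSE
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      greater = pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE),
      less = pnorm((w - mu + 0.5) / sigma)
    )
  }
  structure(
    list(n = n, statistic = w, p_value = min(max(p, 0), 1), exact = exact,
         alternative = alternative, log2_ratios = x),
    class = "wsr_test"
  )
}

#' @export
print.wsr_test <- function(x, ...) {
  cat("One-sided Wilcoxon signed-rank test\n")
  cat(sprintf("  alternative: %s\n", x$alternative))
  cat(sprintf("  n (nonzero) = %d, W+ = %g\n", x$n, x$statistic))
  cat(sprintf("  p = %.4g (%s)\n", x$p_value,
              if (x$exact) "exact" else "normal approximation, tie-corrected"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Wilcoxon signed-rank result
#'
#' @param x A `wsr_test` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `n`, `exact`,
#'   `alternative`, `method`.
#' @method tidy wsr_test
#' @export
tidy.wsr_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p_value, n = x$n,
    exact = x$exact, alternative = x$alternative,
    method = "Wilcoxon signed rank test, one-sided"
  )
}

#' @rdname tidy.wsr_test
#' @method glance wsr_test
#' @export
glance.wsr_test <- function(x, ...) tidy(x)
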
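#' Paired Wilcoxon signed-rank comparison of accuracies
#'
#' Two-sided signed-rank test on the paired differences `a - b`.
#' Zero differences are dropped before ranking; ties in `|d|` receive
#' average ranks. For an effective sample size `n <= exact_max_n` the exact
#' null distribution of the positive-rank sum `W+` is computed by
#' enumerating all `2^n` sign assignments (via a subset-sum convolution over
#' the doubled ranks, so tied average ranks stay exact); otherwise the
#' normal approximation with tie correction is used and the standardized
#' statistic `Z = (W+ - n(n+1)/4) / sigma` is reported. If every difference
#' is zero the comparison is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param a,b Equal-length numeric vectors of paired accuracies.
#' @param alpha Significance level for the verdict (default 0.05).
#' @param exact_max_n Largest effective n for the exact branch (default 25).
#' @return An object of class `wilcoxon_report`: list with `statistic_w`
#'   (W+), `z` (standardized statistic, reported on both branches),
#'   `p_value`, `n_effective`, `method` (`"exact"`, `"normal"` or
#'   `"degenerate"`), `alpha` and `significant`.
#' @examples
#' wilcoxon_compare(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value  # 0.0625
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05, exact_max_n = 25) {
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; comparison is degenerate",
            call. = FALSE)
    return(new_wilcoxon_report(0, NA_real_, 1, 0, "degenerate", alpha))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else NA_real_
  if (n <= exact_max_n) {
    # distribution of W+ over all 2^n sign assignments, on doubled ranks so
    # average ranks (k + 0.5) stay integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (w_i in r2) {
      shifted <- c(numeric(w_i), f[seq_len(total + 1 - w_i)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  new_wilcoxon_report(w, z, p, n, method, alpha)
}

new_wilcoxon_report <- function(w, z, p, n, method, alpha) {
  structure(list(statistic_w = w, z = z, p_value = p, n_effective = n,
                 method = method, alpha = alpha,
                 significant = is.finite(p) && p < alpha),
            class = "wilcoxon_report")
}

#' @export
print.wilcoxon_report <- function(x, ...) {
  cat(sprintf("<wilcoxon_report> W+ = %g, Z = %s, p = %.4g (%s, n = %d): %s at alpha = %g\n",
              x$statistic_w,
              if (is.na(x$z)) "NA" else sprintf("%.3f", x$z),
              x$p_value, x$method, x$n_effective,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}
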
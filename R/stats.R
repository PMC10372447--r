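#' Two-group comparison with normality routing
#'
#' Tests each group for normality with a Kolmogorov-Smirnov test against a
#' gaussian with the sample mean and SD (a Lilliefors-style use of KS; the
#' estimated parameters make the test mildly conservative, which is accepted
#' here). If both groups pass at `ks_alpha`, the groups are compared with an
#' unpaired two-tailed t-test; otherwise with a Mann-Whitney U test.
#' P-values are Bonferroni-corrected for `n_comparisons`.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param n_comparisons number of comparisons in the family (default 1).
#' @param ks_alpha normality-test level routing to the rank test (default 0.05).
#' @param var_equal pooled-variance t-test (default TRUE, the classic
#'   unpaired t-test).
#' @return object of class `group_comparison`: group ns, means, SEMs,
#'   `normality_p`, `test_used` ("t" or "mann_whitney"), `p_raw`,
#'   `p_corrected = min(1, p_raw * n_comparisons)`.
#' @export
compare_groups <- function(a, b, n_comparisons = 1, ks_alpha = 0.05,
                           var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  stopifnot(length(a) >= 3, length(b) >= 3)
  ks <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(0)  # a constant sample is not gaussian
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
  }
  norm_p <- c(ks(a), ks(b))
  if (all(norm_p >= ks_alpha)) {
    test_used <- "t"
    p_raw <- stats::t.test(a, b, var.equal = var_equal)$p.value
  } else {
    test_used <- "mann_whitney"
    p_raw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }
  structure(list(n = c(length(a), length(b)),
                 means = c(mean(a), mean(b)),
                 sems = c(stats::sd(a) / sqrt(length(a)),
                          stats::sd(b) / sqrt(length(b))),
                 normality_p = norm_p,
                 test_used = test_used,
                 p_raw = p_raw,
                 p_corrected = min(1, p_raw * n_comparisons),
                 n_comparisons = n_comparisons),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n = %d vs %d | %.4g +/- %.3g vs %.4g +/- %.3g\n",
              x$n[1], x$n[2], x$means[1], x$sems[1], x$means[2], x$sems[2]))
  cat(sprintf("  test: %s, p_raw = %.4g, p_corrected = %.4g (x%d)\n",
              x$test_used, x$p_raw, x$p_corrected, x$n_comparisons))
  invisible(x)
}
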
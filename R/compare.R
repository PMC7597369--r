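#' Two-group rank comparison of per-cell values
#'
#' Two-sample Kruskal-Wallis test (rank-based, with tie correction;
#' equivalent to a two-sided rank-sum test) for comparing per-cell
#' statistics -- residence times, population fractions, hub rates --
#' between conditions. When every pooled value is identical the test is
#' undefined; by convention p = 1 is returned with a flag.
#'
#' @param x,y Numeric vectors of per-cell values (each `n >= 3`).
#' @return A list of class `group_comparison`: `statistic`, `p_value`,
#'   `n` (group sizes), `identical_values` flag, `method`.
#' @examples
#' compare_groups(rexp(10, 1), rexp(10, 0.5))$p_value
#' @export
compare_groups <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L)
    stopf("each group needs at least 3 values")
  if (length(unique(c(x, y))) == 1L) {
    out <- list(statistic = 0, p_value = 1, n = c(length(x), length(y)),
                identical_values = TRUE,
                method = "two-sample Kruskal-Wallis (degenerate: identical values)")
    class(out) <- "group_comparison"
    return(out)
  }
  kt <- stats::kruskal.test(list(x, y))
  out <- list(statistic = unname(kt$statistic),
              p_value = kt$p.value,
              n = c(length(x), length(y)),
              identical_values = FALSE,
              method = "two-sample Kruskal-Wallis rank test")
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s\n  n = %d vs %d, chi-squared = %.4g, p = %.4g%s\n",
              x$method, x$n[1], x$n[2], x$statistic, x$p_value,
              if (x$identical_values) " [flagged: all values identical]" else ""))
  invisible(x)
}
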
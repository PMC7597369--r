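#' Empirical survival curve (1 - CDF) of binding durations
#'
#' Builds the survival curve used for residence-time and hub-latency
#' analysis: at each distinct duration `t`, the fraction of events lasting
#' at least `t` (so the curve starts at 1 at the minimum observed
#' duration and is non-increasing). [survival_at()] evaluates the
#' right-continuous step function `P(T > t)` at arbitrary times.
#'
#' @param durations Positive durations (s), `n >= 1`.
#' @param source Optional label (e.g. `"residence_per_cell"`,
#'   `"latency_pooled"`).
#' @return An object of class `survival_curve`: data frame with columns
#'   `t` (sorted distinct durations) and `surv` (`P(T >= t)`), attributes
#'   `n` and `source`.
#' @examples
#' sc <- survival_curve(c(1, 2, 3))
#' survival_at(sc, 1.5)  # 2/3
#' @export
survival_curve <- function(durations, source = NULL) {
  d <- as.numeric(durations)
  if (length(d) < 1L) stopf("need at least one duration")
  if (any(!is.finite(d)) || any(d <= 0)) stopf("durations must be positive")
  t <- sort(unique(d))
  n <- length(d)
  # P(T >= t): count of durations >= t, via the ECDF just below t
  surv <- 1 - ecdf_left(d, t)
  out <- data.frame(t = t, surv = surv)
  attr(out, "n") <- n
  attr(out, "source") <- source
  class(out) <- c("survival_curve", "data.frame")
  out
}

# P(T < t) evaluated at each t (left-limit ECDF).
ecdf_left <- function(d, t) {
  sorted <- sort(d)
  vapply(t, function(x) sum(sorted < x), 0) / length(d)
}

#' @rdname survival_curve
#' @param curve A `survival_curve`.
#' @param t Times (s) at which to evaluate `P(T > t)`.
#' @export
survival_at <- function(curve, t) {
  n <- attr(curve, "n")
  counts <- round(curve$surv * n)  # events with duration >= curve$t
  vapply(t, function(x) {
    above <- which(curve$t > x)
    if (!length(above)) 0 else counts[above[1]] / n
  }, 0)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve (1-CDF): n = %d events, %d distinct durations%s\n",
              attr(x, "n"), nrow(x),
              if (!is.null(attr(x, "source")))
                sprintf(" [%s]", attr(x, "source")) else ""))
  NextMethod()
}
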
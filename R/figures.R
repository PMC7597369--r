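#' Render summary figures from a pipeline report
#'
#' Draws the standard panels from an existing [run_pipeline()] report --
#' no computation happens here: the arrival/departure order histogram
#' with bootstrap error bars, the pathway quadrant scatter, the
#' residence-time survival curve with its mixture fit, the per-cell hub
#' rate distribution, and the hub-latency survival curve. Sections
#' missing from the report are skipped with a warning. Files are written
#' as SVG (a deterministic vector format) by default.
#'
#' @param report An `smt_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @param format `"svg"` or `"pdf"`.
#' @return Character vector of written file paths (invisibly).
#' @export
make_figures <- function(report, out_dir, format = c("svg", "pdf")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "smt_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dev <- function(path, w = 6, h = 4.5) switch(
    format,
    svg = grDevices::svg(path, width = w, height = h),
    pdf = grDevices::pdf(path, width = w, height = h))
  written <- character(0)
  emit <- function(name, plot_obj) {
    path <- file.path(out_dir, paste0(name, ".", format))
    dev(path)
    print(plot_obj)
    grDevices::dev.off()
    written <<- c(written, path)
  }

  if (!is.null(report$order)) {
    df <- rbind(cbind(report$order$arrival, margin = "arrival"),
                cbind(report$order$departure, margin = "departure"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = class, y = 100 * fraction)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * (fraction - sd),
                                          ymax = 100 * (fraction + sd)),
                             width = 0.25) +
      ggplot2::facet_wrap(~margin) +
      ggplot2::labs(x = NULL, y = "% of colocalizations",
                    title = "Arrival / departure order") +
      ggplot2::theme_bw()
    emit("order_histogram", p)
  } else warnf("report lacks an order section; figure skipped")

  if (!is.null(report$events) && nrow(report$events)) {
    ev <- report$events
    df <- data.frame(arrival_dt = ev$pold_start - ev$pcna_start,
                     departure_dt = ev$pold_end - ev$pcna_end)
    p <- ggplot2::ggplot(df, ggplot2::aes(arrival_dt, departure_dt)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::geom_point(alpha = 0.5, size = 1) +
      ggplot2::labs(x = "Pol delta arrival relative to PCNA (s)",
                    y = "Pol delta departure relative to PCNA (s)",
                    title = "Assembly/disassembly pathways") +
      ggplot2::theme_bw()
    emit("quadrant_scatter", p)
  } else warnf("report lacks colocalization events; figure skipped")

  if (!is.null(report$per_cell)) {
    fit <- NULL
    for (pc in report$per_cell) {
      f <- pc$fits[["pold"]]
      if (!is.null(f)) { fit <- f; break }
    }
    if (!is.null(fit)) {
      cdf <- fit$curve
      df <- data.frame(t = cdf$t, surv = cdf$surv, fitted = fit$fitted)
      p <- ggplot2::ggplot(df, ggplot2::aes(t, surv)) +
        ggplot2::geom_step() +
        ggplot2::geom_line(ggplot2::aes(y = fitted), color = "red") +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "residence time (s)", y = "1 - CDF",
                      title = sprintf("Residence survival (k = %d)", fit$k)) +
        ggplot2::theme_bw()
      emit("residence_survival", p)
    }
  }

  if (!is.null(report$hubs) && length(report$hubs$per_1000)) {
    df <- data.frame(rate = report$hubs$per_1000)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = "cells", y = rate)) +
      ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
      ggplot2::labs(x = NULL, y = "hubs per 1,000 binding events",
                    title = "Binding-hub rate per cell") +
      ggplot2::theme_bw()
    emit("hub_rate", p)
  } else warnf("report lacks a hub section; figure skipped")

  if (!is.null(report$latency) && !is.null(report$latency$fit)) {
    fit <- report$latency$fit
    cdf <- fit$curve
    df <- data.frame(t = cdf$t, surv = cdf$surv, fitted = fit$fitted)
    p <- ggplot2::ggplot(df, ggplot2::aes(t, surv)) +
      ggplot2::geom_step() +
      ggplot2::geom_line(ggplot2::aes(y = fitted), color = "red") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "revisit latency (s)", y = "1 - CDF",
                    title = sprintf("Hub revisit latencies (k = %d)", fit$k)) +
      ggplot2::theme_bw()
    emit("hub_latency", p)
  } else warnf("report lacks a latency section; figure skipped")

  invisible(written)
}
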
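#' Plot a trace with its segmentation
#'
#' Shows the bp-domain trace (optionally FFT-smoothed for display) with
#' segments coloured by kind.
#'
#' @param trace Tibble with `time_s`, `position_bp`.
#' @param segments Optional segment tibble from [segment_trace()].
#' @param smooth_cutoff_hz Optional display-only FFT low-pass cutoff.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, segments = NULL, smooth_cutoff_hz = NULL) {
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$time_s, y = .data$position_bp)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "position (bp)")
  if (!is.null(smooth_cutoff_hz)) {
    p <- p + ggplot2::geom_line(data = smooth_fft(trace, smooth_cutoff_hz),
                                colour = "black", linewidth = 0.5)
  }
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_rect(
      data = segments, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start_s, xmax = .data$t_end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$kind),
      alpha = 0.15) +
      ggplot2::scale_fill_manual(values = c(
        baseline = "grey50", event = "forestgreen",
        pause = "orange", reanneal = "steelblue"))
  }
  p
}

#' Autoplot methods for fitted objects
#'
#' Histogram fits are drawn as the binned data with the fitted curve
#' (excluded bins hollow); Kd fits as the titration points with the fitted
#' isotherm on a log concentration axis; WLC fits as the force-extension
#' points with the fitted curve.
#'
#' @param object A `histogram_fit`, `kd_fit` or `wlc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-flowstretch
NULL

#' @rdname autoplot-flowstretch
#' @method autoplot histogram_fit
#' @export
autoplot.histogram_fit <- function(object, ...) {
  data <- tibble(x = object$fit$m$getEnv()$x,
                 cnt = object$fit$m$getEnv()$cnt)
  grid <- tibble(x = seq(min(data$x), max(data$x), length.out = 200))
  grid$y <- predict(object$fit, newdata = grid)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$cnt)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "grey70") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                       colour = "black") +
    ggplot2::labs(x = "value", y = "count",
                  title = sprintf("%s fit: mean %.3g +/- %.2g",
                                  object$kind, object$mean, object$sem))
}

#' @rdname autoplot-flowstretch
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  env <- object$fit$m$getEnv()
  data <- tibble(titrant_nM = env$titrant_nM, signal = env$signal)
  grid <- tibble(titrant_nM = exp(seq(log(min(data$titrant_nM)),
                                      log(max(data$titrant_nM)),
                                      length.out = 200)))
  grid$signal <- object$baseline_unbound +
    (object$amplitude_bound - object$baseline_unbound) *
    isotherm(grid$titrant_nM, object$target_nM, object$kd_nM)
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$titrant_nM, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "titrant (nM)", y = "signal",
                  title = sprintf("Kd = %.3g +/- %.2g nM",
                                  object$kd_nM, object$se_nM))
}

#' @rdname autoplot-flowstretch
#' @method autoplot wlc_fit
#' @export
autoplot.wlc_fit <- function(object, ...) {
  env <- object$fit$m$getEnv()
  data <- tibble(extension_nm = env$x, force_pN = env$f)
  grid <- tibble(extension_nm = seq(0, max(data$extension_nm),
                                    length.out = 200))
  grid$force_pN <- wlc_force(grid$extension_nm / object$contour_nm,
                             object$persistence_nm, object$kBT_pN_nm)
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data$extension_nm, y = .data$force_pN)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)",
                  title = sprintf("WLC: P = %.3g nm, L = %.4g nm",
                                  object$persistence_nm, object$contour_nm))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
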
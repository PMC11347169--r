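#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a histogram fit
#'
#' @param x A `histogram_fit` from [fit_rate_gaussian()] or
#'   [fit_exponential()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.histogram_fit <- function(x, ...) {
  if (x$kind == "gaussian") {
    tibble(term = c("mean", "sd"),
           estimate = c(x$mean, x$sd),
           std.error = c(x$sem, NA_real_))
  } else {
    tibble(term = "mean", estimate = x$mean, std.error = x$sem)
  }
}

#' @rdname tidy.histogram_fit
#' @export
glance.histogram_fit <- function(x, ...) {
  tibble(kind = x$kind, mean = x$mean, sem = x$sem, n = x$n,
         bin_width = x$bin_width, mle_mean = x$mle_mean,
         n_excluded_bins = length(x$excluded_bins))
}

#' Tidy a worm-like chain fit
#'
#' @param x A `wlc_fit` from [fit_wlc()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.wlc_fit <- function(x, ...) {
  tibble(term = c("persistence_nm", "contour_nm"),
         estimate = c(x$persistence_nm, x$contour_nm),
         std.error = c(x$se_persistence, x$se_contour))
}

#' @rdname tidy.wlc_fit
#' @export
glance.wlc_fit <- function(x, ...) {
  tibble(persistence_nm = x$persistence_nm, contour_nm = x$contour_nm,
         kBT_pN_nm = x$kBT_pN_nm, residual_norm = x$residual_norm, n = x$n)
}

#' Tidy a dissociation-constant fit
#'
#' @param x A `kd_fit` from [fit_kd()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble(term = "kd_nM", estimate = x$kd_nM, std.error = x$se_nM)
}

#' @rdname tidy.kd_fit
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(kd_nM = x$kd_nM, se_nM = x$se_nM,
         baseline_unbound = x$baseline_unbound,
         amplitude_bound = x$amplitude_bound,
         target_nM = x$target_nM, residual_norm = x$residual_norm, n = x$n)
}

#' Tidy a condition summary
#'
#' @param x A `condition_summary` from [summarize_condition()].
#' @param ... Unused.
#' @return The one-row headline table.
#' @export
tidy.condition_summary <- function(x, ...) x$table
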
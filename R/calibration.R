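#' Equipartition force estimate for a tethered bead
#'
#' The drag force on a flow-stretched bead follows from the equipartition
#' theorem: transverse (perpendicular-to-flow) positional fluctuations of a
#' tether of extension L obey `Var(y) = kBT * L / F`, so
#' `F = kBT * L / Var(y)`. The variance is computed after mean subtraction,
#' which also makes the estimate invariant to a constant offset of the
#' transverse coordinate.
#'
#' @param extension_nm Tether extension (nm), a positive scalar.
#' @param transverse_nm Numeric vector of transverse bead positions (nm);
#'   at least 50 samples.
#' @param kBT_pN_nm Thermal energy (default 4.11 pN nm, 25 C).
#' @param n_boot Bootstrap resamples for the standard error (default 200).
#' @return A tibble with one row: `force_pN`, `se_pN`, `n`.
#' @examples
#' set.seed(1)
#' y <- rnorm(2000, sd = sqrt(4.11 * 2000 / 2.6))
#' equipartition_force(2000, y)
#' @export
equipartition_force <- function(extension_nm, transverse_nm,
                                kBT_pN_nm = .fs_const$kBT_pN_nm,
                                n_boot = 200) {
  if (!is.numeric(extension_nm) || length(extension_nm) != 1 ||
      extension_nm <= 0) {
    abort("extension_nm must be a positive scalar")
  }
  transverse_nm <- transverse_nm[!is.na(transverse_nm)]
  n <- length(transverse_nm)
  if (n < 50) abort("need at least 50 transverse samples")
  v <- var(transverse_nm)
  if (v <= 0) abort("zero transverse variance: stuck bead?")
  force <- kBT_pN_nm * extension_nm / v
  boots <- vapply(seq_len(n_boot), function(i) {
    vb <- var(transverse_nm[sample.int(n, n, replace = TRUE)])
    kBT_pN_nm * extension_nm / vb
  }, numeric(1))
  tibble(force_pN = force, se_pN = sd(boots), n = n)
}

#' Worm-like chain force at a relative extension
#'
#' Interpolation form of the worm-like chain model:
#' `F = (kBT / P) * (1 / (4 (1 - x/L)^2) - 1/4 + x/L)`.
#'
#' @param x_over_L Relative extension in `[0, 1)`, vectorised.
#' @param persistence_nm Persistence length P (nm).
#' @param kBT_pN_nm Thermal energy (pN nm).
#' @return Force in pN.
#' @examples
#' wlc_force(0.9, persistence_nm = 50)  # 2.108 pN
#' @export
wlc_force <- function(x_over_L, persistence_nm,
                      kBT_pN_nm = .fs_const$kBT_pN_nm) {
  if (persistence_nm <= 0) abort("persistence_nm must be > 0")
  if (any(x_over_L < 0 | x_over_L >= 1)) {
    abort("x_over_L must lie in [0, 1)")
  }
  (kBT_pN_nm / persistence_nm) *
    (1 / (4 * (1 - x_over_L)^2) - 0.25 + x_over_L)
}

#' Fit the worm-like chain model to a force-extension curve
#'
#' Nonlinear least squares for persistence length P and contour length L from
#' `(extension_nm, force_pN)` points, with standard errors from the fit
#' covariance.
#'
#' @param points Data frame with columns `extension_nm` and `force_pN`
#'   (at least 5 points spanning a force range).
#' @param kBT_pN_nm Thermal energy (pN nm).
#' @return A `wlc_fit` object; see [tidy.wlc_fit()].
#' @examples
#' fe <- simulate_force_extension(50, 4600, forces = seq(0.2, 8, length.out = 20))
#' fit_wlc(fe)
#' @export
fit_wlc <- function(points, kBT_pN_nm = .fs_const$kBT_pN_nm) {
  stopifnot(is.data.frame(points))
  if (!all(c("extension_nm", "force_pN") %in% names(points))) {
    abort("points must have columns extension_nm and force_pN")
  }
  points <- points[complete.cases(points[c("extension_nm", "force_pN")]), ]
  if (nrow(points) < 5) abort("need at least 5 force-extension points")
  if (diff(range(points$force_pN)) <= 0) {
    abort("points must span a force range")
  }
  x <- points$extension_nm
  f <- points$force_pN
  start <- list(P = 50, L = max(x) * 1.05)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ (kBT_pN_nm / P) * (1 / (4 * (1 - x / L)^2) - 0.25 + x / L),
      start = start,
      lower = c(P = 1e-3, L = max(x) * (1 + 1e-9)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("WLC fit failed to converge: ",
                                     conditionMessage(e)))
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  structure(
    list(persistence_nm = unname(est[["P"]]),
         contour_nm = unname(est[["L"]]),
         se_persistence = unname(se[[1]]), se_contour = unname(se[[2]]),
         kBT_pN_nm = kBT_pN_nm,
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         n = nrow(points), fit = fit),
    class = "wlc_fit"
  )
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "<wlc_fit> P = %.2f +/- %.2g nm, L = %.1f +/- %.2g nm (n = %d, |r| = %.3g)\n",
    x$persistence_nm, x$se_persistence, x$contour_nm, x$se_contour,
    x$n, x$residual_norm))
  invisible(x)
}

#' Simulate a worm-like chain force-extension point set
#'
#' Inverts the worm-like chain force law numerically to obtain the extension
#' at each requested force, optionally adding relative Gaussian noise to the
#' forces.
#'
#' @param persistence_nm,contour_nm WLC parameters (both > 0).
#' @param forces Non-negative forces (pN) at which to evaluate.
#' @param noise_rel Relative Gaussian noise SD applied to the force values
#'   (0 = noise-free).
#' @param kBT_pN_nm Thermal energy (pN nm).
#' @param seed Optional seed when `noise_rel > 0`.
#' @return Tibble with `extension_nm`, `force_pN`.
#' @export
simulate_force_extension <- function(persistence_nm, contour_nm, forces,
                                     noise_rel = 0,
                                     kBT_pN_nm = .fs_const$kBT_pN_nm,
                                     seed = NULL) {
  if (persistence_nm <= 0 || contour_nm <= 0) {
    abort("persistence_nm and contour_nm must be > 0")
  }
  if (any(forces < 0)) abort("forces must be non-negative")
  rel <- vapply(forces, function(f) {
    if (f == 0) return(0)
    uniroot(function(z) wlc_force(z, persistence_nm, kBT_pN_nm) - f,
            lower = 0, upper = 1 - 1e-12, tol = 1e-12)$root
  }, numeric(1))
  out <- tibble(extension_nm = rel * contour_nm, force_pN = forces)
  if (noise_rel > 0) {
    if (!is.null(seed)) set.seed(seed)
    out$force_pN <- out$force_pN * (1 + rnorm(nrow(out), sd = noise_rel))
  }
  out
}
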
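#' Fraction bound from normalized thermophoresis signals
#'
#' Linear normalization between the unbound and bound plateau levels:
#' `(signal - unbound) / (bound - unbound)`. Values outside `[-0.05, 1.05]`
#' are reported clamped to `[0, 1]` with a warning (noise can push normalized
#' points slightly outside the physical range).
#'
#' @param signal Numeric vector of thermophoresis signals.
#' @param unbound_level,bound_level Plateau signals of the free and fully
#'   bound labeled species; must differ.
#' @return Numeric vector of bound fractions.
#' @export
fraction_bound <- function(signal, unbound_level, bound_level) {
  if (bound_level == unbound_level) {
    abort("bound and unbound levels must differ")
  }
  fb <- (signal - unbound_level) / (bound_level - unbound_level)
  if (any(fb < -0.05 | fb > 1.05)) {
    warn("fraction bound outside [-0.05, 1.05]; clamping to [0, 1]")
  }
  pmin(pmax(fb, 0), 1)
}

#' Ligand-depletion (quadratic) binding isotherm
#'
#' Exact mass-action fraction of labeled target bound at total titrant
#' concentration A, total target concentration T and dissociation constant K:
#' `FB = ((K + A + T) - sqrt((K + A + T)^2 - 4 A T)) / (2 T)`.
#' Unlike the hyperbolic isotherm `A / (K + A)`, this form remains exact when
#' the labeled target concentration is comparable to K, which is the case
#' here (20 nM target vs single-digit-nM K).
#'
#' @param titrant_nM Total titrant concentration(s), >= 0 (vectorised).
#' @param target_nM Total labeled target concentration, > 0.
#' @param kd_nM Dissociation constant, >= 0.
#' @return Fraction bound in `[0, 1]`.
#' @examples
#' isotherm(250, target_nM = 20, kd_nM = 6.7)
#' @export
isotherm <- function(titrant_nM, target_nM, kd_nM) {
  if (any(titrant_nM < 0) || kd_nM < 0) {
    abort("concentrations and kd must be >= 0")
  }
  if (target_nM <= 0) abort("target_nM must be > 0")
  s <- kd_nM + titrant_nM + target_nM
  disc <- pmax(s^2 - 4 * titrant_nM * target_nM, 0)
  (s - sqrt(disc)) / (2 * target_nM)
}

#' Simulate a microscale-thermophoresis titration
#'
#' A serial-dilution titrant series (16 points, two-fold, from 250 nM final
#' by default: a 500 nM top stock mixed 1:1 with the labeled target) with
#' signals generated from the ligand-depletion isotherm plus Gaussian noise.
#'
#' @param kd_nM Ground-truth dissociation constant (> 0).
#' @param target_nM Labeled target concentration (default 20 nM final).
#' @param top_titrant_nM Highest final titrant concentration (default 250 nM).
#' @param n_points Number of titration points (>= 4; default 16).
#' @param dilution_factor Serial dilution factor (default 2).
#' @param noise_sd Gaussian signal noise SD, as a fraction of the
#'   bound-unbound amplitude (e.g. 0.02 = 2%).
#' @param seed Optional seed.
#' @param unbound_level,bound_level Plateau signal levels of the simulated
#'   normalized fluorescence.
#' @return An `mst_curve` tibble: `titrant_nM` (descending), `signal`, with
#'   the target concentration in attribute `target_nM`.
#' @export
simulate_mst <- function(kd_nM, target_nM = 20, top_titrant_nM = 250,
                         n_points = 16, dilution_factor = 2, noise_sd = 0,
                         seed = NULL, unbound_level = 0, bound_level = 1) {
  if (kd_nM <= 0 || target_nM <= 0 || top_titrant_nM <= 0) {
    abort("all concentrations must be > 0")
  }
  if (n_points < 4) abort("n_points must be >= 4")
  if (dilution_factor <= 1) abort("dilution_factor must be > 1")
  titrant <- top_titrant_nM / dilution_factor^(0:(n_points - 1))
  fb <- isotherm(titrant, target_nM, kd_nM)
  signal <- unbound_level + (bound_level - unbound_level) * fb
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    signal <- signal +
      rnorm(n_points, sd = noise_sd * abs(bound_level - unbound_level))
  }
  structure(tibble(titrant_nM = titrant, signal = signal),
            target_nM = target_nM,
            class = c("mst_curve", "tbl_df", "tbl", "data.frame"))
}

#' Fit the dissociation constant to an MST titration
#'
#' Nonlinear least squares of
#' `signal = unbound + (bound - unbound) * FB(A; T, K)` with the
#' ligand-depletion isotherm. By default the unbound and bound plateaus are
#' free parameters; they can be fixed when known.
#'
#' @param curve Data frame with columns `titrant_nM` and `signal`
#'   (at least 6 points spanning the transition).
#' @param target_nM Labeled target concentration; defaults to the curve's
#'   `target_nM` attribute, else 20 nM.
#' @param fix_plateaus Optional numeric `c(unbound, bound)` to fix the
#'   plateau signals instead of fitting them.
#' @return A `kd_fit` object with `kd_nM`, `se_nM`, `baseline_unbound`,
#'   `amplitude_bound`, `residual_norm`, `n`.
#' @examples
#' curve <- simulate_mst(6.7)
#' fit_kd(curve)
#' @export
fit_kd <- function(curve, target_nM = NULL, fix_plateaus = NULL) {
  stopifnot(is.data.frame(curve))
  if (!all(c("titrant_nM", "signal") %in% names(curve))) {
    abort("curve must have columns titrant_nM and signal")
  }
  target_nM <- target_nM %||% attr(curve, "target_nM") %||% 20
  df <- as_tibble(curve)[c("titrant_nM", "signal")]
  if (nrow(df) < 6) abort("need at least 6 titration points")
  if (sd(df$signal) == 0) abort("flat curve: no binding transition")
  lo <- mean(df$signal[df$titrant_nM <= quantile(df$titrant_nM, 0.25)])
  hi <- mean(df$signal[df$titrant_nM >= quantile(df$titrant_nM, 0.75)])
  k_half <- df$titrant_nM[which.min(abs(df$signal - (lo + hi) / 2))]
  k_geo <- exp(mean(log(range(df$titrant_nM))))
  starts <- unique(pmax(c(k_half, k_geo, target_nM / 2, k_geo / 10), 1e-3))
  fit <- NULL
  last_err <- NULL
  for (k0 in starts) {
    fit <- tryCatch({
      if (is.null(fix_plateaus)) {
        minpack.lm::nlsLM(
          signal ~ u + (b - u) * isotherm(titrant_nM, target_nM, K),
          data = df, start = list(u = lo, b = hi, K = k0),
          lower = c(u = -Inf, b = -Inf, K = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        u_fix <- fix_plateaus[1]; b_fix <- fix_plateaus[2]
        minpack.lm::nlsLM(
          signal ~ u_fix + (b_fix - u_fix) *
            isotherm(titrant_nM, target_nM, K),
          data = df, start = list(K = k0), lower = c(K = 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, error = function(e) {
      last_err <<- conditionMessage(e)
      NULL
    })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Kd fit failed to converge: ", last_err))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  u <- if (is.null(fix_plateaus)) unname(est[["u"]]) else fix_plateaus[1]
  b <- if (is.null(fix_plateaus)) unname(est[["b"]]) else fix_plateaus[2]
  structure(
    list(kd_nM = unname(est[["K"]]),
         se_nM = if (is.null(se)) NA_real_ else unname(se[["K"]]),
         baseline_unbound = u, amplitude_bound = b,
         target_nM = target_nM,
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         n = nrow(df), fit = fit),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf(
    "<kd_fit> Kd = %.3g +/- %.2g nM (target %.3g nM, n = %d, |r| = %.3g)\n",
    x$kd_nM, x$se_nM, x$target_nM, x$n, x$residual_norm))
  invisible(x)
}
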
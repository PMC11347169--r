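#' Define a kinetic preset for the trace simulator
#'
#' A preset bundles the generative ground truth for one experimental
#' condition: the per-burst rate distribution, exponential per-burst
#' processivity, restart behaviour after a pause, baseline noise, optional
#' post-termination re-annealing, and the substrate geometry.
#'
#' @param name Label for the condition.
#' @param rate_mean Mean per-burst rate (bp/s or nt/s), > 0.
#' @param rate_sd SD of the per-burst rate; draws are truncated to be
#'   positive. Default `0.3 * rate_mean`.
#' @param rate_tail_weight,rate_tail_mean Optional heavy-tail mixture: with
#'   probability `rate_tail_weight` the burst rate is
#'   `rate_mean + Exp(rate_tail_mean)` instead of the truncated normal.
#'   `rate_tail_weight = 0` (default) disables the tail.
#' @param proc_mean Mean of the exponential per-burst processivity (bp), > 0.
#' @param p_restart Probability in `[0, 1)` that a stopped complex restarts
#'   after a pause (a Bernoulli per stop, so the burst count is geometric).
#' @param pause_mean Mean restart-pause duration (s); pauses are drawn as
#'   `3 + Exp(pause_mean - 3)`, i.e. left-bounded at the 3 s detection limit.
#'   Must be >= 3 whenever `p_restart > 0`.
#' @param template_len Maximum total activity (bp); bounds the cumulative
#'   simulated progress.
#' @param noise_sd Baseline Gaussian noise SD in bp-equivalent units; must be
#'   below the 200 bp resolution premise.
#' @param reanneal_rate Re-annealing rate (bp/s) after termination; 0 disables.
#' @param geometry A [substrate_geometry()].
#' @return A `kinetic_preset` object.
#' @seealso [default_presets()], [simulate_trace()]
#' @export
kinetic_preset <- function(name,
                           rate_mean,
                           rate_sd = 0.3 * rate_mean,
                           rate_tail_weight = 0,
                           rate_tail_mean = 0,
                           proc_mean,
                           p_restart = 0,
                           pause_mean = 182,
                           template_len = 7000,
                           noise_sd = 150,
                           reanneal_rate = 0,
                           geometry = substrate_geometry("primer_extension",
                                                         template_len = template_len)) {
  bad <- function(field, msg) abort(paste0("invalid preset field '", field, "': ", msg))
  if (!is.numeric(rate_mean) || rate_mean <= 0) bad("rate_mean", "must be > 0")
  if (rate_sd < 0) bad("rate_sd", "must be >= 0")
  if (rate_tail_weight < 0 || rate_tail_weight >= 1) {
    bad("rate_tail_weight", "must be in [0, 1)")
  }
  if (rate_tail_weight > 0 && rate_tail_mean <= 0) {
    bad("rate_tail_mean", "must be > 0 when the tail is enabled")
  }
  if (!is.numeric(proc_mean) || proc_mean <= 0) bad("proc_mean", "must be > 0")
  if (p_restart < 0 || p_restart >= 1) bad("p_restart", "must be in [0, 1)")
  if (p_restart > 0 && pause_mean < .fs_const$min_pause_s) {
    bad("pause_mean", "must be >= 3 s when restarts are possible")
  }
  if (noise_sd < 0 || noise_sd >= .fs_const$resolution_floor) {
    bad("noise_sd", "must be in [0, 200) bp")
  }
  if (reanneal_rate < 0) bad("reanneal_rate", "must be >= 0")
  if (template_len <= 0) bad("template_len", "must be > 0")
  if (!inherits(geometry, "substrate_geometry")) {
    bad("geometry", "must be a substrate_geometry")
  }
  structure(
    list(name = name, rate_mean = rate_mean, rate_sd = rate_sd,
         rate_tail_weight = rate_tail_weight, rate_tail_mean = rate_tail_mean,
         proc_mean = proc_mean, p_restart = p_restart, pause_mean = pause_mean,
         template_len = template_len, noise_sd = noise_sd,
         reanneal_rate = reanneal_rate, geometry = geometry),
    class = "kinetic_preset"
  )
}

#' @export
print.kinetic_preset <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetic_preset> %s: rate %.3g +/- %.3g bp/s, proc %.3g bp, ",
           "p_restart %.2g, pause %.3g s, noise %.3g bp, geometry %s\n"),
    x$name, x$rate_mean, x$rate_sd, x$proc_mean, x$p_restart, x$pause_mean,
    x$noise_sd, x$geometry$name))
  invisible(x)
}

#' Built-in condition presets
#'
#' Generative parameters for the experimental conditions the package models:
#' Pol delta-PCNA primer extension, L-Tag unwinding alone and with RPA,
#' SV40 leading-strand synthesis with SSB or RPA, and leading-strand synthesis
#' with the fork protection complex and/or Mcm10. Rate and processivity means
#' are the measured condition values; rate SDs (0.3 x mean), the
#' re-annealing rate, and the heavy-tail shape of the FPC rate mixture are
#' package choices documented in the methods vignette.
#'
#' @param names Optional character vector to subset the presets.
#' @return Named list of [kinetic_preset()] objects.
#' @examples
#' names(default_presets())
#' default_presets("sv40_ssb")[[1]]
#' @export
default_presets <- function(names = NULL) {
  geo <- function(g, tl) substrate_geometry(g, template_len = tl)
  presets <- list(
    pol_delta_pe = kinetic_preset(
      "pol_delta_pe", rate_mean = 240, proc_mean = 400, p_restart = 0,
      template_len = 7249, geometry = geo("primer_extension", 7249)),
    ltag_alone = kinetic_preset(
      "ltag_alone", rate_mean = 1.1, proc_mean = 150, p_restart = 0,
      reanneal_rate = 5, template_len = 13500,
      geometry = geo("unwinding_shortening", 13500)),
    ltag_rpa = kinetic_preset(
      "ltag_rpa", rate_mean = 1.4, proc_mean = 640, p_restart = 0.2,
      pause_mean = 182, template_len = 7000,
      geometry = geo("unwinding_lengthening", 7000)),
    sv40_ssb = kinetic_preset(
      "sv40_ssb", rate_mean = 5.3, proc_mean = 300, p_restart = 0.4,
      pause_mean = 182, template_len = 13500,
      geometry = geo("leading_ssb", 13500)),
    sv40_rpa = kinetic_preset(
      "sv40_rpa", rate_mean = 4.5, proc_mean = 300, p_restart = 0.4,
      pause_mean = 182, template_len = 7000,
      geometry = geo("leading_rpa", 7000)),
    sv40_fpc_mcm10 = kinetic_preset(
      "sv40_fpc_mcm10", rate_mean = 3.8, proc_mean = 550, p_restart = 0.5,
      pause_mean = 182, template_len = 7000,
      geometry = geo("leading_ssb", 7000)),
    sv40_fpc = kinetic_preset(
      "sv40_fpc", rate_mean = 3.8, rate_tail_weight = 0.25,
      rate_tail_mean = 80, proc_mean = 400, p_restart = 0.4,
      pause_mean = 120, template_len = 7000,
      geometry = geo("leading_ssb", 7000))
  )
  if (is.null(names)) return(presets)
  missing <- setdiff(names, base::names(presets))
  if (length(missing) > 0) {
    abort(paste0("unknown preset(s): ", paste(missing, collapse = ", ")))
  }
  presets[names]
}

#' Read or write presets as a human-editable YAML config
#'
#' @param presets Named list of [kinetic_preset()] objects.
#' @param path File path.
#' @return `write_preset_config()` returns `path` invisibly;
#'   `read_preset_config()` returns a named list of presets.
#' @export
write_preset_config <- function(presets, path) {
  as_block <- function(p) {
    list(rate_mean = p$rate_mean, rate_sd = p$rate_sd,
         rate_tail_weight = p$rate_tail_weight,
         rate_tail_mean = p$rate_tail_mean,
         proc_mean = p$proc_mean, p_restart = p$p_restart,
         pause_mean = p$pause_mean, template_len = p$template_len,
         noise_sd = p$noise_sd, reanneal_rate = p$reanneal_rate,
         geometry = list(name = p$geometry$name,
                         direction_sign = p$geometry$direction_sign,
                         nt_per_nm = p$geometry$nt_per_nm,
                         force_pN = p$geometry$force_pN,
                         template_len = p$geometry$template_len))
  }
  yaml::write_yaml(lapply(presets, as_block), path)
  invisible(path)
}

#' @rdname write_preset_config
#' @export
read_preset_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    b <- raw[[nm]]
    g <- b$geometry
    kinetic_preset(
      name = nm, rate_mean = b$rate_mean, rate_sd = b$rate_sd,
      rate_tail_weight = b$rate_tail_weight %||% 0,
      rate_tail_mean = b$rate_tail_mean %||% 0,
      proc_mean = b$proc_mean, p_restart = b$p_restart,
      pause_mean = b$pause_mean, template_len = b$template_len,
      noise_sd = b$noise_sd, reanneal_rate = b$reanneal_rate,
      geometry = substrate_geometry(g$name, g$direction_sign, g$nt_per_nm,
                                    g$force_pN, g$template_len))
  })
  setNames(out, names(raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
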
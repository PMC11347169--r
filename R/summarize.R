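#' Ensemble summary of one experimental condition
#'
#' Applies the standard battery of distribution fits to the pooled per-trace
#' statistics of one condition: a Gaussian histogram fit and the arithmetic
#' average of the single-step rates, first-bin-excluded exponential fits of
#' the single- and multi-step processivities (cutoff = spatial resolution)
#' and lifetimes (cutoff = 3 s), an exponential fit of the restart-pause
#' durations, and the restart fraction. Restart pauses are left-bounded at
#' 3 s by the pause definition, so their reported mean duration is
#' `3 s + fitted decay constant`; the other quantities report the decay
#' constant itself.
#'
#' Fits that cannot be computed for the ensemble (e.g. no restarting traces)
#' are reported as `NA` rather than failing the whole summary.
#'
#' @param stats Per-trace statistics from [trace_statistics()].
#' @param label Condition name.
#' @param resolution_bp Spatial resolution (bp) used as the processivity
#'   exclusion cutoff.
#' @param duration_bin_width Histogram bin width for lifetimes and pauses (s).
#' @return A `condition_summary`: list with `table` (one-row tibble of the
#'   headline numbers) and `fits` (the underlying `histogram_fit` objects).
#' @export
summarize_condition <- function(stats, label,
                                resolution_bp = .fs_const$resolution_floor,
                                duration_bin_width = 20) {
  stopifnot(is.data.frame(stats))
  if (nrow(stats) == 0) abort("empty ensemble")
  steps <- tidyr::unnest(select(stats, "single_steps"), "single_steps")
  rates <- steps$rate_bp_s
  pauses <- unlist(stats$restart_pauses_s)
  multi <- stats$multi_step_processivity_bp
  multi <- multi[is.finite(multi)]
  multi_life <- stats$multi_step_lifetime_s
  multi_life <- multi_life[is.finite(multi_life)]
  with_ev <- sum(stats$n_events >= 1)

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  fits <- list(
    rate_gaussian = safe(fit_rate_gaussian(rates)),
    single_proc = safe(fit_exponential(steps$processivity_bp,
                                       cutoff = resolution_bp)),
    single_lifetime = safe(fit_exponential(steps$lifetime_s,
                                           cutoff = .fs_const$min_pause_s,
                                           bin_width = duration_bin_width)),
    multi_proc = safe(fit_exponential(multi, cutoff = resolution_bp)),
    multi_lifetime = safe(fit_exponential(multi_life,
                                          cutoff = .fs_const$min_pause_s,
                                          bin_width = duration_bin_width)),
    restart_pause = safe(fit_exponential(pauses,
                                         cutoff = .fs_const$min_pause_s,
                                         bin_width = duration_bin_width))
  )
  arith <- safe(arithmetic_rate(rates))
  num <- function(f, field = "mean") if (is.null(f)) NA_real_ else f[[field]]
  table <- tibble(
    condition = label,
    n_traces = nrow(stats),
    n_events = nrow(steps),
    rate_gauss_mean = num(fits$rate_gaussian),
    rate_gauss_sem = num(fits$rate_gaussian, "sem"),
    rate_arith_mean = if (is.null(arith)) NA_real_ else arith$mean,
    rate_arith_se = if (is.null(arith)) NA_real_ else arith$se,
    single_proc_bp = num(fits$single_proc),
    single_proc_sem = num(fits$single_proc, "sem"),
    single_lifetime_s = num(fits$single_lifetime),
    multi_proc_bp = num(fits$multi_proc),
    multi_proc_sem = num(fits$multi_proc, "sem"),
    multi_lifetime_s = num(fits$multi_lifetime),
    restart_pause_s = if (is.null(fits$restart_pause)) NA_real_ else {
      .fs_const$min_pause_s + fits$restart_pause$mean
    },
    restart_fraction = if (with_ev > 0) {
      sum(stats$n_events >= 2) / with_ev
    } else NA_real_
  )
  structure(list(table = table, fits = fits), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  t <- x$table
  cat(sprintf("<condition_summary> %s (%d traces, %d events)\n",
              t$condition, t$n_traces, t$n_events))
  cat(sprintf("  rate: gaussian %.3g +/- %.2g, arithmetic %.3g +/- %.2g bp/s\n",
              t$rate_gauss_mean, t$rate_gauss_sem,
              t$rate_arith_mean, t$rate_arith_se))
  cat(sprintf("  processivity: single %.3g bp, multi %.3g bp\n",
              t$single_proc_bp, t$multi_proc_bp))
  cat(sprintf("  lifetime: single %.3g s, multi %.3g s\n",
              t$single_lifetime_s, t$multi_lifetime_s))
  cat(sprintf("  restart pause %.3g s, restart fraction %.2g\n",
              t$restart_pause_s, t$restart_fraction))
  invisible(x)
}

#' Compare condition summaries against a reference condition
#'
#' Aligns the headline statistics of several conditions into one table and
#' adds fold changes relative to a named reference condition.
#'
#' @param summaries List of `condition_summary` objects.
#' @param reference Name of the reference condition; defaults to the first.
#' @return Tibble in long form: `condition`, `metric`, `value`,
#'   `fold_change`.
#' @export
compare_conditions <- function(summaries, reference = NULL) {
  if (length(summaries) == 0) abort("empty summary list")
  tabs <- map_dfr(summaries, function(s) {
    stopifnot(inherits(s, "condition_summary"))
    s$table
  })
  reference <- reference %||% tabs$condition[1]
  if (!reference %in% tabs$condition) {
    abort(paste0("reference condition '", reference, "' not found"))
  }
  metrics <- c("rate_gauss_mean", "rate_arith_mean", "single_proc_bp",
               "single_lifetime_s", "multi_proc_bp", "multi_lifetime_s",
               "restart_pause_s", "restart_fraction")
  long <- tidyr::pivot_longer(select(tabs, "condition", dplyr::all_of(metrics)),
                              -"condition", names_to = "metric",
                              values_to = "value")
  ref <- filter(long, .data$condition == reference) %>%
    select("metric", ref_value = "value")
  long %>%
    left_join(ref, by = "metric") %>%
    mutate(fold_change = .data$value / .data$ref_value) %>%
    select("condition", "metric", "value", "fold_change")
}
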
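#' Pause threshold rate from the one-tenth-of-mean rule
#'
#' The category threshold rate for pause detection is one tenth of the mean
#' rate, rounded to one significant figure (which reproduces the working
#' thresholds 0.1 and 0.5 bp/s from mean rates of 1.1 and 5.3 bp/s).
#'
#' @param mean_rate_bp_s Mean category rate (bp/s), > 0.
#' @return Threshold rate (bp/s).
#' @examples
#' compute_threshold_rate(5.3)  # 0.5
#' @export
compute_threshold_rate <- function(mean_rate_bp_s) {
  if (!is.numeric(mean_rate_bp_s) || mean_rate_bp_s <= 0) {
    abort("mean_rate_bp_s must be > 0")
  }
  signif(mean_rate_bp_s / .fs_const$threshold_divisor, 1)
}

#' Segment every trace of an ensemble
#'
#' @param traces Tibble with `trace_id`, `time_s`, `position_bp`.
#' @param noise_profile A [noise_profile()].
#' @param threshold_rate_bp_s Category threshold rate (bp/s).
#' @param geometry A [substrate_geometry()].
#' @return Tibble of segments with a `trace_id` column.
#' @export
segment_ensemble <- function(traces, noise_profile, threshold_rate_bp_s,
                             geometry, .partitions = NULL) {
  stopifnot(is.data.frame(traces), "trace_id" %in% names(traces))
  groups <- split(traces, traces$trace_id)
  map_dfr(names(groups), function(id) {
    mutate(segment_trace(groups[[id]], noise_profile, threshold_rate_bp_s,
                         geometry, .partition = .partitions[[id]]),
           trace_id = id, .before = 1)
  })
}

#' Two-pass segmentation with a data-derived pause threshold
#'
#' Pass 1 segments every trace with a threshold of zero and collects all
#' event rates exhaustively; the Gaussian-fit mean of those rates sets the
#' category threshold through [compute_threshold_rate()] (one tenth of the
#' mean, one significant figure), and pass 2 re-segments with that threshold.
#'
#' @inheritParams segment_ensemble
#' @return A `two_pass_result`: list with `segments` (pass-2 segments,
#'   tibble), `threshold_bp_s`, `mean_rate_bp_s` (pass-1 Gaussian mean), and
#'   `pass1` (the pass-1 segments).
#' @export
two_pass_segment <- function(traces, noise_profile, geometry) {
  # the penalized partition is threshold-free: compute it once per trace
  # and share it between the two classification passes
  groups <- split(traces, traces$trace_id)
  parts <- lapply(groups, function(tr) {
    .partition_trace(tr$time_s, tr$position_bp, noise_profile$noise_sd_bp)
  })
  pass1 <- segment_ensemble(traces, noise_profile, 0, geometry,
                            .partitions = parts)
  rates <- filter(pass1, .data$kind == "event")$rate_bp_s
  if (length(rates) == 0) abort("no activity detected")
  # the exhaustive pass can be contaminated enough that the plain histogram
  # fit wanders; the guarded estimator falls back to the sample median
  mean_rate <- robust_rate_mean(abs(rates))
  if (!is.finite(mean_rate) || mean_rate <= 0) mean_rate <- mean(abs(rates))
  threshold <- compute_threshold_rate(mean_rate)
  pass2 <- segment_ensemble(traces, noise_profile, threshold, geometry,
                            .partitions = parts)
  structure(
    list(segments = pass2, threshold_bp_s = threshold,
         mean_rate_bp_s = mean_rate, pass1 = pass1),
    class = "two_pass_result"
  )
}

#' @export
print.two_pass_result <- function(x, ...) {
  cat(sprintf(
    "<two_pass_result> threshold %.3g bp/s (pass-1 mean rate %.3g bp/s), %d segments\n",
    x$threshold_bp_s, x$mean_rate_bp_s, nrow(x$segments)))
  invisible(x)
}

#' Per-trace single-step and multi-step kinetic statistics
#'
#' From a segmented trace: every event contributes a single step
#' (processivity = its DNA length change, lifetime = its duration, rate = its
#' OLS slope). The multi-step processivity is the summed single-step
#' processivity of the trace; the multi-step lifetime runs from the start of
#' the first event to the end of the last, so interior pauses are included
#' while leading/trailing baseline is not. With a single event the single-
#' and multi-step quantities coincide. Restart pauses are the pauses lying
#' strictly between two events.
#'
#' @param segments Segment tibble from [segment_trace()] or
#'   [segment_ensemble()] (the latter is split on `trace_id`).
#' @return Tibble with one row per trace: `n_events`, `restarted`,
#'   `multi_step_processivity_bp`, `multi_step_lifetime_s`, plus list-columns
#'   `single_steps` (tibble of `processivity_bp`, `lifetime_s`, `rate_bp_s`)
#'   and `restart_pauses_s` (numeric vector of interior pause durations).
#' @export
trace_statistics <- function(segments) {
  stopifnot(is.data.frame(segments))
  groups <- if ("trace_id" %in% names(segments)) {
    split(segments, segments$trace_id)
  } else list(`1` = segments)
  out <- map_dfr(names(groups), function(id) {
    seg <- arrange(groups[[id]], .data$t_start_s)
    ev <- filter(seg, .data$kind == "event")
    pauses <- filter(seg, .data$kind == "pause")
    n_ev <- nrow(ev)
    interior <- if (n_ev >= 2) {
      filter(pauses,
             .data$t_start_s > min(ev$t_start_s),
             .data$t_end_s < max(ev$t_end_s))$duration_s
    } else numeric(0)
    tibble(
      trace_id = id,
      n_events = n_ev,
      restarted = n_ev >= 2,
      multi_step_processivity_bp = if (n_ev > 0) sum(ev$delta_bp) else NA_real_,
      multi_step_lifetime_s = if (n_ev > 0) {
        max(ev$t_end_s) - min(ev$t_start_s)
      } else NA_real_,
      single_steps = list(tibble(
        processivity_bp = ev$delta_bp,
        lifetime_s = ev$duration_s,
        rate_bp_s = ev$rate_bp_s
      )),
      restart_pauses_s = list(interior)
    )
  })
  if (!"trace_id" %in% names(segments)) out$trace_id <- NULL
  out
}
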
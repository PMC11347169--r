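#' Sample a bead trace from a ground-truth interval table
#'
#' Builds a sampled trace (2 Hz by default) from an explicit table of
#' ground-truth intervals. The cumulative activity path is piecewise linear
#' between interval boundaries; i.i.d. Gaussian noise is added on top, and the
#' bp-domain path is mapped to bead displacement (nm) through the substrate
#' geometry. Useful for constructing fully deterministic traces in tests and
#' examples; [simulate_trace()] uses it internally.
#'
#' @param truth Data frame with columns `kind` (one of `"baseline"`, `"event"`,
#'   `"pause"`, `"reanneal"`), `t_start_s`, `t_end_s`, `rate_bp_s`, `delta_bp`.
#'   Intervals must tile `[0, max(t_end_s)]` without overlap.
#' @param geometry A [substrate_geometry()].
#' @param noise_sd Gaussian noise SD in bp (0 = noise-free).
#' @param acquisition_hz Sampling rate (default 2 Hz).
#' @param seed Optional seed for the noise draw.
#' @return Tibble with `time_s`, `position_bp`, `position_nm`.
#' @export
trace_from_truth <- function(truth, geometry, noise_sd = 0,
                             acquisition_hz = .fs_const$acquisition_hz,
                             seed = NULL) {
  stopifnot(is.data.frame(truth))
  truth <- arrange(as_tibble(truth), .data$t_start_s)
  if (nrow(truth) == 0) abort("truth must have at least one interval")
  if (any(abs(truth$t_start_s[-1] - truth$t_end_s[-nrow(truth)]) > 1e-9)) {
    abort("truth intervals must tile the trace without gaps or overlap")
  }
  dt <- 1 / acquisition_hz
  total <- max(truth$t_end_s)
  # piecewise-linear cumulative activity through the interval breakpoints
  knots_t <- c(truth$t_start_s[1], truth$t_end_s)
  knots_y <- cumsum(c(0, truth$delta_bp))
  times <- seq(0, total + 1e-9, by = dt)
  times <- times[times <= total + 1e-9]
  pos_bp <- stats::approx(knots_t, knots_y, xout = pmin(times, total),
                          rule = 2)$y
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pos_bp <- pos_bp + rnorm(length(pos_bp), sd = noise_sd)
  }
  tibble(time_s = times,
         position_bp = pos_bp,
         position_nm = nt_to_displacement(pos_bp, geometry))
}

#' Simulate one flow-stretching trace with known ground truth
#'
#' Generates a single-molecule trace following the generative model: a
#' baseline, then alternating activity bursts and restart pauses. Each burst
#' has an exponential length (mean `proc_mean`, clamped to the remaining
#' template) and a rate drawn from the preset's (truncated-normal or mixture)
#' rate distribution; after each burst the complex restarts with probability
#' `p_restart`, pausing for `3 + Exp(pause_mean - 3)` seconds, and otherwise
#' terminates. On substrates that support it, termination is followed by
#' re-annealing of the unwound DNA back to the start level at `reanneal_rate`.
#' The bp-domain path is sampled at 2 Hz with i.i.d. Gaussian noise and mapped
#' to bead displacement via the preset geometry.
#'
#' @param preset A [kinetic_preset()].
#' @param seed Integer seed (required: every trace is reproducible).
#' @param baseline_s Leading baseline duration (s), >= 0.
#' @param trailing_s Trailing baseline duration (s); defaults to `baseline_s`.
#' @return A `simulated_trace`: list with `trace` (tibble `time_s`,
#'   `position_bp`, `position_nm`) and `truth` (tibble of ground-truth
#'   intervals `kind`, `t_start_s`, `t_end_s`, `rate_bp_s`, `delta_bp`).
#' @examples
#' sim <- simulate_trace(default_presets("sv40_ssb")[[1]], seed = 1)
#' sim$truth
#' @export
simulate_trace <- function(preset, seed, baseline_s = 30, trailing_s = NULL) {
  stopifnot(inherits(preset, "kinetic_preset"))
  if (missing(seed) || is.null(seed)) abort("seed is required")
  if (baseline_s < 0) abort("baseline_s must be >= 0")
  trailing_s <- trailing_s %||% baseline_s
  set.seed(seed)

  draw_rate <- function() {
    if (preset$rate_tail_weight > 0 &&
        runif(1) < preset$rate_tail_weight) {
      return(preset$rate_mean + rexp(1, rate = 1 / preset$rate_tail_mean))
    }
    if (preset$rate_sd == 0) return(preset$rate_mean)
    repeat {
      r <- rnorm(1, preset$rate_mean, preset$rate_sd)
      if (r > 0) return(r)
    }
  }

  rows <- list()
  t <- 0
  if (baseline_s > 0) {
    rows[[length(rows) + 1]] <-
      list(kind = "baseline", t_start_s = 0, t_end_s = baseline_s,
           rate_bp_s = 0, delta_bp = 0)
    t <- baseline_s
  }
  remaining <- preset$template_len
  cum <- 0
  repeat {
    len <- min(rexp(1, rate = 1 / preset$proc_mean), remaining)
    rate <- draw_rate()
    dur <- len / rate
    rows[[length(rows) + 1]] <-
      list(kind = "event", t_start_s = t, t_end_s = t + dur,
           rate_bp_s = rate, delta_bp = len)
    t <- t + dur
    cum <- cum + len
    remaining <- remaining - len
    if (remaining <= 0) break
    if (runif(1) < preset$p_restart) {
      pdur <- .fs_const$min_pause_s +
        rexp(1, rate = 1 / max(preset$pause_mean - .fs_const$min_pause_s, 1e-9))
      rows[[length(rows) + 1]] <-
        list(kind = "pause", t_start_s = t, t_end_s = t + pdur,
             rate_bp_s = 0, delta_bp = 0)
      t <- t + pdur
    } else break
  }
  if (preset$reanneal_rate > 0 && cum > 0) {
    dur <- cum / preset$reanneal_rate
    rows[[length(rows) + 1]] <-
      list(kind = "reanneal", t_start_s = t, t_end_s = t + dur,
           rate_bp_s = -preset$reanneal_rate, delta_bp = -cum)
    t <- t + dur
  }
  if (trailing_s > 0) {
    rows[[length(rows) + 1]] <-
      list(kind = "baseline", t_start_s = t, t_end_s = t + trailing_s,
           rate_bp_s = 0, delta_bp = 0)
    t <- t + trailing_s
  }
  truth <- bind_rows(rows)
  trace <- trace_from_truth(truth, preset$geometry, preset$noise_sd)
  structure(list(trace = trace, truth = truth, preset_name = preset$name,
                 seed = seed),
            class = "simulated_trace")
}

#' @export
print.simulated_trace <- function(x, ...) {
  cat(sprintf("<simulated_trace> %s (seed %d): %d samples, %d truth intervals\n",
              x$preset_name, x$seed, nrow(x$trace), nrow(x$truth)))
  invisible(x)
}

#' Simulate an ensemble of traces from one preset
#'
#' Per-trace seeds are drawn once from the master seed (a fixed, documented
#' derivation), so ensembles are reproducible element-wise: trace `i` of a
#' given master seed is always the same trace.
#'
#' @param preset A [kinetic_preset()].
#' @param n_traces Number of traces (>= 1).
#' @param seed Master integer seed.
#' @inheritParams simulate_trace
#' @return A `sim_ensemble`: list with `traces` (one tibble, `trace_id` +
#'   trace columns) and `truth` (one tibble, `trace_id` + truth columns).
#' @export
simulate_ensemble <- function(preset, n_traces, seed, baseline_s = 30,
                              trailing_s = NULL) {
  if (!is.numeric(n_traces) || n_traces < 1) abort("n_traces must be >= 1")
  n_traces <- as.integer(n_traces)
  set.seed(seed)
  trace_seeds <- sample.int(.Machine$integer.max, n_traces)
  sims <- map(seq_len(n_traces), function(i) {
    simulate_trace(preset, seed = trace_seeds[i], baseline_s = baseline_s,
                   trailing_s = trailing_s)
  })
  traces <- map_dfr(seq_len(n_traces), function(i) {
    mutate(sims[[i]]$trace, trace_id = paste0(preset$name, "_", i),
           .before = 1)
  })
  truth <- map_dfr(seq_len(n_traces), function(i) {
    mutate(sims[[i]]$truth, trace_id = paste0(preset$name, "_", i),
           .before = 1)
  })
  structure(list(traces = traces, truth = truth, preset = preset,
                 seed = seed),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %s (seed %d): %d traces, %d samples\n",
              x$preset$name, x$seed,
              dplyr::n_distinct(x$traces$trace_id), nrow(x$traces)))
  invisible(x)
}

#' Simulate a pure-noise baseline trace
#'
#' A trace of an unreplicated molecule: zero mean activity, i.i.d. Gaussian
#' noise, sampled at the acquisition rate.
#'
#' @param noise_sd Noise SD in bp (>= 0).
#' @param duration_s Duration (s), must be >= 3 s.
#' @param seed Integer seed.
#' @param acquisition_hz Sampling rate (default 2 Hz).
#' @return Tibble with `time_s`, `position_bp`.
#' @export
simulate_baseline <- function(noise_sd, duration_s, seed,
                              acquisition_hz = .fs_const$acquisition_hz) {
  if (duration_s < .fs_const$min_pause_s) {
    abort("duration_s must be at least 3 s")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  set.seed(seed)
  times <- seq(0, duration_s, by = 1 / acquisition_hz)
  tibble(time_s = times,
         position_bp = rnorm(length(times), sd = noise_sd))
}
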
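# SSE penalty multiple (times sigma^2 log n) for accepting an interior-pause
# split of a fitted event; see the methods vignette for the calibration.
.fs_split_penalty <- 4

# Segmentation of bead traces into baseline / event / pause / re-annealing.
#
# The algorithm exploits the structure of flow-stretching data: traces are
# plateau-dominated (baseline and pauses are flat), and enzymatic activity is
# a monotone transition between plateaus. Three stages:
#
#   1. a globally optimal penalized partition into linear pieces (PELT-style
#      dynamic programming; range OLS in O(1) via cumulative sums);
#   2. plateau assembly: pieces consistent with zero slope and baseline noise
#      are plateaus; adjacent plateaus whose level gap is below the spatial
#      resolution are merged (a length change below the resolution is not
#      observable); what remains between plateaus - including bare level
#      jumps faster than the sampling interval - is a candidate transition;
#   3. each transition is fitted with a continuity-constrained
#      flat-ramp-flat model whose breakpoints are profiled against the
#      flanking plateaus. The plateau levels pin the ramp, so event size and
#      rate do not inherit the slope dilution that free-line breakpoint
#      jitter causes. Transitions below the spatial resolution dissolve into
#      the surrounding flat; the survivors are classified as events (or
#      re-annealing) by the threshold-rate rule.

.range_ols <- function(cs, i, j) {
  n <- j - i + 1
  St  <- cs$t[j + 1]  - cs$t[i]
  St2 <- cs$t2[j + 1] - cs$t2[i]
  Sy  <- cs$y[j + 1]  - cs$y[i]
  Sy2 <- cs$y2[j + 1] - cs$y2[i]
  Sty <- cs$ty[j + 1] - cs$ty[i]
  stt <- St2 - St^2 / n
  sty <- Sty - St * Sy / n
  syy <- Sy2 - Sy^2 / n
  if (n < 2 || stt <= 0) {
    return(list(n = n, slope = 0, intercept = Sy / n, sse = 0,
                se_slope = Inf, syy = max(syy, 0), mean_t = St / n,
                mean_y = Sy / n))
  }
  slope <- sty / stt
  sse <- max(syy - sty^2 / stt, 0)
  se_slope <- if (n > 2) sqrt(sse / (n - 2) / stt) else Inf
  list(n = n, slope = slope, intercept = (Sy - slope * St) / n,
       sse = sse, se_slope = se_slope, syy = max(syy, 0),
       mean_t = St / n, mean_y = Sy / n)
}

.cumstats <- function(t, y) {
  list(t = c(0, cumsum(t)), t2 = c(0, cumsum(t^2)),
       y = c(0, cumsum(y)), y2 = c(0, cumsum(y^2)),
       ty = c(0, cumsum(t * y)))
}

# SSE of a linear fit on [s, j] for a vector of starts s at fixed end j.
.range_sse_vec <- function(cs, s, j) {
  n <- j - s + 1
  St  <- cs$t[j + 1]  - cs$t[s]
  St2 <- cs$t2[j + 1] - cs$t2[s]
  Sy  <- cs$y[j + 1]  - cs$y[s]
  Sy2 <- cs$y2[j + 1] - cs$y2[s]
  Sty <- cs$ty[j + 1] - cs$ty[s]
  stt <- St2 - St^2 / n
  sty <- Sty - St * Sy / n
  syy <- Sy2 - Sy^2 / n
  pmax(syy - sty^2 / pmax(stt, 1e-300), 0)
}

# Globally optimal penalized partition into linear pieces (PELT-style
# dynamic programming): minimizes the sum of piece SSEs + beta per
# breakpoint, minimum piece length 2 samples. Candidate breakpoints are
# placed on a 2-sample grid; the ramp-refinement stage downstream restores
# full (and sub-) sample resolution where it matters.
.partition_trace <- function(t, y, noise_sd, beta_mult = 3, stride = NULL) {
  n <- length(y)
  # short traces are cheap at full resolution; the stride-2 grid is an
  # economy for long ones (downstream refinement restores resolution)
  stride <- stride %||% (if (n <= 500) 1L else 2L)
  cs <- .cumstats(t, y)
  sigma <- max(noise_sd, 0.05)
  beta <- beta_mult * sigma^2 * log(n)
  grid <- seq(1L, n, by = stride)     # allowed segment starts
  f <- rep(Inf, n + 1)
  f[1] <- -beta                       # f[j+1] = optimal cost of y[1..j]
  back <- integer(n + 1)
  cand <- 1L                          # candidate segment starts
  ends <- unique(c(grid[-1] - 1L, n))
  for (j in ends) {
    sse <- .range_sse_vec(cs, cand, j)
    tot <- f[cand] + beta + sse
    best <- which.min(tot)
    f[j + 1] <- tot[best]
    back[j + 1] <- cand[best]
    cand <- cand[tot <= f[j + 1] + beta]    # PELT pruning
    if (j + 1 - 1 >= 2 && ((j + 1) - 1) %% stride == 0) cand <- c(cand, j + 1L)
  }
  starts <- integer(0)
  j <- n + 1
  while (j > 1) {
    s <- back[j]
    starts <- c(s, starts)
    j <- s
  }
  list(cs = cs, starts = starts, n = n, sigma = sigma)
}

# Continuity-constrained ramp fit. Window = flanking plateau samples plus the
# transition; model y = l1 + delta * clamp((t - tau1)/(tau2 - tau1), 0, 1).
# Breakpoint sample indices (i1 before the ramp, i2 its last sample) are
# profiled by coordinate descent within [lo1, i2-1] and [i1+1, hi2].
# Rate of a fitted burst. For bursts spanning more than a few samples the
# ramp-model rate delta/(tau2 - tau1) is used; for very short bursts the
# breakpoint-interval estimate is multiplicative in the noisy duration and
# heavily right-skewed, so the OLS slope over the burst samples plus one
# flanking sample on each side (additive noise, anchored by the plateau
# levels) is used instead.
.event_rate <- function(cs, t, i1, i2, delta, duration, n) {
  if (i2 - i1 > 8L) return(delta / duration)
  o <- .range_ols(cs, max(i1, 1L), min(i2 + 1L, n))
  if (is.finite(o$slope) && o$n >= 3) o$slope else delta / duration
}

.fit_ramp <- function(t, y, a, b, i1, i2, lo1, hi2, free1, free2,
                      max_shift = 80L) {
  tw <- t[a:b]; yw <- y[a:b]
  nw <- length(yw)
  Sy <- sum(yw); Syy_c <- sum(yw^2) - Sy^2 / nw
  eval_at <- function(i1, i2) {
    f <- pmin(pmax((tw - t[i1]) / (t[i2] - t[i1]), 0), 1)
    Sf <- sum(f); Sff_c <- sum(f^2) - Sf^2 / nw
    if (Sff_c <= 1e-12) return(list(sse = Inf))
    Sfy_c <- sum(f * yw) - Sf * Sy / nw
    delta <- Sfy_c / Sff_c
    list(sse = max(Syy_c - Sfy_c^2 / Sff_c, 0), delta = delta,
         l1 = (Sy - delta * Sf) / nw, Sff_c = Sff_c)
  }
  # coarse-to-fine scan: stride-4 sweep, then full resolution around the
  # winner; the continuous polish below removes the remaining granularity
  scan <- function(lo, hi, center, fn) {
    lo <- max(lo, center - max_shift)
    hi <- min(hi, center + max_shift)
    if (lo > hi) return(center)
    if (hi - lo <= 32L) {
      # narrow ranges (and the sharply localized SSE basins of few-sample
      # bursts) are scanned at full resolution
      cand <- seq(lo, hi)
      return(cand[which.min(vapply(cand, fn, numeric(1)))])
    }
    # coarse sweep plus a full-resolution neighborhood of the starting
    # point: sharply localized basins (few-sample bursts) sit at the start
    near <- seq(max(lo, center - 8L), min(hi, center + 8L))
    cand <- unique(c(seq(lo, hi, by = 4L), hi, near))
    best <- cand[which.min(vapply(cand, fn, numeric(1)))]
    cand2 <- seq(max(lo, best - 3L), min(hi, best + 3L))
    cand2[which.min(vapply(cand2, fn, numeric(1)))]
  }
  for (iter in 1:2) {
    if (free1) {
      i1 <- scan(lo1, min(i2 - 1L, hi2 - 1L), i1,
                 function(i) eval_at(i, i2)$sse)
    }
    if (free2) {
      i2 <- scan(max(i1 + 1L, lo1 + 1L), hi2, i2,
                 function(i) eval_at(i1, i)$sse)
    }
    if (!free1 && !free2) break
  }
  # continuous refinement of the breakpoints (sub-sample resolution):
  # removes the duration quantization that biases rates of bursts lasting
  # only a few samples
  dt_min <- t[2] - t[1]   # a burst faster than one sample is unresolvable
  eval_tau <- function(p) {
    if (p[2] - p[1] < dt_min) return(Inf)
    f <- pmin(pmax((tw - p[1]) / (p[2] - p[1]), 0), 1)
    Sf <- sum(f); Sff_c <- sum(f^2) - Sf^2 / nw
    if (Sff_c <= 1e-12) return(Inf)
    Sfy_c <- sum(f * yw) - Sf * Sy / nw
    max(Syy_c - Sfy_c^2 / Sff_c, 0)
  }
  opt <- tryCatch(
    stats::optim(c(t[i1], t[i2]), eval_tau, method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-9)),
    error = function(e) NULL
  )
  tau1 <- t[i1]; tau2 <- t[i2]
  if (!is.null(opt) && is.finite(opt$value) &&
      opt$par[1] >= tw[1] - (t[2] - t[1]) && opt$par[2] <= tw[nw] &&
      opt$value <= eval_tau(c(tau1, tau2))) {
    tau1 <- opt$par[1]; tau2 <- opt$par[2]
    i1 <- max(findInterval(tau1, t), 1L)
    i2 <- max(min(findInterval(tau2, t), length(t)), i1 + 1L)
  }
  f <- pmin(pmax((tw - tau1) / (tau2 - tau1), 0), 1)
  Sf <- sum(f); Sff_c <- sum(f^2) - Sf^2 / nw
  Sfy_c <- sum(f * yw) - Sf * Sy / nw
  delta <- if (Sff_c > 1e-12) Sfy_c / Sff_c else NA_real_
  out <- list(
    sse = if (Sff_c > 1e-12) max(Syy_c - Sfy_c^2 / Sff_c, 0) else Inf,
    delta = delta,
    l1 = (Sy - delta * Sf) / nw, Sff_c = Sff_c)
  out$i1 <- i1; out$i2 <- i2
  out$tau1 <- tau1; out$tau2 <- tau2
  out$se_delta <- if (is.finite(out$sse) && nw > 2 && Sff_c > 1e-12) {
    sqrt(out$sse / (nw - 2) / out$Sff_c)
  } else NA_real_
  out$duration <- tau2 - tau1
  out
}

#' Detect candidate pause intervals by the flat-run rule
#'
#' Implements the operational pause definition directly: maximal runs of at
#' least six consecutive samples (3 s at 2 Hz) whose standard deviation about
#' the run mean does not exceed the baseline noise SD and whose OLS slope
#' magnitude is below the category threshold rate. Runs separated by fewer
#' than two samples are merged; runs shorter than 3 s are discarded. This is
#' the literal textual rule, useful for QC and high signal-to-noise data;
#' [segment_trace()] embeds the same flatness rules in a piecewise-linear
#' partition instead (see the methods vignette for why).
#'
#' @param trace Tibble with `time_s` and `position_bp`.
#' @param noise_sd_bp Baseline noise SD (bp).
#' @param threshold_rate_bp_s Category threshold rate (bp/s); `NULL` disables
#'   the slope condition.
#' @return Tibble of candidate pauses: `t_start_s`, `t_end_s`, `n_pts`.
#' @export
detect_pauses <- function(trace, noise_sd_bp, threshold_rate_bp_s = NULL) {
  stopifnot(is.data.frame(trace), "position_bp" %in% names(trace))
  y <- trace$position_bp
  t <- trace$time_s
  n <- length(y)
  dt <- if (n > 1) t[2] - t[1] else 1 / .fs_const$acquisition_hz
  min_pts <- .fs_const$min_pause_pts
  empty <- tibble(t_start_s = numeric(0), t_end_s = numeric(0),
                  n_pts = integer(0))
  if (n < min_pts) return(empty)
  cs <- .cumstats(t, y)
  sd_lim <- max(noise_sd_bp, 1e-9)
  ok <- function(i, j) {
    o <- .range_ols(cs, i, j)
    if (sqrt(o$syy / (o$n - 1)) > sd_lim) return(FALSE)
    if (!is.null(threshold_rate_bp_s) &&
        abs(o$slope) >= threshold_rate_bp_s) return(FALSE)
    TRUE
  }
  runs <- list()
  i <- 1L
  while (i <= n - min_pts + 1) {
    j <- i + min_pts - 1L
    if (ok(i, j)) {
      while (j < n && ok(i, j + 1L)) j <- j + 1L
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) == 0) return(empty)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] < 2) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- map_dfr(merged, function(r) {
    tibble(t_start_s = t[r[1]], t_end_s = t[r[2]] + dt,
           n_pts = r[2] - r[1] + 1L)
  })
  filter(out, .data$t_end_s - .data$t_start_s >= .fs_const$min_pause_s)
}

#' Segment a bp-domain trace into baseline, events, pauses and re-annealing
#'
#' Partitions the trace into piecewise-linear segments, assembles plateaus,
#' and classifies inter-plateau transitions by the assay's operational
#' rules: a *pause* is a flat stretch of at least six samples (3 s) whose
#' fluctuations are consistent with the baseline noise and whose slope is
#' below the category threshold rate, bracketed by events; an *event* is a
#' transition of forward progress of at least the spatial resolution whose
#' rate reaches the threshold; negative-progress transitions after the final
#' event on a shortening-unwinding substrate are *re-annealing*; everything
#' else is baseline. Segments tile the trace exactly.
#'
#' With `threshold_rate_bp_s = 0` (exhaustive first pass) events only need a
#' statistically significant level change and plateaus a statistically
#' insignificant slope; see [two_pass_segment()].
#'
#' @param trace Tibble with `time_s` and `position_bp` (bp domain; use
#'   [read_traces()] or [displacement_to_nt()] to convert). Must have at
#'   least 6 samples.
#' @param noise_profile A [noise_profile()] (or the tibble from
#'   [characterize_noise()]): supplies `noise_sd_bp` and `resolution_bp`.
#' @param threshold_rate_bp_s Category threshold rate (bp/s), >= 0.
#' @param geometry A [substrate_geometry()] (sign convention for
#'   re-annealing).
#' @return Tibble of segments: `kind`, `t_start_s`, `t_end_s`, `duration_s`,
#'   `n_pts`, `delta_bp`, `rate_bp_s`, `se_rate`, `r2`.
#' @export
segment_trace <- function(trace, noise_profile, threshold_rate_bp_s,
                          geometry, .partition = NULL) {
  stopifnot(is.data.frame(trace), "position_bp" %in% names(trace))
  if (threshold_rate_bp_s < 0) abort("threshold_rate_bp_s must be >= 0")
  y <- trace$position_bp
  t <- trace$time_s
  n <- length(y)
  if (n < .fs_const$min_pause_pts) {
    abort("trace must have at least 6 samples")
  }
  dt <- t[2] - t[1]
  # the penalized partition does not depend on the threshold, so callers
  # that classify the same trace twice (two_pass_segment) can reuse it
  part <- .partition %||% .partition_trace(t, y, noise_profile$noise_sd_bp)
  .classify_partition(part, t, y, dt, noise_profile$noise_sd_bp,
                      noise_profile$resolution_bp, threshold_rate_bp_s,
                      geometry)
}

.classify_partition <- function(part, t, y, dt, noise_sd, resolution,
                                threshold, geometry) {
  cs <- part$cs
  n <- part$n
  sigma <- max(noise_sd, 0.05)
  starts <- part$starts
  ends <- c(starts[-1] - 1L, n)
  ols <- lapply(seq_along(starts), function(k)
    .range_ols(cs, starts[k], ends[k]))

  flat_bound <- function(m) {
    sigma * sqrt(qchisq(0.99, df = max(m - 1, 1)) / max(m - 1, 1))
  }
  plateau_test <- function(o) {
    if (o$n < .fs_const$min_pause_pts) return(FALSE)
    sd_m <- sqrt(o$syy / (o$n - 1))
    if (sd_m > flat_bound(o$n)) return(FALSE)
    if (threshold > 0) {
      abs(o$slope) < max(threshold, 2 * o$se_slope)
    } else {
      abs(o$slope) <= 2 * o$se_slope
    }
  }
  is_plateau <- vapply(ols, plateau_test, logical(1))

  # merge adjacent plateaus whose level gap at the shared boundary is below
  # the spatial resolution (such a change is not observable); the merged
  # piece is retested, so a slow ramp chopped into pseudo-plateaus reverts
  # to a transition
  k <- 1L
  while (k < length(starts)) {
    if (is_plateau[k] && is_plateau[k + 1]) {
      tb <- (t[ends[k]] + t[starts[k + 1]]) / 2
      lv1 <- ols[[k]]$intercept + ols[[k]]$slope * tb
      lv2 <- ols[[k + 1]]$intercept + ols[[k + 1]]$slope * tb
      if (abs(lv1 - lv2) < resolution) {
        starts <- starts[-(k + 1)]
        ends <- ends[-k]
        ols[[k]] <- .range_ols(cs, starts[k], ends[k])
        ols[[k + 1]] <- NULL
        is_plateau <- is_plateau[-(k + 1)]
        is_plateau[k] <- plateau_test(ols[[k]])
        if (!is_plateau[k] && k > 1) k <- k - 1L
        next
      }
    }
    k <- k + 1L
  }

  # nodes: alternate plateaus and transitions (runs of non-plateau pieces,
  # possibly empty between two plateaus separated by a bare level jump)
  nodes <- list()
  kk <- 1L
  np <- length(starts)
  while (kk <= np) {
    if (is_plateau[kk]) {
      nodes[[length(nodes) + 1]] <- list(type = "plateau", i = starts[kk],
                                         j = ends[kk])
      if (kk < np && is_plateau[kk + 1]) {
        nodes[[length(nodes) + 1]] <- list(type = "transition",
                                           pieces = integer(0))
      }
      kk <- kk + 1L
    } else {
      run <- kk
      while (kk <= np && !is_plateau[kk]) kk <- kk + 1L
      nodes[[length(nodes) + 1]] <- list(type = "transition",
                                         pieces = run:(kk - 1L))
    }
  }

  # split multi-sign transitions (e.g. unwinding followed by re-annealing)
  # at sign changes between pieces with statistically significant slopes;
  # insignificant pieces inherit the sign of the last significant one
  nodes2 <- list()
  for (nd in nodes) {
    if (nd$type != "transition" || length(nd$pieces) < 2) {
      nodes2[[length(nodes2) + 1]] <- nd
      next
    }
    sg <- vapply(nd$pieces, function(k) {
      o <- ols[[k]]
      if (is.finite(o$se_slope) && abs(o$slope) > 2 * o$se_slope) {
        sign(o$slope)
      } else 0
    }, numeric(1))
    cur <- 0
    for (q2 in seq_along(sg)) {
      if (sg[q2] == 0) sg[q2] <- cur else cur <- sg[q2]
    }
    grp <- cumsum(c(1, diff(sg) != 0 & sg[-1] != 0 & sg[-length(sg)] != 0))
    for (g in unique(grp)) {
      nodes2[[length(nodes2) + 1]] <-
        list(type = "transition", pieces = nd$pieces[grp == g])
    }
  }
  nodes <- nodes2

  # fit and classify transitions; the clamped ramp model supplies its own
  # plateaus, so both breakpoints are profiled whether or not the partition
  # produced an explicit flanking plateau piece
  out <- list()
  for (q in seq_along(nodes)) {
    nd <- nodes[[q]]
    if (nd$type == "plateau") {
      out[[q]] <- list(list(kind = "flat", i = nd$i, j = nd$j))
      next
    }
    left <- if (q > 1 && nodes[[q - 1]]$type == "plateau") q - 1L else NA
    right <- if (q < length(nodes) && nodes[[q + 1]]$type == "plateau") {
      q + 1L
    } else NA
    if (length(nd$pieces) > 0) {
      ti <- starts[nd$pieces[1]]
      tj <- ends[nd$pieces[length(nd$pieces)]]
    } else {
      ti <- nodes[[q - 1]]$j + 1L
      tj <- ti
    }
    # cap the plateau window at 240 samples (2 min): plenty to pin the
    # levels, and keeps the breakpoint scans linear in the transition size
    a <- if (!is.na(left)) max(out[[left]][[1]]$i, ti - 240L) else ti
    b <- if (!is.na(right)) min(nodes[[right]]$j, tj + 240L) else tj
    i1 <- max(ti - 1L, a, 1L)
    i2 <- min(max(tj, i1 + 1L), n)
    lo1 <- if (!is.na(left)) min(a + 1L, i1) else max(a - 1L, 1L)
    hi2 <- if (!is.na(right)) max(b - 1L, i2) else min(b, n)
    fit <- .fit_ramp(t, y, max(lo1, 1L), min(hi2 + 1L, n), i1, i2, lo1, hi2,
                     free1 = TRUE, free2 = TRUE)
    dissolve <- function() {
      if (length(nd$pieces) > 0) {
        list(list(kind = "flat", i = ti, j = tj))
      } else list(list(kind = "flat", i = ti, j = ti - 1L))
    }
    if (!is.finite(fit$sse)) {
      out[[q]] <- dissolve()
      next
    }
    rate <- .event_rate(cs, t, fit$i1, fit$i2, fit$delta, fit$duration, n)
    sig <- is.finite(fit$se_delta) && abs(fit$delta) > 3 * fit$se_delta
    rate_ok <- if (threshold > 0) abs(rate) >= threshold else sig
    kind <- if (fit$delta >= resolution && rate_ok && sig) {
      "event"
    } else if (fit$delta <= -resolution && rate_ok && sig) {
      "negactivity"
    } else "flat"
    if (kind == "flat") {
      out[[q]] <- dissolve()
      next
    }
    rows <- list()
    if (!is.na(left)) {
      out[[left]][[1]]$j <- fit$i1
    } else if (fit$i1 >= ti) {
      rows[[length(rows) + 1]] <- list(kind = "flat", i = ti, j = fit$i1)
    }
    rows[[length(rows) + 1]] <-
      list(kind = kind, i = fit$i1 + 1L, j = fit$i2,
           delta = fit$delta, rate = rate,
           se_rate = fit$se_delta / fit$duration, sse = fit$sse)
    if (!is.na(right)) {
      nodes[[right]]$i <- fit$i2 + 1L
    } else if (fit$i2 < tj) {
      rows[[length(rows) + 1]] <- list(kind = "flat", i = fit$i2 + 1L, j = tj)
    }
    out[[q]] <- rows
  }
  out <- do.call(c, out)
  segs <- .assemble_segments(out, cs, t, dt, n)
  segs <- .split_paused_events(segs, cs, t, y, dt, sigma, resolution,
                               threshold)

  # relabel flats: pauses only when bracketed by events and satisfying the
  # pause rules; negative activity after the final event on a shortening
  # substrate is re-annealing
  ev <- which(segs$kind == "event")
  segs$kind <- vapply(seq_len(nrow(segs)), function(k) {
    kd <- segs$kind[k]
    if (kd == "flat") {
      if (length(ev) > 0 && k > min(ev) && k < max(ev) &&
          segs$n_pts[k] >= .fs_const$min_pause_pts &&
          segs$duration_s[k] >= .fs_const$min_pause_s) "pause" else "baseline"
    } else if (kd == "negactivity") {
      if (geometry$name == "unwinding_shortening" &&
          length(ev) > 0 && k > max(ev)) "reanneal" else "baseline"
    } else kd
  }, character(1))

  repeat {
    same <- which(segs$kind[-1] == segs$kind[-nrow(segs)])
    if (length(same) == 0) break
    segs <- .merge_seg_rows(segs, same[1], cs, t, dt)
  }
  select(segs, "kind", "t_start_s", "t_end_s", "duration_s", "n_pts",
         "delta_bp", "rate_bp_s", "se_rate", "r2")
}

# Longest interior run satisfying the pause rules (flat at the noise level,
# slope below the category threshold or insignificant) inside [i, j].
.find_interior_flat <- function(cs, t, i, j, sigma, threshold) {
  min_pts <- .fs_const$min_pause_pts
  if (j - i + 1 < min_pts + 4) return(NULL)
  bound <- function(m) {
    sigma * sqrt(qchisq(0.99, df = max(m - 1, 1)) / max(m - 1, 1))
  }
  ok <- function(s, e) {
    o <- .range_ols(cs, s, e)
    if (sqrt(o$syy / (o$n - 1)) > bound(o$n)) return(FALSE)
    if (threshold > 0) {
      abs(o$slope) < max(threshold, 2 * o$se_slope)
    } else {
      abs(o$slope) <= 2 * o$se_slope
    }
  }
  best <- NULL
  s <- i + 2L
  while (s <= j - min_pts - 1L) {
    e <- s + min_pts - 1L
    if (e > j - 2L || !ok(s, e)) {
      s <- s + 1L
      next
    }
    while (e < j - 2L && ok(s, e + 1L)) e <- e + 1L
    if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
    s <- e + 2L
  }
  best
}

# Split fitted activity segments that contain an interior pause the coarse
# partition missed (a restart whose flanking bursts were merged into one
# transition), re-fitting each half with the ramp model against the interior
# flat; iterates until no further split applies.
.split_paused_events <- function(segs, cs, t, y, dt, sigma, resolution,
                                 threshold) {
  guard <- 0L
  k <- 1L
  while (k <= nrow(segs) && guard < 50L) {
    if (!segs$kind[k] %in% c("event", "negactivity")) {
      k <- k + 1L
      next
    }
    i <- segs$i_start[k]; j <- segs$i_end[k]
    flat <- .find_interior_flat(cs, t, i, j, sigma, threshold)
    if (is.null(flat)) {
      k <- k + 1L
      next
    }
    guard <- guard + 1L
    s <- flat[1]; e <- flat[2]
    halves <- list()
    for (side in c("left", "right")) {
      if (side == "left") {
        a0 <- if (k > 1 && segs$kind[k - 1] %in% c("flat", "baseline")) {
          max(segs$i_start[k - 1], i - 240L)
        } else i
        fit <- .fit_ramp(t, y, a0, e, max(i - 1L, a0), s - 1L,
                         lo1 = a0, hi2 = s - 1L, free1 = TRUE, free2 = TRUE)
        rng <- c(i, s - 1L)
      } else {
        b0 <- if (k < nrow(segs) &&
                  segs$kind[k + 1] %in% c("flat", "baseline")) {
          min(segs$i_end[k + 1], j + 240L)
        } else j
        fit <- .fit_ramp(t, y, s, b0, e, min(j, b0 - 1L),
                         lo1 = s + 1L, hi2 = b0, free1 = TRUE, free2 = TRUE)
        rng <- c(e + 1L, j)
      }
      halves[[side]] <- list(fit = fit, rng = rng)
    }
    mk_row <- function(h) {
      fit <- h$fit
      if (!is.finite(fit$sse)) {
        return(list(kind = "flat", i = h$rng[1], j = h$rng[2]))
      }
      rate <- .event_rate(cs, t, fit$i1, fit$i2, fit$delta, fit$duration,
                          length(t))
      sig <- is.finite(fit$se_delta) && abs(fit$delta) > 3 * fit$se_delta
      rate_ok <- if (threshold > 0) abs(rate) >= threshold else sig
      if (abs(fit$delta) >= resolution && rate_ok && sig) {
        list(kind = if (fit$delta > 0) "event" else "negactivity",
             i = max(fit$i1 + 1L, h$rng[1]), j = min(fit$i2, h$rng[2]),
             delta = fit$delta, rate = rate,
             se_rate = fit$se_delta / fit$duration, sse = fit$sse)
      } else {
        list(kind = "flat", i = h$rng[1], j = h$rng[2])
      }
    }
    # model-selection guard: accept the split only if the two-ramp model
    # reduces the SSE by more than the partition penalty for the extra
    # breakpoints; a short run that merely looks flat inside a genuine
    # continuous ramp does not qualify
    a0 <- if (k > 1 && segs$kind[k - 1] %in% c("flat", "baseline")) {
      max(segs$i_start[k - 1], i - 240L)
    } else i
    b0 <- if (k < nrow(segs) && segs$kind[k + 1] %in% c("flat", "baseline")) {
      min(segs$i_end[k + 1], j + 240L)
    } else j
    single <- .fit_ramp(t, y, a0, b0, max(i - 1L, a0), min(j, b0),
                        lo1 = a0, hi2 = b0, free1 = TRUE, free2 = TRUE)
    sse_flat <- .range_ols(cs, s, e)$syy
    sse2 <- halves$left$fit$sse + halves$right$fit$sse - sse_flat
    nW <- b0 - a0 + 1
    if (!is.finite(single$sse) ||
        single$sse - sse2 <= .fs_split_penalty * sigma^2 * log(nW)) {
      k <- k + 1L
      next
    }
    lrow <- mk_row(halves$left)
    rrow <- mk_row(halves$right)
    rows <- list()
    if (lrow$kind == "flat") {
      rows[[length(rows) + 1]] <- list(kind = "flat", i = i, j = s - 1L)
    } else {
      if (lrow$i > i) {
        rows[[length(rows) + 1]] <- list(kind = "flat", i = i, j = lrow$i - 1L)
      }
      rows[[length(rows) + 1]] <- lrow
      if (lrow$j < s - 1L) {
        rows[[length(rows) + 1]] <- list(kind = "flat", i = lrow$j + 1L,
                                         j = s - 1L)
      }
    }
    rows[[length(rows) + 1]] <- list(kind = "flat", i = s, j = e)
    if (rrow$kind == "flat") {
      rows[[length(rows) + 1]] <- list(kind = "flat", i = e + 1L, j = j)
    } else {
      if (rrow$i > e + 1L) {
        rows[[length(rows) + 1]] <- list(kind = "flat", i = e + 1L,
                                         j = rrow$i - 1L)
      }
      rows[[length(rows) + 1]] <- rrow
      if (rrow$j < j) {
        rows[[length(rows) + 1]] <- list(kind = "flat", i = rrow$j + 1L,
                                         j = j)
      }
    }
    # note: when both halves fall below the resolution the whole region
    # dissolves into flat - the interior pause is real (it passed the SSE
    # guard), so the region is two unobservable changes, not one event
    new_rows <- .assemble_segments(rows, cs, t, dt, length(t))
    segs <- bind_rows(
      if (k > 1) segs[seq_len(k - 1), ] else NULL,
      new_rows,
      if (k < nrow(segs)) segs[seq(k + 1, nrow(segs)), ] else NULL
    )
    # stay at k: the first new row may split further
  }
  segs
}

.assemble_segments <- function(out, cs, t, dt, n) {
  # drop zero-length leftovers, merge adjacent flats, emit tibble
  keep <- purrr::keep(out, function(o) o$j >= o$i)
  rows <- list()
  for (o in keep) {
    last <- if (length(rows) > 0) rows[[length(rows)]] else NULL
    if (!is.null(last) && last$kind == "flat" && o$kind == "flat") {
      rows[[length(rows)]]$j <- o$j
      next
    }
    rows[[length(rows) + 1]] <- o
  }
  map_dfr(rows, function(o) {
    i <- o$i; j <- o$j
    r <- .range_ols(cs, i, j)
    if (o$kind %in% c("event", "negactivity")) {
      span <- max(t[j] + dt - t[max(i - 1L, 1L)], dt)
      tibble(kind = o$kind, i_start = i, i_end = j,
             t_start_s = t[i], t_end_s = t[j] + dt,
             duration_s = t[j] + dt - t[i], n_pts = j - i + 1L,
             delta_bp = o$delta, rate_bp_s = o$rate,
             se_rate = o$se_rate,
             r2 = if (r$syy > 0) max(1 - o$sse / r$syy, 0) else NA_real_)
    } else {
      tibble(kind = "flat", i_start = i, i_end = j,
             t_start_s = t[i], t_end_s = t[j] + dt,
             duration_s = t[j] + dt - t[i], n_pts = j - i + 1L,
             delta_bp = r$slope * (t[j] - t[i]), rate_bp_s = r$slope,
             se_rate = r$se_slope,
             r2 = if (r$syy > 0) 1 - r$sse / r$syy else NA_real_)
    }
  })
}

.merge_seg_rows <- function(segs, k, cs, t, dt) {
  i <- segs$i_start[k]
  j <- segs$i_end[k + 1]
  o <- .range_ols(cs, i, j)
  kd <- segs$kind[k]
  segs$i_end[k] <- j
  segs$n_pts[k] <- o$n
  segs$t_end_s[k] <- t[j] + dt
  segs$duration_s[k] <- t[j] + dt - t[i]
  if (kd %in% c("event", "negactivity", "reanneal")) {
    segs$delta_bp[k] <- segs$delta_bp[k] + segs$delta_bp[k + 1]
    segs$rate_bp_s[k] <- segs$delta_bp[k] / (t[j] - t[i])
  } else {
    segs$rate_bp_s[k] <- o$slope
    segs$delta_bp[k] <- o$slope * (t[j] - t[i])
    segs$se_rate[k] <- o$se_slope
  }
  segs$r2[k] <- if (o$syy > 0) 1 - o$sse / o$syy else NA_real_
  segs[-(k + 1), ]
}
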
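geo_ssb <- substrate_geometry("leading_ssb")
np150 <- noise_profile(150, 200)
np0 <- noise_profile(0, 200)

make_truth <- function(...) {
  rows <- list(...)
  tibble::tibble(
    kind = vapply(rows, `[[`, "", 1),
    dur = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    rate_bp_s = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
  ) |>
    dplyr::mutate(t_end_s = cumsum(dur), t_start_s = t_end_s - dur,
                  delta_bp = rate_bp_s * dur) |>
    dplyr::select(kind, t_start_s, t_end_s, rate_bp_s, delta_bp)
}

test_that("flat-run pause detection follows the six-point rule", {
  # 10 flat samples (5 s) bracketed by steep ramps
  tru <- make_truth(list("event", 10, 100), list("pause", 5, 0),
                    list("event", 10, 100))
  tr <- trace_from_truth(tru, geo_ssb, noise_sd = 0)
  pz <- detect_pauses(tr, noise_sd_bp = 10)
  expect_equal(nrow(pz), 1)
  expect_equal(pz$t_end_s - pz$t_start_s, 5, tolerance = 1)

  # 4 interior flat samples (2 s) are below the minimum of six points
  tru2 <- make_truth(list("event", 10, 100), list("pause", 2.0, 0),
                     list("event", 10, 100))
  tr2 <- trace_from_truth(tru2, geo_ssb, noise_sd = 0)
  expect_equal(nrow(detect_pauses(tr2, noise_sd_bp = 10)), 0)

  # an entirely flat trace is one spanning run
  flat <- tibble::tibble(time_s = seq(0, 50, 0.5),
                         position_bp = rep(3, 101))
  pz3 <- detect_pauses(flat, noise_sd_bp = 10)
  expect_equal(nrow(pz3), 1)
  expect_equal(pz3$n_pts, 101L)
})

test_that("noise-free segmentation reproduces the truth to one sample", {
  tru <- make_truth(list("baseline", 30, 0), list("event", 80, 5),
                    list("pause", 100, 0), list("event", 60, 5),
                    list("baseline", 30, 0))
  tr <- trace_from_truth(tru, geo_ssb, noise_sd = 0)
  seg <- segment_trace(tr, np0, 0.5, geo_ssb)
  expect_equal(seg$kind, c("baseline", "event", "pause", "event", "baseline"))
  tru_ev <- dplyr::filter(tru, kind == "event")
  seg_ev <- dplyr::filter(seg, kind == "event")
  expect_equal(seg_ev$t_start_s, tru_ev$t_start_s, tolerance = 0.51)
  expect_equal(seg_ev$t_end_s, tru_ev$t_end_s, tolerance = 0.51)
  expect_equal(seg_ev$rate_bp_s, c(5, 5), tolerance = 0.05)
  expect_equal(seg_ev$delta_bp, c(400, 300), tolerance = 5)
})

test_that("segments tile the trace exactly", {
  p <- default_presets("sv40_ssb")[[1]]
  for (s in 1:5) {
    sim <- simulate_trace(p, seed = 400 + s)
    seg <- segment_trace(sim$trace, np150, 0.5, p$geometry)
    expect_equal(sum(seg$duration_s), nrow(sim$trace) * 0.5)
    expect_equal(seg$t_start_s[-1], seg$t_end_s[-nrow(seg)])
    expect_equal(seg$t_start_s[1], 0)
  }
})

test_that("length changes below the spatial resolution are not events", {
  tru <- make_truth(list("baseline", 60, 0), list("event", 30, 5),
                    list("baseline", 60, 0))  # 150 bp < 200 bp resolution
  tr <- trace_from_truth(tru, geo_ssb, noise_sd = 0)
  seg <- segment_trace(tr, np0, 0.5, geo_ssb)
  expect_false("event" %in% seg$kind)

  tru2 <- make_truth(list("baseline", 60, 0), list("event", 60, 5),
                     list("baseline", 60, 0))  # 300 bp >= 200 bp
  tr2 <- trace_from_truth(tru2, geo_ssb, noise_sd = 0)
  seg2 <- segment_trace(tr2, np0, 0.5, geo_ssb)
  expect_true("event" %in% seg2$kind)
})

test_that("a flat trace is baseline, not pause", {
  flat <- tibble::tibble(time_s = seq(0, 100, 0.5),
                         position_bp = rnorm(201, 0, 150))
  seg <- segment_trace(flat, np150, 0.5, geo_ssb)
  expect_true(all(seg$kind == "baseline"))
  expect_error(segment_trace(flat[1:4, ], np150, 0.5, geo_ssb), "6 samples")
})

test_that("re-annealing after the final event is recognized on shortening geometry", {
  geo_sh <- substrate_geometry("unwinding_shortening")
  tru <- make_truth(list("baseline", 40, 0), list("event", 300, 1.1),
                    list("reanneal", 66, -5), list("baseline", 40, 0))
  tr <- trace_from_truth(tru, geo_sh, noise_sd = 0)
  seg <- segment_trace(tr, np0, 0.1, geo_sh)
  expect_equal(sum(seg$kind == "event"), 1)
  expect_equal(sum(seg$kind == "reanneal"), 1)
  ra <- dplyr::filter(seg, kind == "reanneal")
  expect_lt(ra$delta_bp, -200)

  # same shape on a lengthening geometry: the negative stretch is baseline
  geo_l <- substrate_geometry("unwinding_lengthening")
  seg2 <- segment_trace(tr, np0, 0.1, geo_l)
  expect_false("reanneal" %in% seg2$kind)
})

test_that("event recall and pause durations hold at the working noise level", {
  p <- default_presets("sv40_ssb")[[1]]
  ens <- simulate_ensemble(p, 60, seed = 77)
  seg <- segment_ensemble(ens$traces, np150, 0.5, p$geometry)
  ev <- dplyr::filter(seg, kind == "event")
  tru_ev <- dplyr::filter(ens$truth, kind == "event", delta_bp >= 300)
  # recall of comfortably-resolvable events (>= 1.5x resolution)
  hits <- 0
  for (r in seq_len(nrow(tru_ev))) {
    cand <- dplyr::filter(ev, trace_id == tru_ev$trace_id[r],
                          t_start_s < tru_ev$t_end_s[r],
                          t_end_s > tru_ev$t_start_s[r])
    if (nrow(cand) > 0) hits <- hits + 1
  }
  expect_gte(hits / nrow(tru_ev), 0.9)

  # matched pause durations within 20% in the median
  pz <- dplyr::filter(seg, kind == "pause")
  tru_pz <- dplyr::filter(ens$truth, kind == "pause")
  errs <- c()
  for (r in seq_len(nrow(pz))) {
    cand <- dplyr::filter(tru_pz, trace_id == pz$trace_id[r],
                          t_start_s < pz$t_end_s[r],
                          t_end_s > pz$t_start_s[r])
    if (nrow(cand) == 1) {
      errs <- c(errs, abs(pz$duration_s[r] -
                            (cand$t_end_s - cand$t_start_s)) /
                  (cand$t_end_s - cand$t_start_s))
    }
  }
  expect_gt(length(errs), 3)
  expect_lt(median(errs), 0.2)
})

test_that("event recall does not improve when noise increases", {
  p_lo <- default_presets("sv40_ssb")[[1]]
  p_hi <- p_lo
  p_hi$noise_sd <- 50
  recall <- function(p, noise) {
    ens <- simulate_ensemble(p, 15, seed = 55)
    seg <- segment_ensemble(ens$traces, noise_profile(noise, 200), 0.5,
                            p$geometry)
    ev <- dplyr::filter(seg, kind == "event")
    tru_ev <- dplyr::filter(ens$truth, kind == "event", delta_bp >= 200)
    hits <- 0
    for (r in seq_len(nrow(tru_ev))) {
      cand <- dplyr::filter(ev, trace_id == tru_ev$trace_id[r],
                            t_start_s < tru_ev$t_end_s[r],
                            t_end_s > tru_ev$t_start_s[r])
      if (nrow(cand) > 0) hits <- hits + 1
    }
    hits / nrow(tru_ev)
  }
  expect_gte(recall(p_hi, 50), recall(p_lo, 150))
})
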
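# Ground-truth-level checks of the trace generator (law-of-large-numbers
# oracles run on the truth tables, which is fast and independent of the
# segmentation code).

test_that("noise-free forced single event is exactly piecewise linear", {
  # proc_mean far above the template so the burst clamps to exactly 400 bp
  p <- kinetic_preset("forced", rate_mean = 5, rate_sd = 0, proc_mean = 1e7,
                      noise_sd = 0, template_len = 400,
                      geometry = substrate_geometry("leading_ssb",
                                                    template_len = 400))
  sim <- simulate_trace(p, seed = 1, baseline_s = 10)
  ev <- dplyr::filter(sim$truth, kind == "event")
  # template clamps the exponential draw: exactly 400 bp at 5 bp/s = 80 s
  expect_equal(ev$delta_bp, 400)
  expect_equal(ev$t_end_s - ev$t_start_s, 80)
  inside <- dplyr::filter(sim$trace, time_s >= 10, time_s <= 90)
  slopes <- diff(inside$position_bp) / diff(inside$time_s)
  expect_true(all(abs(slopes - 5) < 1e-9))
  # nm series carries the geometry sign (shortening: bead against the flow)
  expect_true(all(diff(inside$position_nm) < 0))
})

test_that("same preset and seed give bitwise-identical traces", {
  p <- default_presets("sv40_ssb")[[1]]
  s1 <- simulate_trace(p, seed = 99)
  s2 <- simulate_trace(p, seed = 99)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$truth, s2$truth)
  e1 <- simulate_ensemble(p, 5, seed = 42)
  e2 <- simulate_ensemble(p, 5, seed = 42)
  expect_identical(e1$traces, e2$traces)
})

test_that("ensembles are element-wise reproducible and validated", {
  p <- default_presets("pol_delta_pe")[[1]]
  e <- simulate_ensemble(p, 8, seed = 7)
  expect_equal(dplyr::n_distinct(e$traces$trace_id), 8)
  # distinct seeds produce distinct traces
  totals <- tapply(e$traces$position_bp, e$traces$trace_id, sum)
  expect_equal(length(unique(totals)), 8)
  expect_error(simulate_ensemble(p, 0, seed = 1), "n_traces")
})

test_that("truth intervals tile the trace and respect the template bound", {
  for (pname in c("sv40_ssb", "ltag_alone", "sv40_fpc_mcm10")) {
    p <- default_presets(pname)[[1]]
    ens <- simulate_ensemble(p, 20, seed = 5)
    for (id in unique(ens$truth$trace_id)) {
      tru <- dplyr::filter(ens$truth, trace_id == id)
      expect_equal(tru$t_start_s[-1], tru$t_end_s[-nrow(tru)])
      expect_equal(tru$t_start_s[1], 0)
      ev <- dplyr::filter(tru, kind == "event")
      expect_lte(sum(ev$delta_bp), p$template_len + 1e-9)
    }
    # sampling interval is exactly 1 / acquisition_hz
    one <- dplyr::filter(ens$traces, trace_id == ens$traces$trace_id[1])
    expect_true(all(abs(diff(one$time_s) - 0.5) < 1e-12))
  }
})

test_that("per-burst statistics follow the generative model (1000 traces)", {
  p <- default_presets("sv40_ssb")[[1]]
  ens <- simulate_ensemble(p, 1000, seed = 31, baseline_s = 0, trailing_s = 0)
  ev <- dplyr::filter(ens$truth, kind == "event")
  # mean burst length ~ proc_mean within 3 MC SEs
  se_len <- sd(ev$delta_bp) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$delta_bp) - 300), 3 * se_len + 1)
  # fraction of multi-burst traces ~ p_restart
  nev <- table(ev$trace_id)
  frac_multi <- mean(nev >= 2)
  expect_lt(abs(frac_multi - 0.4), 3 * sqrt(0.4 * 0.6 / 1000) + 0.01)
  # multi-step identity: total activity ~ Exp(proc_mean / (1 - p_restart))
  totals <- tapply(ev$delta_bp, ev$trace_id, sum)
  se_tot <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 300 / 0.6), 3 * se_tot)
  # restart pauses are >= 3 s with mean ~ pause_mean
  pz <- dplyr::filter(ens$truth, kind == "pause")
  dur <- pz$t_end_s - pz$t_start_s
  expect_true(all(dur >= 3))
  expect_lt(abs(mean(dur) - 182) / 182, 0.1)
})

test_that("ensemble truth rates recover the preset mean within sampling error", {
  p <- default_presets("pol_delta_pe")[[1]]
  ens <- simulate_ensemble(p, 151, seed = 13)
  ev <- dplyr::filter(ens$truth, kind == "event")
  se <- sd(ev$rate_bp_s) / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$rate_bp_s) - 240), 3 * se + 240 * 0.02)
})

test_that("baseline simulation has the requested noise and no correlation", {
  b <- simulate_baseline(150, 500, seed = 2)
  expect_lt(abs(sd(b$position_bp) - 150) / 150, 0.10)
  expect_equal(mean(b$position_bp), 0, tolerance = 15)
  b0 <- simulate_baseline(0, 100, seed = 3)
  expect_true(all(b0$position_bp == 0))
  x <- simulate_baseline(150, 500, seed = 10)$position_bp
  y <- simulate_baseline(150, 500, seed = 11)$position_bp
  expect_lt(abs(cor(x, y)), 0.2)
  expect_error(simulate_baseline(100, 2, seed = 1), "3 s")
})

test_that("re-annealing returns the ltag_alone substrate to the start level", {
  p <- default_presets("ltag_alone")[[1]]
  sim <- simulate_trace(p, seed = 21)
  kinds <- sim$truth$kind
  expect_true("reanneal" %in% kinds)
  ra <- dplyr::filter(sim$truth, kind == "reanneal")
  ev <- dplyr::filter(sim$truth, kind == "event")
  expect_equal(ra$delta_bp, -sum(ev$delta_bp))
  expect_equal(ra$rate_bp_s, -5)
})

test_that("invalid preset fields are rejected by name", {
  expect_error(kinetic_preset("x", rate_mean = -1, proc_mean = 10),
               "rate_mean")
  expect_error(kinetic_preset("x", rate_mean = 1, proc_mean = 0),
               "proc_mean")
  expect_error(kinetic_preset("x", rate_mean = 1, proc_mean = 10,
                              p_restart = 1), "p_restart")
  expect_error(kinetic_preset("x", rate_mean = 1, proc_mean = 10,
                              p_restart = 0.5, pause_mean = 2), "pause_mean")
  expect_error(kinetic_preset("x", rate_mean = 1, proc_mean = 10,
                              noise_sd = 250), "noise_sd")
  expect_error(default_presets("nope"), "unknown")
})
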
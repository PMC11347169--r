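fake_stats <- function(n, proc_mean = 400, rate_mean = 5, seed = 1,
                       p_restart = 0) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    k <- 1 + stats::rgeom(1, prob = 1 - p_restart)
    proc <- rexp(k, 1 / proc_mean)
    rates <- pmax(rnorm(k, rate_mean, 0.3 * rate_mean), 0.01)
    pauses <- if (k > 1) 3 + rexp(k - 1, 1 / 179) else numeric(0)
    tibble::tibble(
      trace_id = as.character(i), n_events = k, restarted = k >= 2,
      multi_step_processivity_bp = sum(proc),
      multi_step_lifetime_s = sum(proc / rates) + sum(pauses),
      single_steps = list(tibble::tibble(
        processivity_bp = proc, lifetime_s = proc / rates,
        rate_bp_s = rates)),
      restart_pauses_s = list(pauses))
  })
}

test_that("single-event ensembles have identical single- and multi-step fits", {
  st <- fake_stats(120, seed = 3)
  sm <- summarize_condition(st, "one-step", resolution_bp = 200)
  expect_equal(sm$table$single_proc_bp, sm$table$multi_proc_bp,
               tolerance = 1e-8)
  expect_equal(sm$table$restart_fraction, 0)
  expect_true(is.na(sm$table$restart_pause_s))
  expect_equal(tidy(sm), sm$table)
})

test_that("condition summary recovers generative parameters", {
  st <- fake_stats(150, proc_mean = 300, rate_mean = 5.3, seed = 9,
                   p_restart = 0.4)
  sm <- summarize_condition(st, "sv40-like", resolution_bp = 200)
  expect_lt(abs(sm$table$rate_gauss_mean - 5.3) / 5.3, 0.15)
  expect_lt(abs(sm$table$multi_proc_bp - 500) / 500, 0.25)
  expect_lt(abs(sm$table$restart_pause_s - 182) / 182, 0.25)
  expect_lt(abs(sm$table$restart_fraction - 0.4), 0.12)
  expect_gte(sm$table$multi_proc_bp, sm$table$single_proc_bp * 0.95)
  expect_error(summarize_condition(st[0, ], "empty"), "empty")
})

test_that("restart scaling: multi-step mean ~ single-step / (1 - p_restart)", {
  st <- fake_stats(400, proc_mean = 300, rate_mean = 5.3, seed = 12,
                   p_restart = 0.4)
  sm <- summarize_condition(st, "x", resolution_bp = 200)
  fold <- sm$table$multi_proc_bp / sm$table$single_proc_bp
  expect_lt(abs(fold - 1 / 0.6) / (1 / 0.6), 0.2)
})

test_that("condition comparison computes fold changes against the reference", {
  a <- summarize_condition(fake_stats(100, proc_mean = 300, seed = 5,
                                      p_restart = 0.4), "base")
  b <- summarize_condition(fake_stats(100, proc_mean = 550, seed = 6,
                                      p_restart = 0.5), "boosted")
  cmp <- compare_conditions(list(a, b), reference = "base")
  self <- dplyr::filter(cmp, condition == "base")
  expect_true(all(abs(self$fold_change[is.finite(self$fold_change)] - 1)
                  < 1e-9))
  mp <- dplyr::filter(cmp, condition == "boosted", metric == "multi_proc_bp")
  expect_gt(mp$fold_change, 1.4)
  expect_error(compare_conditions(list(a, b), reference = "nope"),
               "not found")
  expect_error(compare_conditions(list()), "empty")
})
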
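test_that("fraction bound normalizes between plateau levels", {
  expect_equal(fraction_bound(0.3, 0.3, 0.8), 0)
  expect_equal(fraction_bound(0.8, 0.3, 0.8), 1)
  expect_equal(fraction_bound(0.55, 0.3, 0.8), 0.5)
  expect_error(fraction_bound(0.5, 0.4, 0.4), "differ")
  expect_warning(fraction_bound(1.5, 0, 1), "clamp")
})

test_that("quadratic isotherm matches a numerical mass-action solve to 1e-9", {
  # free-concentration root-finding oracle for A_tot, T_tot, K
  oracle <- function(A, T, K) {
    ab <- uniroot(function(x) {
      # x = bound complex; free A = A - x, free T = T - x
      (A - x) * (T - x) - K * x
    }, lower = 0, upper = min(A, T) * (1 - 1e-12), tol = 1e-14)$root
    ab / T
  }
  for (case in list(c(250, 20, 6.7), c(10, 20, 6.7), c(3, 20, 50),
                    c(100, 5, 1))) {
    expect_equal(isotherm(case[1], case[2], case[3]),
                 oracle(case[1], case[2], case[3]), tolerance = 1e-9)
  }
})

test_that("isotherm limits: saturation, stoichiometric, and hyperbolic", {
  expect_gt(isotherm(1e9, 20, 6.7), 1 - 1e-6)
  expect_equal(isotherm(5, 20, 0), 5 / 20)
  expect_equal(isotherm(50, 20, 0), 1)
  # T << K: quadratic converges to A/(K+A) within 1%
  A <- c(1, 5, 20, 100, 500)
  K <- 50
  fb_quad <- isotherm(A, target_nM = 0.05, kd_nM = K)
  fb_hyp <- A / (K + A)
  expect_lt(max(abs(fb_quad - fb_hyp) / fb_hyp), 0.01)
})

test_that("isotherm is monotone in titrant and in Kd", {
  A <- 2^(0:10)
  fb <- isotherm(A, 20, 6.7)
  expect_true(all(diff(fb) > 0))
  ks <- c(0.5, 2, 6.7, 30, 100)
  fb_k <- vapply(ks, function(k) isotherm(50, 20, k), numeric(1))
  expect_true(all(diff(fb_k) < 0))
})

test_that("Kd fit round-trips a noise-free titration to 0.1%", {
  curve <- simulate_mst(6.7)
  expect_equal(nrow(curve), 16)
  expect_true(all(diff(curve$titrant_nM) < 0))
  expect_true(all(diff(curve$signal) < 0))  # monotone with titrant
  fit <- fit_kd(curve)
  expect_lt(abs(fit$kd_nM - 6.7) / 6.7, 1e-3)
  expect_equal(glance(fit)$target_nM, 20)

  # fixed-plateau mode agrees in the noise-free limit
  fit2 <- fit_kd(curve, fix_plateaus = c(0, 1))
  expect_lt(abs(fit2$kd_nM - 6.7) / 6.7, 1e-3)
})

test_that("Kd fit recovers the truth within 15% under 2% noise (median of 50)", {
  kds <- vapply(1:50, function(i) {
    curve <- simulate_mst(6.7, noise_sd = 0.02, seed = 1000 + i)
    tryCatch(fit_kd(curve)$kd_nM, error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(median(kds, na.rm = TRUE) - 6.7) / 6.7, 0.15)
})

test_that("degenerate MST inputs error", {
  flat <- tibble::tibble(titrant_nM = 2^(10:1), signal = rep(1, 10))
  expect_error(fit_kd(flat), "flat")
  expect_error(fit_kd(tibble::tibble(titrant_nM = c(1, 2), signal = c(0, 1))),
               "6")
  expect_error(simulate_mst(0), "> 0")
  expect_error(simulate_mst(5, n_points = 3), "n_points")
  # Kd far above any titrant: signal stays near the unbound plateau
  weak <- simulate_mst(1e9)
  expect_lt(max(weak$signal), 1e-3)
})
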
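test_that("displacement/progress conversion follows the geometry sign and factor", {
  pe <- substrate_geometry("primer_extension")
  un <- substrate_geometry("unwinding_shortening")

  expect_equal(displacement_to_nt(376, pe), 376 * 3.76)
  expect_equal(displacement_to_nt(-100, un), 376)  # shortening = progress
  for (g in list(pe, un, substrate_geometry("leading_rpa"))) {
    expect_equal(displacement_to_nt(0, g), 0)
    x <- c(-500, -1.5, 0.25, 123.4)
    expect_equal(nt_to_displacement(displacement_to_nt(x, g), g), x)
  }
})

test_that("equipartition force matches the closed form and is offset-invariant", {
  # variance chosen so kBT * L / var = 2.60 pN exactly
  y <- c(rep(-sqrt(3162 / 2), 50), rep(sqrt(3162 / 2), 50))
  y <- y * sqrt(3162 / var(y))
  f <- equipartition_force(2000, y, kBT_pN_nm = 4.11)
  expect_equal(f$force_pN, 4.11 * 2000 / 3162, tolerance = 1e-10)
  expect_equal(round(f$force_pN, 2), 2.60)

  f_off <- equipartition_force(2000, y + 12345, kBT_pN_nm = 4.11)
  expect_equal(f_off$force_pN, f$force_pN)
})

test_that("equipartition force recovers a simulated 2.6 pN within 5% at n = 2000", {
  set.seed(42)
  target_var <- 4.11 * 2000 / 2.6
  y <- rnorm(2000, sd = sqrt(target_var))
  f <- equipartition_force(2000, y)
  expect_lt(abs(f$force_pN - 2.6) / 2.6, 0.05)
  expect_true(f$se_pN > 0)
})

test_that("equipartition force rejects degenerate input", {
  expect_error(equipartition_force(2000, rep(1, 100)), "variance")
  expect_error(equipartition_force(2000, rnorm(10)), "50")
  expect_error(equipartition_force(-5, rnorm(100)), "positive")
})

test_that("WLC force is exact at the boundary and reference point, and monotone", {
  expect_equal(wlc_force(0, 50), 0)
  expect_equal(wlc_force(0.9, 50, kBT_pN_nm = 4.11),
               (4.11 / 50) * (25 - 0.25 + 0.9))
  expect_equal(round(wlc_force(0.9, 50, kBT_pN_nm = 4.11), 3), 2.108)
  x <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(wlc_force(x, 50)) > 0))
  expect_error(wlc_force(1, 50), "\\[0, 1\\)")
})

test_that("WLC fit round-trips simulated force-extension curves", {
  fe <- simulate_force_extension(50, 4600, forces = seq(0.2, 8, length.out = 20))
  # the simulated extension at 2.108 pN sits at 90% relative extension
  x_at <- simulate_force_extension(50, 4600, forces = 2.108)$extension_nm
  expect_equal(x_at / 4600, 0.9, tolerance = 1e-3)

  fit <- fit_wlc(fe)
  expect_lt(abs(fit$persistence_nm - 50) / 50, 1e-3)
  expect_lt(abs(fit$contour_nm - 4600) / 4600, 1e-3)

  td <- tidy(fit)
  expect_equal(td$term, c("persistence_nm", "contour_nm"))

  set.seed(7)
  fe_noisy <- simulate_force_extension(50, 4600,
                                       forces = seq(0.2, 8, length.out = 20),
                                       noise_rel = 0.05)
  fit_n <- fit_wlc(fe_noisy)
  expect_lt(abs(fit_n$persistence_nm - 50) / 50, 0.10)
  expect_lt(abs(fit_n$contour_nm - 4600) / 4600, 0.10)
})

test_that("WLC fit refuses too few points and zero force range", {
  expect_error(fit_wlc(tibble::tibble(extension_nm = 1:3 * 1000,
                                      force_pN = 1:3)), "5")
  expect_error(fit_wlc(tibble::tibble(extension_nm = 1:6 * 500,
                                      force_pN = rep(2, 6))), "range")
  expect_error(simulate_force_extension(50, 4600, forces = -1), "non-negative")
})
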
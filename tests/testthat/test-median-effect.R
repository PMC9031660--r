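test_that("exact-law points are recovered to machine precision with r = 1", {
  cases <- list(c(m = 1, dm = 5), c(m = 2, dm = 4), c(m = 0.7, dm = 22))
  for (p in cases) {
    pts <- exact_points(p[["m"]], p[["dm"]], doses = c(1, 3, 10, 30, 100))
    fit <- fit_median_effect(pts$dose, pts$fa)
    expect_equal(fit$m, p[["m"]], tolerance = 1e-9)
    expect_equal(fit$Dm, p[["dm"]], tolerance = 1e-9)
    expect_equal(fit$r, 1, tolerance = 1e-9)
  }
})

test_that("two-point fit matches the closed-form line through the log-odds", {
  fit <- fit_median_effect(c(1, 10), c(0.2, 0.8))
  # slope = (log10(4) - log10(1/4)) / (log10 10 - log10 1) = 2*log10(4)
  expect_equal(fit$m, 2 * log10(4), tolerance = 1e-9)
  expect_equal(fit$m, 1.20412, tolerance = 1e-5)
  expect_equal(fit$Dm, sqrt(10), tolerance = 1e-9)
  expect_equal(fit$Dm, 3.16228, tolerance = 1e-5)
  expect_equal(fit$r, 1)
})

test_that("noisy fit recovers generating parameters and beats the grid oracle", {
  truth <- drug_truth("x", m_true = 2, dm_true = 4, noise_sd = 0.02)
  plate <- simulate_plate(truth, doses = dose_grid(4, n = 8), seed = 42)
  tab <- fa_table(plate)
  fit <- fit_median_effect(tab$dose_uM, tab$fa)
  expect_lt(abs(fit$m - 2), 0.2)
  expect_lt(abs(fit$Dm - 4) / 4, 0.10)
  # OLS must fit the linearized data at least as well as a brute-force grid
  oracle <- grid_fit_oracle(tab$dose_uM, tab$fa)
  y <- log10(tab$fa / (1 - tab$fa))
  x <- log10(tab$dose_uM)
  sse_fit <- sum((y - fit$m * (x - log10(fit$Dm)))^2)
  expect_lte(sse_fit, oracle$sse + 1e-12)
  expect_lt(abs(oracle$m - fit$m), 0.05)
})

test_that("dose_for_effect matches hand-computed values and monotonicity", {
  expect_equal(dose_for_effect(median_effect_fit(3.7, 5), 0.5), 5)
  expect_equal(dose_for_effect(median_effect_fit(2, 4), 0.8), 8)
  expect_equal(dose_for_effect(median_effect_fit(1, 22), 0.9), 198)
  fa <- seq(0.05, 0.95, by = 0.05)
  dx <- dose_for_effect(median_effect_fit(1.4, 7), fa)
  expect_true(all(diff(dx) > 0))
})

test_that("effect_at_dose evaluates the law and inverts dose_for_effect", {
  fit <- median_effect_fit(1, 5)
  expect_equal(effect_at_dose(fit, 5), 0.5)
  expect_equal(effect_at_dose(fit, 20), 0.8)
  expect_lt(effect_at_dose(fit, 1e-9), 1e-6)  # fa -> 0 as dose -> 0+
  # round trip at many levels and parameter sets
  for (p in list(c(0.5, 1), c(2, 4), c(3.3, 50))) {
    f <- median_effect_fit(p[1], p[2])
    fa <- c(0.01, 0.25, 0.5, 0.75, 0.99)
    expect_equal(effect_at_dose(f, dose_for_effect(f, fa)), fa,
                 tolerance = 1e-9)
  }
})

test_that("fit is equivariant under a change of dose unit", {
  pts <- exact_points(1.8, 6, doses = c(1, 2, 5, 10, 30))
  fa_noisy <- pmin(pmax(pts$fa * exp(rnorm(5, 0, 0.01)), 1e-6), 1 - 1e-6)
  f1 <- fit_median_effect(pts$dose, fa_noisy)
  f2 <- fit_median_effect(pts$dose * 1000, fa_noisy)  # uM -> nM
  expect_equal(f2$m, f1$m, tolerance = 1e-9)
  expect_equal(f2$r, f1$r, tolerance = 1e-9)
  expect_equal(f2$Dm, f1$Dm * 1000, tolerance = 1e-9)
})

test_that("out-of-range fa points are excluded with warning, or clamped", {
  dose <- c(1, 2, 5, 10, 20)
  fa <- c(-0.1, 0.2, 0.5, 0.8, 1.0)
  expect_warning(fit <- fit_median_effect(dose, fa), "excluded")
  expect_equal(fit$n_points, 3)
  expect_equal(fit$n_excluded, 2)
  expect_silent(fit_c <- fit_median_effect(dose, fa, clamp = TRUE))
  expect_equal(fit_c$n_points, 5)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(suppressWarnings(fit_median_effect(c(1, 2), c(1.2, 1.1))),
               "at least 2 usable")
  expect_error(fit_median_effect(c(3, 3, 3), c(0.2, 0.5, 0.8)), "singular")
  expect_error(fit_median_effect(c(1, 10), c(0.5, 0.5)), "non-identifiable")
  expect_error(fit_median_effect(c(-1, 2), c(0.2, 0.5)), "positive")
  expect_error(dose_for_effect(median_effect_fit(1, 5), 1), "strictly inside")
  expect_error(dose_for_effect(median_effect_fit(1, 5), 0), "strictly inside")
  expect_error(effect_at_dose(median_effect_fit(1, 5), 0), "positive")
})
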
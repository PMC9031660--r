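test_that("combination_design derives weights from basis doses", {
  d <- combination_design(c("cisplatin", "paclitaxel"), basis = c(22, 0.38))
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_equal(unname(d$weights[1] / d$weights[2]), 22 / 0.38)
  expect_error(combination_design("one"), "at least 2")
  expect_error(combination_design(c("a", "b"), weights = c(0.6, 0.5)),
               "sum to 1")
  expect_error(combination_design(c("a", "b"), weights = c(1.2, -0.2)),
               "strictly positive")
})

test_that("component doses split the mixture dose by the ratio weights", {
  fit <- median_effect_fit(2, 10)  # Dx(0.5) = 10
  d1 <- component_doses(combination_design(c("a", "b"),
                                           weights = c(0.5, 0.5)), fit, 0.5)
  expect_equal(unname(d1), c(5, 5))
  d2 <- component_doses(combination_design(c("a", "b"),
                                           weights = c(0.9, 0.1)),
                        median_effect_fit(1, 20), 0.5)
  expect_equal(unname(d2), c(18, 2))
  # three drugs: components always sum to the total mixture dose
  des3 <- combination_design(c("a", "b", "c"),
                             weights = c(0.98, 0.017, 0.003))
  for (fa in c(0.3, 0.5, 0.9)) {
    d3 <- component_doses(des3, fit, fa)
    expect_equal(sum(d3), dose_for_effect(fit, fa), tolerance = 1e-12)
  }
})

test_that("CI equals the reciprocal DRI sum on every computed row", {
  fits <- list(a = median_effect_fit(2, 10), b = median_effect_fit(1.3, 0.5))
  for (fa in c(0.2, 0.5, 0.75, 0.9)) {
    doses <- c(a = 1.7, b = 0.21)
    ci <- combination_index(doses, fits, fa)
    dri <- dose_reduction_index(doses, fits, fa)
    expect_equal(ci, sum(1 / dri), tolerance = 1e-12)
    expect_equal(ci, ci_from_dri(dri), tolerance = 1e-15)
  }
})

test_that("sham self-combination gives CI = 1 at every effect level", {
  fit <- median_effect_fit(1.7, 8)
  fits <- list(half1 = fit, half2 = fit)
  for (fa in seq(0.1, 0.9, by = 0.1)) {
    dx <- dose_for_effect(fit, fa)
    ci <- combination_index(c(half1 = dx / 2, half2 = dx / 2), fits, fa)
    expect_equal(ci, 1, tolerance = 1e-12)
  }
})

test_that("each component at its own single-agent dose has DRI = 1", {
  fits <- list(a = median_effect_fit(2, 10), b = median_effect_fit(1, 3))
  dx <- c(a = dose_for_effect(fits$a, 0.75), b = dose_for_effect(fits$b, 0.75))
  dri <- dose_reduction_index(dx, fits, 0.75)
  expect_equal(unname(dri), c(1, 1), tolerance = 1e-12)
})

test_that("CI is invariant to a global rescaling of dose units", {
  fits <- list(a = median_effect_fit(2, 10), b = median_effect_fit(1.3, 0.5))
  doses <- c(a = 1.7, b = 0.21)
  k <- 1000
  fits_k <- list(a = median_effect_fit(2, 10 * k),
                 b = median_effect_fit(1.3, 0.5 * k))
  expect_equal(combination_index(doses * k, fits_k, 0.6),
               combination_index(doses, fits, 0.6), tolerance = 1e-12)
})

test_that("reduced_dose reproduces the published reduced concentrations", {
  expect_equal(round(reduced_dose(22, 51.06), 1), 0.4)
  expect_equal(round(reduced_dose(0.38, 11.89), 2), 0.03)
  expect_equal(reduced_dose(7, 1), 7)
  expect_error(reduced_dose(5, 0), "positive")
})

test_that("classify_ci thresholds strictly at 1, with optional band", {
  expect_equal(classify_ci(c(0.104, 1, 3.170)),
               c("synergism", "additive", "antagonism"))
  expect_equal(classify_ci(0.97, band = 0.05), "additive")
  expect_equal(classify_ci(0.97), "synergism")
  expect_error(classify_ci(-1), "positive")
})

test_that("fa_ci_curve recovers a constant true CI from the construction", {
  # equal slopes: the constant-ratio mixture then follows the composite
  # median-effect law exactly and the noiseless construction is invertible
  truths <- list(drug_truth("a", 2, 10, 0), drug_truth("b", 2, 0.5, 0))
  fits <- list(a = median_effect_fit(2, 10), b = median_effect_fit(2, 0.5))
  design <- combination_design(c("a", "b"), basis = c(10, 0.5))
  plate <- simulate_combination(truths, combo_truth(design, 0.5),
                                noise_sd = 0, seed = 7)
  tab <- fa_table(plate)
  combo_fit <- fit_median_effect(tab$dose_uM, tab$fa)
  curve <- fa_ci_curve(design, combo_fit, fits, fa_grid = c(0.5, 0.75, 0.9))
  expect_equal(curve$ci, rep(0.5, 3), tolerance = 1e-6)
  expect_true(all(curve$classification == "synergism"))
  expect_true(all(curve[, c("dri_a", "dri_b")] > 1))
  # row-wise identity
  expect_equal(curve$ci, 1 / curve$dri_a + 1 / curve$dri_b,
               tolerance = 1e-12)
})

test_that("a rising CI profile is recovered within fitting noise", {
  truths <- list(drug_truth("a", 2, 10, 0), drug_truth("b", 2, 0.5, 0))
  fits <- list(a = median_effect_fit(2, 10), b = median_effect_fit(2, 0.5))
  design <- combination_design(c("a", "b"), basis = c(10, 0.5))
  profile <- function(fa) 0.3 + 0.75 * (fa - 0.5)  # 0.3 at fa=.5, 0.6 at .9
  gen_grid <- seq(0.5, 0.9, by = 0.05)
  plate <- simulate_combination(truths, combo_truth(design, profile),
                                fa_grid = gen_grid,
                                noise_sd = 0.01, seed = 11)
  tab <- fa_table(plate)
  ok <- tab$fa > 0 & tab$fa < 1
  # an fa-varying interaction calls for the pointwise CI estimate
  pw <- ci_at_observations(design, tab$dose_uM[ok], tab$fa[ok], fits)
  expect_lt(max(abs(pw$ci - profile(gen_grid[ok]))), 0.05)
})

test_that("missing or mismatched single-drug fits raise configuration errors", {
  fits <- list(a = median_effect_fit(2, 10))
  expect_error(combination_index(c(a = 1, b = 2), fits, 0.5),
               "one single-drug fit per")
  expect_error(
    combination_index(c(a = 1, b = 2),
                      list(a = median_effect_fit(2, 10), c = median_effect_fit(1, 1)),
                      0.5),
    "no single-drug fit")
})
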
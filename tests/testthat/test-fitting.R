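test_that("linear fit recovers the gradient of exact and generated lines", {
  s <- seq(0, 0.3, by = 0.02)
  ft <- fit_material(stress_strain_curve(s, 2.0 * s), "linear")
  expect_equal(unname(coef(ft)["youngs_modulus"]), 2.0)
  expect_equal(unname(coef(ft)["poisson_ratio"]), 0.45)
  # noiseless generated curve from a linear truth: exact self-consistency
  truth <- ground_truth(elastic_material(3, 0.45), thickness_sd = 0, seed = 5)
  sp <- generate_cohort(1, "model", truth)
  cv <- generate_ramp_curve(sp[1, ], truth)
  ft2 <- fit_material(cv, "linear")
  expect_equal(unname(coef(ft2)["youngs_modulus"]), 3, tolerance = 1e-10)
})

test_that("linear fit on a nonlinear curve equals the least-squares secant slope", {
  og <- ogden_material(OG_MU, OG_AL)
  s <- seq(0, 0.35, by = 0.01)
  p <- -uniaxial_nominal_stress(og, 1 - s)
  ft <- fit_material(stress_strain_curve(s, p), "linear")
  expect_equal(unname(coef(ft)["youngs_modulus"]), sum(p * s) / sum(s^2),
               tolerance = 1e-8)
})

test_that("Neo-Hookean fit recovers the generating constant", {
  nh <- neo_hookean_material(5.0)
  s <- seq(0, 0.3, by = 0.01)
  cv <- stress_strain_curve(s, -uniaxial_nominal_stress(nh, 1 - s))
  ft <- fit_material(cv, "neo_hookean")
  expect_equal(unname(coef(ft)["c10"]), 5.0, tolerance = 1e-4)
  expect_error(fit_material(stress_strain_curve(s, rep(0, length(s))),
                            "neo_hookean"), "no stress signal")
})

test_that("Neo-Hookean recovery tolerates 2% stress noise across replicates", {
  nh <- neo_hookean_material(5.0)
  s <- seq(0, 0.3, by = 0.01)
  p0 <- -uniaxial_nominal_stress(nh, 1 - s)
  set.seed(99)
  for (rep in 1:20) {
    p <- p0 * (1 + stats::rnorm(length(p0), 0, 0.02))
    ft <- fit_material(stress_strain_curve(s, p), "neo_hookean")
    expect_lt(abs(coef(ft)["c10"] - 5.0) / 5.0, 0.05)
  }
})

test_that("Ogden fit recovers the reference material in stress space", {
  og <- ogden_material(OG_MU, OG_AL)
  s <- seq(0, 0.35, length.out = 30)
  cv <- stress_strain_curve(s, -uniaxial_nominal_stress(og, 1 - s))
  ft <- fit_material(cv, "ogden3", seed = 11, n_starts = 32)
  expect_lte(sqrt(mean(residuals(ft)^2)), 1e-3)
  expect_identical(ft$diagnostics$starts, 32L)
  expect_gt(ft$diagnostics$converged, 0)
})

test_that("Ogden fit nests the Neo-Hookean response", {
  nh <- neo_hookean_material(4.89)
  s <- seq(0, 0.3, length.out = 25)
  cv <- stress_strain_curve(s, -uniaxial_nominal_stress(nh, 1 - s))
  ft <- fit_material(cv, "ogden3", seed = 21, n_starts = 24)
  expect_lte(sqrt(mean(residuals(ft)^2)), 1e-3)
})

test_that("Ogden fit objective never increases with more starts", {
  og <- ogden_material(OG_MU, OG_AL)
  s <- seq(0, 0.3, length.out = 20)
  cv <- stress_strain_curve(s, -uniaxial_nominal_stress(og, 1 - s))
  f8 <- fit_material(cv, "ogden3", seed = 4, n_starts = 8)
  f16 <- fit_material(cv, "ogden3", seed = 4, n_starts = 16)
  expect_lte(f16$objective, f8$objective + 1e-12)
})

test_that("Ogden fit requires enough samples and strain span", {
  s <- seq(0, 0.05, length.out = 20)
  cv <- stress_strain_curve(s, 2 * s + 0.01 * s^2)
  expect_error(fit_material(cv, "ogden3"), "10% strain")
  cv2 <- stress_strain_curve(c(0, 0.2), c(0, 0.4))
  expect_error(fit_material(cv2, "ogden3"), ">= 8 samples")
})

test_that("stability flag is consistent with the Drucker screen", {
  bad <- unstable_ogden()
  s <- seq(0, 0.32, length.out = 25)       # reaches the unstable regime
  cv <- stress_strain_curve(s, pmax(-uniaxial_nominal_stress(bad, 1 - s), 1e-6))
  ft <- fit_material(cv, "ogden3", seed = 31, n_starts = 16)
  expect_identical(ft$stable,
                   nrow(drucker_stability(ft$model, range(1 - s),
                                          n_scan = 400)) == 0L)
  # a fit to a globally stable law is reported stable
  nh <- neo_hookean_material(5)
  cv2 <- stress_strain_curve(s, -uniaxial_nominal_stress(nh, 1 - s))
  expect_true(fit_material(cv2, "neo_hookean")$stable)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  s <- seq(0, 0.3, by = 0.02)
  cv <- stress_strain_curve(s, 2.5 * s, specimen_id = "demo")
  ft <- fit_material(cv, "linear")
  expect_equal(predict(ft), 2.5 * s, tolerance = 1e-12)
  expect_equal(predict(ft, newdata = c(0.1, 0.2)), c(0.25, 0.5))
  expect_equal(unname(residuals(ft)), rep(0, length(s)), tolerance = 1e-12)
  expect_output(print(ft), "material fit")
  expect_output(summary(ft), "specimen demo")
})

test_that("curve files in both supported layouts are read back", {
  f <- tempfile(fileext = ".tsv")
  s <- seq(0, 0.3, by = 0.05)
  utils::write.table(data.frame(strain = s, stress_MPa = 2 * s), f,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cv <- read_stress_strain(f)
  expect_s3_class(cv, "stress_strain_curve")
  expect_equal(cv$stress, 2 * s)
  # raw force-displacement log with geometry conversion
  utils::write.table(data.frame(time_s = s * 10, force_N = 61.6 * s / 0.3,
                                displacement_um = 1305 * s), f,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cv2 <- read_stress_strain(f, diameter = 8, thickness = 1.305)
  expect_equal(max(cv2$stress), 61.6 / (pi * 16))
  expect_equal(max(cv2$strain), 0.3)
  unlink(f)
})
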
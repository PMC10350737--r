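test_that("solve_stretch recovers the applied pressure (round trip)", {
  models <- list(elastic_material(2.5, 0.45), neo_hookean_material(4.48),
                 ogden_material(OG_MU, OG_AL))
  for (m in models) for (mode in c("uniaxial_free", "lateral_locked")) {
    expect_identical(solve_stretch(m, 0, mode), 1)
    for (p in c(0.1, 0.75, 1.225, 1.7)) {
      lam <- solve_stretch(m, p, mode)
      expect_lt(lam, 1)
      expect_lt(abs(nominal_stress(m, lam, mode) + p), 1e-9)
    }
  }
})

test_that("elastic small-pressure limit is lambda = 1 - p/E", {
  el <- elastic_material(3, 0.45)
  expect_equal(solve_stretch(el, 0.003, "uniaxial_free"), 1 - 0.003 / 3,
               tolerance = 1e-9)
})

test_that("Ogden stretch under mean pressure matches the bisection oracle", {
  og <- ogden_material(OG_MU, OG_AL)
  # frozen from a 200-step bisection on the independent stress function
  expect_equal(solve_stretch(og, 1.225, "uniaxial_free"), 0.636197907286,
               tolerance = 1e-9)
  expect_equal(displacement_under(og, 1.225, 1.305, "uniaxial_free"),
               474.761730992, tolerance = 1e-6)
})

test_that("displacement is exactly linear in thickness and zero at rest", {
  og <- ogden_material(OG_MU, OG_AL)
  expect_identical(displacement_under(og, 0, 1.305), 0)
  d1 <- displacement_under(og, 1.0, 1.0)
  expect_equal(displacement_under(og, 1.0, 2.0), 2 * d1)
  expect_error(displacement_under(og, 1.0, -1), "positive")
})

test_that("displacement increases monotonically with pressure", {
  for (m in list(neo_hookean_material(5.13), ogden_material(OG_MU, OG_AL))) {
    d <- vapply(seq(0.1, 1.7, by = 0.2), function(p)
      displacement_under(m, p, 1.305), numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("lateral lock stiffens: locked displacement <= free displacement", {
  for (m in list(elastic_material(2.5, 0.45), neo_hookean_material(4.89),
                 ogden_material(OG_MU, OG_AL))) {
    for (p in c(0.3, 1.225, 1.7)) {
      expect_lte(displacement_under(m, p, 1.305, "lateral_locked"),
                 displacement_under(m, p, 1.305, "uniaxial_free"))
    }
  }
})

test_that("protocol simulation of a linear material is proportional to load", {
  el <- elastic_material(2.5, 0.45)
  pr <- loading_protocol()
  tr <- simulate_protocol(el, pr, 1.305, "lateral_locked")
  ratio <- tr$displacement_um[-1] / tr$pressure_MPa[-1]
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
  # end-of-ramp displacement equals the single-pressure solution
  expect_equal(ramp_compression(tr),
               displacement_under(el, pr$p_mean, 1.305, "lateral_locked"),
               tolerance = 1e-9)
  # cyclic peak-to-peak equals thickness * dp_pp / E_eff (closed form)
  E_eff <- 2.5 / (1 - 0.45^2)
  expect_equal(dynamic_amplitude(tr), 1.305 * 1000 * 2 * pr$amplitude / E_eff,
               tolerance = 1e-9)
})

test_that("trace invariants hold and delimited-text IO round-trips", {
  og <- ogden_material(OG_MU, OG_AL)
  tr <- simulate_protocol(og, loading_protocol(sample_interval = 0.02), 1.305)
  expect_identical(tr$displacement_um[1], 0)
  expect_true(all(diff(tr$time_s) > 0))
  expect_identical(unique(tr$step), c("ramp", "cyclic"))
  f <- tempfile(fileext = ".tsv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_equal(tr2$displacement_um, tr$displacement_um, tolerance = 1e-9)
  unlink(f)
  expect_error(solution_trace(c(0, 0), c(0, 1), c(0, 1), c("ramp", "ramp")),
               "increasing")
})

test_that("destabilising materials raise a classed stability failure", {
  bad <- unstable_ogden()
  err <- tryCatch(solve_stretch(bad, 1.225, "uniaxial_free"), error = identity)
  expect_s3_class(err, "cartdyn_stability_error")
  expect_gt(err$last_stable_stretch, 0.6)
  expect_lt(err$last_stable_stretch, 0.95)
  expect_lt(err$max_pressure, 1.225)
  # the protocol simulation reports the time of failure
  err2 <- tryCatch(simulate_protocol(bad, loading_protocol(), 1.305),
                   error = identity)
  expect_s3_class(err2, "cartdyn_stability_error")
  expect_gt(err2$time_s, 0)
  expect_match(conditionMessage(err2), "t = ")
})
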
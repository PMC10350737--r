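test_that("energy and stress vanish exactly at the identity for every model", {
  models <- list(elastic_material(2.9, 0.45),
                 neo_hookean_material(4.89),
                 neo_hookean_material(4.89, "paper_eq2"),
                 ogden_material(OG_MU, OG_AL))
  for (m in models) {
    expect_identical(strain_energy(m, c(1, 1, 1)), 0)
    expect_identical(uniaxial_nominal_stress(m, 1), 0)
    expect_identical(constrained_nominal_stress(m, 1), 0)
  }
})

test_that("initial shear moduli follow the small-strain limits", {
  expect_equal(initial_shear_modulus(elastic_material(2.9, 0.45)), 1)
  expect_equal(initial_shear_modulus(neo_hookean_material(4.89, "paper_eq2")), 4.89)
  expect_equal(initial_shear_modulus(neo_hookean_material(4.89)), 2 * 4.89)
  expect_equal(initial_shear_modulus(ogden_material(OG_MU, OG_AL)), sum(OG_MU))
})

test_that("Ogden energy matches the independent term-by-term oracle", {
  og <- ogden_material(OG_MU, OG_AL)
  lam <- c(0.8, 0.8^-0.5, 0.8^-0.5)
  # value frozen from the independent summation before implementation
  expect_equal(strain_energy(og, lam), 0.00750565388368, tolerance = 1e-10)
  expect_equal(strain_energy(og, lam), og_energy_indep(0.8, 0.8^-0.5, 0.8^-0.5))
})

test_that("uniaxial stresses match finite differences of the energy path", {
  og <- ogden_material(OG_MU, OG_AL)
  # frozen finite-difference oracle value at deep compression
  expect_equal(uniaxial_nominal_stress(og, 0.65), -1.05574410614,
               tolerance = 1e-7)
  expect_gt(uniaxial_nominal_stress(og, 0.65), -1.1)
  expect_lt(uniaxial_nominal_stress(og, 0.65), -1.0)
  nh <- neo_hookean_material(4.89)
  mu0 <- initial_shear_modulus(nh)
  expect_equal(uniaxial_nominal_stress(nh, 0.99), 3 * mu0 * (0.99 - 1),
               tolerance = 0.02)
})

test_that("analytic stresses agree with energy finite differences to 1e-6", {
  models <- list(neo_hookean_material(4.89), ogden_material(OG_MU, OG_AL))
  for (m in models) {
    for (lam in seq(0.5, 1.5, by = 0.1)) {
      if (abs(lam - 1) < 1e-9) next
      W_uni <- function(l) strain_energy(m, c(l, l^-0.5, l^-0.5))
      W_lock <- function(l) strain_energy(m, c(1, l, 1 / l))
      expect_equal(uniaxial_nominal_stress(m, lam), fd_path_stress(W_uni, lam),
                   tolerance = 1e-6)
      expect_equal(constrained_nominal_stress(m, lam), fd_path_stress(W_lock, lam),
                   tolerance = 1e-6)
    }
  }
})

test_that("small-strain tangents equal 3 mu0 (free) and 4 mu0 (locked)", {
  h <- 1e-7
  for (m in list(neo_hookean_material(5.13), ogden_material(OG_MU, OG_AL))) {
    mu0 <- initial_shear_modulus(m)
    t_free <- (uniaxial_nominal_stress(m, 1 + h) -
                 uniaxial_nominal_stress(m, 1 - h)) / (2 * h)
    t_lock <- (constrained_nominal_stress(m, 1 + h) -
                 constrained_nominal_stress(m, 1 - h)) / (2 * h)
    expect_equal(t_free, 3 * mu0, tolerance = 1e-6)
    expect_equal(t_lock, 4 * mu0, tolerance = 1e-6)
  }
  el <- elastic_material(2.9, 0.45)
  expect_equal(nominal_stress(el, 0.95, "lateral_locked"),
               2.9 / (1 - 0.45^2) * (0.95 - 1))
  expect_equal(nominal_stress(el, 0.95, "uniaxial_free"), 2.9 * (0.95 - 1))
})

test_that("Neo-Hookean conventions differ by exactly a factor two", {
  std <- neo_hookean_material(4.89, "standard_c10")
  eq2 <- neo_hookean_material(4.89, "paper_eq2")
  lam <- seq(0.6, 1.4, by = 0.05)
  expect_equal(uniaxial_nominal_stress(std, lam),
               2 * uniaxial_nominal_stress(eq2, lam))
  expect_equal(constrained_nominal_stress(std, lam),
               2 * constrained_nominal_stress(eq2, lam))
})

test_that("invalid inputs raise domain errors", {
  og <- ogden_material(OG_MU, OG_AL)
  expect_error(strain_energy(og, c(-0.5, 1, 1)), "positive")
  expect_error(uniaxial_nominal_stress(og, 0), "positive")
  expect_error(elastic_material(-1), "positive")
  expect_error(elastic_material(1, 0.5), "between 0 and 0.5")
  expect_error(neo_hookean_material(0), "positive")
  expect_error(ogden_material(c(1, 2), c(0, 1)), "nonzero")
  expect_error(ogden_material(1, c(1, 2)), "equal length")
})

test_that("Drucker screening: positive-moduli laws are globally stable", {
  expect_identical(nrow(drucker_stability(neo_hookean_material(4.89),
                                          c(0.5, 1.5))), 0L)
  expect_identical(nrow(drucker_stability(elastic_material(3), c(0.5, 1.5))), 0L)
})

test_that("Drucker screening localises the instability of a mixed-sign set", {
  bad <- unstable_ogden()
  v <- drucker_stability(bad, c(0.5, 1.0), n_scan = 600)
  expect_gt(nrow(v), 0)
  expect_lt(max(v$lam_to), 0.97)              # violation confined to compression
  expect_true(all(v$min_eigenvalue <= 0))
  near_id <- drucker_stability(bad, c(0.97, 1.03), n_scan = 200)
  expect_identical(nrow(near_id), 0L)
  # deterministic for a fixed scan grid
  expect_identical(v, drucker_stability(bad, c(0.5, 1.0), n_scan = 600))
})

test_that("material config serialisation round-trips", {
  for (m in list(elastic_material(2.2, 0.45), neo_hookean_material(5.48),
                 ogden_material(OG_MU, OG_AL))) {
    m2 <- material_from_config(material_to_config(m))
    expect_equal(uniaxial_nominal_stress(m2, 0.9), uniaxial_nominal_stress(m, 0.9))
  }
  expect_error(material_from_config(list(type = "mystery")), "unknown")
})
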
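test_that("mesh generation reproduces the reference element counts", {
  m50 <- build_mesh(8, 1.305, 50)
  m100 <- build_mesh(8, 1.305, 100)
  m200 <- build_mesh(8, 1.305, 200)
  expect_identical(m50$n_x * m50$n_y, 4160L)
  expect_identical(m100$n_x * m100$n_y, 1040L)
  expect_identical(m200$n_x * m200$n_y, 280L)
  expect_identical(nrow(m200$nodes), (m200$n_x + 1L) * (m200$n_y + 1L))
  # top-centre node sits mid-width on the top surface
  expect_equal(unname(m100$nodes[m100$top_centre_node, ]), c(4, 1.305))
  expect_error(build_mesh(8, 1.305, 5000), "zero elements")
})

test_that("near-zero pressure produces near-zero displacement", {
  pr <- loading_protocol(p_mean = 1e-12, amplitude = 0,
                         sample_interval = 0.05)
  sol <- fe_simulate(elastic_material(2.5, 0.45), build_mesh(2, 1, 500), pr)
  expect_lt(max(abs(sol$trace$displacement_um)), 1e-6)
})

test_that("linear elastic response is exactly proportional to the load", {
  mesh <- build_mesh(4, 1.305, 500)
  full <- fe_simulate(elastic_material(2.5, 0.45), mesh, loading_protocol())
  half <- fe_simulate(elastic_material(2.5, 0.45), mesh,
                      loading_protocol(p_mean = 1.225 / 2, amplitude = 0.475 / 2))
  expect_equal(half$trace$displacement_um, full$trace$displacement_um / 2,
               tolerance = 1e-12)
})

test_that("patch test: homogeneous compression matches the material-point solution", {
  # 2x2-element patch with frictionless (lateral-free) boundary conditions
  mesh <- build_mesh(0.4, 0.4, 200)
  expect_identical(mesh$n_x * mesh$n_y, 4L)
  pr <- loading_protocol(sample_interval = 0.05)
  for (integ in c("full", "reduced")) {
    sol <- fe_simulate(neo_hookean_material(4.89), mesh, pr,
                       bc = "frictionless", steps = "ramp",
                       options = fe_options(n_incr_ramp = 5, integration = integ))
    lam_fe <- 1 - ramp_compression(sol$trace) / 1000 / mesh$height
    lam_pt <- nh_penalty_uniaxial_indep(4.89, 1.225)
    expect_equal(lam_fe, lam_pt, tolerance = 1e-8)
  }
})

test_that("frictionless FE agrees with the uniaxial closed form to 0.5%", {
  mesh <- build_mesh(2, 0.6, 200)
  sol <- fe_simulate(neo_hookean_material(4.89), mesh,
                     loading_protocol(), bc = "frictionless", steps = "ramp",
                     options = fe_options(n_incr_ramp = 8))
  d_fe <- ramp_compression(sol$trace)
  d_or <- displacement_under(neo_hookean_material(4.89), 1.225, 0.6,
                             "uniaxial_free")
  expect_lt(abs(d_fe - d_or) / d_or, 0.005)
})

test_that("platen FE lies between the two homogeneous deformation modes", {
  nh <- neo_hookean_material(4.89)
  sol <- fe_simulate(nh, build_mesh(8, 1.305, 400), loading_protocol(),
                     bc = "platen", steps = "ramp",
                     options = fe_options(n_incr_ramp = 8))
  d_fe <- ramp_compression(sol$trace)
  d_lock <- displacement_under(nh, 1.225, 1.305, "lateral_locked")
  d_free <- displacement_under(nh, 1.225, 1.305, "uniaxial_free")
  expect_gte(d_fe, d_lock - 1e-6)
  expect_lte(d_fe, d_free)
})

test_that("base reactions balance the applied pressure at every increment", {
  sol <- fe_simulate(neo_hookean_material(5.48), build_mesh(8, 1.305, 400),
                     loading_protocol(), bc = "platen",
                     options = fe_options(n_incr_ramp = 6, n_incr_cyclic = 8))
  d <- sol$diagnostics
  applied <- pressure_at(d$time_s, loading_protocol()) * 8
  expect_lt(max(abs(d$reaction_sum - applied) / applied), 1e-6)
})

test_that("rigid translation of the mesh leaves the solution unchanged", {
  mesh <- build_mesh(2, 0.6, 300)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes + matrix(rep(c(11.3, -4.2), each = nrow(mesh$nodes)),
                                     ncol = 2)
  pr <- loading_protocol(sample_interval = 0.05)
  o <- fe_options(n_incr_ramp = 5, n_incr_cyclic = 8)
  s1 <- fe_simulate(neo_hookean_material(4.48), mesh, pr, options = o)
  s2 <- fe_simulate(neo_hookean_material(4.48), mesh2, pr, options = o)
  expect_equal(s1$trace$displacement_um, s2$trace$displacement_um,
               tolerance = 1e-10)
})

test_that("mesh convergence table reports counts and successive changes", {
  el <- elastic_material(2.5, 0.45)
  tab <- mesh_convergence(el, loading_protocol(), c(400, 200, 100))
  expect_identical(tab$n_elements, c(60L, 280L, 1040L))
  expect_true(is.na(tab$rel_change[1]))
  expect_lt(tab$rel_change[3], 0.01)
  one <- mesh_convergence(el, loading_protocol(), 400)
  expect_identical(nrow(one), 1L)
  expect_true(is.na(one$rel_change))
})

test_that("element quality flags skewed corners and high aspect ratios", {
  mesh <- build_mesh(1, 1, 500)            # 2x2 square elements
  expect_identical(nrow(check_element_quality(mesh)), 0L)
  # collapse one corner of element 1 towards its diagonal: angle below 10 deg
  U <- matrix(0, nrow(mesh$nodes), 2)
  U[1, ] <- c(0.49, 0.49)
  q <- check_element_quality(mesh, U)
  expect_true("skewness" %in% q$type)
  # stretch the top row of nodes far sideways: aspect ratio above 10
  U2 <- matrix(0, nrow(mesh$nodes), 2)
  U2[mesh$top_nodes, 1] <- c(0, 5.5, 11)
  q2 <- check_element_quality(mesh, U2)
  expect_true("aspect_ratio" %in% q2$type)
})

test_that("legacy VTK export writes a well-formed unstructured grid", {
  mesh <- build_mesh(1, 1, 500)
  f <- tempfile(fileext = ".vtk")
  write_vtk(mesh, f, U = matrix(0.1, nrow(mesh$nodes), 2))
  lines <- readLines(f)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 9 double", lines)))
  expect_true(any(grepl("^CELLS 4 20", lines)))
  expect_true(any(grepl("^VECTORS displacement", lines)))
  unlink(f)
})
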
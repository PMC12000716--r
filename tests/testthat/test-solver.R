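test_that("closed-form oracles: frozen value, positivity, asymptotic slope", {
  expect_equal(semi_infinite_fluence(2, 0.1, 10), 0.004428510059,
               tolerance = 1e-9)
  rho <- seq(0.5, 8, 0.5)
  phi <- semi_infinite_fluence(rho, 0.1, 10)
  expect_true(all(phi > 0))
  # d ln(rho^2 phi)/d rho -> -mueff in the far field
  mueff <- sqrt(0.1 * 3 * 10.1)
  slope <- diff(log(rho^2 * phi)) / diff(rho)
  expect_equal(slope[length(slope)], -mueff, tolerance = 0.01)
  # exact Robin half-space agrees with the dipole in the far field
  expect_equal(robin_halfspace_fluence(6, 0.1, 10),
               semi_infinite_fluence(6, 0.1, 10), tolerance = 0.03)
})

test_that("layered oracle reduces to the homogeneous one", {
  one <- layered_halfspace_fluence(c(1, 3), c(0.1, 0.1), c(10, 10), 1.5)
  hom <- robin_halfspace_fluence(c(1, 3), 0.1, 10)
  expect_equal(one, hom, tolerance = 1e-4)
})

test_that("FE solution matches the exact Robin half-space on a padded block", {
  f <- small_block_solve(0.1, 10)
  lay <- place_sensor(f$mesh, "horizontal", sdds = 1:4, source = c(0, 0, 0))
  ro <- read_detectors(f, lay)
  exact <- robin_halfspace_fluence(ro$sdd, 0.1, 10)
  expect_equal(ro$fluence, exact, tolerance = 0.05)
  expect_true(all(diff(ro$fluence) < 0))
})

test_that("FE solution matches the exact two-layer solution", {
  mesh <- fixture("block2l", {
    g <- tet_grid(
      graded_axis(-6, 10, -1, 5, 0.25, features = c(0, 1:4)),
      graded_axis(-6, 6, -1.4, 1.4, 0.25, features = 0),
      depth_axis(7, 0.25, z_fine = c(1 / 20), fine_to = 3,
                 h0 = 1 / 20))
    cent_z <- (g$nodes[g$elems[, 1], 3] + g$nodes[g$elems[, 2], 3] +
                 g$nodes[g$elems[, 3], 3] + g$nodes[g$elems[, 4], 3]) / 4
    labeled_mesh(g$nodes, g$elems, ifelse(cent_z < 1.2, 1L, 2L),
                 c("adipose", "intestine"))
  })
  props <- optical_props(c("adipose", "intestine"), c(0.05, 0.21), c(20, 5))
  f <- solve_fluence(mesh, props, c(0, 0, 0))
  lay <- place_sensor(mesh, "horizontal", sdds = 1:4, source = c(0, 0, 0))
  ro <- read_detectors(f, lay)
  exact <- layered_halfspace_fluence(ro$sdd, c(0.05, 0.21), c(20, 5), 1.2)
  expect_equal(ro$fluence, exact, tolerance = 0.05)
})

test_that("source handling: zero power, linearity, burial depth", {
  mesh <- small_block(10)
  props <- optical_props("medium", 0.1, 10)
  src0 <- point_source(mesh, props, c(0, 0, 0), S0 = 0)
  f0 <- solve_fluence(mesh, props, src0)
  expect_equal(f0$values, rep(0, nrow(mesh$nodes)))
  src2 <- point_source(mesh, props, c(0, 0, 0), S0 = 2)
  f1 <- small_block_solve(0.1, 10)
  f2 <- solve_fluence(mesh, props, src2)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
  expect_equal(src2$r_s, c(0, 0, 0.1), tolerance = 1e-9)
  expect_equal(src2$tissue, "medium")
})

test_that("discrete reciprocity: swapping source and detector nodes", {
  mesh <- small_block(10)
  props <- optical_props("medium", 0.1, 10)
  fA <- solve_fluence(mesh, props, c(0, 0, 0))
  fB <- solve_fluence(mesh, props, c(3, 0, 0))
  phi_AB <- interp_field(fA, matrix(c(3, 0, 0), 1))
  phi_BA <- interp_field(fB, matrix(c(0, 0, 0), 1))
  expect_equal(phi_AB, phi_BA, tolerance = 0.03)
})

test_that("maximum principle: raising absorption never raises a readout", {
  mesh <- small_block(10)
  lay <- place_sensor(mesh, "horizontal", sdds = 1:4, source = c(0, 0, 0))
  ro1 <- read_detectors(small_block_solve(0.1, 10), lay)
  f2 <- fixture("bsolve_mup", solve_fluence(
    mesh, optical_props("medium", 0.15, 10), c(0, 0, 0)))
  ro2 <- read_detectors(f2, lay)
  expect_true(all(ro2$fluence <= ro1$fluence))
})

test_that("fluence fields are non-negative and diagnosed", {
  f <- small_block_solve(0.1, 10)
  expect_gte(f$diagnostics$min_value, -1e-12 * f$diagnostics$max_value)
  expect_lt(f$diagnostics$residual, 1e-10)
})

test_that("readout interpolation is exact at nodes and errors off-mesh", {
  f <- small_block_solve(0.1, 10)
  mesh <- f$mesh
  node <- which(mesh$nodes[, 1] == 2 & mesh$nodes[, 2] == 0 &
                  mesh$nodes[, 3] == 0)[1]
  expect_equal(interp_field(f, mesh$nodes[node, , drop = FALSE]),
               f$values[node])
  expect_error(interp_field(f, matrix(c(100, 0, 0), 1)), "outside the mesh")
  lay <- place_sensor(mesh, "horizontal", sdds = seq(0.5, 4, 0.5),
                      source = c(0, 0, 0))
  ro <- read_detectors(f, lay)
  expect_equal(nrow(ro), 8)
  expect_equal(ro$sdd, sort(ro$sdd))
})

test_that("assembly rejects meshes with unlabeled tissues", {
  mesh <- small_block(10)
  expect_error(assemble_diffusion(mesh, default_properties()),
               "no optical properties")
})

test_that("phantom truncation: a 10 cm and a 30 cm tube agree at 1 cm SDD", {
  ro <- lapply(c(10, 30), function(len) {
    mesh <- build_phantom_block(length = len, resolution = 0.3,
                                core = c(len / 2 - 1.5, len / 2 + 2.5))
    src <- mesh$geometry$surface_center
    props <- optical_props("phantom", 0.25, 10)
    f <- solve_fluence(mesh, props, src)
    lay <- place_sensor(mesh, "horizontal", sdds = 1, source = src)
    read_detectors(f, lay)$fluence
  })
  expect_equal(ro[[1]], ro[[2]], tolerance = 0.01)
})
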
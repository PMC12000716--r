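test_that("tensor tet grid tiles the box exactly", {
  g <- tet_grid(c(0, 0.5, 1.2), c(0, 1), c(0, 0.3, 0.7, 1))
  expect_equal(nrow(g$nodes), 3 * 2 * 4)
  v <- tet_volumes(g$nodes, g$elems)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1.2 * 1 * 1, tolerance = 1e-12)
  bf <- boundary_faces(g$elems)
  # closed surface: every boundary edge is shared by exactly two facets
  ed <- rbind(bf$faces[, c(1, 2)], bf$faces[, c(2, 3)], bf$faces[, c(1, 3)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(paste(ed[, 1], ed[, 2]))
  expect_true(all(cnt == 2))
})

test_that("abdomen mesh conserves labeled volume and contains every tissue", {
  mesh <- coarse_abdomen()
  vols <- label_volumes(mesh)
  expect_setequal(names(vols),
                  c("epidermis", "adipose", "intestine", "SMA", "SMV"))
  expect_true(all(vols > 0))
  nd <- mesh$nodes
  domain <- prod(apply(nd, 2, function(x) diff(range(x))))
  expect_equal(sum(vols), domain, tolerance = 1e-3)
  expect_equal(sum(mesh$volumes), domain, tolerance = 1e-12)
})

test_that("shortest skin-to-ellipsoid distance equals the adipose thickness", {
  mesh <- coarse_abdomen()
  ell <- mesh$geometry$ellipsoid
  # analytic support point
  expect_equal(ell$center[3] - ell$support_z, 2.4, tolerance = 1e-10)
  # realized in the mesh: shallowest intestine-labeled cell within one edge
  cent <- (mesh$nodes[mesh$elems[, 1], ] + mesh$nodes[mesh$elems[, 2], ] +
             mesh$nodes[mesh$elems[, 3], ] + mesh$nodes[mesh$elems[, 4], ]) / 4
  zmin <- min(cent[mesh$tissue == match("intestine", mesh$tissue_levels), 3])
  expect_lt(abs(zmin - 2.4), 0.55)
})

test_that("adipose-thickness sweep translates the ellipsoid, axes unchanged", {
  p24 <- abdomen_params(adipose_thickness = 2.4)
  p28 <- abdomen_params(adipose_thickness = 2.8)
  e24 <- intestine_ellipsoid(p24)
  e28 <- intestine_ellipsoid(p28)
  expect_equal(e24$s, e28$s)
  expect_equal(e24$U, e28$U)
  expect_equal(e28$center[3] - e24$center[3], 0.4, tolerance = 1e-12)
  # volume conservation across the sweep (exact for a translation)
  vol <- function(e) 4 / 3 * pi * prod(e$s)
  expect_equal(vol(e24), vol(e28), tolerance = 1e-12)
})

test_that("infeasible geometry is rejected with the violated constraint", {
  expect_error(abdomen_params(adipose_thickness = 0), "positive")
  expect_error(abdomen_params(adipose_thickness = 0.004),
               "adipose_thickness")
  expect_error(build_abdomen(abdomen_params(adipose_thickness = 0.008,
                                            epidermis_thickness = 0.008)),
               "protrudes")
  expect_error(abdomen_params(intestine_thickness = 20), "semi-axis")
})

test_that("phantom block has the 1-inch cross-section and a single label", {
  mesh <- fixture("phantom", build_phantom_block(resolution = 0.3))
  expect_equal(diff(range(mesh$nodes[, 2])), 2.54)
  expect_equal(diff(range(mesh$nodes[, 3])), 2.54)
  expect_equal(diff(range(mesh$nodes[, 1])), 15)
  expect_equal(unique(mesh$tissue_levels[mesh$tissue]), "phantom")
  # mesh is symmetric under reflection across the tube midplane
  y <- sort(unique(round(mesh$nodes[, 2], 9)))
  expect_equal(y, sort(unique(round(2.54 - y, 9))))
})

test_that("sensor layouts sit on the surface with correct spacing and depth", {
  mesh <- coarse_abdomen()
  lay <- place_sensor(mesh, "vertical", sdds = 1:10)
  expect_equal(nrow(lay$detectors), 10)
  expect_equal(lay$source, c(0, 1, 0))
  expect_true(all(lay$detectors$z == 0))
  d <- sqrt((lay$detectors$x - lay$source[1])^2 +
              (lay$detectors$y - lay$source[2])^2)
  expect_equal(d, as.numeric(1:10), tolerance = 1e-9)
  # detectors above the ellipsoid sit 2.2-2.7 cm from the intestinal surface
  expect_true(all(lay$detectors$depth_to_intestine[1:4] > 2.2 &
                    lay$detectors$depth_to_intestine[1:4] < 2.7))
  # horizontal placement is slightly deeper off the apex
  lh <- place_sensor(mesh, "horizontal", sdds = 1:4)
  expect_true(all(lh$detectors$depth_to_intestine >=
                    lay$detectors$depth_to_intestine[1:4] - 0.3))
})

test_that("sensor layout edge cases", {
  mesh <- coarse_abdomen()
  empty <- place_sensor(mesh, "vertical", sdds = numeric())
  expect_s3_class(empty, "sensor_layout")
  expect_equal(nrow(empty$detectors), 0)
  expect_error(place_sensor(mesh, "vertical", sdds = c(1, 50)),
               "exceeds the meshed surface")
  expect_error(place_sensor(mesh, "vertical", sdds = c(2, 1)),
               "strictly increasing")
})

test_that("ellipsoid distance agrees with a direct minimization", {
  p <- abdomen_params()
  ell <- intestine_ellipsoid(p)
  pt <- c(0.7, 2.1, 0)
  d <- ellipsoid_distance(ell, pt)
  # brute-force surface sampling oracle
  th <- seq(0, pi, length.out = 400)
  ph <- seq(0, 2 * pi, length.out = 800)
  grid <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  pts <- sweep(dirs %*% (t(ell$U) * ell$s), 2, ell$center, "+")
  d_brute <- sqrt(min(colSums((t(pts) - pt)^2)))
  expect_equal(d, d_brute, tolerance = 1e-3)
  inside <- ell$center + 0.1 * ell$U[, 1]
  expect_equal(ellipsoid_distance(ell, inside), 0)
})
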
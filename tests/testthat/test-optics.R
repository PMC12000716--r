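test_that("packaged baseline table carries the 750 nm tissue properties", {
  p <- default_properties()
  expect_equal(props_row(p, "intestine")$mua, 0.21)
  expect_equal(props_row(p, "intestine")$musp, 5)
  expect_equal(props_row(p, "adipose")$mua, 0.05)
  expect_equal(props_row(p, "epidermis")$musp, 38)
  expect_equal(props_row(p, "SMA")$mua, 2.5)
  expect_equal(props_row(p, "SMV")$mua, 4.0)
  expect_error(default_properties(810), "750")
  expect_error(props_row(p, "bone"), "adipose")
})

test_that("derived diffusion constants follow their definitions", {
  p <- default_properties()
  a <- props_row(p, "adipose")
  expect_equal(a$D, 1 / (3 * 20.05))
  expect_equal(a$ltr, 0.05)
  expect_equal(a$zb, 0.09815910585, tolerance = 1e-9)
  p0 <- optical_props("m", 0.1, 10, Reff = 0)
  expect_equal(p0$zb, 2 * 0.1 / 3)
  expect_warning(optical_props("m", 12, 10), "diffusion")
})

test_that("blood absorption reproduces the arterial/venous table values", {
  # SMA: SO2 98%, SMV: SO2 75%, [Hb] 14.1 g/dL, 750 nm extinctions
  expect_equal(blood_absorption(0.98), 2.696702583, tolerance = 1e-8)
  expect_equal(blood_absorption(0.75), 3.723876626, tolerance = 1e-8)
  expect_equal(blood_absorption(0.98), 2.5, tolerance = 0.15)
  expect_equal(blood_absorption(0.75), 4.0, tolerance = 0.15)
})

test_that("blood absorption is linear in [Hb], affine in SO2, deoxy-dominant", {
  expect_equal(blood_absorption(0.8, hb_gdl = 0), 0)
  expect_equal(blood_absorption(0.8, hb_gdl = 28.2),
               2 * blood_absorption(0.8, hb_gdl = 14.1))
  s <- seq(0, 1, 0.25)
  mu <- vapply(s, blood_absorption, 0)
  expect_equal(diff(mu, differences = 2), rep(0, 3), tolerance = 1e-12)
  expect_lt(blood_absorption(0.98), blood_absorption(0.75))
  expect_error(blood_absorption(1.2), "so2")
  expect_error(blood_absorption(0.5, hb_gdl = -1), "hb_gdl")
})

test_that("perturbing one tissue changes only that row and its D", {
  p <- default_properties()
  q <- perturb_mua(p, "intestine", 0.24)
  expect_equal(q$mua[q$tissue == "intestine"], 0.24)
  expect_equal(q$D[q$tissue == "intestine"], 1 / (3 * (0.24 + 5)))
  keep <- q$tissue != "intestine"
  expect_equal(q[keep, ], p[p$tissue != "intestine", ])
  expect_equal(perturb_mua(p, "adipose", 0.05), p)
  q2 <- perturb_mua(p, "adipose", 0.08)
  expect_equal(q2$D[q2$tissue == "adipose"], 1 / (3 * 20.08))
  expect_error(perturb_mua(p, "muscle", 0.1), "unknown tissue")
})

test_that("property tables round-trip through the config representation", {
  p <- default_properties()
  expect_identical(props_from_list(props_to_list(p)), p)
})
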
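test_that("differential pathlength: frozen value, origin, asymptote", {
  expect_equal(differential_pathlength(4), 60.54335214, tolerance = 1e-8)
  expect_equal(differential_pathlength(0), 0)
  # large-absorption limit: L -> (SDD/2) sqrt(3 musp/mua)
  mua <- 40; musp <- 20; sdd <- 15
  stopifnot(sdd * sqrt(3 * mua * musp) >= 100)
  expect_equal(differential_pathlength(sdd, mua, musp),
               sdd / 2 * sqrt(3 * musp / mua), tolerance = 0.01)
})

test_that("modified Beer-Lambert recovery identities", {
  expect_equal(mbll_delta_mua(1e-5, 1e-5, 30), 0)
  expect_equal(mbll_delta_mua(exp(-1) * 2e-4, 2e-4, 50), 0.02)
  for (L in c(5, 50, 500))
    expect_equal(mbll_delta_mua(7e-6 * exp(-0.03 * L), 7e-6, L), 0.03)
  expect_error(mbll_delta_mua(0, 1e-5, 30), "positive")
  expect_error(mbll_delta_mua(1e-5, 1e-5, 0), "positive")
  expect_error(layer_sensitivity(0.01, 0), "non-zero")
  expect_equal(layer_sensitivity(0.015, 0.03), 0.5)
})

test_that("whole-domain perturbation recovers itself (MBLL consistency)", {
  mesh <- build_block(pad = 6, sdd_max = 4, resolution = 0.2, musp = 20)
  props <- optical_props("medium", 0.05, 20)
  lay <- place_sensor(mesh, "horizontal", sdds = 2:4, source = c(0, 0, 0))
  sc <- run_sensitivity(mesh, lay, props,
                        perturbations = c(medium = 0.08),
                        dpl_tissue = "medium")
  expect_true(all(abs(sc$S - 1) < 0.15))
})

test_that("sensitivity experiment structure and bookkeeping", {
  sc <- coarse_abdomen_sensitivity()
  expect_s3_class(sc, "sensitivity_curve")
  # one record per (tissue, sdd)
  expect_equal(nrow(sc), 3 * 5)
  expect_true(all(table(sc$tissue) == 5))
  expect_true(all(sc$S >= 0))
  expect_true(all(sc$L > 0))
  expect_equal(unique(sc$dmua_true[sc$tissue == "epidermis"]), 0.3)
  expect_equal(unique(sc$dmua_true[sc$tissue == "intestine"]), 0.03)
  # L is computed from baseline adipose properties
  expect_equal(sc$L[sc$tissue == "adipose"],
               differential_pathlength(sc$sdd[sc$tissue == "adipose"]))
  expect_equal(sensitivity_at(sc, "adipose", 3),
               sc$S[sc$tissue == "adipose" & sc$sdd == 3][1])
  b <- attr(sc, "baseline")
  expect_true(all(diff(b$fluence[order(b$sdd)]) < 0))
})

test_that("empty perturbation set yields a baseline-only curve", {
  mesh <- coarse_abdomen()
  lay <- place_sensor(mesh, "vertical", sdds = c(1, 2))
  sc <- run_sensitivity(mesh, lay, perturbations = c())
  expect_equal(nrow(sc), 0)
  expect_equal(nrow(attr(sc, "baseline")), 2)
  expect_error(run_sensitivity(mesh, lay, perturbations = c(bone = 0.1)),
               "absent")
  expect_error(run_sensitivity(mesh, lay,
                               perturbations = c(adipose = 0.05)),
               "equals the baseline")
})

test_that("layer sensitivities have the layered-medium shape", {
  sc <- coarse_abdomen_sensitivity()
  s_int <- sc$S[sc$tissue == "intestine"]
  s_adi <- sc$S[sc$tissue == "adipose"]
  s_epi <- sc$S[sc$tissue == "epidermis"]
  # intestine sensitivity grows with SDD; epidermis decays; epidermis is
  # far below adipose everywhere
  expect_true(all(diff(s_int) > 0))
  expect_true(all(diff(s_epi) < 0))
  expect_true(all(s_epi < s_adi))
})

test_that("collapsed-epidermis surrogate tracks the resolved thin sheet", {
  mesh_c <- fixture("abdomen_collapsed",
                    build_abdomen(resolution = 0.55,
                                  epidermis_mode = "collapsed"))
  lay <- place_sensor(mesh_c, "vertical", sdds = c(1, 2, 3))
  sc_c <- run_sensitivity(mesh_c, lay,
                          perturbations = c(epidermis = 1.5,
                                            intestine = 0.24))
  sc_l <- coarse_abdomen_sensitivity()
  for (ti in c("epidermis", "intestine")) {
    a <- sc_c$S[sc_c$tissue == ti & sc_c$sdd %in% c(1, 3)]
    b <- sc_l$S[sc_l$tissue == ti & sc_l$sdd %in% c(1, 3)]
    expect_equal(a, b, tolerance = 0.35)
  }
})
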
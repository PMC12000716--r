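# Shared fixtures, built lazily and cached for the session so expensive
# meshes and solves are reused across test files.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# small homogeneous block for solver checks (desk-scale, ~15k nodes)
small_block <- function(musp = 10) {
  fixture(sprintf("block_musp%g", musp),
          build_block(pad = 6, sdd_max = 4, resolution = 0.3, musp = musp))
}

small_block_solve <- function(mua = 0.1, musp = 10) {
  fixture(sprintf("bsolve_%g_%g", mua, musp), {
    mesh <- small_block(musp)
    props <- optical_props("medium", mua = mua, musp = musp)
    solve_fluence(mesh, props, c(0, 0, 0))
  })
}

# coarse abdomen used by geometry and analysis tests (not accuracy-critical)
coarse_abdomen <- function() {
  fixture("abdomen_coarse", build_abdomen(resolution = 0.55))
}

coarse_abdomen_sensitivity <- function() {
  fixture("abdomen_coarse_sens", {
    mesh <- coarse_abdomen()
    lay <- place_sensor(mesh, "vertical", sdds = c(1, 2, 3, 4.5, 6))
    run_sensitivity(mesh, lay)
  })
}
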
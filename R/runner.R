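#' Experiment configuration
#'
#' Bundles every knob of a full sensor-design study: geometry parameters,
#' optical properties, the perturbation set, sensor orientations and SDD
#' list, the adipose-thickness sweep, acquisition rates, the noise model and
#' mesh resolution. Serializes losslessly to YAML or JSON.
#'
#' @param geometry an [abdomen_params()] (or plain list of its fields).
#' @param properties an [optical_props()] table.
#' @param perturbations named numeric vector of perturbed absorptions.
#' @param orientations subset of `c("vertical", "horizontal")`.
#' @param sdds detector distances (cm).
#' @param adipose_thicknesses sweep values (cm).
#' @param rates acquisition rates (Hz).
#' @param noise a [noise_model()] or list of its generative parameters.
#' @param resolution mesh core edge length (cm).
#' @param epidermis_mode `"layer"` or `"collapsed"` thin-sheet handling.
#' @param seed integer seed stored with the run (the pipeline itself is
#'   deterministic; the seed covers any stochastic noise realizations layered
#'   on top).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(geometry = abdomen_params(),
                              properties = default_properties(),
                              perturbations = c(epidermis = 1.5,
                                                adipose = 0.08,
                                                intestine = 0.24),
                              orientations = c("vertical", "horizontal"),
                              sdds = seq(0.5, 10, by = 0.5),
                              adipose_thicknesses = c(2.0, 2.2, 2.4, 2.6, 2.8),
                              rates = c(0.1, 0.5, 1, 5, 10),
                              noise = noise_model(),
                              resolution = 0.3,
                              epidermis_mode = "layer",
                              seed = 1L) {
  if (!inherits(geometry, "abdomen_params"))
    geometry <- do.call(abdomen_params, geometry)
  if (!inherits(noise, "noise_model"))
    noise <- do.call(noise_model, noise)
  orientations <- match.arg(orientations, c("vertical", "horizontal"),
                            several.ok = TRUE)
  stopifnot(length(sdds) >= 1, length(adipose_thicknesses) >= 1,
            length(rates) >= 1, resolution > 0)
  missing <- setdiff(names(perturbations), properties$tissue)
  if (length(missing))
    stop(sprintf("perturbed tissue(s) without properties: %s",
                 paste(missing, collapse = ", ")))
  structure(list(geometry = geometry, properties = properties,
                 perturbations = perturbations, orientations = orientations,
                 sdds = sdds, adipose_thicknesses = adipose_thicknesses,
                 rates = rates, noise = noise, resolution = resolution,
                 epidermis_mode = epidermis_mode, seed = as.integer(seed)),
            class = "experiment_config")
}

config_to_list <- function(cfg) {
  list(geometry = unclass(cfg$geometry),
       properties = props_to_list(cfg$properties),
       perturbations = as.list(cfg$perturbations),
       orientations = cfg$orientations,
       sdds = cfg$sdds,
       adipose_thicknesses = cfg$adipose_thicknesses,
       rates = cfg$rates,
       noise = cfg$noise[c("a", "b", "f_ref", "rates", "kappa")],
       resolution = cfg$resolution,
       epidermis_mode = cfg$epidermis_mode,
       seed = cfg$seed)
}

config_from_list <- function(x) {
  experiment_config(
    geometry = do.call(abdomen_params, x$geometry),
    properties = props_from_list(x$properties),
    perturbations = unlist(x$perturbations),
    orientations = unlist(x$orientations),
    sdds = unlist(x$sdds),
    adipose_thicknesses = unlist(x$adipose_thicknesses),
    rates = unlist(x$rates),
    noise = do.call(noise_model, lapply(x$noise, unlist)),
    resolution = x$resolution,
    epidermis_mode = x$epidermis_mode,
    seed = x$seed)
}

#' Read / write experiment configurations
#'
#' YAML (`.yml`/`.yaml`) or JSON, chosen by file extension. A written
#' configuration reads back to an identical run plan.
#'
#' @param cfg an [experiment_config()].
#' @param file path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "experiment_config"))
  x <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(x, file, precision = 15L)
  } else if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension (use .yaml/.yml/.json)")
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
  else if (grepl("\\.json$", file)) jsonlite::read_json(file,
                                                        simplifyVector = TRUE)
  else stop("unsupported config extension (use .yaml/.yml/.json)")
  config_from_list(x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full sensor-design study
#'
#' For every (adipose thickness, orientation): builds the abdomen mesh,
#' solves the baseline and each perturbed diffusion problem (one
#' factorization per property set, shared across orientations), assembles
#' the sensitivity curve, and computes CNR-vs-SDD curves at every acquisition
#' rate. Writes tidy CSV files and a summary JSON with the optimal SDD per
#' condition. Deterministic for a fixed configuration; on error, partial
#' outputs in `out_dir` are removed and the error is tagged with the failing
#' stage.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param progress print one line per stage.
#' @return (invisibly) list with `sensitivity` (per thickness), `cnr` (per
#'   thickness x orientation x rate), and `summary` (optimal SDD table).
#' @export
run_full_study <- function(config, out_dir = NULL, progress = interactive()) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  wrote <- character()
  emit <- function(f) wrote <<- c(wrote, f)
  on_error_cleanup <- function() unlink(wrote)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (progress) message(sprintf(...))
  res <- withCallingHandlers({
    sens <- list(); cnrs <- list(); summ <- list()
    for (th in config$adipose_thicknesses) {
      g <- config$geometry
      g$adipose_thickness <- th
      g <- do.call(abdomen_params, unclass(g)[names(formals(abdomen_params))])
      mesh <- run_stage("build-geometry",
                        build_abdomen(g, resolution = config$resolution,
                                      epidermis_mode = config$epidermis_mode,
                                      sdd_max = max(config$sdds)))
      say("thickness %.1f cm: mesh %d nodes / %d cells", th,
          nrow(mesh$nodes), nrow(mesh$elems))
      layouts <- run_stage("place-sensor", lapply(
        config$orientations, function(o)
          place_sensor(mesh, o, sdds = config$sdds)))
      t0 <- Sys.time()
      sc <- run_stage("sensitivity",
                      run_sensitivity(mesh, layouts, config$properties,
                                      config$perturbations))
      say("thickness %.1f cm: %d solves in %.1f s", th,
          (length(config$perturbations) + 1L),
          as.numeric(Sys.time() - t0, units = "secs"))
      key <- sprintf("thickness_%.1f", th)
      sens[[key]] <- sc
      if (!is.null(out_dir)) {
        f <- file.path(out_dir, sprintf("sensitivity_%s.csv", key))
        write_sensitivity_csv(sc, f,
                              meta_file = file.path(
                                out_dir, sprintf("sensitivity_%s.json", key)))
        emit(f)
      }
      for (o in config$orientations) for (r in config$rates) {
        cc <- run_stage("cnr", cnr_curve(sc, config$noise, rate = r,
                                         orientation = o))
        ckey <- sprintf("%s_%s_rate_%g", key, o, r)
        cnrs[[ckey]] <- cc
        summ[[length(summ) + 1L]] <- data.frame(
          adipose_thickness_cm = th, orientation = o, rate_hz = r,
          optimal_sdd_cm = optimal_sdd(cc), max_cnr = max(cc$cnr))
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, sprintf("cnr_%s.csv", ckey))
          utils::write.csv(as.data.frame(cc), f, row.names = FALSE)
          emit(f)
        }
      }
    }
    summary_df <- do.call(rbind, summ)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "summary.json")
      jsonlite::write_json(summary_df, f, dataframe = "rows", digits = NA)
      emit(f)
      write_config(config, file.path(out_dir, "config.json"))
    }
    list(sensitivity = sens, cnr = cnrs, summary = summary_df)
  }, error = function(e) on_error_cleanup())
  invisible(res)
}

#' In-silico analogue of the optical phantom test
#'
#' Solves the rectangular phantom-tube geometry for an absorption sweep at
#' fixed scattering, reads the fluence at the given SDD, normalizes both the
#' FE and the closed-form semi-infinite fluences to the lowest-absorption
#' value, and reports the per-absorption discrepancy. The normalization
#' mirrors the coupling-coefficient calibration of a real sensor: the ratio
#' of measurement to FE fluence at the reference absorption is the coupling
#' coefficient.
#'
#' @param mua_values absorption sweep (cm^-1).
#' @param musp reduced scattering (cm^-1).
#' @param sdd source-detector distance (cm).
#' @param resolution mesh core edge length (cm).
#' @return list with the comparison table (`mua`, `phi_fe`, `phi_analytic`,
#'   normalized columns, `rel_discrepancy`) and `max_discrepancy`.
#' @export
validate_against_analytic <- function(mua_values = c(0.25, 0.44, 0.62,
                                                     0.81, 1.0),
                                      musp = 10, sdd = 1,
                                      resolution = 0.08) {
  stopifnot(length(mua_values) >= 2, all(mua_values > 0))
  mesh <- run_stage("build-geometry",
                    build_phantom_block(resolution = resolution,
                                        musp = musp))
  src_pt <- mesh$geometry$surface_center
  lay <- place_sensor(mesh, "horizontal", sdds = sdd, source = src_pt)
  phi <- vapply(mua_values, function(mua) {
    props <- optical_props("phantom", mua = mua, musp = musp)
    f <- run_stage("solve", solve_fluence(mesh, props,
                                          point_source(mesh, props, src_pt)))
    read_detectors(f, lay)$fluence
  }, 0)
  ana <- semi_infinite_fluence(sdd, mua_values, musp)
  tab <- data.frame(mua = mua_values, phi_fe = phi, phi_analytic = ana,
                    fe_norm = phi / phi[1L], analytic_norm = ana / ana[1L])
  tab$rel_discrepancy <- tab$fe_norm / tab$analytic_norm - 1
  list(table = tab, max_discrepancy = max(abs(tab$rel_discrepancy)),
       sdd = sdd, musp = musp)
}
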
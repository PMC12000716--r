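#' Per-tissue optical properties
#'
#' Container mapping tissue labels to absorption (`mua`, cm^-1) and reduced
#' scattering (`musp`, cm^-1) at a stated wavelength, with the derived
#' diffusion-model constants: photon diffusion coefficient
#' `D = 1/(3 (mua + musp))` (cm), transport mean free path `ltr = 1/musp`
#' (cm), and the Robin extrapolation length
#' `zb = 2 ltr (1 + Reff) / (3 (1 - Reff))` (cm) with effective Fresnel
#' reflectance `Reff` (0.493 for an air-tissue boundary).
#'
#' @param tissue character vector of tissue names.
#' @param mua,musp absorption and reduced scattering coefficients (cm^-1).
#' @param wavelength wavelength (nm).
#' @param Reff effective Fresnel reflectance at the boundary.
#' @return object of class `optical_props`: a data frame with one row per
#'   tissue and columns `tissue, mua, musp, D, ltr, zb`.
#' @export
optical_props <- function(tissue, mua, musp, wavelength = 750, Reff = 0.493) {
  stopifnot(length(tissue) == length(mua), length(mua) == length(musp))
  if (anyDuplicated(tissue)) stop("duplicate tissue names")
  if (any(mua <= 0) || any(musp <= 0))
    stop("mua and musp must be positive")
  if (Reff < 0 || Reff >= 1) stop("Reff must be in [0, 1)")
  if (any(mua >= musp))
    warning("mua >= musp for some tissue: the diffusion approximation is ",
            "of limited validity there", call. = FALSE)
  d <- data.frame(tissue = as.character(tissue), mua = as.numeric(mua),
                  musp = as.numeric(musp), stringsAsFactors = FALSE)
  wavelength <- as.numeric(wavelength)
  Reff <- as.numeric(Reff)
  d$D <- 1 / (3 * (d$mua + d$musp))
  d$ltr <- 1 / d$musp
  d$zb <- 2 * d$ltr * (1 + Reff) / (3 * (1 - Reff))
  rownames(d) <- NULL
  attr(d, "wavelength") <- wavelength
  attr(d, "Reff") <- Reff
  class(d) <- c("optical_props", "data.frame")
  d
}

#' Baseline tissue optical properties at 750 nm
#'
#' The packaged per-tissue baseline: subcutaneous adipose (0.05, 20),
#' epidermis (1.2, 38), SMA (2.5, 25), SMV (4.0, 25) and intestine
#' (0.21, 5) cm^-1 for (`mua`, `musp`). Blood-vessel absorptions can
#' alternatively be recomputed from oxygen saturation with
#' [blood_absorption()]. Only the 750 nm table is packaged; build properties
#' at other wavelengths with [optical_props()].
#'
#' @param wavelength wavelength in nm; must be 750.
#' @param Reff effective Fresnel reflectance.
#' @return an [optical_props()] table.
#' @export
default_properties <- function(wavelength = 750, Reff = 0.493) {
  if (!identical(as.numeric(wavelength), 750))
    stop("packaged baseline properties are tabulated at 750 nm only; ",
         "use optical_props() to supply other wavelengths")
  optical_props(
    tissue = c("adipose", "epidermis", "SMA", "SMV", "intestine"),
    mua = c(0.05, 1.2, 2.5, 4.0, 0.21),
    musp = c(20, 38, 25, 25, 5),
    wavelength = wavelength, Reff = Reff
  )
}

#' Hemoglobin molar extinction coefficients
#'
#' Base-10 molar extinction coefficients (cm^-1 M^-1) of oxy- and
#' deoxyhemoglobin from the standard tabulated compilation. Only 750 nm is
#' packaged; pass explicit values to [blood_absorption()] for other
#' wavelengths.
#'
#' @param wavelength wavelength in nm.
#' @return list with `eps_oxy`, `eps_deoxy` (cm^-1 M^-1, base 10) and
#'   `base` = `"10"`.
#' @export
hb_extinction <- function(wavelength = 750) {
  tab <- data.frame(wavelength = 750, eps_oxy = 518.0, eps_deoxy = 1405.24)
  i <- match(wavelength, tab$wavelength)
  if (is.na(i))
    stop("extinction coefficients packaged at 750 nm only; ",
         "supply eps_oxy/eps_deoxy explicitly")
  list(eps_oxy = tab$eps_oxy[i], eps_deoxy = tab$eps_deoxy[i], base = "10")
}

#' Blood absorption from the Beer-Lambert law
#'
#' Computes the (base-e) absorption coefficient of whole blood,
#' `mua = [Hb] (eps_oxy SO2 + eps_deoxy (1 - SO2))`, from the oxygen
#' saturation and total hemoglobin concentration. The concentration in g/dL
#' is converted to molarity via the hemoglobin molar mass (64,500 g/mol),
#' and base-10 extinction coefficients are converted to base e by ln(10).
#'
#' @param so2 oxygen saturation as a fraction in `[0, 1]`.
#' @param hb_gdl total hemoglobin concentration (g/dL); default 14.1.
#' @param wavelength wavelength (nm) used to look up packaged extinctions.
#' @param eps_oxy,eps_deoxy molar extinction coefficients (cm^-1 M^-1)
#'   overriding the packaged table.
#' @param base convention of the supplied extinctions, `"10"` or `"e"`.
#' @return absorption coefficient in cm^-1 (base e).
#' @examples
#' blood_absorption(0.98)  # arterial, ~2.5 cm^-1 at 750 nm
#' blood_absorption(0.75)  # venous, ~4 cm^-1 at 750 nm
#' @export
blood_absorption <- function(so2, hb_gdl = 14.1, wavelength = 750,
                             eps_oxy = NULL, eps_deoxy = NULL,
                             base = c("10", "e")) {
  base <- match.arg(base)
  if (any(so2 < 0 | so2 > 1)) stop("so2 must be within [0, 1]")
  if (any(hb_gdl < 0)) stop("hb_gdl must be non-negative")
  if (is.null(eps_oxy) || is.null(eps_deoxy)) {
    e <- hb_extinction(wavelength)
    eps_oxy <- e$eps_oxy; eps_deoxy <- e$eps_deoxy; base <- e$base
  }
  conc_molar <- hb_gdl * 10 / 64500       # g/dL -> g/L -> mol/L
  eps <- eps_oxy * so2 + eps_deoxy * (1 - so2)
  if (base == "10") eps <- eps * log(10)
  conc_molar * eps
}

#' Perturb one tissue's absorption
#'
#' Returns a new property table with the named tissue's `mua` replaced and
#' its derived diffusion coefficient recomputed; all other rows unchanged.
#'
#' @param props an [optical_props()] table.
#' @param tissue tissue name to perturb.
#' @param mua new absorption coefficient (cm^-1).
#' @export
perturb_mua <- function(props, tissue, mua) {
  stopifnot(inherits(props, "optical_props"), length(tissue) == 1L,
            length(mua) == 1L, mua > 0)
  i <- match(tissue, props$tissue)
  if (is.na(i))
    stop(sprintf("unknown tissue '%s'; known: %s", tissue,
                 paste(props$tissue, collapse = ", ")))
  props$mua[i] <- mua
  props$D[i] <- 1 / (3 * (props$mua[i] + props$musp[i]))
  props
}

#' Look up the property rows for one or more tissues
#' @param props an [optical_props()] table.
#' @param tissue tissue name(s).
#' @return the matching row(s) of `props`.
#' @export
props_row <- function(props, tissue) {
  i <- match(tissue, props$tissue)
  if (anyNA(i))
    stop(sprintf("no optical properties for tissue '%s'; known: %s",
                 paste(tissue[is.na(i)], collapse = ", "),
                 paste(props$tissue, collapse = ", ")))
  props[i, , drop = FALSE]
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("Optical properties at %g nm (Reff = %g)\n",
              attr(x, "wavelength"), attr(x, "Reff")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize / restore an optical property table
#'
#' Round-trips bit-exactly through the list representation used in YAML/JSON
#' experiment configurations.
#' @param props an [optical_props()] table.
#' @export
props_to_list <- function(props) {
  list(wavelength = attr(props, "wavelength"), Reff = attr(props, "Reff"),
       tissue = as.list(stats::setNames(
         lapply(seq_len(nrow(props)),
                function(i) list(mua = props$mua[i], musp = props$musp[i])),
         props$tissue)))
}

#' @rdname props_to_list
#' @param x a list as produced by [props_to_list()].
#' @export
props_from_list <- function(x) {
  optical_props(tissue = names(x$tissue),
                mua = vapply(x$tissue, function(t) t$mua, 0),
                musp = vapply(x$tissue, function(t) t$musp, 0),
                wavelength = x$wavelength, Reff = x$Reff)
}
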
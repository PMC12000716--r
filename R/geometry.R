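#' Parametric infant abdomen geometry
#'
#' Parameters of the layered abdomen surrogate: a flat skin surface at z = 0,
#' a thin epidermal sheet, a homogeneous adipose layer, and an ellipsoidal
#' intestinal region whose major axis is tilted from the superior-inferior
#' axis, optionally with superior mesenteric artery/vein (SMA/SMV) cylinders.
#' The adipose thickness is the shortest distance from the skin surface to the
#' ellipsoid surface; sweeping it translates the ellipsoid in depth while its
#' dimensions stay constant.
#'
#' Coordinates are right-handed, in cm: x lateral, y superior, z depth beneath
#' the skin (z >= 0 inside tissue), origin at the umbilicus landmark.
#'
#' @param epidermis_thickness epidermal sheet thickness (cm).
#' @param adipose_thickness shortest skin-to-ellipsoid distance (cm);
#'   design sweeps cover 2.0-2.8 with 2.4 the reference anatomy.
#' @param intestine_thickness anterior-posterior extent of the intestinal
#'   ellipsoid (cm); twice its smallest semi-axis.
#' @param intestine_tilt_deg tilt of the ellipsoid major axis from the
#'   superior-inferior axis, in degrees (rotation about the lateral axis).
#' @param intestine_major_axis,intestine_lateral_axis superior-inferior and
#'   lateral semi-axes (cm). These control how the intestine thins and deepens
#'   away from the umbilicus.
#' @param include_vessels include SMA/SMV cylinders.
#' @param sma_radius,smv_radius vessel radii (cm).
#' @param domain_padding lateral/inferior padding beyond the sensor lines and
#'   depth padding below the ellipsoid (cm).
#' @return list of class `abdomen_params`.
#' @export
abdomen_params <- function(epidermis_thickness = 0.008,
                           adipose_thickness = 2.4,
                           intestine_thickness = 2.6,
                           intestine_tilt_deg = 10,
                           intestine_major_axis = 6,
                           intestine_lateral_axis = 5,
                           include_vessels = TRUE,
                           sma_radius = 0.15,
                           smv_radius = 0.25,
                           domain_padding = 3) {
  p <- list(epidermis_thickness = epidermis_thickness,
            adipose_thickness = adipose_thickness,
            intestine_thickness = intestine_thickness,
            intestine_tilt_deg = intestine_tilt_deg,
            intestine_major_axis = intestine_major_axis,
            intestine_lateral_axis = intestine_lateral_axis,
            include_vessels = include_vessels,
            sma_radius = sma_radius, smv_radius = smv_radius,
            domain_padding = domain_padding)
  validate_abdomen_params(p)
  class(p) <- "abdomen_params"
  p
}

validate_abdomen_params <- function(p) {
  num_pos <- c("epidermis_thickness", "adipose_thickness",
               "intestine_thickness", "intestine_major_axis",
               "intestine_lateral_axis", "sma_radius", "smv_radius",
               "domain_padding")
  for (f in num_pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop(sprintf("abdomen_params: '%s' must be a positive number", f))
  if (p$adipose_thickness < p$epidermis_thickness)
    stop("abdomen_params: adipose_thickness must be >= epidermis_thickness")
  if (p$intestine_thickness / 2 > p$intestine_major_axis ||
      p$intestine_thickness / 2 > p$intestine_lateral_axis)
    stop("abdomen_params: intestine_thickness/2 must be the smallest semi-axis")
  invisible(p)
}

# Ellipsoid of the intestinal region: center, orthonormal axis matrix U
# (columns: major/superior, lateral, anterior-posterior), semi-axes s.
intestine_ellipsoid <- function(p) {
  th <- p$intestine_tilt_deg * pi / 180
  # The major axis tilts so that the shallow apex of the ellipsoid lies on
  # the superior side, under the sensor lines: detectors a few cm from the
  # umbilicus then sit 2.3-2.6 cm above the intestinal surface, and the
  # intestine thins and deepens with distance from the apex.
  u_major <- c(0, cos(th), -sin(th))    # superior-inferior, rising superiorly
  u_lat <- c(1, 0, 0)
  u_ap <- c(0, sin(th), cos(th))
  s <- c(p$intestine_major_axis, p$intestine_lateral_axis,
         p$intestine_thickness / 2)
  # support in the depth direction: distance from center to shallowest point
  support_z <- sqrt(sum((s * c(u_major[3], u_lat[3], u_ap[3]))^2))
  center <- c(0, 0, p$adipose_thickness + support_z)
  list(center = center, U = cbind(u_major, u_lat, u_ap), s = s,
       support_z = support_z)
}

ellipsoid_inside <- function(ell, pts) {
  q <- sweep(pts, 2L, ell$center) %*% ell$U
  (q[, 1] / ell$s[1])^2 + (q[, 2] / ell$s[2])^2 + (q[, 3] / ell$s[3])^2 <= 1
}

#' Distance from an exterior point to an ellipsoid surface
#' @keywords internal
ellipsoid_distance <- function(ell, pt) {
  q <- as.numeric(crossprod(ell$U, pt - ell$center))
  s2 <- ell$s^2
  val <- sum(q^2 / s2)
  if (val <= 1) return(0)
  f <- function(t) sum((ell$s * q / (s2 + t))^2) - 1
  hi <- max(ell$s) * (sqrt(val) + 1)
  hi2 <- hi
  while (f(hi2) > 0) hi2 <- hi2 * 2
  t0 <- stats::uniroot(f, c(0, hi2), tol = 1e-12)$root
  y <- s2 * q / (s2 + t0)
  sqrt(sum((q - y)^2))
}

# depth axis: fine spacing near the surface growing into uniform `h`, then
# geometric coarsening below `fine_to` down to `zmax`
depth_axis <- function(zmax, h, z_fine = numeric(), fine_to = zmax,
                       ratio = 1.45, h0 = NULL) {
  z <- sort(unique(c(0, z_fine[z_fine > 0 & z_fine < zmax])))
  if (is.null(h0)) h0 <- max(h / 8, if (length(z) > 1) max(diff(z)) else h / 8)
  p <- max(z); step <- h0
  while (p < fine_to - 1e-9 && step < h) {
    p <- p + step
    z <- c(z, p)
    step <- min(step * 1.5, h)
  }
  while (p < fine_to - 1e-9) {
    p <- min(p + h, fine_to)
    z <- c(z, p)
  }
  while (p < zmax - 1e-9) {
    step <- step * ratio
    p <- min(p + step, zmax)
    z <- c(z, p)
  }
  sort(unique(round(z, 10)))
}

#' Build the parametric abdomen mesh
#'
#' Constructs a labeled tetrahedral mesh of the layered abdomen: epidermal
#' sheet (0 to `epidermis_thickness`), adipose tissue, ellipsoidal intestinal
#' region and optional SMA/SMV vessel cylinders, on a graded tensor grid that
#' is fine near the skin and the sensor lines and coarsens towards the domain
#' boundary. The domain extends `domain_padding` cm beyond the farthest
#' detector of the standard 1-10 cm vertical and horizontal sensor lines.
#'
#' The 80-micron epidermis is realized as a single sheet of thin anisotropic
#' cells (`epidermis_mode = "layer"`); with `epidermis_mode = "collapsed"` the
#' sheet is omitted from the mesh and folded into an equivalent surface
#' absorption film handled by the solver.
#'
#' @param params an [abdomen_params()] object.
#' @param resolution target edge length (cm) in the core region.
#' @param epidermis_mode `"layer"` or `"collapsed"`.
#' @param sdd_max farthest source-detector distance the mesh must support (cm).
#' @return a [labeled_mesh()] carrying the geometry metadata.
#' @export
build_abdomen <- function(params = abdomen_params(), resolution = 0.4,
                          epidermis_mode = c("layer", "collapsed"),
                          sdd_max = 10) {
  validate_abdomen_params(params)
  epidermis_mode <- match.arg(epidermis_mode)
  stopifnot(resolution > 0, sdd_max > 0)
  ell <- intestine_ellipsoid(params)
  if (ell$center[3] - ell$support_z <= params$epidermis_thickness + 1e-9)
    stop("infeasible geometry: intestinal ellipsoid protrudes through the ",
         "epidermis (adipose_thickness too small)")
  pad <- params$domain_padding
  hi <- 1 + sdd_max + pad            # sensor lines start 1 cm from umbilicus
  lo <- -max(pad + 1.5, params$intestine_lateral_axis + 1)
  zmax <- ell$center[3] + ell$support_z + max(2.5, pad - 0.5)
  ax_core_hi <- 1 + sdd_max + 0.5
  x <- graded_axis(lo, hi, -1.5, ax_core_hi, resolution,
                   features = c(0, 1))
  y <- graded_axis(lo, hi, -1.5, ax_core_hi, resolution,
                   features = c(0, 1))
  t_epi <- params$epidermis_thickness
  z_fine <- if (epidermis_mode == "layer") c(t_epi, 1 / 38) else c(1 / 20)
  z <- depth_axis(zmax, resolution, z_fine = z_fine,
                  fine_to = ell$center[3] + ell$support_z + 0.3)
  g <- tet_grid(x, y, z)
  cent <- (g$nodes[g$elems[, 1L], ] + g$nodes[g$elems[, 2L], ] +
             g$nodes[g$elems[, 3L], ] + g$nodes[g$elems[, 4L], ]) / 4
  levels <- c("epidermis", "adipose", "intestine", "SMA", "SMV")
  lab <- rep(2L, nrow(cent))
  if (epidermis_mode == "layer") lab[cent[, 3] < t_epi] <- 1L
  lab[ellipsoid_inside(ell, cent)] <- 3L
  vessels <- NULL
  if (params$include_vessels) {
    vessels <- vessel_spec(params, ell)
    for (v in vessels) {
      d <- point_line_distance(cent, v$p0, v$dir, v$t_range)
      lab[d <= v$radius] <- match(v$name, levels)
    }
  }
  labeled_mesh(g$nodes, g$elems, lab, levels,
               geometry = list(kind = "abdomen", params = params,
                               ellipsoid = ell, vessels = vessels,
                               epidermis_mode = epidermis_mode,
                               umbilicus = c(0, 0, 0)))
}

# SMA/SMV as cylinders parallel to the ellipsoid major axis, just posterior to
# the ellipsoid center, truncated 3 cm superior to the intestine.
vessel_spec <- function(p, ell) {
  dir <- ell$U[, 1]
  t_max <- p$intestine_major_axis + 3
  list(
    list(name = "SMA", radius = p$sma_radius,
         p0 = ell$center + c(-0.4, 0, 0.4), dir = dir,
         t_range = c(-0.5 * p$intestine_major_axis, t_max)),
    list(name = "SMV", radius = p$smv_radius,
         p0 = ell$center + c(0.4, 0, 0.4), dir = dir,
         t_range = c(-0.5 * p$intestine_major_axis, t_max))
  )
}

point_line_distance <- function(pts, p0, dir, t_range) {
  rel <- sweep(pts, 2L, p0)
  t <- rel %*% dir
  d2 <- rowSums(rel^2) - t^2
  out <- sqrt(pmax(d2, 0))
  out[t < t_range[1] | t > t_range[2]] <- Inf
  out
}

#' Rectangular phantom block
#'
#' Homogeneous single-label mesh of the flat acrylic-tube phantom (1 in x 1 in
#' cross-section). The tube length is truncated to a desk-scale default of
#' 15 cm; at 1 cm source-detector distance the fluence never reaches the far
#' ends (verified by the truncation test).
#'
#' Surface coordinates: x runs along the tube, y across the 2.54 cm width,
#' z is depth through the 2.54 cm height; the measurement face is z = 0.
#'
#' @param width,height cross-section (cm); defaults 2.54 (1 inch).
#' @param length tube length (cm).
#' @param resolution core edge length (cm).
#' @param core x-interval meshed at full resolution (source/detector zone).
#' @param musp reduced scattering used only to place a grid plane at the
#'   source burial depth 1/musp.
#' @return a [labeled_mesh()] with single label `"phantom"`.
#' @export
build_phantom_block <- function(width = 2.54, height = 2.54, length = 15,
                                resolution = 0.16, core = NULL, musp = 10) {
  stopifnot(width > 0, height > 0, length > 0)
  if (is.null(core)) core <- c(length / 2 - 1.5, length / 2 + 2.5)
  core[1] <- max(core[1], 0); core[2] <- min(core[2], length)
  x <- graded_axis(0, length, core[1], core[2], resolution, ratio = 1.5,
                   features = mean(core))
  ny <- max(2L, ceiling(width / resolution))
  y <- seq(0, width, length.out = ny + 1L)
  if (!any(abs(y - width / 2) < 1e-9)) y <- sort(c(y, width / 2))
  z <- depth_axis(height, resolution, z_fine = c(1 / musp),
                  fine_to = height, h0 = min(1 / musp, resolution / 4))
  g <- tet_grid(x, y, z)
  labeled_mesh(g$nodes, g$elems, rep(1L, nrow(g$elems)), "phantom",
               geometry = list(kind = "phantom",
                               surface_center = c(mean(core), width / 2, 0)))
}

#' Homogeneous validation block
#'
#' Graded homogeneous block used to compare the finite-element solution with
#' the closed-form semi-infinite medium: fine around the source-detector line
#' (source at the origin of the top surface, detectors along +x), coarsening
#' geometrically to the padded domain boundary.
#'
#' @param pad padding (cm) beyond the source and farthest detector in every
#'   lateral direction and in depth.
#' @param sdd_max farthest detector distance to support (cm).
#' @param resolution core edge length (cm).
#' @param label tissue label of the single region.
#' @param musp reduced scattering, used to align a grid plane with the source
#'   burial depth 1/musp.
#' @param ratio geometric grading ratio towards the boundary.
#' @param core_halfwidth transverse half-width of the fine corridor (cm).
#' @param fine_depth depth to which the core resolution extends (cm); the
#'   corridor should cover the photon path between source and farthest
#'   detector, which shallows and narrows as the medium's effective
#'   attenuation grows.
#' @return a [labeled_mesh()].
#' @export
build_block <- function(pad = 8, sdd_max = 6, resolution = 0.35,
                        label = "medium", musp = 10, ratio = 1.45,
                        core_halfwidth = 1.2, fine_depth = 2.2) {
  stopifnot(pad > 0, sdd_max > 0, resolution > 0)
  x <- graded_axis(-pad, sdd_max + pad, -1, sdd_max + 1, resolution,
                   ratio = ratio, features = c(0, seq_len(sdd_max)))
  y <- graded_axis(-pad, pad, -core_halfwidth, core_halfwidth, resolution,
                   ratio = ratio, features = 0)
  z <- depth_axis(pad, resolution, z_fine = c(1 / musp),
                  fine_to = fine_depth,
                  ratio = ratio, h0 = min(1 / musp, resolution / 4))
  g <- tet_grid(x, y, z)
  labeled_mesh(g$nodes, g$elems, rep(1L, nrow(g$elems)), label,
               geometry = list(kind = "block"))
}

#' Place a NIRS sensor line on the skin surface
#'
#' Lays out one point source and an ordered set of point detectors along a
#' line on the air-tissue boundary. On the abdomen, the vertical orientation
#' puts the source 1 cm superior to the umbilicus with detectors along +y,
#' and the horizontal orientation 1 cm lateral with detectors along +x. For
#' other meshes supply `source` (and the line runs along +y for vertical,
#' +x for horizontal).
#'
#' @param mesh a [labeled_mesh()].
#' @param orientation `"vertical"` or `"horizontal"`.
#' @param sdds strictly increasing source-detector distances (cm).
#' @param source optional source surface point (length-3, cm).
#' @return object of class `sensor_layout` with the source point and a
#'   detector table (sdd, coordinates, and distance to the intestinal
#'   ellipsoid where the mesh carries one).
#' @export
place_sensor <- function(mesh, orientation = c("vertical", "horizontal"),
                         sdds = seq(1, 10), source = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  orientation <- match.arg(orientation)
  sdds <- as.numeric(sdds)
  if (length(sdds) && any(diff(sdds) <= 0))
    stop("sdds must be strictly increasing")
  if (length(sdds) && any(sdds <= 0)) stop("sdds must be positive")
  dir <- if (orientation == "vertical") c(0, 1, 0) else c(1, 0, 0)
  if (is.null(source)) {
    if (!is.null(mesh$geometry$umbilicus)) {
      source <- mesh$geometry$umbilicus + dir * 1
    } else if (!is.null(mesh$geometry$surface_center)) {
      source <- mesh$geometry$surface_center
    } else stop("supply `source` for meshes without a sensor landmark")
  }
  source <- snap_to_surface(mesh, source)
  pts <- if (length(sdds))
    sweep(outer(sdds, dir), 2L, source, "+") else
    matrix(numeric(), 0L, 3L)
  if (length(sdds)) {
    bb <- apply(mesh$nodes[unique(as.vector(mesh$boundary)), , drop = FALSE],
                2L, range)
    inside <- pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
      pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2]
    if (!all(inside))
      stop(sprintf("SDD %.2f cm exceeds the meshed surface",
                   sdds[which(!inside)[1]]))
    pts <- t(apply(pts, 1L, function(p) snap_to_surface(mesh, p)))
  }
  depth <- rep(NA_real_, length(sdds))
  if (!is.null(mesh$geometry$ellipsoid) && length(sdds))
    depth <- apply(pts, 1L, function(p)
      ellipsoid_distance(mesh$geometry$ellipsoid, p))
  structure(list(
    source = source, orientation = orientation,
    detectors = data.frame(sdd = sdds,
                           x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           depth_to_intestine = depth)
  ), class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("Sensor layout (%s): source at (%.2f, %.2f, %.2f) cm, %d detectors\n",
              x$orientation, x$source[1], x$source[2], x$source[3],
              nrow(x$detectors)))
  if (nrow(x$detectors)) print(x$detectors, row.names = FALSE)
  invisible(x)
}

# project a point onto the boundary surface: nearest boundary node, then the
# closest point on its incident facets
snap_to_surface <- function(mesh, p) {
  bn <- unique(as.vector(mesh$boundary))
  d2 <- (mesh$nodes[bn, 1] - p[1])^2 + (mesh$nodes[bn, 2] - p[2])^2 +
    (mesh$nodes[bn, 3] - p[3])^2
  n0 <- bn[which.min(d2)]
  fac <- which(mesh$boundary[, 1] == n0 | mesh$boundary[, 2] == n0 |
                 mesh$boundary[, 3] == n0)
  best <- mesh$nodes[n0, ]; bd <- sum((best - p)^2)
  for (f in fac) {
    tri <- mesh$nodes[mesh$boundary[f, ], , drop = FALSE]
    q <- project_triangle(p, tri)
    dq <- sum((q - p)^2)
    if (dq < bd) { best <- q; bd <- dq }
  }
  as.numeric(best)
}

# closest point on triangle (rows of `tri`) to p
project_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c_ <- tri[3, ]
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c_; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c_)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c_ - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}
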
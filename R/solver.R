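#' Assemble the CW photon diffusion system
#'
#' First-order (P1) finite-element discretization of
#' `-div(D grad phi) + mua phi = S` on a labeled tetrahedral mesh with the
#' Robin (partial-flux) boundary condition `phi + zb n.grad(phi) = 0` applied
#' on every exterior facet, realized as the weak-form boundary term
#' `(D/zb) phi v` with the local boundary tissue's `D` and `zb`. Absorption
#' and boundary mass terms are lumped. When the mesh was built with the
#' collapsed-epidermis option, the epidermal sheet enters as an equivalent
#' surface absorption film `mua_epi * t_epi * phi v` on the skin facets.
#'
#' @param mesh a [labeled_mesh()].
#' @param props an [optical_props()] table covering every label present.
#' @return list with the symmetric sparse system matrix `A`, the lumped
#'   volume weights `lumped_volume` (cm^3 per node), and bookkeeping used by
#'   the source and readout helpers.
#' @export
assemble_diffusion <- function(mesh, props) {
  stopifnot(inherits(mesh, "labeled_mesh"), inherits(props, "optical_props"))
  present <- sort(unique(mesh$tissue))
  tl <- mesh$tissue_levels[present]
  pr <- props_row(props, tl)            # errors on missing tissue
  mua_by <- musp_by <- D_by <- zb_by <- rep(NA_real_,
                                            length(mesh$tissue_levels))
  mua_by[present] <- pr$mua; musp_by[present] <- pr$musp
  D_by[present] <- pr$D; zb_by[present] <- pr$zb

  el <- mesh$elems
  nd <- mesh$nodes
  n <- nrow(nd)
  a <- nd[el[, 1L], , drop = FALSE]
  e1 <- nd[el[, 2L], , drop = FALSE] - a
  e2 <- nd[el[, 3L], , drop = FALSE] - a
  e3 <- nd[el[, 4L], , drop = FALSE] - a
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cross3(e2, e3); c31 <- cross3(e3, e1); c12 <- cross3(e1, e2)
  det <- rowSums(e1 * c23)              # 6 * volume, positive by construction
  V <- det / 6
  g <- vector("list", 4L)               # basis-function gradients, m x 3 each
  g[[2L]] <- c23 / det; g[[3L]] <- c31 / det; g[[4L]] <- c12 / det
  g[[1L]] <- -(g[[2L]] + g[[3L]] + g[[4L]])

  rm(a, e1, e2, e3, c23, c31, c12)
  De <- D_by[mesh$tissue]
  mue <- mua_by[mesh$tissue]
  m <- nrow(el)
  # upper-triangle triplets only (the matrix is symmetric)
  ii <- jj <- xx <- list()
  k <- 0L
  for (i in 1:4) for (j in i:4) {
    k <- k + 1L
    kij <- De * V * rowSums(g[[i]] * g[[j]])
    if (i == j) {
      ii[[k]] <- el[, i]; jj[[k]] <- el[, j]
      # lumped absorption mass joins the diagonal: mua * V / 4 per vertex
      xx[[k]] <- kij + mue * V / 4
    } else {
      ii[[k]] <- pmin.int(el[, i], el[, j])
      jj[[k]] <- pmax.int(el[, i], el[, j])
      xx[[k]] <- kij
    }
  }
  rm(g)

  # Robin boundary term, lumped: (D/zb) * area / 3 per facet vertex
  bf <- mesh$boundary
  bt <- mesh$tissue[mesh$boundary_elem]
  p1 <- nd[bf[, 1L], , drop = FALSE]
  u <- nd[bf[, 2L], , drop = FALSE] - p1
  v <- nd[bf[, 3L], , drop = FALSE] - p1
  area <- 0.5 * sqrt(rowSums(cross3(u, v)^2))
  robin <- D_by[bt] / zb_by[bt]
  film <- numeric(nrow(bf))
  gm <- mesh$geometry
  if (!is.null(gm$epidermis_mode) && gm$epidermis_mode == "collapsed") {
    epi <- props_row(props, "epidermis")
    cz <- (p1[, 3] + nd[bf[, 2L], 3] + nd[bf[, 3L], 3]) / 3
    top <- cz < 1e-9
    film[top] <- epi$mua * gm$params$epidermis_thickness
  }
  for (i in 1:3) {
    ii <- c(ii, list(bf[, i])); jj <- c(jj, list(bf[, i]))
    xx <- c(xx, list((robin + film) * area / 3))
  }

  iv <- unlist(ii); jv <- unlist(jj); xv <- unlist(xx)
  rm(ii, jj, xx)
  A <- Matrix::sparseMatrix(i = iv, j = jv, x = xv, dims = c(n, n),
                            symmetric = TRUE)
  rm(iv, jv, xv)
  lumped <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(el), j = rep(1L, 4L * m), x = rep(V / 4, 4L),
    dims = c(n, 1L)))
  list(A = A, lumped_volume = lumped,
       mua_by = mua_by, musp_by = musp_by, props = props, n = n)
}

#' Isotropic point source buried one transport mean free path deep
#'
#' Places the equivalent isotropic source of a pencil beam entering at a
#' surface point: the entry point is snapped to the boundary and the source
#' position `r_s` is one local transport mean free path `ltr = 1/musp`
#' beneath it along the inward surface normal. By default the delta source is
#' discretized as a nodal load at the mesh node nearest `r_s` (the meshes
#' built by this package carry a grid plane at that depth); alternatively a
#' narrow Gaussian of width `ltr/2` can be used.
#'
#' @param mesh a [labeled_mesh()].
#' @param props an [optical_props()] table (for the local `ltr`).
#' @param entry surface entry point (length-3, cm) or a `sensor_layout` whose
#'   source is used.
#' @param S0 source power (W).
#' @param mollify `"delta"` or `"gaussian"`.
#' @return object of class `point_source`.
#' @export
point_source <- function(mesh, props, entry, S0 = 1,
                         mollify = c("delta", "gaussian")) {
  mollify <- match.arg(mollify)
  if (inherits(entry, "sensor_layout")) entry <- entry$source
  stopifnot(is.numeric(entry), length(entry) == 3L, S0 >= 0)
  entry <- snap_to_surface(mesh, entry)
  # local boundary tissue at the entry: owner of the nearest boundary facet
  bn <- unique(as.vector(mesh$boundary))
  d2 <- colSums((t(mesh$nodes[bn, , drop = FALSE]) - entry)^2)
  n0 <- bn[which.min(d2)]
  fac <- which(mesh$boundary[, 1] == n0 | mesh$boundary[, 2] == n0 |
                 mesh$boundary[, 3] == n0)
  own <- mesh$boundary_elem[fac[1L]]
  tis <- mesh$tissue_levels[mesh$tissue[own]]
  ltr <- props_row(props, tis)$ltr
  # inward normal averaged over the facets incident to the nearest node
  nrm <- c(0, 0, 0)
  for (f in fac) {
    tri <- mesh$nodes[mesh$boundary[f, ], , drop = FALSE]
    fn <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
              (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
            (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
              (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
            (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
              (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
    ec <- colMeans(mesh$nodes[mesh$elems[mesh$boundary_elem[f], ], ])
    if (sum(fn * (ec - colMeans(tri))) < 0) fn <- -fn
    nrm <- nrm + fn / sqrt(sum(fn^2))
  }
  nrm <- nrm / sqrt(sum(nrm^2))
  r_s <- unname(entry + ltr * nrm)
  entry <- unname(entry)
  d2n <- colSums((t(mesh$nodes) - r_s)^2)
  node <- which.min(d2n)
  off <- sqrt(d2n[node])
  if (off > ltr / 4 + 1e-12)
    warning(sprintf(paste0("nearest mesh node is %.4f cm from the buried ",
                           "source position (> ltr/4 = %.4f cm); refine the ",
                           "mesh near the source"), off, ltr / 4),
            call. = FALSE)
  structure(list(entry = entry, r_s = r_s, node = node, S0 = S0,
                 ltr = ltr, tissue = tis, mollify = mollify,
                 sigma = ltr / 2),
            class = "point_source")
}

source_load <- function(sys, mesh, src) {
  b <- numeric(sys$n)
  if (src$S0 == 0) return(b)
  if (src$mollify == "delta") {
    b[src$node] <- src$S0
  } else {
    d2 <- colSums((t(mesh$nodes) - src$r_s)^2)
    w <- sys$lumped_volume * exp(-d2 / (2 * src$sigma^2))
    b <- src$S0 * w / sum(w)
  }
  b
}

#' Solve the diffusion system for one or more point sources
#'
#' Assembles (or reuses) the finite-element system, factors it once with a
#' sparse Cholesky decomposition, and solves for every source. The system is
#' symmetric positive definite; the factorization is shared across sources,
#' so multi-source studies cost one factorization plus cheap triangular
#' solves.
#'
#' @param mesh a [labeled_mesh()].
#' @param props an [optical_props()] table.
#' @param source a [point_source()] (or list of them), a `sensor_layout`, or
#'   a length-3 surface point.
#' @param rtol maximum admissible relative residual of the linear solve.
#' @param system optional pre-assembled system from [assemble_diffusion()].
#' @return a `fluence_field` (or list of them when `source` is a list):
#'   nodal fluence values (W/cm^2), the mesh and source, and solver
#'   diagnostics.
#' @export
solve_fluence <- function(mesh, props, source, rtol = 1e-10, system = NULL) {
  sys <- if (is.null(system)) assemble_diffusion(mesh, props) else system
  many <- is.list(source) && !inherits(source, "point_source") &&
    !inherits(source, "sensor_layout")
  srcs <- if (many) source else list(source)
  srcs <- lapply(srcs, function(s) {
    if (inherits(s, "point_source")) s else point_source(mesh, props, s)
  })
  ch <- Matrix::Cholesky(sys$A, LDL = FALSE, perm = TRUE, super = TRUE)
  fields <- lapply(srcs, function(src) {
    b <- source_load(sys, mesh, src)
    phi <- as.numeric(Matrix::solve(ch, b, system = "A"))
    nb <- sqrt(sum(b^2))
    res <- if (nb > 0) {
      r <- b - as.numeric(sys$A %*% phi)
      sqrt(sum(r^2)) / nb
    } else 0
    if (res > rtol) {
      # one step of iterative refinement before giving up
      phi <- phi + as.numeric(Matrix::solve(ch, b - sys$A %*% phi,
                                            system = "A"))
      r <- b - as.numeric(sys$A %*% phi)
      res <- sqrt(sum(r^2)) / nb
      if (res > rtol)
        stop(sprintf(paste0("linear solve did not reach rtol = %.1e ",
                            "(relative residual %.2e, n = %d); the system ",
                            "may be ill-conditioned"), rtol, res, sys$n))
    }
    structure(list(values = phi, mesh = mesh, source = src, props = props,
                   diagnostics = list(residual = res, n_nodes = sys$n,
                                      min_value = min(phi),
                                      max_value = max(phi))),
              class = "fluence_field")
  })
  if (many) fields else fields[[1L]]
}

#' @export
print.fluence_field <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("Fluence field: %d nodes, max %.3e W/cm^2, ",
                     "relative residual %.1e\n"),
              d$n_nodes, d$max_value, d$residual))
  invisible(x)
}

#' Interpolate a fluence field at arbitrary points
#'
#' Locates the tetrahedron containing each query point (with a small
#' tolerance so surface points on facets are accepted) and evaluates the P1
#' shape functions, so a point coincident with a mesh node returns the nodal
#' value exactly.
#'
#' @param field a `fluence_field`.
#' @param pts k x 3 matrix of points (cm).
#' @return numeric vector of fluence values (W/cm^2).
#' @export
interp_field <- function(field, pts) {
  mesh <- field$mesh
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  el <- mesh$elems; nd <- mesh$nodes
  x1 <- nd[el[, 1], 1]; x2 <- nd[el[, 2], 1]
  x3 <- nd[el[, 3], 1]; x4 <- nd[el[, 4], 1]
  y1 <- nd[el[, 1], 2]; y2 <- nd[el[, 2], 2]
  y3 <- nd[el[, 3], 2]; y4 <- nd[el[, 4], 2]
  z1 <- nd[el[, 1], 3]; z2 <- nd[el[, 2], 3]
  z3 <- nd[el[, 3], 3]; z4 <- nd[el[, 4], 3]
  xmin <- pmin(x1, x2, x3, x4); xmax <- pmax(x1, x2, x3, x4)
  ymin <- pmin(y1, y2, y3, y4); ymax <- pmax(y1, y2, y3, y4)
  zmin <- pmin(z1, z2, z3, z4); zmax <- pmax(z1, z2, z3, z4)
  out <- rep(NA_real_, nrow(pts))
  tol <- 1e-9
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    cand <- which(p[1] >= xmin - tol & p[1] <= xmax + tol &
                    p[2] >= ymin - tol & p[2] <= ymax + tol &
                    p[3] >= zmin - tol & p[3] <= zmax + tol)
    best <- NA_real_; best_neg <- -Inf
    for (e in cand) {
      vid <- el[e, ]
      M <- t(nd[vid[2:4], , drop = FALSE]) - nd[vid[1], ]
      lam <- try(solve(M, p - nd[vid[1], ]), silent = TRUE)
      if (inherits(lam, "try-error")) next
      l <- c(1 - sum(lam), lam)
      mn <- min(l)
      if (mn > best_neg) {
        best_neg <- mn
        best <- sum(l * field$values[vid])
      }
      if (mn >= -1e-8) break
    }
    if (best_neg < -1e-6)
      stop(sprintf("point (%.3f, %.3f, %.3f) lies outside the mesh",
                   p[1], p[2], p[3]))
    out[q] <- best
  }
  out
}

#' Detector readout table
#'
#' Evaluates a solved fluence field at the detector points of a sensor
#' layout.
#'
#' @param field a `fluence_field` from [solve_fluence()].
#' @param layout a [place_sensor()] layout on the same mesh.
#' @return data frame with columns `sdd` (cm), `fluence` (W/cm^2) and the
#'   detector coordinates, ordered by SDD.
#' @export
read_detectors <- function(field, layout) {
  stopifnot(inherits(field, "fluence_field"),
            inherits(layout, "sensor_layout"))
  det <- layout$detectors
  if (!nrow(det))
    return(data.frame(sdd = numeric(), fluence = numeric(),
                      x = numeric(), y = numeric(), z = numeric()))
  phi <- interp_field(field, as.matrix(det[, c("x", "y", "z")]))
  data.frame(sdd = det$sdd, fluence = phi, x = det$x, y = det$y, z = det$z)
}

#' Closed-form fluence in a homogeneous semi-infinite medium
#'
#' Extrapolated-boundary dipole solution for a CW point source of power `S0`
#' buried at depth `ltr = 1/musp` beneath the surface of a homogeneous
#' half-space:
#' `phi(rho) = S0/(4 pi D) (exp(-mueff r1)/r1 - exp(-mueff r2)/r2)` with
#' `r1 = sqrt(rho^2 + ltr^2)`, `r2 = sqrt(rho^2 + (ltr + 2 zb)^2)` and
#' `mueff = sqrt(mua/D)`. Used as the independent validation oracle for the
#' finite-element solver.
#'
#' @param sdd source-detector distance(s) rho along the surface (cm).
#' @param mua,musp absorption and reduced scattering (cm^-1).
#' @param Reff effective Fresnel reflectance.
#' @param S0 source power (W).
#' @return fluence rate (W/cm^2).
#' @export
semi_infinite_fluence <- function(sdd, mua, musp, Reff = 0.493, S0 = 1) {
  stopifnot(mua > 0, musp > 0, all(sdd > 0))
  D <- 1 / (3 * (mua + musp))
  ltr <- 1 / musp
  zb <- 2 * ltr * (1 + Reff) / (3 * (1 - Reff))
  mueff <- sqrt(mua / D)
  r1 <- sqrt(sdd^2 + ltr^2)
  r2 <- sqrt(sdd^2 + (ltr + 2 * zb)^2)
  S0 / (4 * pi * D) * (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2)
}

#' Exact partial-current half-space fluence (Hankel transform)
#'
#' Surface fluence of a CW point source buried at `ltr` in a homogeneous
#' half-space under the exact partial-current (Robin) boundary condition
#' `phi = zb d(phi)/dz` at the surface, evaluated by numerical Hankel
#' inversion:
#' `phi(rho, 0) = 1/(2 pi D) Int q J0(q rho) exp(-k ltr) zb/(zb k + 1) dq`
#' with `k = sqrt(q^2 + mueff^2)`.
#'
#' This is the boundary-condition model the finite-element solver
#' discretizes, so it is the sharp reference for solver accuracy. The
#' extrapolated-boundary dipole of [semi_infinite_fluence()] approximates it;
#' the two differ by several percent at short distances, most visibly for
#' weakly scattering media.
#'
#' @inheritParams semi_infinite_fluence
#' @return fluence rate (W/cm^2).
#' @export
robin_halfspace_fluence <- function(sdd, mua, musp, Reff = 0.493, S0 = 1) {
  stopifnot(mua > 0, musp > 0, all(sdd > 0))
  layered_halfspace_fluence(sdd, mua, musp, numeric(0), Reff = Reff, S0 = S0)
}
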
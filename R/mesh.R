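#' Tensor-product tetrahedral grid
#'
#' Builds a conforming tetrahedral mesh on the tensor grid defined by three
#' strictly increasing coordinate vectors. Each hexahedral cell is split into
#' six tetrahedra with the Kuhn (Freudenthal) decomposition, which is
#' translation invariant and therefore conforming across cells.
#'
#' @param x,y,z strictly increasing coordinate vectors (cm).
#' @return list with `nodes` (n x 3 matrix, cm) and `elems` (m x 4 integer
#'   matrix of node indices, positively oriented).
#' @keywords internal
tet_grid <- function(x, y, z) {
  stopifnot(length(x) >= 2, length(y) >= 2, length(z) >= 2,
            all(diff(x) > 0), all(diff(y) > 0), all(diff(z) > 0))
  nx <- length(x); ny <- length(y); nz <- length(z)
  nodes <- cbind(
    x = rep(x, times = ny * nz),
    y = rep(rep(y, each = nx), times = nz),
    z = rep(z, each = nx * ny)
  )
  idx <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * (nx * ny)
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  # hex corners indexed by (dx, dy, dz) bit offsets
  corner <- function(dx, dy, dz) idx(ci + dx, cj + dy, ck + dz)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  # Kuhn split: one tet per permutation of the axes, shared diagonal c000-c111
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111)
  )
  storage.mode(tets) <- "integer"
  # enforce positive orientation (det of edge matrix > 0)
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(2L, 3L)] <- tets[neg, c(3L, 2L)]
  list(nodes = nodes, elems = tets)
}

#' Signed tetrahedron volumes
#' @keywords internal
tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 1L], , drop = FALSE]
  e1 <- nodes[elems[, 2L], , drop = FALSE] - a
  e2 <- nodes[elems[, 3L], , drop = FALSE] - a
  e3 <- nodes[elems[, 4L], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Extract boundary faces of a tetrahedral mesh
#'
#' A face is on the boundary iff it belongs to exactly one tetrahedron.
#'
#' @return list with `faces` (f x 3 integer matrix) and `elem` (owning element
#'   index for each face).
#' @keywords internal
boundary_faces <- function(elems) {
  m <- nrow(elems)
  # the 4 faces of each tet (local vertex triples)
  loc <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  faces <- rbind(elems[, loc[1L, ]], elems[, loc[2L, ]],
                 elems[, loc[3L, ]], elems[, loc[4L, ]])
  owner <- rep.int(seq_len(m), 4L)
  lo <- pmin.int(faces[, 1L], faces[, 2L], faces[, 3L])
  hi <- pmax.int(faces[, 1L], faces[, 2L], faces[, 3L])
  key <- cbind(lo, faces[, 1L] + faces[, 2L] + faces[, 3L] - lo - hi, hi)
  # radix order on the three sorted columns; unmatched rows are boundary
  o <- order(key[, 1L], key[, 2L], key[, 3L], method = "radix")
  k <- key[o, , drop = FALSE]
  same_next <- c(rowSums(k[-nrow(k), , drop = FALSE] ==
                           k[-1L, , drop = FALSE]) == 3L, FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  bnd <- !(same_next | same_prev)
  sel <- o[bnd]
  list(faces = faces[sel, , drop = FALSE], elem = owner[sel])
}

#' Labeled tetrahedral mesh
#'
#' Container for a tetrahedral mesh with one tissue label per cell and the
#' extracted air-tissue boundary. Coordinates are in cm; `z` is depth beneath
#' the skin surface (z = 0 at the surface, increasing into the tissue).
#'
#' @param nodes n x 3 numeric matrix of node coordinates (cm).
#' @param elems m x 4 integer matrix of tetrahedra (node indices).
#' @param tissue integer vector of length m indexing `tissue_levels`, or a
#'   character vector of per-cell tissue names.
#' @param tissue_levels character vector naming the tissue labels.
#' @param geometry optional list of geometric metadata (e.g. the ellipsoid
#'   parameters of the intestinal region) used by [place_sensor()].
#' @return object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(nodes, elems, tissue, tissue_levels = NULL,
                         geometry = NULL) {
  if (is.character(tissue)) {
    if (is.null(tissue_levels)) tissue_levels <- unique(tissue)
    tissue <- match(tissue, tissue_levels)
  }
  if (is.null(tissue_levels))
    stop("tissue_levels required when tissue is given as integer codes")
  tissue <- as.integer(tissue)
  if (length(tissue) != nrow(elems))
    stop("need exactly one tissue label per cell")
  if (anyNA(tissue) || any(tissue < 1L) || any(tissue > length(tissue_levels)))
    stop("tissue labels outside tissue_levels")
  vol <- tet_volumes(nodes, elems)
  if (any(vol <= 0)) stop("mesh contains inverted or zero-volume cells")
  bnd <- boundary_faces(elems)
  structure(list(
    nodes = nodes, elems = elems, tissue = tissue,
    tissue_levels = tissue_levels, volumes = vol,
    boundary = bnd$faces, boundary_elem = bnd$elem,
    units = "cm", geometry = geometry
  ), class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("Labeled tetrahedral mesh (cm)\n")
  cat(sprintf("  nodes: %d, cells: %d, boundary facets: %d\n",
              nrow(x$nodes), nrow(x$elems), nrow(x$boundary)))
  v <- tapply(x$volumes, x$tissue_levels[x$tissue], sum)
  for (nm in names(v))
    cat(sprintf("  %-10s %10.3f cm^3\n", nm, v[[nm]]))
  invisible(x)
}

#' Per-label tissue volumes
#' @param mesh a [labeled_mesh()].
#' @return named numeric vector of volumes (cm^3), one entry per label present.
#' @export
label_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  out <- tapply(mesh$volumes, factor(mesh$tissue_levels[mesh$tissue],
                                     levels = mesh$tissue_levels), sum)
  out[is.na(out)] <- 0
  out
}

#' Graded coordinate axis
#'
#' Uniform spacing `h` on the core interval, geometrically growing cells
#' (ratio `ratio`) towards the domain ends, with optional feature coordinates
#' inserted exactly (nearby regular points are dropped to keep spacing sane).
#'
#' @keywords internal
graded_axis <- function(lo, hi, core_lo, core_hi, h, ratio = 1.4,
                        features = numeric()) {
  stopifnot(lo <= core_lo, core_lo < core_hi, core_hi <= hi, h > 0, ratio > 1)
  n <- max(1L, round((core_hi - core_lo) / h))
  pts <- seq(core_lo, core_hi, length.out = n + 1L)
  step <- h
  p <- core_hi
  while (p < hi - 1e-12) {
    step <- step * ratio
    p <- min(p + step, hi)
    pts <- c(pts, p)
  }
  step <- h
  p <- core_lo
  left <- numeric()
  while (p > lo + 1e-12) {
    step <- step * ratio
    p <- max(p - step, lo)
    left <- c(p, left)
  }
  pts <- c(left, pts)
  features <- features[features > lo + 1e-12 & features < hi - 1e-12]
  if (length(features)) {
    for (f in features) {
      d <- abs(pts - f)
      # drop regular points crowding the feature, then insert it exactly
      near <- d < 0.35 * h & abs(pts - lo) > 1e-12 & abs(pts - hi) > 1e-12
      if (any(near) && min(d) > 1e-12) pts <- pts[!near]
      pts <- c(pts, f)
    }
  }
  sort(unique(round(pts, 10)))
}
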
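#' Write a labeled mesh in legacy VTK format
#'
#' ASCII legacy VTK unstructured grid with the tissue label as integer cell
#' data field `tissue_id` and, optionally, a nodal field (e.g. a solved
#' fluence) as point data `fluence_W_per_cm2`. A JSON sidecar mapping label
#' ids to tissue names is written alongside.
#'
#' @param mesh a [labeled_mesh()].
#' @param file output `.vtk` path.
#' @param point_data optional numeric vector (one value per node).
#' @param point_data_name name of the point data field.
#' @param label_map write the `<file>.labels.json` sidecar.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = NULL,
                           point_data_name = "fluence_W_per_cm2",
                           label_map = TRUE) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "labeled tetrahedral mesh (cm)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS tissue_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$tissue), con)
  if (!is.null(point_data)) {
    stopifnot(length(point_data) == n)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 sprintf("SCALARS %s double 1", point_data_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(point_data, digits = 10, trim = TRUE), con)
  }
  if (label_map) write_label_map(mesh, paste0(file, ".labels.json"))
  invisible(file)
}

write_label_map <- function(mesh, path) {
  jsonlite::write_json(
    as.list(stats::setNames(seq_along(mesh$tissue_levels),
                            mesh$tissue_levels)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a labeled mesh in Gmsh MSH 2.2 ASCII format
#'
#' Tetrahedra are written as element type 4 with the tissue label id as both
#' physical and geometrical tag; a JSON label-map sidecar accompanies the
#' file.
#'
#' @param mesh a [labeled_mesh()].
#' @param file output `.msh` path.
#' @param label_map write the `<file>.labels.json` sidecar.
#' @export
write_mesh_msh <- function(mesh, file, label_map = TRUE) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  utils::write.table(cbind(seq_len(n),
                           format(mesh$nodes, digits = 10, trim = TRUE,
                                  scientific = FALSE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c("$EndNodes", "$Elements", as.character(m)), con)
  utils::write.table(cbind(seq_len(m), 4L, 2L, mesh$tissue, mesh$tissue,
                           mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndElements", con)
  if (label_map) write_label_map(mesh, paste0(file, ".labels.json"))
  invisible(file)
}

#' Read a labeled tetrahedral mesh from Gmsh MSH 2.2 ASCII
#'
#' Reads nodes and type-4 (tetrahedral) elements; the first element tag
#' (physical group) becomes the tissue id. Tissue names are taken from the
#' `<file>.labels.json` sidecar when present, otherwise labels are named
#' `tissue_<id>`.
#'
#' @param file `.msh` path.
#' @param tissue_levels optional character vector naming the label ids.
#' @return a [labeled_mesh()].
#' @export
read_mesh_msh <- function(file, tissue_levels = NULL) {
  lines <- readLines(file)
  sec <- function(tag) {
    i <- match(paste0("$", tag), lines)
    j <- match(paste0("$End", tag), lines)
    if (is.na(i) || is.na(j)) stop(sprintf("section $%s not found", tag))
    lines[(i + 2L):(j - 1L)]
  }
  nd <- utils::read.table(text = sec("Nodes"))
  nodes <- as.matrix(nd[order(nd[[1]]), 2:4])
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  el <- utils::read.table(text = sec("Elements"), fill = TRUE)
  el <- el[el[[2]] == 4L, , drop = FALSE]
  if (!nrow(el)) stop("no tetrahedral (type 4) elements in file")
  ntags <- el[[3]]
  if (length(unique(ntags)) != 1L)
    stop("mixed tag counts are not supported")
  k <- 3L + ntags[1L]
  tissue <- as.integer(el[[4]])
  elems <- as.matrix(el[, (k + 1L):(k + 4L)])
  storage.mode(elems) <- "integer"
  if (is.null(tissue_levels)) {
    side <- paste0(file, ".labels.json")
    if (file.exists(side)) {
      lm <- jsonlite::read_json(side)
      tissue_levels <- character(max(unlist(lm)))
      for (nm in names(lm)) tissue_levels[lm[[nm]]] <- nm
    } else {
      tissue_levels <- paste0("tissue_", seq_len(max(tissue)))
    }
  }
  # re-orient if needed (writers are not required to orient positively)
  v <- tet_volumes(nodes, elems)
  neg <- v < 0
  if (any(neg)) elems[neg, c(2L, 3L)] <- elems[neg, c(3L, 2L)]
  labeled_mesh(nodes, elems, tissue, tissue_levels)
}

#' Export a fluence field with its mesh as VTK
#' @param field a `fluence_field`.
#' @param file output `.vtk` path.
#' @export
write_fluence_vtk <- function(field, file) {
  stopifnot(inherits(field, "fluence_field"))
  write_mesh_vtk(field$mesh, file, point_data = field$values)
}
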
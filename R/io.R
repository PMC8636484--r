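# Writers for the standard interchange formats: legacy VTK (unstructured
# quads), Gmsh MSH 2.2 ASCII, CSV. All text; all cell data on active cells.

mesh_nodes_cells <- function(mesh) {
  # dedup corner nodes of active cells
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h
  idx <- which(mesh$active)
  ii <- ((idx - 1L) %% nx) + 1L
  jj <- ((idx - 1L) %/% nx) + 1L
  corner_key <- function(ci, cj) (cj - 1L) * (nx + 1L) + ci  # 1-based corners
  k1 <- corner_key(ii, jj); k2 <- corner_key(ii + 1L, jj)
  k3 <- corner_key(ii + 1L, jj + 1L); k4 <- corner_key(ii, jj + 1L)
  keys <- sort(unique(c(k1, k2, k3, k4)))
  remap <- integer(max(keys)); remap[keys] <- seq_along(keys)
  ci <- ((keys - 1L) %% (nx + 1L)) + 1L
  cj <- ((keys - 1L) %/% (nx + 1L)) + 1L
  list(
    nodes = cbind(mesh$x0 + (ci - 1L) * h, mesh$y0 + (cj - 1L) * h),
    quads = cbind(remap[k1], remap[k2], remap[k3], remap[k4]),
    cell_ii = ii, cell_jj = jj
  )
}

#' Export a mesh to legacy VTK
#'
#' Unstructured-grid ASCII file of the active quad cells.
#'
#' @param mesh A `flow_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  mc <- mesh_nodes_cells(mesh)
  np <- nrow(mc$nodes); nc <- nrow(mc$quads)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "carinaflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  utils::write.table(cbind(mc$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nc, 5L * nc), con)
  utils::write.table(cbind(4L, mc$quads - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(rep("9", nc), con)
  invisible(path)
}

#' Export a flow field to legacy VTK
#'
#' Same grid as [write_mesh_vtk()] plus cell data arrays `velocity` (m/s,
#' 3-component with zero z) and `pressure` (Pa).
#'
#' @param field A `flow_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  mesh <- field$mesh
  write_mesh_vtk(mesh, path)
  mc <- mesh_nodes_cells(mesh)
  uc <- 0.5 * (field$u[cbind(mc$cell_ii, mc$cell_jj)] +
                 field$u[cbind(mc$cell_ii + 1L, mc$cell_jj)])
  vc <- 0.5 * (field$v[cbind(mc$cell_ii, mc$cell_jj)] +
                 field$v[cbind(mc$cell_ii, mc$cell_jj + 1L)])
  pc <- field$p[cbind(mc$cell_ii, mc$cell_jj)]
  con <- file(path, "a"); on.exit(close(con))
  writeLines(sprintf("CELL_DATA %d", length(uc)), con)
  writeLines("VECTORS velocity double", con)
  utils::write.table(cbind(uc, vc, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines("SCALARS pressure double 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(format(pc, digits = 12, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}

#' Export a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Quad elements plus tagged boundary line elements (physical tags: 1 inlet,
#' 2 outlet_1, 3 outlet_2, 4 wall).
#'
#' @param mesh A `flow_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  mc <- mesh_nodes_cells(mesh)
  np <- nrow(mc$nodes); nq <- nrow(mc$quads)
  nx <- mesh$nx

  # boundary line elements from tagged faces (u faces are vertical lines)
  phys <- c(`3` = 1L, `4` = 2L, `5` = 3L, `2` = 4L)  # face code -> physical tag
  lines <- list()
  corner_key <- function(ci, cj) (cj - 1L) * (nx + 1L) + ci
  uidx <- which(mesh$uType %in% c(2L, 3L, 4L, 5L))
  if (length(uidx)) {
    ii <- ((uidx - 1L) %% (nx + 1L)) + 1L
    jj <- ((uidx - 1L) %/% (nx + 1L)) + 1L
    lines$u <- cbind(corner_key(ii, jj), corner_key(ii, jj + 1L),
                     phys[as.character(mesh$uType[uidx])])
  }
  vidx <- which(mesh$vType %in% c(2L, 3L, 4L, 5L))
  if (length(vidx)) {
    ii <- ((vidx - 1L) %% nx) + 1L
    jj <- ((vidx - 1L) %/% nx) + 1L
    lines$v <- cbind(corner_key(ii, jj), corner_key(ii + 1L, jj),
                     phys[as.character(mesh$vType[vidx])])
  }
  lin <- do.call(rbind, lines)
  # remap corner keys to node ids; drop lines touching corners of no active cell
  allkeys <- sort(unique(c(corner_key(mc$cell_ii, mc$cell_jj),
                           corner_key(mc$cell_ii + 1L, mc$cell_jj),
                           corner_key(mc$cell_ii + 1L, mc$cell_jj + 1L),
                           corner_key(mc$cell_ii, mc$cell_jj + 1L))))
  remap <- integer(max(allkeys, lin[, 1:2]))
  remap[allkeys] <- seq_along(allkeys)
  ok <- remap[lin[, 1]] > 0 & remap[lin[, 2]] > 0
  lin <- lin[ok, , drop = FALSE]

  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", as.character(np)), con)
  utils::write.table(cbind(seq_len(np), mc$nodes, 0), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines("$EndNodes", con)
  ne <- nrow(lin) + nq
  writeLines(c("$Elements", as.character(ne)), con)
  eid <- 0L
  if (nrow(lin)) {
    utils::write.table(cbind(seq_len(nrow(lin)), 1L, 2L, lin[, 3], lin[, 3],
                             remap[lin[, 1]], remap[lin[, 2]]),
                       con, row.names = FALSE, col.names = FALSE)
    eid <- nrow(lin)
  }
  utils::write.table(cbind(eid + seq_len(nq), 3L, 2L, 0L, 0L, mc$quads),
                     con, row.names = FALSE, col.names = FALSE)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export stored trajectories as CSV
#'
#' Columns: `particle_id`, `t`, `x`, `y`, `u`, `v`, `status`.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(ensemble, path) {
  p <- ensemble$paths
  st <- ensemble$summary$status[match(p$particle_id,
                                      ensemble$summary$particle_id)]
  utils::write.csv(dplyr::mutate(p, status = st), path, row.names = FALSE)
  invisible(path)
}
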
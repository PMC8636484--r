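# Face type codes shared with the C++ kernels:
#   0 external, 1 interior, 2 wall (no-slip, value 0), 3 inlet (Dirichlet
#   profile), 4 outlet_1, 5 outlet_2 (zero-gradient velocity, p = 0 ghost).
FACE_EXTERNAL <- 0L; FACE_INTERIOR <- 1L; FACE_WALL <- 2L
FACE_INLET <- 3L; FACE_OUTLET1 <- 4L; FACE_OUTLET2 <- 5L

#' Discretise a geometry on a masked Cartesian staggered grid
#'
#' The fluid domain is embedded in a uniform marker-and-cell (MAC) grid:
#' pressure at cell centres, velocity components on cell faces. Cells whose
#' centre falls inside the outline polygon are active; boundary faces between
#' active and inactive cells are tagged `wall`, `inlet`, `outlet_1` or
#' `outlet_2` by nearest boundary feature. The grid spacing is snapped so that
#' an integer (even) number of cells spans the calibre, which puts the parent
#' walls and the inlet plane exactly on grid faces and keeps the grid
#' mirror-symmetric about the bifurcation axis.
#'
#' Walls that are oblique to the grid (the daughter branches) are represented
#' by a staircase of cell faces; the signed-distance field stored with the
#' mesh is computed from the exact outline polygon, so particle-wall proximity
#' checks do not inherit the staircase error.
#'
#' @param geometry A [bifurcation_geometry] (or [straight_channel]).
#' @param target_cell_size Requested cell size in m; must not exceed
#'   `calibre / 10`.
#' @param wall_layers Accepted for protocol compatibility with boundary-layer
#'   meshers and recorded in the mesh metadata; the uniform Cartesian grid has
#'   no prism layers, so the value does not alter the discretisation.
#' @return An object of class `flow_mesh`.
#' @examples
#' msh <- generate_mesh(bifurcation_geometry(90), target_cell_size = 2e-4)
#' msh$n_active
#' @export
generate_mesh <- function(geometry, target_cell_size, wall_layers = 0L) {
  stopifnot(inherits(geometry, "bifurcation_geometry"))
  w <- geometry$calibre
  if (!is.numeric(target_cell_size) || target_cell_size <= 0)
    stop("target_cell_size must be positive", call. = FALSE)
  if (target_cell_size > w / 10)
    stop("target_cell_size must be at most calibre / 10", call. = FALSE)

  n_across <- max(10L, as.integer(round(w / target_cell_size)))
  if (n_across %% 2L == 1L) n_across <- n_across + 1L
  h <- w / n_across

  out <- geometry$outline
  x0 <- geometry$inlet$x
  xmax <- max(out[, 1])
  nx <- as.integer(ceiling((xmax - x0) / h - 1e-9))
  ymax <- max(abs(out[, 2]))
  ny2 <- as.integer(ceiling(ymax / h - 1e-9))
  ny <- 2L * ny2
  y0 <- -ny2 * h

  xc <- x0 + (seq_len(nx) - 0.5) * h
  yc <- y0 + (seq_len(ny) - 0.5) * h
  PX <- matrix(rep(xc, times = ny), nx, ny)
  PY <- matrix(rep(yc, each = nx), nx, ny)
  act <- matrix(points_in_polygon(as.vector(PX), as.vector(PY), out), nx, ny)
  symmetric <- geometry$kind == "bifurcation"
  if (symmetric) {
    # enforce exact mirror symmetry: floating-point ray casting can classify
    # mirrored near-wall centres differently along oblique walls
    act[, 1:(ny / 2)] <- act[, ny:(ny / 2 + 1)]
  }
  if (!any(act)) stop("meshing failure: no cell centre falls inside the outline",
                      call. = FALSE)

  # signed distance to the solid walls at every cell centre (exact geometry;
  # the open inlet/outlet planes do not count as walls); replaced near walls
  # by the distance to the discrete staircase boundary after face tagging
  dist <- matrix(distance_to_polylines(as.vector(PX), as.vector(PY),
                                       geometry$walls), nx, ny)
  dist[!act] <- -dist[!act]
  if (symmetric) dist[, 1:(ny / 2)] <- dist[, ny:(ny / 2 + 1)]

  caps <- lapply(geometry$outlets, function(o) rbind(o$p1, o$p2))

  classify_boundary <- function(qx, qy) {
    # nearest-feature classification of the *outside* cell centre
    dw <- distance_to_outline(qx, qy, out)
    best <- rep.int(FACE_WALL, length(qx))
    bestd <- rep.int(Inf, length(qx))
    for (k in seq_along(caps)) {
      cap <- caps[[k]]
      dx <- cap[2, 1] - cap[1, 1]; dy <- cap[2, 2] - cap[1, 2]
      L2 <- dx * dx + dy * dy
      t <- pmin(1, pmax(0, ((qx - cap[1, 1]) * dx + (qy - cap[1, 2]) * dy) / L2))
      dk <- sqrt((qx - (cap[1, 1] + t * dx))^2 + (qy - (cap[1, 2] + t * dy))^2)
      upd <- dk < bestd
      best[upd] <- FACE_OUTLET1 + (k - 1L)
      bestd[upd] <- dk[upd]
    }
    # the cap is part of the outline, so dw <= min cap distance always;
    # an outlet face is one whose outside centre is (numerically) nearest a cap
    ifelse(bestd <= dw + 1e-12, best, FACE_WALL)
  }

  actp <- rbind(rep(FALSE, ny), act)          # (nx+1) x ny : west cell of u face
  actq <- rbind(act, rep(FALSE, ny))          # east cell of u face
  uType <- matrix(FACE_EXTERNAL, nx + 1L, ny)
  uType[actp & actq] <- FACE_INTERIOR
  # boundary u faces
  bidx <- which(xor(actp, actq))
  if (length(bidx)) {
    ii <- ((bidx - 1L) %% (nx + 1L)) + 1L
    jj <- ((bidx - 1L) %/% (nx + 1L)) + 1L
    westAct <- actp[bidx]
    # outside cell centre
    qx <- x0 + (ifelse(westAct, ii, ii - 1L) - 0.5) * h
    qy <- y0 + (jj - 0.5) * h
    tp <- classify_boundary(qx, qy)
    tp[ii == 1L] <- FACE_INLET                # inlet plane is the x = x0 face
    uType[bidx] <- tp
  }
  uSign <- matrix(0L, nx + 1L, ny)
  uSign[uType >= FACE_OUTLET1] <- ifelse(actp[uType >= FACE_OUTLET1], 1L, -1L)

  actb <- cbind(rep(FALSE, nx), act)          # (nx) x (ny+1): south cell of v face
  actt <- cbind(act, rep(FALSE, nx))
  vType <- matrix(FACE_EXTERNAL, nx, ny + 1L)
  vType[actb & actt] <- FACE_INTERIOR
  bidx <- which(xor(actb, actt))
  if (length(bidx)) {
    ii <- ((bidx - 1L) %% nx) + 1L
    jj <- ((bidx - 1L) %/% nx) + 1L
    southAct <- actb[bidx]
    qx <- x0 + (ii - 0.5) * h
    qy <- y0 + (ifelse(southAct, jj, jj - 1L) - 0.5) * h
    vType[bidx] <- classify_boundary(qx, qy)
  }
  vSign <- matrix(0L, nx, ny + 1L)
  vSign[vType >= FACE_OUTLET1] <- ifelse(actb[vType >= FACE_OUTLET1], 1L, -1L)

  if (symmetric) {
    # mirror the face tags from the upper half (outlet_1 <-> outlet_2 swap)
    swap <- function(m) {
      m2 <- m
      m2[m == FACE_OUTLET1] <- FACE_OUTLET2
      m2[m == FACE_OUTLET2] <- FACE_OUTLET1
      m2
    }
    uType[, 1:(ny / 2)] <- swap(uType[, ny:(ny / 2 + 1)])
    uSign[, 1:(ny / 2)] <- uSign[, ny:(ny / 2 + 1)]
    vType[, 1:(ny / 2)] <- swap(vType[, (ny + 1L):(ny / 2 + 2L)])
    vSign[, 1:(ny / 2)] <- -vSign[, (ny + 1L):(ny / 2 + 2L)]
  }

  # near walls, measure proximity to the staircase boundary the solver
  # actually enforces (exact within `reach` cells; polygon distance farther out)
  dstair <- cpp_staircase_distance(uType, vType, h, 4L)
  near <- is.finite(dstair)
  dist[near] <- ifelse(act[near], dstair[near], -dstair[near])
  if (symmetric) dist[, 1:(ny / 2)] <- dist[, ny:(ny / 2 + 1)]

  cellIdx <- matrix(0L, nx, ny)
  cellIdx[act] <- seq_len(sum(act))

  structure(list(
    geometry = geometry,
    h = h, nx = nx, ny = ny, x0 = x0, y0 = y0,
    n_across = n_across,
    active = act, cellIdx = cellIdx, n_active = sum(act),
    uType = uType, vType = vType, uSign = uSign, vSign = vSign,
    dist = dist,
    wall_layers = as.integer(wall_layers),
    cache = new.env(parent = emptyenv())
  ), class = "flow_mesh")
}

#' @export
print.flow_mesh <- function(x, ...) {
  cat(sprintf(
    "<flow_mesh> h = %.3g um (%d cells across calibre), %d active / %d x %d cells\n",
    x$h * 1e6, x$n_across, x$n_active, x$nx, x$ny))
  print(boundary_tag_table(x))
  invisible(x)
}

#' Tabulate tagged boundary faces of a mesh
#'
#' @param mesh A `flow_mesh`.
#' @return A tibble with the number of boundary faces per tag.
#' @export
boundary_tag_table <- function(mesh) {
  codes <- c(wall = FACE_WALL, inlet = FACE_INLET,
             outlet_1 = FACE_OUTLET1, outlet_2 = FACE_OUTLET2)
  tibble::tibble(
    tag = names(codes),
    faces = vapply(codes, function(cd)
      sum(mesh$uType == cd) + sum(mesh$vType == cd), integer(1))
  )
}

# centre coordinates of active cells, as a tibble
cell_centres <- function(mesh) {
  idx <- which(mesh$active)
  ii <- ((idx - 1L) %% mesh$nx) + 1L
  jj <- ((idx - 1L) %/% mesh$nx) + 1L
  tibble::tibble(
    i = ii, j = jj,
    x = mesh$x0 + (ii - 0.5) * mesh$h,
    y = mesh$y0 + (jj - 0.5) * mesh$h
  )
}

# Assemble (and cache) the pressure-Poisson operator and its Cholesky factor.
# Matrix entries are face counts (the 1/h^2 scaling is folded into the RHS);
# outlet faces contribute a Dirichlet p = 0 ghost at distance h, which renders
# the operator positive definite.
poisson_factor <- function(mesh) {
  if (!is.null(mesh$cache$chol)) return(mesh$cache$chol)
  nx <- mesh$nx; ny <- mesh$ny
  idx <- mesh$cellIdx
  act <- mesh$active

  ivec <- integer(0); jvec <- integer(0); xvec <- numeric(0)
  diagv <- numeric(mesh$n_active)

  add_pairs <- function(iA, iB) {
    ivec <<- c(ivec, iA, iB); jvec <<- c(jvec, iB, iA)
    xvec <<- c(xvec, rep(-1, 2 * length(iA)))
  }
  # east-west neighbours: u face (i+1, j) interior
  intEW <- mesh$uType[2:nx, , drop = FALSE] == FACE_INTERIOR
  w_id <- idx[1:(nx - 1), , drop = FALSE][intEW]
  e_id <- idx[2:nx, , drop = FALSE][intEW]
  add_pairs(w_id, e_id)
  tab <- tabulate(c(w_id, e_id), nbins = mesh$n_active)
  diagv <- diagv + tab
  # north-south neighbours: v face (i, j+1) interior
  intNS <- mesh$vType[, 2:ny, drop = FALSE] == FACE_INTERIOR
  s_id <- idx[, 1:(ny - 1), drop = FALSE][intNS]
  n_id <- idx[, 2:ny, drop = FALSE][intNS]
  add_pairs(s_id, n_id)
  diagv <- diagv + tabulate(c(s_id, n_id), nbins = mesh$n_active)
  # outlet faces add a Dirichlet ghost
  outU <- mesh$uType >= FACE_OUTLET1
  if (any(outU)) {
    bidx <- which(outU)
    ii <- ((bidx - 1L) %% (nx + 1L)) + 1L
    jj <- ((bidx - 1L) %/% (nx + 1L)) + 1L
    west <- mesh$uSign[outU] == 1L
    ci <- ifelse(west, ii - 1L, ii)
    ids <- idx[cbind(ci, jj)]
    diagv <- diagv + tabulate(ids, nbins = mesh$n_active)
  }
  outV <- mesh$vType >= FACE_OUTLET1
  if (any(outV)) {
    bidx <- which(outV)
    ii <- ((bidx - 1L) %% nx) + 1L
    jj <- ((bidx - 1L) %/% nx) + 1L
    south <- mesh$vSign[outV] == 1L
    cj <- ifelse(south, jj - 1L, jj)
    ids <- idx[cbind(ii, cj)]
    diagv <- diagv + tabulate(ids, nbins = mesh$n_active)
  }

  A <- Matrix::sparseMatrix(
    i = c(ivec, seq_len(mesh$n_active)),
    j = c(jvec, seq_len(mesh$n_active)),
    x = c(xvec, diagv),
    dims = c(mesh$n_active, mesh$n_active)
  )
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  mesh$cache$chol <- ch
  ch
}
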
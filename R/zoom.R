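# Nested carina refinement patch.
#
# The observables that matter - low-velocity area, residence time, fraction of
# trajectories approaching the apex - live inside the stagnation boundary
# layer at the carina, whose thickness sqrt(nu / k) (k the apex strain rate)
# is ~100 um: comparable to the affordable global cell size. A uniform grid
# fine enough to resolve it would be prohibitively large, so the pipeline
# embeds a rectangular refinement patch around the apex, solved with the same
# MAC projection scheme: velocity Dirichlet data on the patch rim taken from
# the converged global solve, implicit (backward-Euler) diffusion so the fine
# grid is not viscously time-step-limited, and an all-Neumann (regularised)
# pressure Poisson problem.

generate_zoom_mesh <- function(geometry, cell_size, half_width) {
  h <- cell_size
  apex <- geometry$apex
  nyh <- ceiling(half_width / h)
  ny <- 2L * as.integer(nyh)
  nx <- as.integer(ceiling(2 * half_width / h))
  x0 <- apex[1] - half_width
  y0 <- -(ny / 2) * h

  # cell-centre in-polygon status on an extended (ghost ring) lattice,
  # symmetrised about the axis
  exi <- seq_len(nx + 2L) - 1L   # extended cell i = 0 .. nx+1
  exj <- seq_len(ny + 2L) - 1L
  cx <- x0 + (exi - 0.5) * h
  cy <- y0 + (exj - 0.5) * h
  PX <- matrix(rep(cx, times = ny + 2L), nx + 2L, ny + 2L)
  PY <- matrix(rep(cy, each = nx + 2L), nx + 2L, ny + 2L)
  PIN <- matrix(points_in_polygon(as.vector(PX), as.vector(PY),
                                  geometry$outline), nx + 2L, ny + 2L)
  PIN[, 1:((ny + 2L) / 2)] <- PIN[, (ny + 2L):((ny + 2L) / 2 + 1L)]

  act <- PIN[2:(nx + 1L), 2:(ny + 1L)]
  # keep a one-cell Dirichlet ring: edge cells are never unknowns
  act[c(1L, nx), ] <- FALSE
  act[, c(1L, ny)] <- FALSE

  uType <- matrix(FACE_EXTERNAL, nx + 1L, ny)
  for (code_only in 1L) {
    fi <- matrix(rep(seq_len(nx + 1L), times = ny), nx + 1L, ny)
    fj <- matrix(rep(seq_len(ny), each = nx + 1L), nx + 1L, ny)
    W <- PIN[cbind(as.vector(fi), as.vector(fj) + 1L)]
    E <- PIN[cbind(as.vector(fi) + 1L, as.vector(fj) + 1L)]
    WA <- as.vector(fi) > 1L &
      act[cbind(pmax(as.vector(fi) - 1L, 1L), as.vector(fj))]
    EA <- as.vector(fi) <= nx &
      act[cbind(pmin(as.vector(fi), nx), as.vector(fj))]
    tp <- ifelse(WA & EA, FACE_INTERIOR,
                 ifelse(W & E, FACE_INLET,
                        ifelse(xor(W, E), FACE_WALL, FACE_EXTERNAL)))
    uType[] <- tp
  }
  vType <- matrix(FACE_EXTERNAL, nx, ny + 1L)
  for (code_only in 1L) {
    fi <- matrix(rep(seq_len(nx), times = ny + 1L), nx, ny + 1L)
    fj <- matrix(rep(seq_len(ny + 1L), each = nx), nx, ny + 1L)
    S <- PIN[cbind(as.vector(fi) + 1L, as.vector(fj))]
    N <- PIN[cbind(as.vector(fi) + 1L, as.vector(fj) + 1L)]
    SA <- as.vector(fj) > 1L &
      act[cbind(as.vector(fi), pmax(as.vector(fj) - 1L, 1L))]
    NA_ <- as.vector(fj) <= ny &
      act[cbind(as.vector(fi), pmin(as.vector(fj), ny))]
    tp <- ifelse(SA & NA_, FACE_INTERIOR,
                 ifelse(S & N, FACE_INLET,
                        ifelse(xor(S, N), FACE_WALL, FACE_EXTERNAL)))
    vType[] <- tp
  }

  dist <- matrix(distance_to_polylines(
    as.vector(PX[2:(nx + 1L), 2:(ny + 1L)]),
    as.vector(PY[2:(nx + 1L), 2:(ny + 1L)]), geometry$walls), nx, ny)
  inp <- PIN[2:(nx + 1L), 2:(ny + 1L)]
  dist[!inp] <- -dist[!inp]
  dstair <- cpp_staircase_distance(uType, vType, h, 4L)
  near <- is.finite(dstair)
  dist[near] <- ifelse(inp[near], dstair[near], -dstair[near])
  dist[, 1:(ny / 2)] <- dist[, ny:(ny / 2 + 1)]

  cellIdx <- matrix(0L, nx, ny)
  cellIdx[act] <- seq_len(sum(act))

  list(h = h, nx = nx, ny = ny, x0 = x0, y0 = y0,
       active = act, cellIdx = cellIdx, n_active = sum(act),
       uType = uType, vType = vType,
       uSign = matrix(0L, nx + 1L, ny), vSign = matrix(0L, nx, ny + 1L),
       dist = dist, geometry = geometry,
       cache = new.env(parent = emptyenv()))
}

# staggered node coordinates of a component grid
face_coords <- function(m, comp) {
  if (comp == "u") {
    list(x = m$x0 + (seq_len(m$nx + 1L) - 1L) * m$h,
         y = m$y0 + (seq_len(m$ny) - 0.5) * m$h)
  } else {
    list(x = m$x0 + (seq_len(m$nx) - 0.5) * m$h,
         y = m$y0 + (seq_len(m$ny + 1L) - 1L) * m$h)
  }
}

# Backward-Euler Helmholtz operator (I - dt nu Lap) for one velocity
# component on the masked staggered grid.  Known-valued neighbour faces
# (walls, Dirichlet rim) are folded into the RHS through the sparse gather
# matrix K; external neighbours use the no-slip mirror.
build_helmholtz <- function(type_mat, h, dt, nu) {
  nr <- nrow(type_mat); nc <- ncol(type_mat)
  unk <- which(type_mat == FACE_INTERIOR)
  idx <- matrix(0L, nr, nc)
  idx[unk] <- seq_along(unk)
  cc <- dt * nu / h^2
  n <- length(unk)
  ii <- ((unk - 1L) %% nr) + 1L
  jj <- ((unk - 1L) %/% nr) + 1L

  ai <- integer(0); aj <- integer(0); ax <- numeric(0)
  ki <- integer(0); kj <- integer(0)
  diagv <- rep(1 + 4 * cc, n)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ni <- ii + d[1]; nj <- jj + d[2]
    inb <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    ntype <- rep.int(FACE_EXTERNAL, n)
    ntype[inb] <- type_mat[cbind(ni[inb], nj[inb])]
    is_unk <- ntype == FACE_INTERIOR
    ai <- c(ai, which(is_unk))
    aj <- c(aj, idx[cbind(ni[is_unk], nj[is_unk])])
    ax <- c(ax, rep(-cc, sum(is_unk)))
    is_mirror <- ntype == FACE_EXTERNAL
    diagv[is_mirror] <- diagv[is_mirror] + cc
    is_known <- !is_unk & !is_mirror
    ki <- c(ki, which(is_known))
    kj <- c(kj, (nj[is_known] - 1L) * nr + ni[is_known])
  }
  A <- Matrix::sparseMatrix(i = c(ai, seq_len(n)), j = c(aj, seq_len(n)),
                            x = c(ax, diagv), dims = c(n, n))
  K <- Matrix::sparseMatrix(i = ki, j = kj, x = rep(cc, length(ki)),
                            dims = c(n, nr * nc))
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE),
       K = K, unk = unk)
}

# All-Neumann pressure Poisson operator with a small ridge (the pressure
# level is indeterminate in a velocity-Dirichlet patch).
poisson_factor_neumann <- function(m) {
  if (!is.null(m$cache$chol)) return(m$cache$chol)
  nx <- m$nx; ny <- m$ny
  idx <- m$cellIdx
  ivec <- integer(0); jvec <- integer(0); xvec <- numeric(0)
  diagv <- numeric(m$n_active)
  intEW <- m$uType[2:nx, , drop = FALSE] == FACE_INTERIOR
  w_id <- idx[1:(nx - 1), , drop = FALSE][intEW]
  e_id <- idx[2:nx, , drop = FALSE][intEW]
  ivec <- c(ivec, w_id, e_id); jvec <- c(jvec, e_id, w_id)
  xvec <- c(xvec, rep(-1, 2 * length(w_id)))
  diagv <- diagv + tabulate(c(w_id, e_id), nbins = m$n_active)
  intNS <- m$vType[, 2:ny, drop = FALSE] == FACE_INTERIOR
  s_id <- idx[, 1:(ny - 1), drop = FALSE][intNS]
  n_id <- idx[, 2:ny, drop = FALSE][intNS]
  ivec <- c(ivec, s_id, n_id); jvec <- c(jvec, n_id, s_id)
  xvec <- c(xvec, rep(-1, 2 * length(s_id)))
  diagv <- diagv + tabulate(c(s_id, n_id), nbins = m$n_active)
  A <- Matrix::sparseMatrix(i = c(ivec, seq_len(m$n_active)),
                            j = c(jvec, seq_len(m$n_active)),
                            x = c(xvec, diagv + 1e-8),
                            dims = c(m$n_active, m$n_active))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  m$cache$chol <- ch
  ch
}

#' Add a carina refinement patch to a solved flow field
#'
#' Solves the flow again on a fine rectangular patch centred on the carina
#' apex (cell size `mesh$h / zoom_factor`), with velocity boundary data
#' interpolated from the global solution on the patch rim. The stagnation
#' boundary layer that controls the carina metrics is ~100 um thick; the
#' patch resolves it with micron-scale cells that would be unaffordable
#' globally. Tracking and near-apex metrics automatically use the patch
#' where it is available.
#'
#' @param field A converged `flow_field` from [solve_steady_flow()].
#' @param zoom_factor Refinement ratio relative to the global grid
#'   (default 8).
#' @param half_width Patch half-width in m (default 0.45 mm, several
#'   boundary-layer thicknesses around the apex).
#' @param control A [solver_control] (tolerance and step cap reused).
#' @return The `flow_field` with a `$zoom` component.
#' @export
solve_carina_zoom <- function(field, zoom_factor = 8, half_width = 0.45e-3,
                              control = field$control) {
  stopifnot(inherits(field, "flow_field"))
  geo <- field$mesh$geometry
  if (!is.finite(geo$apex[1]))
    stop("geometry has no carina apex", call. = FALSE)
  gm <- field$mesh
  zm <- generate_zoom_mesh(geo, cell_size = gm$h / zoom_factor,
                           half_width = half_width)
  h <- zm$h
  nu <- field$fluid$viscosity / field$fluid$density

  # Dirichlet data and initial condition interpolated from the global field
  fc <- face_coords(zm, "u")
  gu <- cpp_interp_velocity(rep(fc$x, times = zm$ny),
                            rep(fc$y, each = zm$nx + 1L),
                            field$u, field$v, gm$x0, gm$y0, gm$h)
  u <- matrix(gu[, 1], zm$nx + 1L, zm$ny)
  fc <- face_coords(zm, "v")
  gv <- cpp_interp_velocity(rep(fc$x, times = zm$ny + 1L),
                            rep(fc$y, each = zm$nx),
                            field$u, field$v, gm$x0, gm$y0, gm$h)
  v <- matrix(gv[, 2], zm$nx, zm$ny + 1L)
  u[zm$uType == FACE_EXTERNAL | zm$uType == FACE_WALL] <- 0
  v[zm$vType == FACE_EXTERNAL | zm$vType == FACE_WALL] <- 0
  cx <- zm$x0 + (seq_len(zm$nx) - 0.5) * h
  cy <- zm$y0 + (seq_len(zm$ny) - 0.5) * h
  q <- matrix(cpp_interp_cellfield(rep(cx, times = zm$ny),
                                   rep(cy, each = zm$nx),
                                   field$p / field$fluid$density,
                                   gm$x0, gm$y0, gm$h), zm$nx, zm$ny)

  # fixed convective time step (the Helmholtz factorisation pins dt)
  umax <- max(abs(u), abs(v), field$vbar / 10)
  dt <- 0.4 * h / umax
  hu <- build_helmholtz(zm$uType, h, dt, nu)
  hv <- build_helmholtz(zm$vType, h, dt, nu)
  chP <- poisson_factor_neumann(zm)
  actIdx <- which(zm$active)
  accel_scale <- field$vbar^2 / geo$calibre

  converged <- FALSE
  u_prev <- u
  res <- Inf
  step <- 0L
  max_steps <- control$max_steps
  while (step < max_steps) {
    step <- step + 1L
    pr <- cpp_predict(u, v, q, zm$uType, zm$vType, zm$uSign, zm$vSign,
                      zm$cellIdx, zm$n_active, h, dt, nu, FALSE)
    us <- pr$us; vs <- pr$vs
    rhs_u <- us[hu$unk] + as.numeric(hu$K %*% as.vector(us))
    us[hu$unk] <- as.numeric(Matrix::solve(hu$chol, rhs_u))
    rhs_v <- vs[hv$unk] + as.numeric(hv$K %*% as.vector(vs))
    vs[hv$unk] <- as.numeric(Matrix::solve(hv$chol, rhs_v))
    div <- cpp_divergence(us, vs, zm$cellIdx, zm$n_active, h)
    div <- div - mean(div)
    phi <- as.numeric(Matrix::solve(chP, -div * h^2 / dt))
    cpp_correct(us, vs, phi, zm$uType, zm$vType, zm$uSign, zm$vSign,
                zm$cellIdx, h, dt)
    u <- us; v <- vs
    q[actIdx] <- q[actIdx] + phi
    if (step %% control$check_every == 0L) {
      res <- max(abs(u - u_prev)) / (control$check_every * dt) / accel_scale
      u_prev <- u
      if (res <= control$tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning(sprintf("carina zoom stopped at %d steps, residual %.3g", step,
                    res), call. = FALSE)

  pad <- 2.5 * h
  field$zoom <- list(
    mesh = zm, u = u, v = v, p = field$fluid$density * q,
    converged = converged, steps = step, residual = res,
    zoom_factor = zoom_factor, half_width = half_width,
    box = c(zm$x0 + pad, zm$x0 + zm$nx * h - pad,
            zm$y0 + pad, zm$y0 + zm$ny * h - pad)
  )
  field
}
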
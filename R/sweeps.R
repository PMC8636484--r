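#' Run one full configuration (mesh, solve, track, metrics)
#'
#' The workhorse behind [run_pipeline()] and the sweeps. Tracking can be
#' skipped when only field-level metrics (low-velocity area, max velocity)
#' are needed.
#'
#' @param config A [run_config()] list.
#' @param track Track particles (default `TRUE`).
#' @param mesh Optional pre-built mesh (reused across a viscosity sweep so
#'   every fluid sees the identical grid and Poisson factorisation).
#' @param seeds Optional pre-drawn seeds (reused for paired comparisons).
#' @return List with `mesh`, `field`, `ensemble` (or `NULL`) and a one-row
#'   `metrics` tibble.
#' @export
run_once <- function(config, track = TRUE, mesh = NULL, seeds = NULL) {
  config <- validate_config(config)
  geo <- do.call(bifurcation_geometry, config$geometry)
  if (is.null(mesh))
    mesh <- generate_mesh(geo, target_cell_size = config$solver$cell_size)
  fluid <- config_fluid(config)
  bc <- do.call(boundary_conditions, config$bc)
  ctl <- solver_control(tol = config$solver$tol,
                        max_steps = config$solver$max_steps)
  field <- solve_steady_flow(mesh, fluid, bc, ctl)
  zf <- config$solver$zoom_factor %||% 1
  if (zf > 1 && is.finite(geo$apex[1]))
    field <- solve_carina_zoom(field, zoom_factor = zf,
                               half_width = config$solver$zoom_half_width,
                               control = ctl)
  ens <- NULL
  if (track) {
    particle <- particle_properties(config$particle$diameter,
                                    config$particle$density)
    if (is.null(seeds))
      seeds <- seed_inlet(geo, config$particle$n,
                          distribution = config$tracking$distribution,
                          rng_seed = config$tracking$rng_seed,
                          margin = particle$diameter / 2)
    tctl <- tracking_control(
      dt = config$tracking$dt, max_time = config$tracking$max_time,
      region_radius = config$metrics$region_radius,
      store_paths = config$tracking$store_paths
    )
    ens <- track_particles(seeds, field, particle, fluid, tctl)
  }
  list(mesh = mesh, field = field, ensemble = ens,
       metrics = carina_metrics(field, ens, config$metrics$threshold_fraction))
}

#' Bifurcation-angle sweep
#'
#' Re-runs the configuration across opening angles and tabulates the carina
#' metrics. The study prediction is that the low-velocity area at the carina
#' grows with the opening angle (30 -> 45 -> 90 degrees) and residence times
#' grow with it.
#'
#' @param angles Numeric vector of opening angles in degrees.
#' @param base_config A [run_config()] list.
#' @param track Track particles per angle (set `FALSE` for the cheaper
#'   field-only sweep).
#' @return A tibble with one row per angle (a `carina_sweep`), with a
#'   `monotonicity` attribute holding the verdicts.
#' @export
angle_sweep <- function(angles, base_config = run_config(), track = TRUE) {
  if (length(angles) < 1L) stop("no angles supplied", call. = FALSE)
  rows <- purrr::map(angles, function(a) {
    cfg <- base_config
    cfg$geometry$angle_deg <- a
    run_once(cfg, track = track)$metrics
  })
  out <- dplyr::bind_rows(rows)
  verdict <- list(
    low_velocity_area_increasing =
      all(diff(out$low_velocity_area[order(out$angle_deg)]) > 0),
    residence_non_decreasing = if (track)
      all(diff(out$mean_residence[order(out$angle_deg)]) >= 0) else NA
  )
  attr(out, "monotonicity") <- verdict
  class(out) <- c("carina_sweep", class(out))
  out
}

#' Carrier-fluid viscosity sweep
#'
#' Solves and tracks the same geometry, mesh and seeds for each fluid and
#' reports carina metrics plus residence-time ratios relative to the least
#' viscous fluid. Raising viscosity at fixed flow rate lowers the Reynolds
#' number, thickens the slow zone hugging the carina and lengthens residence.
#'
#' @param fluids List of [fluid_properties] (or names accepted by [medium()]);
#'   at least two.
#' @param base_config A [run_config()] list.
#' @param track Track particles per fluid.
#' @return A `carina_sweep` tibble with `residence_ratio` and
#'   `area_ratio` columns (reference: smallest viscosity).
#' @export
viscosity_sweep <- function(fluids, base_config = run_config(), track = TRUE) {
  if (length(fluids) < 2L) stop("need at least two fluids", call. = FALSE)
  fluids <- lapply(fluids, function(f)
    if (inherits(f, "fluid_properties")) f else medium(f))
  cfg <- validate_config(base_config)
  geo <- do.call(bifurcation_geometry, cfg$geometry)
  mesh <- generate_mesh(geo, target_cell_size = cfg$solver$cell_size)
  particle <- particle_properties(cfg$particle$diameter, cfg$particle$density)
  seeds <- seed_inlet(geo, cfg$particle$n,
                      distribution = cfg$tracking$distribution,
                      rng_seed = cfg$tracking$rng_seed,
                      margin = particle$diameter / 2)
  rows <- purrr::map(fluids, function(f) {
    c2 <- cfg
    c2$fluid <- list(density = f$density, viscosity = f$viscosity,
                     label = f$label)
    run_once(c2, track = track, mesh = mesh, seeds = seeds)$metrics
  })
  out <- dplyr::bind_rows(rows)
  ref <- which.min(out$viscosity)
  if (track) out$residence_ratio <- out$mean_residence / out$mean_residence[ref]
  out$area_ratio <- out$low_velocity_area / out$low_velocity_area[ref]
  attr(out, "monotonicity") <- list(
    low_velocity_area_increasing =
      all(diff(out$low_velocity_area[order(out$viscosity)]) > 0))
  class(out) <- c("carina_sweep", class(out))
  out
}

#' Mesh-independence study
#'
#' Solves the same configuration on successively refined grids and reports
#' the two control variables - maximum fluid velocity and mean carina
#' residence time - with their pairwise relative variations, judged against
#' the 5% independence criterion (evaluated between the two finest meshes).
#'
#' Residence is probed with a deterministic fan of seeds at fixed transverse
#' offsets spanning the streamtube that feeds the carina region (identical
#' for every mesh). The control variable is the unconditional mean residence
#' over the fan - a continuous functional of the velocity field, free of the
#' set-membership noise that a random ensemble ("mean over whichever
#' particles happened to enter") would add between grids.
#'
#' @param geometry A [bifurcation_geometry].
#' @param cell_sizes Strictly decreasing vector of at least 3 target cell
#'   sizes in m.
#' @param config A [run_config()] list (fluid defaults to FBS here, the fluid
#'   used for the original grid study).
#' @param fan_half_width Largest probe offset from the axis in m; the default
#'   6 um spans the feeding streamtube of the default 70 um carina region.
#' @param n_probe Number of probe particles in the fan.
#' @param criterion Relative-variation threshold (default 0.05).
#' @return A `mesh_convergence` tibble, one row per mesh, with attributes
#'   `variation` (pairwise table) and `pass`.
#' @export
mesh_convergence_study <- function(geometry, cell_sizes,
                                   config = run_config(fluid = "fbs"),
                                   fan_half_width = 6e-6,
                                   n_probe = 48L, criterion = 0.05) {
  if (length(cell_sizes) < 3L)
    stop("need at least three cell sizes", call. = FALSE)
  if (any(diff(cell_sizes) >= 0))
    stop("cell_sizes must be strictly decreasing", call. = FALSE)
  cfg <- validate_config(config)
  fluid <- config_fluid(cfg)
  bc <- do.call(boundary_conditions, cfg$bc)
  particle <- particle_properties(cfg$particle$diameter, cfg$particle$density)
  off <- seq_len(n_probe %/% 2L) / (n_probe %/% 2L) * fan_half_width
  seeds <- tibble::tibble(
    x = geometry$inlet$x + 0.05 * geometry$parent_length,
    y = c(-rev(off), off)   # axis itself excluded: symmetric equilibrium
  )
  rows <- purrr::map(cell_sizes, function(hs) {
    mesh <- generate_mesh(geometry, target_cell_size = hs)
    ctl <- solver_control(tol = cfg$solver$tol,
                          max_steps = cfg$solver$max_steps)
    field <- solve_steady_flow(mesh, fluid, bc, ctl)
    zf <- cfg$solver$zoom_factor %||% 1
    if (zf > 1 && is.finite(geometry$apex[1]))
      field <- solve_carina_zoom(field, zoom_factor = zf,
                                 half_width = cfg$solver$zoom_half_width,
                                 control = ctl)
    ens <- track_particles(seeds, field, particle, fluid,
                           tracking_control(
                             max_time = cfg$tracking$max_time,
                             region_radius = cfg$metrics$region_radius))
    tibble::tibble(
      cell_size = mesh$h, n_cells = mesh$n_active,
      max_velocity = max_speed(field),
      mean_residence = mean(ens$summary$residence_time),
      converged = field$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  relvar <- function(a, b) abs(a - b) / abs(b)
  k <- nrow(out)
  pairs <- tibble::tibble(
    coarse = out$cell_size[-k], fine = out$cell_size[-1],
    dv_max_velocity = relvar(out$max_velocity[-k], out$max_velocity[-1]),
    dv_residence = relvar(out$mean_residence[-k], out$mean_residence[-1])
  )
  finest <- pairs[k - 1L, ]
  pass <- finest$dv_max_velocity < criterion & finest$dv_residence < criterion
  attr(out, "variation") <- pairs
  attr(out, "pass") <- pass
  attr(out, "criterion") <- criterion
  class(out) <- c("mesh_convergence", class(out))
  out
}

#' @export
print.mesh_convergence <- function(x, ...) {
  NextMethod()
  v <- attr(x, "variation")
  cat(sprintf(
    "finest-pair variation: max velocity %.2f%%, residence %.2f%% -> %s (criterion %.0f%%)\n",
    100 * v$dv_max_velocity[nrow(v)], 100 * v$dv_residence[nrow(v)],
    if (isTRUE(attr(x, "pass"))) "PASS" else "FAIL",
    100 * attr(x, "criterion")))
  invisible(x)
}
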
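#' Assemble a run configuration
#'
#' Central configuration for the full pipeline, defaulting to the reference
#' configuration: 90 degree bifurcation of 2 mm calibre, non-conditioned
#' medium, 3 mL/min inlet flow with zero-pressure outlets, 20,000 particles
#' of 14 um and 1.05 g/mL. All values SI.
#'
#' @param angle_deg Opening angle in degrees.
#' @param calibre Vessel calibre in m.
#' @param parent_length,branch_length Channel lengths in m.
#' @param carina_shape `"sharp"` or `"blunt"`.
#' @param blunt_radius Blunt tip radius in m (blunt carina only).
#' @param fluid A [fluid_properties], or a name accepted by [medium()].
#' @param n_particles Ensemble size.
#' @param particle_diameter,particle_density Particle properties (m, kg/m^3).
#' @param flow_rate Inlet flow rate in m^3/s.
#' @param inlet_profile `"parabolic"` or `"uniform"`.
#' @param cell_size Target mesh cell size in m (default calibre / 32).
#' @param zoom_factor Carina refinement-patch ratio (see
#'   [solve_carina_zoom()]); 1 disables the patch.
#' @param zoom_half_width Refinement-patch half-width in m.
#' @param tol Solver convergence monitor.
#' @param max_steps Solver step cap.
#' @param rng_seed Seeding RNG seed.
#' @param distribution Seeding distribution, see [seed_inlet()].
#' @param max_time Trajectory time cap in s.
#' @param dt Tracking time step (NULL = automatic).
#' @param store_paths Number of stored trajectories.
#' @param threshold_fraction Low-velocity threshold fraction.
#' @param region_radius Carina region radius in m.
#' @return A validated `run_config` list.
#' @export
run_config <- function(angle_deg = 90, calibre = 2e-3,
                       parent_length = 10e-3, branch_length = 10e-3,
                       carina_shape = "sharp", blunt_radius = NULL,
                       fluid = "non_conditioned",
                       n_particles = 20000L,
                       particle_diameter = 14e-6, particle_density = 1050,
                       flow_rate = 3e-6 / 60, inlet_profile = "parabolic",
                       cell_size = calibre / 32,
                       zoom_factor = 8, zoom_half_width = 0.45e-3,
                       tol = 1e-5, max_steps = 2e5,
                       rng_seed = 1L, distribution = "uniform",
                       max_time = 20, dt = NULL, store_paths = 0L,
                       threshold_fraction = 0.01, region_radius = NULL) {
  if (is.character(fluid)) fluid <- medium(fluid)
  cfg <- list(
    geometry = list(angle_deg = angle_deg, calibre = calibre,
                    parent_length = parent_length,
                    branch_length = branch_length,
                    carina_shape = carina_shape, blunt_radius = blunt_radius),
    fluid = list(density = fluid$density, viscosity = fluid$viscosity,
                 label = fluid$label),
    particle = list(diameter = particle_diameter, density = particle_density,
                    n = as.integer(n_particles)),
    bc = list(flow_rate = flow_rate, outlet_pressure = 0,
              inlet_profile = inlet_profile),
    solver = list(cell_size = cell_size, tol = tol, max_steps = max_steps,
                  zoom_factor = zoom_factor,
                  zoom_half_width = zoom_half_width),
    tracking = list(rng_seed = as.integer(rng_seed),
                    distribution = distribution, max_time = max_time,
                    dt = dt, store_paths = as.integer(store_paths)),
    metrics = list(threshold_fraction = threshold_fraction,
                   region_radius = region_radius %||% (5 * particle_diameter))
  )
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks positivity and consistency of every block before any compute.
#'
#' @param config A `run_config`-shaped list.
#' @return The config, classed `run_config`.
#' @export
validate_config <- function(config) {
  g <- config$geometry
  stopifnot(is.list(g), is.list(config$fluid), is.list(config$particle),
            is.list(config$bc), is.list(config$solver),
            is.list(config$tracking), is.list(config$metrics))
  pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("configuration error: %s must be a positive number", what),
           call. = FALSE)
  }
  if (!is.na(g$angle_deg) && (g$angle_deg <= 0 || g$angle_deg >= 180))
    stop("configuration error: angle_deg outside (0, 180)", call. = FALSE)
  pos(g$calibre, "calibre"); pos(g$parent_length, "parent_length")
  pos(config$fluid$density, "fluid density")
  pos(config$fluid$viscosity, "fluid viscosity")
  pos(config$particle$diameter, "particle diameter")
  pos(config$particle$density, "particle density")
  pos(config$bc$flow_rate, "flow rate")
  pos(config$solver$cell_size, "cell_size")
  pos(config$metrics$region_radius, "region_radius")
  if (config$particle$n < 1L)
    stop("configuration error: need at least one particle", call. = FALSE)
  structure(config, class = "run_config")
}

config_fluid <- function(config) {
  fluid_properties(config$fluid$density, config$fluid$viscosity,
                   config$fluid$label %||% "fluid")
}

# unit-suffixed external representation <-> SI internal representation
config_to_external <- function(config) {
  list(
    geometry = list(
      angle_deg = config$geometry$angle_deg,
      calibre_mm = config$geometry$calibre * 1e3,
      parent_length_mm = config$geometry$parent_length * 1e3,
      branch_length_mm = config$geometry$branch_length * 1e3,
      carina_shape = config$geometry$carina_shape,
      blunt_radius_mm = (config$geometry$blunt_radius %||% 0) * 1e3
    ),
    fluid = list(density_kg_m3 = config$fluid$density,
                 viscosity_mPa_s = config$fluid$viscosity * 1e3,
                 label = config$fluid$label),
    particle = list(diameter_um = config$particle$diameter * 1e6,
                    density_g_mL = config$particle$density * 1e-3,
                    n = config$particle$n),
    bc = list(flow_rate_mL_min = config$bc$flow_rate * 6e7,
              outlet_pressure_Pa = config$bc$outlet_pressure,
              inlet_profile = config$bc$inlet_profile),
    solver = list(cell_size_um = config$solver$cell_size * 1e6,
                  zoom_factor = config$solver$zoom_factor %||% 1,
                  zoom_half_width_um =
                    (config$solver$zoom_half_width %||% 0) * 1e6,
                  tol = config$solver$tol,
                  max_steps = config$solver$max_steps),
    tracking = list(rng_seed = config$tracking$rng_seed,
                    distribution = config$tracking$distribution,
                    max_time_s = config$tracking$max_time,
                    store_paths = config$tracking$store_paths),
    metrics = list(threshold_fraction = config$metrics$threshold_fraction,
                   region_radius_um = config$metrics$region_radius * 1e6)
  )
}

config_from_external <- function(x) {
  blunt <- (x$geometry$blunt_radius_mm %||% 0) * 1e-3
  run_config(
    angle_deg = x$geometry$angle_deg,
    calibre = x$geometry$calibre_mm * 1e-3,
    parent_length = x$geometry$parent_length_mm * 1e-3,
    branch_length = x$geometry$branch_length_mm * 1e-3,
    carina_shape = x$geometry$carina_shape,
    blunt_radius = if (blunt > 0) blunt else NULL,
    fluid = fluid_properties(x$fluid$density_kg_m3,
                             x$fluid$viscosity_mPa_s * 1e-3,
                             x$fluid$label %||% "fluid"),
    n_particles = x$particle$n,
    particle_diameter = x$particle$diameter_um * 1e-6,
    particle_density = x$particle$density_g_mL * 1e3,
    flow_rate = x$bc$flow_rate_mL_min / 6e7,
    inlet_profile = x$bc$inlet_profile,
    cell_size = x$solver$cell_size_um * 1e-6,
    zoom_factor = x$solver$zoom_factor %||% 1,
    zoom_half_width = (x$solver$zoom_half_width_um %||% 0) * 1e-6,
    tol = x$solver$tol, max_steps = x$solver$max_steps,
    rng_seed = x$tracking$rng_seed, distribution = x$tracking$distribution,
    max_time = x$tracking$max_time_s,
    store_paths = x$tracking$store_paths %||% 0L,
    threshold_fraction = x$metrics$threshold_fraction,
    region_radius = x$metrics$region_radius_um * 1e-6
  )
}

#' Read / write a run configuration file
#'
#' The on-disk format is JSON with explicit unit suffixes in every key
#' (`calibre_mm`, `viscosity_mPa_s`, `flow_rate_mL_min`, ...); parsing
#' converts to SI and writing converts back, and the round trip is exact.
#'
#' @param path File path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  config_from_external(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_external(validate_config(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline and write its artifacts
#'
#' Executes mesh generation, the steady flow solve, particle tracking and the
#' carina metrics, and (when `outdir` is given) writes the standard artifact
#' set: the config copy, geometry JSON, mesh (VTK + MSH), field (VTK),
#' residual history (CSV), stored trajectories (CSV), ensemble census (JSON)
#' and the metrics summary (JSON).
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing); `NULL` skips writing.
#' @return A `pipeline_summary` list: `metrics`, `census`, `field`,
#'   `ensemble`, `mesh`, `artifacts` (paths written).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  config <- validate_config(config)
  res <- run_once(config, track = TRUE)
  artifacts <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_run_config(config, p("config.json"))
    write_geometry_json(res$mesh$geometry, p("geometry.json"))
    write_mesh_vtk(res$mesh, p("mesh.vtk"))
    write_mesh_msh(res$mesh, p("mesh.msh"))
    write_field_vtk(res$field, p("field.vtk"))
    utils::write.csv(res$field$residuals, p("residuals.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ensemble$summary, p("particles.csv"),
                     row.names = FALSE)
    if (nrow(res$ensemble$paths))
      utils::write.csv(res$ensemble$paths, p("trajectories.csv"),
                       row.names = FALSE)
    census <- stats::setNames(as.list(res$ensemble$census$n),
                              as.character(res$ensemble$census$status))
    jsonlite::write_json(
      list(census = census,
           rng_seed = config$tracking$rng_seed,
           version = as.character(utils::packageVersion("carinaflow")),
           metrics = as.list(res$metrics)),
      p("metrics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- list.files(outdir, full.names = TRUE)
  }
  structure(list(
    config = config, metrics = res$metrics, census = res$ensemble$census,
    field = res$field, ensemble = res$ensemble, mesh = res$mesh,
    artifacts = artifacts
  ), class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("<pipeline_summary>\n")
  print(x$metrics)
  invisible(x)
}
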
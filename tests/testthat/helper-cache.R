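# Lazily computed heavy runs, shared across test files. Everything is
# deterministic (fixed seeds, deterministic solver), so sharing is safe.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# reference 90-degree configuration at production resolution, solved + zoomed
ref_field <- function() {
  cached("ref_field", {
    geo <- bifurcation_geometry(90)
    msh <- generate_mesh(geo, target_cell_size = geo$calibre / 32)
    ff <- solve_steady_flow(msh, medium("non_conditioned"),
                            boundary_conditions())
    solve_carina_zoom(ff)
  })
}

# full 20,000-particle tracking run on the reference field
ref_ensemble <- function() {
  cached("ref_ensemble", {
    ff <- ref_field()
    seeds <- seed_inlet(ff$mesh$geometry, 20000L, rng_seed = 1L)
    track_particles(seeds, ff, particle_properties(),
                    medium("non_conditioned"),
                    tracking_control(max_time = 60))
  })
}

# three-medium viscosity sweep at production resolution
ref_viscosity_sweep <- function() {
  cached("ref_viscosity_sweep",
         viscosity_sweep(list("non_conditioned", "fbs", "methylcellulose"),
                         run_config()))
}

# field-only angle sweep (low-velocity area monotonicity)
ref_angle_sweep <- function() {
  cached("ref_angle_sweep", angle_sweep(c(30, 45, 90), run_config(),
                                        track = FALSE))
}

# three-level mesh-independence study (FBS, the grid-study fluid)
ref_mesh_study <- function() {
  cached("ref_mesh_study", {
    geo <- bifurcation_geometry(90)
    mesh_convergence_study(geo, geo$calibre / c(10, 20, 40),
                           run_config(fluid = "fbs"))
  })
}

# straight-channel Poiseuille validation solve
ref_channel <- function() {
  cached("ref_channel", {
    geo <- straight_channel(length = 10e-3, width = 2e-3)
    msh <- generate_mesh(geo, target_cell_size = geo$calibre / 48)
    solve_steady_flow(msh, medium("non_conditioned"), boundary_conditions())
  })
}
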
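#' Fluid properties of the carrier medium
#'
#' Bundles the density and dynamic viscosity of the (Newtonian) carrier fluid.
#' Three named media are built in, matching the cell-culture fluids used for
#' the perfusion experiments the model emulates: non-conditioned basal medium
#' (1.46 mPa s), foetal bovine serum (1.935 mPa s) and basal medium with 0.5%
#' methylcellulose (2.29 mPa s). All are aqueous, so the density defaults to
#' 1000 kg/m^3.
#'
#' @param density Fluid density \eqn{\rho} in kg/m^3.
#' @param viscosity Dynamic viscosity \eqn{\mu} in Pa s.
#' @param label Free-text label for reports.
#' @return An object of class `fluid_properties`: a list with fields
#'   `density`, `viscosity`, `label`.
#' @examples
#' fluid_properties(1000, 1.46e-3, "non-conditioned medium")
#' medium("fbs")
#' @export
fluid_properties <- function(density, viscosity, label = "fluid") {
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            is.numeric(viscosity), length(viscosity) == 1L, is.finite(viscosity))
  if (density <= 0) stop("fluid density must be positive", call. = FALSE)
  if (viscosity <= 0) stop("fluid viscosity must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity, label = label),
            class = "fluid_properties")
}

#' @rdname fluid_properties
#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> %s: rho = %g kg/m^3, mu = %g mPa s\n",
              x$label, x$density, x$viscosity * 1e3))
  invisible(x)
}

# viscosities of the three perfusion media; densities taken as water-like
.media_table <- list(
  non_conditioned = list(density = 1000, viscosity = 1.46e-3,
                         label = "non-conditioned medium"),
  fbs             = list(density = 1000, viscosity = 1.935e-3,
                         label = "foetal bovine serum"),
  methylcellulose = list(density = 1000, viscosity = 2.29e-3,
                         label = "0.5% methylcellulose medium")
)

#' Named carrier media
#'
#' @param name One of `"non_conditioned"`, `"fbs"`, `"methylcellulose"`.
#' @return A [fluid_properties] object.
#' @export
medium <- function(name = c("non_conditioned", "fbs", "methylcellulose")) {
  name <- match.arg(name)
  m <- .media_table[[name]]
  fluid_properties(m$density, m$viscosity, m$label)
}

#' All built-in media as a tibble
#'
#' @return A tibble with one row per medium (name, label, density, viscosity).
#' @export
media <- function() {
  tibble::tibble(
    name = names(.media_table),
    label = purrr::map_chr(.media_table, "label"),
    density = purrr::map_dbl(.media_table, "density"),
    viscosity = purrr::map_dbl(.media_table, "viscosity")
  )
}

#' Rigid spherical particle (CTC analogue) properties
#'
#' The defaults are the circulating-tumour-cell analogue: a rigid sphere of
#' 14 micrometre diameter and 1.05 g/mL density. Mass and projected area are
#' derived from the diameter and density.
#'
#' @param diameter Sphere diameter \eqn{D_p} in m.
#' @param density Particle density \eqn{\rho_p} in kg/m^3.
#' @return An object of class `particle_properties` with fields `diameter`,
#'   `density`, `mass` (\eqn{\rho_p \pi D_p^3/6}) and `area`
#'   (projected area \eqn{\pi D_p^2/4}).
#' @examples
#' ctc <- particle_properties()
#' ctc$mass     # ~1.51e-12 kg
#' @export
particle_properties <- function(diameter = 14e-6, density = 1050) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L,
            is.numeric(density), length(density) == 1L)
  if (diameter <= 0) stop("particle diameter must be positive", call. = FALSE)
  if (density <= 0) stop("particle density must be positive", call. = FALSE)
  structure(list(
    diameter = diameter,
    density = density,
    mass = density * pi * diameter^3 / 6,
    area = pi * diameter^2 / 4
  ), class = "particle_properties")
}

#' @rdname particle_properties
#' @export
print.particle_properties <- function(x, ...) {
  cat(sprintf("<particle_properties> D_p = %g um, rho_p = %g kg/m^3, m_p = %.4g kg\n",
              x$diameter * 1e6, x$density, x$mass))
  invisible(x)
}

#' Inlet/outlet boundary conditions
#'
#' @param flow_rate Volumetric inlet flow rate Q in m^3/s. The default is the
#'   perfusion-pump setting of 3 mL/min.
#' @param outlet_pressure Static pressure at the outlets in Pa (default 0).
#' @param inlet_profile `"parabolic"` (fully developed) or `"uniform"`.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(flow_rate = 3e-6 / 60, outlet_pressure = 0,
                                inlet_profile = c("parabolic", "uniform")) {
  inlet_profile <- match.arg(inlet_profile)
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate <= 0)
    stop("inlet flow rate must be a positive scalar", call. = FALSE)
  structure(list(flow_rate = flow_rate, outlet_pressure = outlet_pressure,
                 inlet_profile = inlet_profile),
            class = "boundary_conditions")
}
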
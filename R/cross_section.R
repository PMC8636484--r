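#' Duct cross-sections and the hydraulic diameter
#'
#' The physical vessel phantom has a semicircular cross-section (flat face up,
#' 2 mm diameter). The hydraulic diameter `4 A / P` generalises the pipe
#' diameter for such non-circular ducts and feeds the channel Reynolds number.
#'
#' @param shape `"semicircle"`, `"circle"` or `"rectangle"`.
#' @param diameter Diameter in m (semicircle / circle).
#' @param width,height Side lengths in m (rectangle).
#' @return An object of class `cross_section` with `shape`, `area` (m^2) and
#'   `perimeter` (wetted perimeter, m).
#' @examples
#' cs <- cross_section("semicircle", diameter = 2e-3)
#' hydraulic_diameter(cs)   # 1.222e-3 m
#' @export
cross_section <- function(shape = c("semicircle", "circle", "rectangle"),
                          diameter = NULL, width = NULL, height = NULL) {
  shape <- match.arg(shape)
  dims <- switch(shape,
    semicircle = {
      stopifnot(is.numeric(diameter), diameter > 0)
      r <- diameter / 2
      list(area = pi * r^2 / 2, perimeter = pi * r + 2 * r,
           characteristic = diameter)
    },
    circle = {
      stopifnot(is.numeric(diameter), diameter > 0)
      r <- diameter / 2
      list(area = pi * r^2, perimeter = 2 * pi * r, characteristic = diameter)
    },
    rectangle = {
      stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0)
      list(area = width * height, perimeter = 2 * (width + height),
           characteristic = width)
    }
  )
  structure(c(list(shape = shape), dims), class = "cross_section")
}

#' @rdname cross_section
#' @param cs A `cross_section`.
#' @export
hydraulic_diameter <- function(cs) {
  stopifnot(inherits(cs, "cross_section"))
  if (cs$perimeter <= 0) stop("cross-section has zero perimeter", call. = FALSE)
  4 * cs$area / cs$perimeter
}

#' Channel Reynolds number
#'
#' `Re = rho * vbar * D_h / mu` with the bulk velocity `vbar = Q / A` and the
#' hydraulic diameter of the duct cross-section. For the default configuration
#' (3 mL/min through a 2 mm semicircular duct, media between 1.46 and
#' 2.29 mPa s) this stays well below 100, i.e. firmly laminar.
#'
#' @param fluid A [fluid_properties] object.
#' @param bc A [boundary_conditions] object (supplies Q), or a bare
#'   non-negative flow rate in m^3/s.
#' @param cs A [cross_section] object.
#' @return Dimensionless Reynolds number (scalar).
#' @examples
#' channel_reynolds(medium("non_conditioned"), boundary_conditions(),
#'                  cross_section("semicircle", diameter = 2e-3))  # ~26.6
#' @export
channel_reynolds <- function(fluid, bc, cs) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(cs, "cross_section"))
  q <- if (inherits(bc, "boundary_conditions")) bc$flow_rate
       else if (is.numeric(bc) && length(bc) == 1L && bc >= 0) bc
       else stop("bc must be boundary_conditions or a non-negative flow rate",
                 call. = FALSE)
  if (cs$area <= 0) stop("cross-section has zero area", call. = FALSE)
  vbar <- q / cs$area
  fluid$density * vbar * hydraulic_diameter(cs) / fluid$viscosity
}
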
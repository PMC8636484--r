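#' Parametric Y-bifurcation geometry
#'
#' Builds the planar mid-plane outline of a symmetric Y-shaped vessel
#' bifurcation: a parent channel of width `calibre` along the x-axis that
#' splits into two daughter channels of the same width, whose inner walls meet
#' at the carina apex with interior angle `angle_deg`. The apex of the sharp
#' carina sits at the origin; the geometry is mirror-symmetric about the
#' x-axis. A blunt carina replaces the sharp wedge tip by a circular arc of
#' radius `blunt_radius` tangent to both inner walls.
#'
#' @param angle_deg Bifurcation opening angle \eqn{\alpha} in degrees,
#'   strictly between 0 and 180. The study angles are 30, 45 and 90.
#' @param calibre Vessel width (2-D calibre) in m; default 2 mm.
#' @param parent_length Length of the parent channel in m (measured from the
#'   inlet to the start of the junction); must be at least 5 calibres so the
#'   inlet profile is insulated from the junction.
#' @param branch_length Length of each daughter branch in m, measured from the
#'   sharp apex along the inner wall; same 5-calibre minimum.
#' @param carina_shape `"sharp"` or `"blunt"`.
#' @param blunt_radius Tip radius in m for the blunt carina; must be below
#'   `calibre / 2`.
#' @return An object of class `bifurcation_geometry` carrying the closed
#'   outline polygon (`outline`, counter-clockwise, metres), the carina `apex`,
#'   the inlet segment and per-outlet cap segments with outward directions.
#' @examples
#' geo <- bifurcation_geometry(90)
#' geo$apex
#' @export
bifurcation_geometry <- function(angle_deg, calibre = 2e-3,
                                 parent_length = 10e-3, branch_length = 10e-3,
                                 carina_shape = c("sharp", "blunt"),
                                 blunt_radius = NULL) {
  carina_shape <- match.arg(carina_shape)
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L ||
      angle_deg <= 0 || angle_deg >= 180)
    stop("angle_deg must lie strictly between 0 and 180 degrees", call. = FALSE)
  if (calibre <= 0) stop("calibre must be positive", call. = FALSE)
  if (parent_length < 5 * calibre || branch_length < 5 * calibre)
    stop("parent_length and branch_length must be at least 5 calibres ",
         "(entrance-length margin)", call. = FALSE)
  if (carina_shape == "blunt") {
    if (is.null(blunt_radius) || !is.numeric(blunt_radius) || blunt_radius <= 0)
      stop("blunt carina requires a positive blunt_radius", call. = FALSE)
    if (blunt_radius >= calibre / 2)
      stop("blunt_radius must be smaller than calibre / 2", call. = FALSE)
  } else {
    blunt_radius <- 0
  }

  w <- calibre
  th <- angle_deg * pi / 360          # half opening angle, radians
  up <- c(cos(th), sin(th))           # upper daughter axis direction
  um <- c(cos(th), -sin(th))          # lower daughter axis direction
  npl <- c(-sin(th), cos(th))         # outward (away from x-axis) normal, upper
  nmi <- c(-sin(th), -cos(th))        # outward normal, lower

  # corner where the daughter outer wall meets the parent wall y = +/- w/2
  s_c <- (w / 2 - w * cos(th)) / sin(th)
  corner_x <- s_c * cos(th) - w * sin(th)
  x_in <- corner_x - parent_length

  e_in_p <- branch_length * up        # inner end of upper outlet cap
  e_out_p <- e_in_p + w * npl
  e_in_m <- branch_length * um
  e_out_m <- e_in_m + w * nmi

  # carina wall polyline, lower inner wall -> apex (arc) -> upper inner wall
  if (carina_shape == "sharp") {
    carina_pts <- matrix(c(0, 0), ncol = 2)
    apex <- c(0, 0)
  } else {
    cc <- blunt_radius / sin(th)      # arc centre on the axis, inside the wedge
    # arc from the tangency on the lower inner wall, through the upstream-most
    # tip point (cc - r, 0), to the upper tangency; centre angles run from
    # -(pi/2 + th) down through -pi to -(3 pi/2 - th)
    a0 <- -(pi / 2 + th)
    a1 <- -(3 * pi / 2 - th)
    na <- max(8L, ceiling(abs(a1 - a0) * blunt_radius / (w / 200)))
    aa <- seq(a0, a1, length.out = na + 1L)
    carina_pts <- cbind(cc + blunt_radius * cos(aa), blunt_radius * sin(aa))
    apex <- c(cc - blunt_radius, 0)   # most upstream point of the blunt tip
  }

  outline <- rbind(
    c(x_in, -w / 2),
    c(corner_x, -w / 2),
    e_out_m,
    e_in_m,
    carina_pts,
    e_in_p,
    e_out_p,
    c(corner_x, w / 2),
    c(x_in, w / 2)
  )
  colnames(outline) <- c("x", "y")

  # wall-only polylines (the inlet plane and outlet caps are open boundaries
  # and must not register as walls in proximity checks)
  walls <- list(
    rbind(c(x_in, -w / 2), c(corner_x, -w / 2), e_out_m),   # lower outer
    rbind(e_in_m, carina_pts, e_in_p),                      # inner / carina
    rbind(e_out_p, c(corner_x, w / 2), c(x_in, w / 2))      # upper outer
  )

  structure(list(
    kind = "bifurcation",
    angle_deg = angle_deg,
    calibre = calibre,
    parent_length = parent_length,
    branch_length = branch_length,
    carina_shape = carina_shape,
    blunt_radius = blunt_radius,
    outline = outline,
    walls = walls,
    apex = apex,
    inlet = list(p1 = c(x_in, -w / 2), p2 = c(x_in, w / 2),
                 normal = c(-1, 0), x = x_in),
    outlets = list(
      outlet_1 = list(p1 = e_in_p, p2 = e_out_p, direction = up,
                      origin = c(0, 0), distance = branch_length),
      outlet_2 = list(p1 = e_in_m, p2 = e_out_m, direction = um,
                      origin = c(0, 0), distance = branch_length)
    )
  ), class = "bifurcation_geometry")
}

#' Straight-channel degenerate geometry
#'
#' A plain rectangular channel used to validate the flow solver against the
#' plane-Poiseuille solution. Inlet on the left, single outlet on the right.
#'
#' @param length Channel length in m.
#' @param width Channel width in m.
#' @return A `bifurcation_geometry` object with `kind = "straight"`.
#' @export
straight_channel <- function(length = 10e-3, width = 2e-3) {
  stopifnot(length > 0, width > 0)
  w <- width
  outline <- rbind(c(0, -w / 2), c(length, -w / 2), c(length, w / 2), c(0, w / 2))
  colnames(outline) <- c("x", "y")
  walls <- list(rbind(c(0, -w / 2), c(length, -w / 2)),
                rbind(c(length, w / 2), c(0, w / 2)))
  structure(list(
    kind = "straight",
    angle_deg = NA_real_,
    calibre = width,
    parent_length = length,
    branch_length = 0,
    carina_shape = "none",
    blunt_radius = 0,
    outline = outline,
    walls = walls,
    apex = c(NA_real_, NA_real_),
    inlet = list(p1 = c(0, -w / 2), p2 = c(0, w / 2), normal = c(-1, 0), x = 0),
    outlets = list(
      outlet_1 = list(p1 = c(length, -w / 2), p2 = c(length, w / 2),
                      direction = c(1, 0), origin = c(0, 0), distance = length)
    )
  ), class = "bifurcation_geometry")
}

#' @export
print.bifurcation_geometry <- function(x, ...) {
  if (x$kind == "straight") {
    cat(sprintf("<straight channel> length %.3g mm, width %.3g mm\n",
                x$parent_length * 1e3, x$calibre * 1e3))
  } else {
    cat(sprintf(
      "<bifurcation_geometry> alpha = %g deg, calibre %.3g mm, %s carina%s\n",
      x$angle_deg, x$calibre * 1e3, x$carina_shape,
      if (x$carina_shape == "blunt")
        sprintf(" (r = %.3g mm)", x$blunt_radius * 1e3) else ""))
    cat(sprintf("  apex at (%.4g, %.4g) mm; parent %.3g mm, branches %.3g mm\n",
                x$apex[1] * 1e3, x$apex[2] * 1e3,
                x$parent_length * 1e3, x$branch_length * 1e3))
  }
  invisible(x)
}

#' Outline perimeter of a geometry
#'
#' @param geometry A `bifurcation_geometry`.
#' @return Total length of the closed outline polygon in m.
#' @export
outline_perimeter <- function(geometry) {
  p <- geometry$outline
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

# Vectorised even-odd point-in-polygon test (ray cast in +x).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Vectorised unsigned distance from points to a set of open polylines.
distance_to_polylines <- function(px, py, polylines) {
  d2 <- rep(Inf, length(px))
  for (pl in polylines) {
    for (i in seq_len(nrow(pl) - 1L)) {
      ax <- pl[i, 1]; ay <- pl[i, 2]
      vx <- pl[i + 1L, 1] - ax; vy <- pl[i + 1L, 2] - ay
      L2 <- vx * vx + vy * vy
      t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
      d2 <- pmin(d2, dx * dx + dy * dy)
    }
  }
  sqrt(d2)
}

# Vectorised unsigned distance from points to the closed outline polygon.
distance_to_outline <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

#' Signed distance from points to the domain walls
#'
#' Distance to the nearest solid wall (inlet and outlet planes are open
#' boundaries and do not count), positive inside the fluid domain, negative
#' outside.
#'
#' @param geometry A `bifurcation_geometry`.
#' @param x,y Point coordinates in m (vectorised).
#' @return Numeric vector of signed distances in m.
#' @export
signed_wall_distance <- function(geometry, x, y) {
  d <- distance_to_polylines(x, y, geometry$walls)
  ifelse(points_in_polygon(x, y, geometry$outline), d, -d)
}

#' Serialize a geometry to JSON
#'
#' Writes the construction parameters together with the outline polyline.
#'
#' @param geometry A `bifurcation_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  obj <- list(
    kind = geometry$kind,
    angle_deg = geometry$angle_deg,
    calibre_m = geometry$calibre,
    parent_length_m = geometry$parent_length,
    branch_length_m = geometry$branch_length,
    carina_shape = geometry$carina_shape,
    blunt_radius_m = geometry$blunt_radius,
    apex_m = geometry$apex,
    outline_m = unname(geometry$outline)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
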
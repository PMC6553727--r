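#' Refractive indices used by the corneal model
#'
#' The three physical media (air, corneal stroma, aqueous humour) plus the
#' fictitious keratometric index used by clinical keratometers to fold both
#' corneal surfaces into a single virtual one.
#'
#' @param n_air Refractive index of air.
#' @param n_cornea Refractive index of the corneal stroma.
#' @param n_aqueous Refractive index of the aqueous humour.
#' @param n_keratometric Fictitious keratometric index used for simulated
#'   keratometry (SimK / Km).
#'
#' @return An object of class `optical_constants` (a named list).
#' @export
#'
#' @examples
#' optical_constants()
optical_constants <- function(n_air = 1.0, n_cornea = 1.376,
                              n_aqueous = 1.336, n_keratometric = 1.3375) {
  if (any(c(n_air, n_cornea, n_aqueous, n_keratometric) < 1)) {
    abort("all refractive indices must be >= 1", class = "keratrace_domain_error")
  }
  if (!(n_cornea > n_aqueous && n_aqueous > n_air)) {
    abort("expected n_cornea > n_aqueous > n_air", class = "keratrace_domain_error")
  }
  structure(
    list(n_air = n_air, n_cornea = n_cornea, n_aqueous = n_aqueous,
         n_keratometric = n_keratometric),
    class = "optical_constants"
  )
}

#' Conicoid (conic-of-revolution) refracting surface
#'
#' A rotationally symmetric conicoid \eqn{x^2 + y^2 = 2 R z - (1+Q) z^2}
#' with apical radius of curvature `apical_radius` (mm) and asphericity `Q`
#' (Q < 0 prolate, Q = 0 spherical, Q > 0 oblate).  The frame is
#' right-handed with +z pointing from air into the eye and the surface apex
#' at `apex_z` on the optical axis; the surface is convex toward the
#' incoming light.
#'
#' @param apical_radius Apical radius of curvature in mm (> 0).
#' @param asphericity_Q Conic asphericity (dimensionless).
#' @param apex_z Axial position of the apex in mm.
#'
#' @return An object of class `conic_surface`.
#' @export
#'
#' @examples
#' conic_surface(7.7, -0.25)
conic_surface <- function(apical_radius, asphericity_Q = 0, apex_z = 0) {
  stopifnot(is.numeric(apical_radius), length(apical_radius) == 1)
  if (!is.finite(apical_radius) || apical_radius <= 0) {
    abort("apical_radius must be positive", class = "keratrace_domain_error")
  }
  structure(
    list(apical_radius = apical_radius, asphericity_Q = asphericity_Q,
         apex_z = apex_z),
    class = "conic_surface"
  )
}

#' Two-surface corneal model
#'
#' The cornea as two coaxial conicoids: an anterior surface with apex at
#' z = 0 and a posterior surface with apex at z = `central_thickness`.
#' The pupil center may be displaced laterally from the corneal apex by
#' `pupil_offset`; this is the only source of decentration in the model.
#'
#' @param anterior,posterior `conic_surface` objects (posterior `apex_z` is
#'   overwritten with `central_thickness`).
#' @param central_thickness Central corneal thickness in mm, in (0.2, 1.0).
#' @param pupil_offset Numeric length-2, (dx, dy) displacement of the pupil
#'   center from the corneal apex, mm.
#' @param constants An [optical_constants()] object.
#'
#' @return An object of class `corneal_model`.
#' @export
#'
#' @examples
#' corneal_model(conic_surface(7.7, -0.25), conic_surface(6.4, -0.20), 0.54)
corneal_model <- function(anterior, posterior, central_thickness,
                          pupil_offset = c(0, 0),
                          constants = optical_constants()) {
  stopifnot(inherits(anterior, "conic_surface"), inherits(posterior, "conic_surface"),
            inherits(constants, "optical_constants"))
  if (!is.finite(central_thickness) ||
      central_thickness <= 0.2 || central_thickness >= 1.0) {
    abort("central_thickness must lie in (0.2, 1.0) mm",
          class = "keratrace_domain_error")
  }
  if (length(pupil_offset) != 2 || any(!is.finite(pupil_offset))) {
    abort("pupil_offset must be a finite (dx, dy) pair",
          class = "keratrace_domain_error")
  }
  anterior$apex_z <- 0
  posterior$apex_z <- central_thickness
  m <- structure(
    list(anterior = anterior, posterior = posterior,
         central_thickness = central_thickness,
         pupil_offset = as.numeric(pupil_offset), constants = constants),
    class = "corneal_model"
  )
  # surfaces must not intersect within the 8 mm aperture
  r <- seq(0, 4, by = 0.25)
  za <- suppressWarnings(sag(anterior, pmin(r, max_sag_radius(anterior) * 0.999)))
  zp <- suppressWarnings(sag(posterior, pmin(r, max_sag_radius(posterior) * 0.999))) +
    central_thickness
  if (any(is.finite(za) & is.finite(zp) & za >= zp)) {
    abort("anterior and posterior surfaces intersect within the 8 mm aperture",
          class = "keratrace_domain_error")
  }
  m
}

#' @export
print.corneal_model <- function(x, ...) {
  cat(sprintf(
    "<corneal_model> R1 = %.4f mm (Q = %+.3f), R2 = %.4f mm (Q = %+.3f), CCT = %.3f mm, pupil offset = (%.3f, %.3f) mm\n",
    x$anterior$apical_radius, x$anterior$asphericity_Q,
    x$posterior$apical_radius, x$posterior$asphericity_Q,
    x$central_thickness, x$pupil_offset[1], x$pupil_offset[2]))
  invisible(x)
}

# largest radial coordinate where the conicoid sag is real-valued
max_sag_radius <- function(surface) {
  R <- surface$apical_radius
  Q <- surface$asphericity_Q
  if (Q > -1) R / sqrt(1 + Q) else Inf
}

#' Conicoid sag
#'
#' Axial depth of the surface at radial distance `r` from its axis,
#' measured from the apex toward the eye:
#' \deqn{z(r) = \frac{r^2}{R\,(1 + \sqrt{1 - (1+Q)\,r^2/R^2})}.}
#'
#' @param surface A [conic_surface()].
#' @param r Radial distance(s) from the axis, mm (vectorized).
#'
#' @return Sag in mm, same length as `r`.
#' @export
#'
#' @examples
#' sag(conic_surface(7.5), 3)   # sphere: 7.5 - sqrt(7.5^2 - 9)
sag <- function(surface, r) {
  stopifnot(inherits(surface, "conic_surface"))
  R <- surface$apical_radius
  Q <- surface$asphericity_Q
  arg <- 1 - (1 + Q) * r^2 / R^2
  if (any(arg < 0, na.rm = TRUE)) {
    abort("sag undefined: point outside the conicoid's real-valued domain",
          class = "keratrace_domain_error")
  }
  r^2 / (R * (1 + sqrt(arg)))
}

#' Outward unit normal of a conicoid surface
#'
#' Unit normal at the surface point with polar coordinates (`r`, `theta`),
#' oriented toward the incoming light (negative z component).  On the axis
#' the normal is the optical axis, (0, 0, -1).
#'
#' @param surface A [conic_surface()].
#' @param r Radial distance from the axis, mm.
#' @param theta Meridian angle, degrees.
#'
#' @return A length-3 unit vector.
#' @export
surface_normal <- function(surface, r, theta = 0) {
  stopifnot(length(r) == 1, length(theta) == 1)
  if (r > max_sag_radius(surface)) {
    abort("point outside the surface's valid aperture",
          class = "keratrace_domain_error")
  }
  z <- sag(surface, r)
  th <- theta * pi / 180
  g <- c(r * cos(th), r * sin(th),
         (1 + surface$asphericity_Q) * z - surface$apical_radius)
  g / sqrt(sum(g^2))
}

# vectorized gradient-based normals at points already on the surface
# (x, y in the surface frame, z measured from the surface apex)
conic_normals <- function(R, Q, x, y, z_rel) {
  gz <- (1 + Q) * z_rel - R
  nrm <- sqrt(x^2 + y^2 + gz^2)
  cbind(x / nrm, y / nrm, gz / nrm)
}

#' First ray-conicoid intersection
#'
#' Intersects a ray `origin + t * direction` (t > 0) with the conicoid.
#' The intersection is solved in closed form as a quadratic in the path
#' length; when the quadratic degenerates (axis-parallel rays on a
#' paraboloid, Q = -1) the equation is linear and solved directly.
#'
#' @param surface A [conic_surface()].
#' @param origin Length-3 numeric, ray origin in mm.
#' @param direction Length-3 unit vector with positive z component.
#'
#' @return The intersection point (length-3, mm).
#' @export
ray_surface_intersect <- function(surface, origin, direction) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (direction[3] <= 0) {
    abort("ray direction must have a positive axial component",
          class = "keratrace_domain_error")
  }
  hit <- conic_intersections(
    surface$apical_radius, surface$asphericity_Q, surface$apex_z,
    matrix(origin, 1), matrix(direction, 1))
  if (any(is.na(hit))) {
    abort("ray does not intersect the surface aperture",
          class = "keratrace_no_intersection")
  }
  drop(hit)
}

# vectorized core: rows of `o` are origins, rows of `d` are unit directions.
# Returns an n x 3 matrix of first-hit points (front sheet), NA rows on miss.
conic_intersections <- function(R, Q, z0, o, d) {
  K <- 1 + Q
  oz <- o[, 3] - z0
  A <- d[, 1]^2 + d[, 2]^2 + K * d[, 3]^2
  B <- 2 * (o[, 1] * d[, 1] + o[, 2] * d[, 2]) - 2 * R * d[, 3] + 2 * K * oz * d[, 3]
  C <- o[, 1]^2 + o[, 2]^2 - 2 * R * oz + K * oz^2
  t <- rep(NA_real_, nrow(o))
  lin <- abs(A) < 1e-12
  t[lin] <- -C[lin] / B[lin]
  disc <- B^2 - 4 * A * C
  ok <- !lin & disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-B[ok] - sq) / (2 * A[ok])
    t2 <- (-B[ok] + sq) / (2 * A[ok])
    # first strictly positive root along the direction of travel
    t1[t1 <= 1e-12] <- Inf
    t2[t2 <= 1e-12] <- Inf
    tt <- pmin(t1, t2)
    tt[!is.finite(tt)] <- NA_real_
    t[ok] <- tt
  }
  t[!is.na(t) & t <= 0] <- NA_real_
  p <- o + d * t
  # restrict to the front sheet: for Q > -1 the near branch has
  # z - z0 <= R / (1 + Q) (the conicoid's axial extent)
  if (K > 0) {
    back <- is.finite(p[, 3]) & (p[, 3] - z0) > R / K + 1e-9
    p[back, ] <- NA_real_
  }
  p
}
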
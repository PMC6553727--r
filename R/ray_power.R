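#' Vector Snell refraction
#'
#' Refracts a unit direction at a surface with unit normal `normal`,
#' going from index `n_in` to `n_out`, using the vector form of Snell's
#' law.  The plane of incidence is preserved; the normal's orientation is
#' normalized internally so either sign convention is accepted.
#'
#' @param incident Length-3 unit direction of the incident ray.
#' @param normal Length-3 unit surface normal.
#' @param n_in,n_out Refractive indices on the incident / transmitted side.
#'
#' @return The refracted unit direction (length-3).
#' @export
#'
#' @examples
#' snell_refract(c(0, 0, 1), c(0, 0, -1), 1, 1.376)  # normal incidence
snell_refract <- function(incident, normal, n_in, n_out) {
  stopifnot(length(incident) == 3, length(normal) == 3, n_in >= 1, n_out >= 1)
  out <- snell_refract_m(matrix(incident, 1), matrix(normal, 1), n_in, n_out)
  if (any(is.na(out))) {
    abort("total internal reflection: refraction discriminant is negative",
          class = "keratrace_tir_error")
  }
  drop(out)
}

# vectorized Snell: d, n are row-wise unit vectors; returns refracted rows,
# NA rows on total internal reflection
snell_refract_m <- function(d, n, n_in, n_out) {
  dn <- rowSums(d * n)
  flip <- !is.na(dn) & dn > 0   # make the normal oppose the incident ray
  n[flip, ] <- -n[flip, , drop = FALSE]
  ci <- -rowSums(d * n)
  eta <- n_in / n_out
  s2 <- eta^2 * (1 - ci^2)
  t <- eta * d + (eta * ci - sqrt(pmax(1 - s2, 0))) * n
  t <- t / sqrt(rowSums(t^2))
  t[!is.na(s2) & s2 > 1, ] <- NA_real_
  t
}

#' Gaussian equivalent power of the two-surface cornea
#'
#' Paraxial thick-lens power
#' \deqn{P = P_1 + P_2 - (d / n_c)\, P_1 P_2}
#' with \eqn{P_1 = (n_c - n_0)/r_1}, \eqn{P_2 = (n_a - n_c)/r_2}, radii
#' and thickness converted to meters.  This is the paraxial limit of the
#' exact ray trace and serves as its oracle.
#'
#' @param model A [corneal_model()].
#'
#' @return Equivalent power in diopters.
#' @export
#'
#' @examples
#' m <- corneal_model(conic_surface(7.7), conic_surface(6.4), 0.5)
#' gaussian_equivalent_power(m)  # 42.692 D
gaussian_equivalent_power <- function(model) {
  stopifnot(inherits(model, "corneal_model"))
  cst <- model$constants
  P1 <- (cst$n_cornea - cst$n_air) / (model$anterior$apical_radius * 1e-3)
  P2 <- (cst$n_aqueous - cst$n_cornea) / (model$posterior$apical_radius * 1e-3)
  d <- model$central_thickness * 1e-3
  P1 + P2 - (d / cst$n_cornea) * P1 * P2
}

# Trace axis-parallel rays entering the cornea at (x, y) mm (vectorized).
# Returns a list with the exit point (mm), exit unit direction, and the
# per-ray power in D under either definition:
#   snell : P = n_aq * sin(U') / h   (h = entry height, meters)
#   axial : P = n_aq / f             (f = axial crossing distance from the
#                                      anterior apex plane, meters)
trace_rays <- function(model, x, y, power_definition = c("snell", "axial")) {
  power_definition <- match.arg(power_definition)
  cst <- model$constants
  ant <- model$anterior
  post <- model$posterior
  n <- length(x)
  h <- sqrt(x^2 + y^2)

  # anterior hit: axis-parallel rays intersect at z = sag(r)
  arg <- 1 - (1 + ant$asphericity_Q) * h^2 / ant$apical_radius^2
  z1 <- ifelse(arg >= 0,
               h^2 / (ant$apical_radius * (1 + sqrt(pmax(arg, 0)))),
               NA_real_)
  n1 <- conic_normals(ant$apical_radius, ant$asphericity_Q, x, y, z1)
  d0 <- cbind(rep(0, n), rep(0, n), rep(1, n))
  d1 <- snell_refract_m(d0, n1, cst$n_air, cst$n_cornea)

  p1 <- cbind(x, y, z1)
  p2 <- conic_intersections(post$apical_radius, post$asphericity_Q,
                            post$apex_z, p1, d1)
  z2_rel <- p2[, 3] - post$apex_z
  n2 <- conic_normals(post$apical_radius, post$asphericity_Q,
                      p2[, 1], p2[, 2], z2_rel)
  d2 <- snell_refract_m(d1, n2, cst$n_cornea, cst$n_aqueous)

  if (power_definition == "snell") {
    # signed transverse direction toward the entry meridian's axis
    radial <- (d2[, 1] * x + d2[, 2] * y) / h
    P <- -cst$n_aqueous * radial / (h * 1e-3)
  } else {
    r2pos <- sqrt(p2[, 1]^2 + p2[, 2]^2)
    radial <- (d2[, 1] * p2[, 1] + d2[, 2] * p2[, 2]) / r2pos
    s <- -r2pos / radial                      # path length to the axis
    z_cross <- p2[, 3] + d2[, 3] * s          # mm from the anterior apex
    P <- cst$n_aqueous / (z_cross * 1e-3)
  }
  P <- unname(as.vector(P))
  P[!is.finite(P)] <- NA_real_
  list(exit_point = p2, exit_dir = d2, power = P)
}

#' Ray-traced corneal power at one entry height
#'
#' Traces a single ray, parallel to the optical axis, entering the cornea
#' at height `h` on meridian `theta`, refracting at the anterior and
#' posterior surfaces by Snell's law, and converts the exit ray into a
#' power.  With the default `"snell"` definition
#' \deqn{P(h) = n_{aq} \sin U' / h} (h in meters, U' the exit angle with
#' the axis), which tends to the Gaussian equivalent power as h tends to 0.
#' The `"axial"` alternative divides \eqn{n_{aq}} by the distance from the
#' anterior apex plane to the ray's axis crossing.
#'
#' @param model A [corneal_model()].
#' @param h Entry height in mm, 0 < h (rays beyond ~4.5 mm typically miss
#'   the posterior surface and raise a no-intersection error).
#' @param theta Meridian, degrees.
#' @param power_definition `"snell"` (default) or `"axial"`.
#'
#' @return Power in diopters.
#' @export
#'
#' @examples
#' m <- corneal_model(conic_surface(7.7, -0.25), conic_surface(6.4, -0.2), 0.54)
#' trace_power_at(m, 0.01)
#' gaussian_equivalent_power(m)
trace_power_at <- function(model, h, theta = 0,
                           power_definition = c("snell", "axial")) {
  stopifnot(inherits(model, "corneal_model"), length(h) == 1)
  if (!is.finite(h) || h <= 0) {
    abort("entry height h must be positive", class = "keratrace_domain_error")
  }
  th <- theta * pi / 180
  tr <- trace_rays(model, h * cos(th), h * sin(th),
                   power_definition = match.arg(power_definition))
  if (is.na(tr$power)) {
    abort("ray could not be traced through both surfaces at this height",
          class = "keratrace_no_intersection")
  }
  tr$power
}
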
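#' Sample ray-traced power on a polar grid
#'
#' Builds a sampled power distribution P(r, theta) over the cornea by
#' tracing axis-parallel rays on a polar grid.  The grid origin is the
#' corneal apex (`center_ref = "apex"`) or the apex shifted by the model's
#' pupil offset (`center_ref = "pupil"`); sample radii are measured from
#' that center while all rays remain parallel to the common optical axis,
#' mimicking instrument-axis acquisition with off-axis aggregation.
#'
#' @param model A [corneal_model()].
#' @param center_ref `"apex"` or `"pupil"`.
#' @param radial_step Radial grid step, mm (default 0.05).
#' @param meridians Number of equally spaced meridians (default 256, >= 8).
#' @param max_radius Outermost sampled radius, mm (default 4.0, i.e. the
#'   8 mm aperture).
#' @param power_definition Passed to the tracer; see [trace_power_at()].
#'
#' @return A tibble of class `power_map` with columns `r_mm`, `theta_deg`,
#'   `power_D` (NA where the ray could not be traced) and attributes
#'   `center_ref`, `radial_step`, `meridians`.
#' @export
#'
#' @examples
#' m <- corneal_model(conic_surface(7.7, -0.25), conic_surface(6.4, -0.2), 0.54)
#' pm <- build_power_map(m, meridians = 32)
#' tcrp_zone(pm, 4)
build_power_map <- function(model, center_ref = c("apex", "pupil"),
                            radial_step = 0.05, meridians = 256,
                            max_radius = 4.0,
                            power_definition = c("snell", "axial")) {
  stopifnot(inherits(model, "corneal_model"))
  center_ref <- match.arg(center_ref)
  power_definition <- match.arg(power_definition)
  if (radial_step <= 0) abort("radial_step must be > 0", class = "keratrace_domain_error")
  if (meridians < 8) abort("need at least 8 meridians", class = "keratrace_domain_error")

  center <- if (center_ref == "pupil") model$pupil_offset else c(0, 0)
  r <- seq(radial_step, max_radius + 1e-12, by = radial_step)
  theta <- seq(0, 360, length.out = meridians + 1)[-(meridians + 1)]
  grid <- expand.grid(r_mm = r, theta_deg = theta, KEEP.OUT.ATTRS = FALSE)
  th <- grid$theta_deg * pi / 180
  x <- center[1] + grid$r_mm * cos(th)
  y <- center[2] + grid$r_mm * sin(th)
  tr <- trace_rays(model, x, y, power_definition = power_definition)
  out <- tibble::tibble(r_mm = grid$r_mm, theta_deg = grid$theta_deg,
                        power_D = tr$power)
  structure(out,
            center_ref = center_ref, radial_step = radial_step,
            meridians = meridians, max_radius = max_radius,
            class = c("power_map", class(out)))
}

# map -> radii x meridians matrix of powers (regular grid assumed)
power_map_matrix <- function(map) {
  r <- sort(unique(map$r_mm))
  th <- sort(unique(map$theta_deg))
  P <- matrix(NA_real_, length(r), length(th))
  P[cbind(match(map$r_mm, r), match(map$theta_deg, th))] <- map$power_D
  list(r = r, theta = th, P = P)
}

check_map_diameter <- function(map, diameter, what) {
  if (!inherits(map, "power_map") &&
      !all(c("r_mm", "theta_deg", "power_D") %in% names(map))) {
    abort("expected a power_map (columns r_mm, theta_deg, power_D)",
          class = "keratrace_domain_error")
  }
  if (diameter <= 0 || diameter / 2 > max(map$r_mm) + 1e-9) {
    abort(sprintf("%s diameter %.2f mm outside the sampled range", what, diameter),
          class = "keratrace_domain_error")
  }
}

#' Ring-averaged total corneal refractive power
#'
#' Unweighted mean of the traced power over all meridians on the circle of
#' the given diameter (a single-diameter readout, not an annulus).  Powers
#' are interpolated linearly in radius when the grid does not land on
#' `diameter / 2`.  Errors if more than 10% of the ring samples are
#' missing.
#'
#' @param map A `power_map` from [build_power_map()].
#' @param diameter Ring diameter, mm.
#'
#' @return Mean ring power in diopters.
#' @export
tcrp_ring <- function(map, diameter) {
  check_map_diameter(map, diameter, "ring")
  mm <- power_map_matrix(map)
  rho <- diameter / 2
  i <- findInterval(rho, mm$r, rightmost.closed = TRUE)
  if (i == 0) {                         # inside the innermost sample
    vals <- mm$P[1, ]
  } else if (i >= length(mm$r)) {
    vals <- mm$P[length(mm$r), ]
  } else {
    w <- (rho - mm$r[i]) / (mm$r[i + 1] - mm$r[i])
    vals <- (1 - w) * mm$P[i, ] + w * mm$P[i + 1, ]
  }
  miss <- mean(is.na(vals))
  if (miss > 0.10) {
    abort(sprintf("insufficient ring coverage at %.1f mm: %.0f%% samples missing",
                  diameter, 100 * miss),
          class = "keratrace_coverage_error")
  }
  mean(vals, na.rm = TRUE)
}

#' Zone-averaged total corneal refractive power
#'
#' Area-weighted mean of the traced power over the filled disc of the
#' given diameter.  Each sample at radius r represents an annulus sector
#' of half-step width, clipped at the zone boundary, so the weights are
#' exact annulus areas; as diameter tends to 0 the zone value tends to the
#' central power.  Errors if more than 10% of the zone's area is missing.
#'
#' @inheritParams tcrp_ring
#' @param diameter Zone diameter, mm.
#'
#' @return Area-weighted mean power in diopters.
#' @export
tcrp_zone <- function(map, diameter) {
  check_map_diameter(map, diameter, "zone")
  mm <- power_map_matrix(map)
  rho <- diameter / 2
  step <- if (length(mm$r) > 1) mm$r[2] - mm$r[1] else mm$r[1]
  lo <- pmax(mm$r - step / 2, 0)
  lo[1] <- 0                             # innermost sample absorbs the center disc
  hi <- pmin(mm$r + step / 2, rho)
  w <- pmax(hi^2 - lo^2, 0)              # annulus area (per sector, /2 constant)
  keep <- w > 0
  W <- matrix(w[keep], sum(keep), length(mm$theta), byrow = FALSE)
  P <- mm$P[keep, , drop = FALSE]
  na <- is.na(P)
  miss <- sum(W[na]) / sum(W)
  if (miss > 0.10) {
    abort(sprintf("insufficient zone coverage at %.1f mm: %.0f%% of area missing",
                  diameter, 100 * miss),
          class = "keratrace_coverage_error")
  }
  W[na] <- 0
  sum(W * ifelse(na, 0, P)) / sum(W)
}
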
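# shared fixtures: corneal models and an independent 2-D meridional tracer

default_model <- function(r1 = 7.7, r2 = 6.4, cct = 0.54,
                          q1 = -0.25, q2 = -0.20, offset = c(0, 0)) {
  corneal_model(conic_surface(r1, q1), conic_surface(r2, q2), cct,
                pupil_offset = offset)
}

# randomized physiologic corneas (preop-like and postop-like mixed)
random_models <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    r1 <- runif(1, 7.2, 9.2)
    default_model(
      r1 = r1,
      r2 = runif(1, 0.78, 0.86) * r1,
      cct = runif(1, 0.45, 0.62),
      q1 = runif(1, -0.4, 0.3),
      q2 = runif(1, -0.35, 0),
      offset = c(runif(1, -0.25, 0.25), runif(1, -0.25, 0.25)))
  })
}

# Independent meridional (2-D) ray tracer used as the oracle for
# trace_power_at: scalar-angle Snell refraction and uniroot intersection,
# sharing no code path with the vectorized 3-D implementation.
sag2d <- function(R, Q, r) {
  r^2 / (R * (1 + sqrt(1 - (1 + Q) * r^2 / R^2)))
}
slope2d <- function(R, Q, r) r / sqrt(R^2 - (1 + Q) * r^2)

trace2d <- function(model, h) {
  cst <- model$constants
  a <- model$anterior; p <- model$posterior
  # anterior hit (axis-parallel): z = sag(h), direction angle u = 0
  z1 <- sag2d(a$apical_radius, a$asphericity_Q, h)
  nu1 <- -atan(slope2d(a$apical_radius, a$asphericity_Q, h))  # inward normal angle
  th_i <- 0 - nu1
  th_t <- asin(cst$n_air / cst$n_cornea * sin(th_i))
  u1 <- nu1 + th_t
  # propagate to posterior: (r, z) = (h, z1) + t (sin u1, cos u1)
  f <- function(t) {
    r <- h + sin(u1) * t
    (z1 + cos(u1) * t) -
      (p$apex_z + sag2d(p$apical_radius, p$asphericity_Q, abs(r)))
  }
  t2 <- uniroot(f, c(1e-9, 10), tol = 1e-14)$root
  r2 <- h + sin(u1) * t2
  nu2 <- -atan(slope2d(p$apical_radius, p$asphericity_Q, r2)) * sign(r2)
  th_i2 <- u1 - nu2
  th_t2 <- asin(cst$n_cornea / cst$n_aqueous * sin(th_i2))
  u2 <- nu2 + th_t2
  -cst$n_aqueous * sin(u2) / (h * 1e-3)
}

# synthetic power map on a regular polar grid with power = f(r)
radial_map <- function(f, radial_step = 0.05, meridians = 64, max_radius = 4) {
  r <- seq(radial_step, max_radius, by = radial_step)
  theta <- seq(0, 360, length.out = meridians + 1)[-(meridians + 1)]
  g <- expand.grid(r_mm = r, theta_deg = theta, KEEP.OUT.ATTRS = FALSE)
  structure(tibble::tibble(r_mm = g$r_mm, theta_deg = g$theta_deg,
                           power_D = f(g$r_mm)),
            class = c("power_map", "tbl_df", "tbl", "data.frame"))
}
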
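#' Synthetic post-SMILE cohort configuration
#'
#' The generator's distributions reproduce the study cohort's printed
#' summary statistics: preoperative Km 42.52 +/- 1.30 D truncated to
#' [39.80, 44.50], preoperative spherical equivalent -4.91 +/- 2.01 D
#' truncated to [-9.50, -1.50], postoperative SE 0.20 +/- 0.40 D truncated
#' to [-0.62, 1.12], optical zones of 6.0 or 6.5 mm, an
#' anterior-to-posterior radius ratio of 0.822 and a mean central
#' thickness of 540 um.
#'
#' `refraction_noise_sd` is the part of the postoperative SE scatter
#' attributed to refraction measurement rather than to the cornea: the
#' cornea is reshaped to deliver `se_post - noise`, so the recorded
#' postoperative SE keeps the configured marginal distribution while the
#' refraction and the corneal geometry disagree by independent noise.
#' Setting it and `radius_noise_sd` to 0 yields a noise-free pipeline in
#' which CHM equals the reshaped anterior keratometry.
#'
#' @param n Number of eyes (>= 2).
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @param pre_km_mean,pre_km_sd,pre_km_range Preoperative Km distribution, D.
#' @param pre_se_mean,pre_se_sd,pre_se_range Preoperative SE distribution, D.
#' @param post_se_mean,post_se_sd,post_se_range Recorded postoperative SE
#'   distribution, D.
#' @param optical_zones Candidate lenticule optical-zone diameters, mm.
#' @param ap_ratio Posterior/anterior apical radius ratio.
#' @param cct_mean,cct_sd Preoperative central corneal thickness, mm.
#' @param q_anterior,q_posterior Preoperative surface asphericities.
#' @param q_shift_per_D Anterior Q increase per diopter of correction.
#' @param pupil_offset_sd SD of each pupil-offset component, mm.
#' @param radius_noise_sd SD of the radius measurement noise, mm.
#' @param refraction_noise_sd SD of the refraction measurement noise, D.
#' @param vertex_distance Vertex distance, mm.
#' @param grid Ray-sampling spec: list with `radial_step` (mm) and
#'   `meridians`.
#'
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(n = 40, seed = 1,
                          pre_km_mean = 42.52, pre_km_sd = 1.30,
                          pre_km_range = c(39.80, 44.50),
                          pre_se_mean = -4.91, pre_se_sd = 2.01,
                          pre_se_range = c(-9.50, -1.50),
                          post_se_mean = 0.20, post_se_sd = 0.40,
                          post_se_range = c(-0.62, 1.12),
                          optical_zones = c(6.0, 6.5),
                          ap_ratio = 0.822,
                          cct_mean = 0.540, cct_sd = 0.030,
                          q_anterior = -0.25, q_posterior = -0.20,
                          q_shift_per_D = 0.08,
                          pupil_offset_sd = 0.1,
                          radius_noise_sd = 0.01,
                          refraction_noise_sd = 0.25,
                          vertex_distance = 12,
                          grid = list(radial_step = 0.05, meridians = 256)) {
  if (n < 2) abort("cohort needs n >= 2", class = "keratrace_config_error")
  for (rng in list(pre_km_range, pre_se_range, post_se_range)) {
    if (length(rng) != 2 || rng[1] >= rng[2]) {
      abort("truncation bounds must be ordered (lo < hi)",
            class = "keratrace_config_error")
    }
  }
  sds <- c(pre_km_sd, pre_se_sd, post_se_sd, cct_sd, pupil_offset_sd,
           radius_noise_sd, refraction_noise_sd)
  if (any(sds < 0)) abort("all SDs must be >= 0", class = "keratrace_config_error")
  structure(as.list(environment()), class = "cohort_config")
}

# moments of N(mu, sigma) truncated to [lo, hi]
trunc_norm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# underlying normal parameters whose truncation to [lo, hi] has the target
# mean and sd (the configured values describe the truncated distribution)
trunc_norm_params <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- trunc_norm_moments(p[1], exp(p[2]), lo, hi)
    (mo["mean"] - mean)^2 + (mo["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# truncated-normal sampling by rejection, calibrated so the sample's
# expectation and SD equal `mean` and `sd`; exact for sd = 0
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- trunc_norm_params(mean, sd, lo, hi)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, p["mu"], p["sigma"])
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Reshape a cornea for a myopic SMILE correction
#'
#' Applies a lenticule extraction of `delta_se_corneal` diopters (at the
#' corneal plane, > 0 for myopic corrections) over optical zone
#' `optical_zone`: the anterior apical power in keratometric diopters is
#' reduced by the correction, central thickness is reduced by a
#' Munnerlyn-approximation central lenticule thickness
#' `delta * OZ^2 / 3` um plus a 15 um base cut, and the anterior
#' asphericity is shifted oblate-ward by `q_shift_per_D` per diopter so
#' the ray-traced power rises toward the periphery as observed after
#' myopic keratorefractive surgery.  The posterior surface shape and the
#' pupil offset are unchanged.
#'
#' @param preop A preoperative [corneal_model()].
#' @param delta_se_corneal Corneal-plane refractive change, D (> 0).
#' @param optical_zone Lenticule optical zone, mm.
#' @param q_shift_per_D Anterior Q increment per diopter (default 0.08).
#' @param base_thickness_um Fixed lenticule base thickness, um.
#'
#' @return The postoperative [corneal_model()].
#' @export
#'
#' @examples
#' pre <- corneal_model(conic_surface(7.94, -0.25), conic_surface(6.53, -0.2), 0.54)
#' smile_reshape(pre, 4.84, 6.5)
smile_reshape <- function(preop, delta_se_corneal, optical_zone,
                          q_shift_per_D = 0.08, base_thickness_um = 15) {
  stopifnot(inherits(preop, "corneal_model"))
  if (delta_se_corneal < 0) {
    abort("delta_se_corneal must be >= 0 (myopic correction removes power)",
          class = "keratrace_domain_error")
  }
  nk <- preop$constants$n_keratometric
  R <- preop$anterior$apical_radius
  k_new <- (nk - 1) / (R * 1e-3) - delta_se_corneal     # D
  if (k_new <= 0) {
    abort("reshape infeasible: anterior power would be non-positive",
          class = "keratrace_reshape_error")
  }
  R_new <- (nk - 1) / k_new * 1e3                       # mm
  lenticule_um <- if (delta_se_corneal > 0) {
    delta_se_corneal * optical_zone^2 / 3 + base_thickness_um
  } else 0
  cct_new <- preop$central_thickness - lenticule_um * 1e-3
  if (cct_new < 0.25) {
    abort("reshape infeasible: residual thickness below 0.25 mm",
          class = "keratrace_reshape_error")
  }
  corneal_model(
    anterior = conic_surface(R_new,
                             preop$anterior$asphericity_Q +
                               q_shift_per_D * delta_se_corneal),
    posterior = conic_surface(preop$posterior$apical_radius,
                              preop$posterior$asphericity_Q),
    central_thickness = cct_new,
    pupil_offset = preop$pupil_offset,
    constants = preop$constants
  )
}

#' Generate a synthetic post-SMILE cohort
#'
#' Draws eyes from the configured truncated-normal distributions, builds a
#' preoperative two-conicoid cornea per eye (anterior radius from the
#' keratometric index, posterior radius from the anterior-to-posterior
#' ratio), reshapes it with [smile_reshape()] by the corneal-plane
#' refractive change, and (optionally) computes the full pre- and
#' postoperative keratometry sets by ray tracing.  Deterministic given
#' `config$seed`.
#'
#' Measurement noise: the keratometry sets are computed from a "measured"
#' copy of each model whose surface radii carry independent Gaussian noise
#' (`radius_noise_sd`), and the recorded postoperative SE differs from the
#' corneally delivered change by `refraction_noise_sd` noise.
#'
#' @param config A [cohort_config()].
#' @param keratometry Compute the per-eye keratometry sets (TRUE, default)
#'   or only the geometry and refraction columns (FALSE; much faster for
#'   large moment-recovery runs).
#' @param diameters TCRP diameters, mm.
#'
#' @return A tibble with one row per eye: scalar columns `id`, `se_pre_D`,
#'   `se_post_D`, `vertex_mm`, `oz_mm`, geometry columns, list-columns
#'   `preop` and `postop` holding the [corneal_model()]s, and (when
#'   `keratometry = TRUE`) one `pre_*` / `post_*` column per measure.
#'   The config and seed are attached as attributes.
#' @export
#'
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 3, seed = 7), keratometry = FALSE)
#' cohort$postop[[1]]
generate_cohort <- function(config = cohort_config(), keratometry = TRUE,
                            diameters = 1:8) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n

  pre_km <- rtrunc_norm(n, config$pre_km_mean, config$pre_km_sd,
                        config$pre_km_range[1], config$pre_km_range[2])
  se_pre <- rtrunc_norm(n, config$pre_se_mean, config$pre_se_sd,
                        config$pre_se_range[1], config$pre_se_range[2])
  se_post <- rtrunc_norm(n, config$post_se_mean, config$post_se_sd,
                         config$post_se_range[1], config$post_se_range[2])
  oz <- config$optical_zones[
    sample.int(length(config$optical_zones), n, replace = TRUE)]
  cct <- rtrunc_norm(n, config$cct_mean, config$cct_sd, 0.40, 0.70)
  dx <- rnorm(n, 0, config$pupil_offset_sd)
  dy <- rnorm(n, 0, config$pupil_offset_sd)
  refr_noise <- rnorm(n, 0, config$refraction_noise_sd)
  r_noise <- matrix(rnorm(4 * n, 0, config$radius_noise_sd), n, 4)

  nk <- optical_constants()$n_keratometric
  r1_pre <- (nk - 1) / pre_km * 1e3       # mm
  r2 <- config$ap_ratio * r1_pre
  vd <- config$vertex_distance

  eyes <- purrr::map(seq_len(n), function(i) {
    preop <- corneal_model(
      conic_surface(r1_pre[i], config$q_anterior),
      conic_surface(r2[i], config$q_posterior),
      cct[i], pupil_offset = c(dx[i], dy[i]))
    # the cornea delivers the change implied by (se_pre -> se_post - noise)
    se_delivered <- se_post[i] - refr_noise[i]
    delta <- vertex_to_corneal_plane(se_delivered, vd) -
      vertex_to_corneal_plane(se_pre[i], vd)
    postop <- tryCatch(
      smile_reshape(preop, delta, oz[i], q_shift_per_D = config$q_shift_per_D),
      error = function(e) {
        abort(sprintf("eye %d: %s", i, conditionMessage(e)),
              class = "keratrace_reshape_error")
      })
    list(preop = preop, postop = postop)
  })

  out <- tibble::tibble(
    id = sprintf("eye%03d", seq_len(n)),
    se_pre_D = se_pre, se_post_D = se_post, vertex_mm = vd,
    oz_mm = oz,
    r1_pre_mm = r1_pre,
    r1_post_mm = purrr::map_dbl(eyes, ~ .x$postop$anterior$apical_radius),
    r2_mm = r2,
    cct_pre_mm = cct,
    cct_post_mm = purrr::map_dbl(eyes, ~ .x$postop$central_thickness),
    pupil_dx_mm = dx, pupil_dy_mm = dy,
    preop = purrr::map(eyes, "preop"),
    postop = purrr::map(eyes, "postop")
  )

  if (keratometry) {
    ks <- purrr::map(seq_len(n), function(i) {
      refr <- refraction_pair(se_pre[i], se_post[i], vd)
      pre_meas <- measured_model(eyes[[i]]$preop, r_noise[i, 1], r_noise[i, 2])
      post_meas <- measured_model(eyes[[i]]$postop, r_noise[i, 3], r_noise[i, 4])
      pre_km_meas <- sim_k(pre_meas$anterior$apical_radius * 1e-3)
      pre_set <- eye_keratometry(pre_meas, pre_km_meas, refr, config$grid, diameters)
      post_set <- eye_keratometry(post_meas, pre_km_meas, refr, config$grid, diameters)
      names(pre_set) <- paste0("pre_", names(pre_set))
      names(post_set) <- paste0("post_", names(post_set))
      dplyr::bind_cols(pre_set, post_set)
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(ks))
  }

  attr(out, "cohort_config") <- config
  attr(out, "seed") <- config$seed
  out
}

# apply measurement noise (mm) to the two apical radii
measured_model <- function(model, eps1, eps2) {
  corneal_model(
    conic_surface(model$anterior$apical_radius + eps1,
                  model$anterior$asphericity_Q),
    conic_surface(model$posterior$apical_radius + eps2,
                  model$posterior$asphericity_Q),
    model$central_thickness, model$pupil_offset, model$constants)
}

# build both centration maps and the keratometry set for one eye
eye_keratometry <- function(model, pre_km, refraction, grid, diameters = 1:8,
                            constants = formula_constants()) {
  map_apex <- build_power_map(model, "apex", radial_step = grid$radial_step,
                              meridians = grid$meridians)
  map_pupil <- build_power_map(model, "pupil", radial_step = grid$radial_step,
                               meridians = grid$meridians)
  keratometry_set(model, map_apex, map_pupil, pre_km, refraction, diameters,
                  constants = constants)
}

#' Flatten a cohort to a plain numeric table
#'
#' Drops the model list-columns, yielding the stable CSV schema: `id`,
#' refraction and geometry columns, then one `pre_*` / `post_*` column per
#' keratometry measure (present as NA when keratometry was not computed).
#'
#' @param records A cohort tibble from [generate_cohort()].
#' @param diameters TCRP diameters used when keratometry columns must be
#'   added as explicit NA.
#'
#' @return A tibble of numeric/character columns only.
#' @export
cohort_to_table <- function(records, diameters = 1:8) {
  if (nrow(records) == 0) {
    abort("empty cohort", class = "keratrace_domain_error")
  }
  tbl <- records[, !vapply(records, is.list, logical(1))]
  expected <- c(paste0("pre_", keratometry_measures(diameters)),
                paste0("post_", keratometry_measures(diameters)))
  for (nm in setdiff(expected, names(tbl))) tbl[[nm]] <- NA_real_
  for (a in c("cohort_config", "seed")) attr(tbl, a) <- attr(records, a)
  tbl
}
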
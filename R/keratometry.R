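#' Correction-formula constants
#'
#' Constants of the post-refractive-surgery keratometry corrections: the
#' Haigis and Shammas linear corrections of postoperative Km, the additive
#' TCRP-to-keratometric conversion, the limits-of-agreement multiplier and
#' the default vertex distance.
#'
#' @param haigis_slope,haigis_intercept Haigis: Kc = slope * Km - intercept.
#' @param shammas_slope,shammas_intercept Shammas: Kc = slope * Km - intercept.
#' @param tcrp_conversion Additive conversion applied to the 4.0 mm zone
#'   TCRP, diopters.
#' @param loa_multiplier Multiplier of the SD of differences in the 95%
#'   limits of agreement.
#' @param vertex_distance_default Spectacle vertex distance, mm.
#'
#' @return A named list of class `formula_constants`.
#' @export
formula_constants <- function(haigis_slope = 1.119, haigis_intercept = 5.78,
                              shammas_slope = 1.14, shammas_intercept = 6.8,
                              tcrp_conversion = 0.70, loa_multiplier = 1.96,
                              vertex_distance_default = 12) {
  vals <- c(haigis_slope, haigis_intercept, shammas_slope, shammas_intercept,
            tcrp_conversion, loa_multiplier, vertex_distance_default)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all formula constants must be positive", class = "keratrace_domain_error")
  }
  structure(list(haigis_slope = haigis_slope, haigis_intercept = haigis_intercept,
                 shammas_slope = shammas_slope, shammas_intercept = shammas_intercept,
                 tcrp_conversion = tcrp_conversion, loa_multiplier = loa_multiplier,
                 vertex_distance_default = vertex_distance_default),
            class = "formula_constants")
}

#' Pre/post refraction pair
#'
#' Spherical-equivalent refraction before and after surgery, at the
#' spectacle plane, with the vertex distance used to move it to the
#' corneal plane.
#'
#' @param se_pre,se_post Spherical equivalents, diopters.
#' @param vertex_distance Vertex distance, mm, in [0, 20].
#'
#' @return A named list of class `refraction_pair`.
#' @export
refraction_pair <- function(se_pre, se_post, vertex_distance = 12) {
  if (vertex_distance < 0 || vertex_distance > 20) {
    abort("vertex_distance must lie in [0, 20] mm", class = "keratrace_domain_error")
  }
  structure(list(se_pre = se_pre, se_post = se_post,
                 vertex_distance = vertex_distance),
            class = "refraction_pair")
}

check_radius <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("radius must be positive", class = "keratrace_domain_error")
  }
}

#' Simulated keratometry (Km / SimK)
#'
#' Keratometric power of the anterior surface using the fictitious
#' keratometric index: Km = (n_k - 1) / r1, r1 in meters.
#'
#' @param r1 Anterior radius of curvature, meters.
#' @param n_keratometric Keratometric index (default 1.3375).
#'
#' @return Power in diopters.
#' @export
#'
#' @examples
#' sim_k(7.5e-3)  # 45 D
sim_k <- function(r1, n_keratometric = 1.3375) {
  check_radius(r1)
  (n_keratometric - 1) / r1
}

#' True net power (TNP)
#'
#' Thin-lens sum of the two surface powers with the true refractive
#' indices: TNP = (1.376 - 1)/r1 + (1.336 - 1.376)/r2 (radii in meters).
#' Note this instrument definition carries no thickness term, unlike
#' [gaussian_equivalent_power()].
#'
#' @param r1,r2 Anterior and posterior radii of curvature, meters.
#' @param constants An [optical_constants()] object.
#'
#' @return Power in diopters.
#' @export
#'
#' @examples
#' tnp(7.7e-3, 6.4e-3)  # 42.58 D
tnp <- function(r1, r2, constants = optical_constants()) {
  check_radius(c(r1, r2))
  (constants$n_cornea - constants$n_air) / r1 +
    (constants$n_aqueous - constants$n_cornea) / r2
}

#' Equivalent keratometry reading (EKR)
#'
#' Simplified equivalent-K formula EKR = 0.376/r1 - 0.03165/r2 (radii in
#' meters): total power rescaled so it can stand in where 1.3375-based
#' keratometry is expected.
#'
#' @param r1,r2 Anterior and posterior radii of curvature, meters.
#'
#' @return Power in diopters.
#' @export
#'
#' @examples
#' ekr(7.7e-3, 6.4e-3)  # 43.89 D
ekr <- function(r1, r2) {
  check_radius(c(r1, r2))
  0.376 / r1 - 0.03165 / r2
}

#' Spectacle-to-corneal-plane refraction conversion
#'
#' Moves a spherical equivalent from the spectacle plane to the corneal
#' plane across vertex distance `vd`: se / (1 - (vd/1000) * se).
#'
#' @param se Spherical equivalent at the spectacle plane, diopters.
#' @param vd Vertex distance, mm.
#'
#' @return Spherical equivalent at the corneal plane, diopters.
#' @export
#'
#' @examples
#' vertex_to_corneal_plane(-4.91, 12)
vertex_to_corneal_plane <- function(se, vd = 12) {
  denom <- 1 - (vd / 1000) * se
  if (any(abs(denom) < 1e-9)) {
    abort("singular vertex conversion: 1 - vd*se/1000 is zero",
          class = "keratrace_domain_error")
  }
  se / denom
}

#' Clinical history method (CHM)
#'
#' The benchmark postoperative corneal power: preoperative keratometry
#' minus the surgically induced refractive change at the corneal plane.
#'
#' @param pre_km Preoperative mean keratometry, diopters.
#' @param refraction A [refraction_pair()].
#'
#' @return CHM power in diopters.
#' @export
#'
#' @examples
#' chm(42.52, refraction_pair(-4.91, 0.20))
chm <- function(pre_km, refraction) {
  stopifnot(inherits(refraction, "refraction_pair"))
  vd <- refraction$vertex_distance
  pre_km - (vertex_to_corneal_plane(refraction$se_post, vd) -
              vertex_to_corneal_plane(refraction$se_pre, vd))
}

#' Haigis post-surgical keratometry correction
#'
#' Kc = 1.119 * post Km - 5.78.
#'
#' @param post_km Postoperative mean keratometry, diopters.
#' @param constants A [formula_constants()] object.
#'
#' @return Corrected power in diopters.
#' @export
k_haigis <- function(post_km, constants = formula_constants()) {
  check_radius(post_km)
  constants$haigis_slope * post_km - constants$haigis_intercept
}

#' Shammas post-surgical keratometry correction
#'
#' Kc = 1.14 * post Km - 6.8.
#'
#' @inheritParams k_haigis
#' @return Corrected power in diopters.
#' @export
k_shammas <- function(post_km, constants = formula_constants()) {
  check_radius(post_km)
  constants$shammas_slope * post_km - constants$shammas_intercept
}

#' Modified TCRP
#'
#' Additive conversion of a 4.0 mm zone TCRP into an equivalent
#' keratometric reading: TCRP + 0.70 D.
#'
#' @param tcrp_zone_4mm TCRP over the 4.0 mm zone, diopters.
#' @param constants A [formula_constants()] object.
#'
#' @return Converted power in diopters.
#' @export
modified_tcrp <- function(tcrp_zone_4mm, constants = formula_constants()) {
  tcrp_zone_4mm + constants$tcrp_conversion
}

#' Names of every keratometric measure the pipeline reports
#'
#' @param diameters TCRP diameters, mm.
#' @return Character vector of measure names.
#' @export
keratometry_measures <- function(diameters = 1:8) {
  c("Km", "TNP", "EKR_4.0", "EKR_4.5",
    as.vector(outer(
      c("TCRP_pupil_zone", "TCRP_pupil_ring", "TCRP_apex_zone", "TCRP_apex_ring"),
      diameters, paste, sep = "_")),
    "CHM", "K_Haigis", "K_Shammas",
    "modTCRP_pupil_zone_4", "modTCRP_apex_zone_4")
}

#' All keratometric estimates for one eye
#'
#' Assembles the full set of dioptric estimates for a single eye: Km, TNP
#' and EKR from the model's apical radii, every TCRP ring/zone variant at
#' the requested diameters from the two centration power maps, CHM /
#' Haigis / Shammas from the preoperative keratometry, refraction and the
#' set's own Km, and the additive modified TCRP.
#'
#' @param model A postoperative [corneal_model()] (radii source for the
#'   formula measures).
#' @param map_apex,map_pupil Apex- and pupil-centered `power_map`s of the
#'   same model (see [build_power_map()]).
#' @param pre_km Preoperative Km, diopters.
#' @param refraction A [refraction_pair()].
#' @param diameters TCRP diameters, mm (default 1:8).
#' @param constants A [formula_constants()] object.
#'
#' @return A one-row tibble with one column per measure in
#'   [keratometry_measures()].
#' @export
keratometry_set <- function(model, map_apex, map_pupil, pre_km, refraction,
                            diameters = 1:8, constants = formula_constants()) {
  stopifnot(inherits(model, "corneal_model"))
  if (missing(map_apex) || missing(map_pupil) ||
      is.null(map_apex) || is.null(map_pupil)) {
    abort("both apex- and pupil-centered power maps are required",
          class = "keratrace_missing_map")
  }
  r1 <- model$anterior$apical_radius * 1e-3
  r2 <- model$posterior$apical_radius * 1e-3
  km <- sim_k(r1, model$constants$n_keratometric)
  ekr_val <- ekr(r1, r2)

  tcrp_one <- function(map, geom, d) {
    tryCatch(if (geom == "zone") tcrp_zone(map, d) else tcrp_ring(map, d),
             error = function(e) NA_real_)
  }
  tc <- list()
  for (center in c("pupil", "apex")) {
    map <- if (center == "pupil") map_pupil else map_apex
    for (geom in c("zone", "ring")) {
      for (d in diameters) {
        tc[[paste("TCRP", center, geom, d, sep = "_")]] <- tcrp_one(map, geom, d)
      }
    }
  }
  out <- c(
    list(Km = km, TNP = tnp(r1, r2, model$constants),
         `EKR_4.0` = ekr_val, `EKR_4.5` = ekr_val),
    tc,
    list(CHM = chm(pre_km, refraction),
         K_Haigis = k_haigis(km, constants),
         K_Shammas = k_shammas(km, constants),
         modTCRP_pupil_zone_4 = modified_tcrp(tc[["TCRP_pupil_zone_4"]], constants),
         modTCRP_apex_zone_4 = modified_tcrp(tc[["TCRP_apex_zone_4"]], constants))
  )
  tibble::as_tibble(out)[, keratometry_measures(diameters)]
}
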
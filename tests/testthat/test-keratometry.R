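test_that("keratometric formulas reproduce hand arithmetic", {
  # SimK
  expect_equal(sim_k(7.5e-3), 45)
  expect_equal(sim_k(0.3375), 1)
  expect_equal(sim_k(7.94e-3), 0.3375 / 0.00794, tolerance = 1e-12)
  expect_equal(sim_k(7.94e-3), 42.506, tolerance = 1e-4)
  expect_error(sim_k(-1), class = "keratrace_domain_error")
  # TNP: no thickness term
  expect_equal(tnp(7.7e-3, 6.4e-3), 0.376 / 0.0077 - 0.040 / 0.0064,
               tolerance = 1e-12)
  expect_equal(tnp(7.7e-3, 6.4e-3), 42.5812, tolerance = 1e-4)
  expect_equal(tnp(7.7e-3, 1e9), 0.376 / 0.0077, tolerance = 1e-6)
  # EKR
  expect_equal(ekr(7.7e-3, 6.4e-3), 0.376 / 0.0077 - 0.03165 / 0.0064,
               tolerance = 1e-12)
  expect_equal(ekr(7.7e-3, 6.4e-3), 43.8859, tolerance = 1e-4)
  expect_gt(ekr(7.7e-3, 6.4e-3), tnp(7.7e-3, 6.4e-3))
  # ordering TNP < EKR < Km for physiologic anterior/posterior ratio
  for (r1 in seq(7.0e-3, 8.6e-3, by = 0.2e-3)) {
    r2 <- 0.822 * r1
    expect_lt(tnp(r1, r2), ekr(r1, r2))
    expect_lt(ekr(r1, r2), sim_k(r1))
  }
})

test_that("vertex conversion and the clinical history method match hand arithmetic", {
  expect_equal(vertex_to_corneal_plane(0, 12), 0)
  expect_equal(vertex_to_corneal_plane(-4.91, 12), -4.91 / (1 + 0.012 * 4.91),
               tolerance = 1e-12)
  expect_equal(vertex_to_corneal_plane(-4.91, 12), -4.6368, tolerance = 1e-4)
  expect_equal(vertex_to_corneal_plane(0.20, 12), 0.2005, tolerance = 1e-4)
  # strictly increasing on a myopic-to-hyperopic sweep
  se <- seq(-10, 5, by = 0.25)
  expect_true(all(diff(vertex_to_corneal_plane(se, 12)) > 0))
  expect_error(vertex_to_corneal_plane(1000 / 12, 12),
               class = "keratrace_domain_error")

  rp <- refraction_pair(-4.91, 0.20, 12)
  expect_equal(chm(42.52, rp),
               42.52 - (vertex_to_corneal_plane(0.20, 12) -
                          vertex_to_corneal_plane(-4.91, 12)),
               tolerance = 1e-12)
  expect_equal(chm(42.52, rp), 37.6827, tolerance = 1e-4)
  # no refractive change: pre Km unchanged
  expect_equal(chm(42.52, refraction_pair(-1, -1, 12)), 42.52)
  # unit slope in pre Km; larger myopic correction -> smaller CHM
  expect_equal(chm(43.52, rp) - chm(42.52, rp), 1)
  expect_lt(chm(42.52, refraction_pair(-6, 0.2, 12)), chm(42.52, rp))
  expect_error(refraction_pair(-4, 0, vertex_distance = 30),
               class = "keratrace_domain_error")
})

test_that("Haigis, Shammas and modified TCRP corrections are the printed linear maps", {
  expect_equal(k_haigis(38.50), 1.119 * 38.50 - 5.78, tolerance = 1e-12)
  expect_equal(round(k_haigis(38.50), 2), 37.30)
  expect_equal(k_shammas(38.50), 1.14 * 38.50 - 6.8, tolerance = 1e-12)
  expect_equal(round(k_shammas(38.50), 2), 37.09)
  # exact slopes by linearity
  expect_equal(k_haigis(40) - k_haigis(39), 1.119, tolerance = 1e-12)
  expect_equal(k_shammas(40) - k_shammas(39), 1.14, tolerance = 1e-12)
  # fixed point of the Haigis line with the identity
  fp <- 5.78 / 0.119
  expect_equal(k_haigis(fp), fp, tolerance = 1e-9)
  # Shammas below Haigis left of the crossing
  expect_lt(k_shammas(38.5), k_haigis(38.5))
  # modified TCRP is additive, not idempotent
  expect_equal(modified_tcrp(37.06), 37.76)
  expect_equal(modified_tcrp(modified_tcrp(37.06)), 37.06 + 1.40)
  expect_error(formula_constants(haigis_slope = -1),
               class = "keratrace_domain_error")
})

test_that("keratometry_set populates every measure and is centration-invariant at zero offset", {
  m <- default_model(7.7, 6.4, 0.54)
  grid <- list(radial_step = 0.05, meridians = 64)
  map_a <- build_power_map(m, "apex", grid$radial_step, grid$meridians)
  map_p <- build_power_map(m, "pupil", grid$radial_step, grid$meridians)
  rp <- refraction_pair(-4.91, 0.20, 12)
  ks <- keratometry_set(m, map_a, map_p, pre_km = 42.52, refraction = rp)
  expect_setequal(names(ks), keratometry_measures())
  expect_true(all(vapply(ks, is.finite, logical(1))))
  # formula measures from the apical radii
  expect_equal(ks$Km, 0.3375 / 0.0077, tolerance = 1e-10)
  expect_equal(ks$TNP, tnp(7.7e-3, 6.4e-3), tolerance = 1e-12)
  expect_equal(ks$`EKR_4.0`, ekr(7.7e-3, 6.4e-3), tolerance = 1e-12)
  expect_equal(ks$`EKR_4.0`, ks$`EKR_4.5`)
  expect_equal(ks$K_Haigis, k_haigis(ks$Km), tolerance = 1e-12)
  expect_equal(ks$modTCRP_apex_zone_4, ks$TCRP_apex_zone_4 + 0.70,
               tolerance = 1e-12)
  # zero pupil offset: pupil-named TCRP equal apex-named TCRP
  for (d in 1:8) {
    expect_equal(ks[[paste0("TCRP_pupil_zone_", d)]],
                 ks[[paste0("TCRP_apex_zone_", d)]], tolerance = 1e-9)
    expect_equal(ks[[paste0("TCRP_pupil_ring_", d)]],
                 ks[[paste0("TCRP_apex_ring_", d)]], tolerance = 1e-9)
  }
  expect_error(keratometry_set(m, NULL, NULL, 42.52, rp),
               class = "keratrace_missing_map")
})
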
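test_that("vector Snell refraction matches scalar Snell and conserves the invariant", {
  # normal incidence: direction unchanged
  expect_equal(snell_refract(c(0, 0, 1), c(0, 0, -1), 1, 1.376), c(0, 0, 1))
  # 30 degree incidence into the cornea: refraction angle asin(0.5/1.376)
  d <- c(sin(pi / 6), 0, cos(pi / 6))
  t <- snell_refract(d, c(0, 0, -1), 1.0, 1.376)
  expect_equal(asin(t[1]) * 180 / pi, asin(0.5 / 1.376) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(asin(t[1]) * 180 / pi, 21.3074, tolerance = 1e-4)
  # n_in sin(i) == n_out sin(t) over 1000 random incidences
  set.seed(5)
  for (i in 1:1000) {
    ang <- runif(1, 0, 0.45 * pi)
    n_in <- runif(1, 1, 1.6); n_out <- runif(1, 1, 1.6)
    if (n_in / n_out * sin(ang) >= 1) next
    # random plane of incidence
    phi <- runif(1, 0, 2 * pi)
    d <- c(sin(ang) * cos(phi), sin(ang) * sin(phi), cos(ang))
    tt <- snell_refract(d, c(0, 0, -1), n_in, n_out)
    expect_lt(abs(n_in * sin(ang) - n_out * sqrt(tt[1]^2 + tt[2]^2)), 1e-12)
  }
  # total internal reflection is a typed error
  d <- c(sin(1.2), 0, cos(1.2))
  expect_error(snell_refract(d, c(0, 0, -1), 1.6, 1.0),
               class = "keratrace_tir_error")
})

test_that("Gaussian equivalent power matches hand arithmetic and thin-lens limit", {
  m <- default_model(7.7, 6.4, 0.5, q1 = 0, q2 = 0)
  P1 <- 0.376 / 0.0077
  P2 <- -0.040 / 0.0064
  expect_equal(gaussian_equivalent_power(m),
               P1 + P2 - (0.0005 / 1.376) * P1 * P2, tolerance = 1e-12)
  expect_equal(gaussian_equivalent_power(m), 42.6921, tolerance = 1e-4)
  # d -> 0: exactly P1 + P2 (thickness at the lower bound of validity)
  thin <- default_model(7.7, 6.4, 0.2001, q1 = 0, q2 = 0)
  expect_equal(gaussian_equivalent_power(thin),
               P1 + P2 - (0.0002001 / 1.376) * P1 * P2, tolerance = 1e-12)
})

test_that("ray-traced power has the paraxial Gaussian limit and the single-surface closed form", {
  # paraxial limit over 100 randomized physiologic corneas
  for (m in random_models(100)) {
    expect_lt(abs(trace_power_at(m, 0.005) - gaussian_equivalent_power(m)), 1e-4)
  }
  # single refracting surface: set aqueous index equal to corneal index
  cst <- optical_constants(n_aqueous = 1.3759999, n_cornea = 1.376)
  m1 <- corneal_model(conic_surface(7.7, 0), conic_surface(6.4, 0), 0.5,
                      constants = cst)
  expect_equal(trace_power_at(m1, 0.01), 0.376 / 0.0077, tolerance = 1e-3)
  expect_error(trace_power_at(m1, -1), class = "keratrace_domain_error")
})

test_that("3-D trace agrees with an independent meridional tracer at finite heights", {
  for (m in random_models(25, seed = 9)) {
    for (h in c(0.5, 1.5, 3.0)) {
      expect_equal(trace_power_at(m, h), trace2d(m, h), tolerance = 1e-9)
    }
  }
  # meridian invariance on a rotationally symmetric model
  m <- default_model()
  expect_equal(trace_power_at(m, 3, 0), trace_power_at(m, 3, 137.5),
               tolerance = 1e-9)
})

test_that("axial-crossing power definition is available and paraxially consistent", {
  m <- default_model()
  expect_equal(trace_power_at(m, 0.005, power_definition = "axial"),
               gaussian_equivalent_power(m), tolerance = 0.1)
  # the two definitions diverge at finite aperture but stay within diopters
  expect_lt(abs(trace_power_at(m, 3, power_definition = "axial") -
                  trace_power_at(m, 3)), 5)
})

test_that("power maps sample the tracer consistently and respect symmetry", {
  m <- default_model()
  map <- build_power_map(m, "apex", radial_step = 0.25, meridians = 32)
  expect_equal(nrow(map), 16 * 32)
  # sampling consistency with single traces
  sub <- map[map$r_mm %in% c(1, 2.5) & map$theta_deg == 45, ]
  for (i in seq_len(nrow(sub))) {
    expect_equal(sub$power_D[i], trace_power_at(m, sub$r_mm[i], 45),
                 tolerance = 1e-10)
  }
  # rotational symmetry: all meridians equal at fixed radius
  spread <- tapply(map$power_D, map$r_mm, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
  # zero pupil offset: apex- and pupil-centered maps identical
  map_p <- build_power_map(m, "pupil", radial_step = 0.25, meridians = 32)
  expect_equal(map$power_D, map_p$power_D, tolerance = 1e-12)
  # nonzero offset: they differ
  mo <- default_model(offset = c(0.3, -0.2))
  expect_false(isTRUE(all.equal(
    build_power_map(mo, "apex", radial_step = 0.25, meridians = 32)$power_D,
    build_power_map(mo, "pupil", radial_step = 0.25, meridians = 32)$power_D)))
  expect_error(build_power_map(m, meridians = 4), class = "keratrace_domain_error")
})

test_that("ring and zone averaging match closed forms and ordering properties", {
  # uniform map: both equal the constant
  u <- radial_map(function(r) rep(43, length(r)))
  expect_equal(tcrp_ring(u, 6), 43)
  expect_equal(tcrp_zone(u, 6), 43)
  expect_equal(tcrp_zone(u, 0.4), 43)
  # P(r) = 40 + r^2: ring(6 mm) = 40 + 9; zone(6 mm) = 40 + 4.5
  q <- radial_map(function(r) 40 + r^2)
  expect_equal(tcrp_ring(q, 6), 49, tolerance = 1e-6)
  expect_equal(tcrp_zone(q, 6), 44.5, tolerance = 5e-3)
  # monotone-weighting: zone < ring for radially increasing maps, > for decreasing
  for (d in c(2, 4, 6, 8)) {
    expect_lt(tcrp_zone(q, d), tcrp_ring(q, d))
  }
  dec <- radial_map(function(r) 45 - r)
  expect_gt(tcrp_zone(dec, 6), tcrp_ring(dec, 6))
  # quadrature stability in meridian count on a symmetric model
  m <- default_model()
  v32 <- tcrp_ring(build_power_map(m, meridians = 32, radial_step = 0.05), 6)
  v256 <- tcrp_ring(build_power_map(m, meridians = 256, radial_step = 0.05), 6)
  expect_equal(v32, v256, tolerance = 1e-6)
  # coverage errors
  holey <- radial_map(function(r) 40 + r)
  holey$power_D[holey$r_mm > 2.8] <- NA
  expect_error(tcrp_ring(holey, 6), class = "keratrace_coverage_error")
  expect_error(tcrp_zone(holey, 8), class = "keratrace_coverage_error")
  expect_error(tcrp_ring(u, 9), class = "keratrace_domain_error")
})
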
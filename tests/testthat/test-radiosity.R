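# The optical transfer chain: occlusion-resolved direct illumination,
# Lambertian multiple scattering, energy bookkeeping.

test_that("an unoccluded horizontal facet under uniform sky receives pi*L", {
  # quadrature refinement: 90 zenith bins, 32 azimuth samples
  bins <- zenith_bins(90)
  rad <- one_band_rad(level = 1, bins = bins)
  sc <- facetize(single_leaf_scene(area = 4e-4, height = 0.3))
  fo <- direct_illumination(sc, rad, transfer = trace_canopy(sc, bins,
                                                             n_az = 32,
                                                             seed = 2))
  leaf_up <- 2 * which(sc$role == "leaf") - 1
  expect_equal(mean(fo[leaf_up, 1]), pi, tolerance = 0.005 * pi)
  # the down faces point away from the sky: no first-order light
  leaf_dn <- leaf_up + 1
  expect_equal(max(fo[leaf_dn, 1]), 0)
})

test_that("a facet directly beneath an opaque continuous slab gets no direct light", {
  tile <- c(0.2, 0.2)
  slab <- opaque_slab_scene(height = 0.3, tile = tile)
  leaf <- single_leaf_scene(area = 5e-4, height = 0.1, tile = tile)
  sc <- facetize(merge_scenes(slab, leaf))
  rad <- test_noon_rad()
  fo <- direct_illumination(sc, rad, transfer = trace_canopy(sc, seed = 1))
  under <- 2 * which(sc$role == "leaf") - 1
  expect_equal(max(fo[under, ]), 0)
})

test_that("the transfer operator is linear in the boundary radiance", {
  sc <- facetize(tiny_canopy(1.2, seed = 5), 2e-4)
  rad <- test_noon_rad()
  mat <- material_library()
  tr <- trace_canopy(sc, seed = 3)
  fo1 <- direct_illumination(sc, rad, transfer = tr)
  fo2 <- direct_illumination(sc, apply_shading(rad, 0.5), transfer = tr)
  expect_equal(fo2, fo1 * 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  s1 <- solve_scattering(sc, mat, fo1)
  s2 <- solve_scattering(sc, mat, fo2)
  nz <- s1$E > 1e-12
  expect_lt(max(abs(s2$E[nz] / s1$E[nz] - 0.5)), 1e-9)
})

test_that("a black canopy scatters nothing", {
  sc <- facetize(tiny_canopy(0.8, seed = 6), 2e-4)
  rad <- test_noon_rad()
  black <- material_library(leaf_reflectance = rep(0, 17),
                            leaf_transmittance = rep(0, 17),
                            substrate_reflectance = rep(0, 17),
                            stem_reflectance = rep(0, 17))
  fo <- direct_illumination(sc, rad, transfer = trace_canopy(sc, seed = 4))
  sol <- solve_scattering(sc, black, fo)
  expect_equal(sol$E, fo, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lte(sol$iterations, 2L)
})

test_that("total absorbed power agrees with a brute-force path tracer", {
  sc <- facetize(random_facet_scene(50L, seed = 8), 2e-4)
  bins <- zenith_bins()
  rad <- one_band_rad(level = 2, bins = bins)
  mat <- material_library()
  rho_b1 <- mat$rho[, 1]; tau_b1 <- mat$tau[, 1]
  fo <- direct_illumination(sc, rad, transfer = trace_canopy(sc, seed = 5))
  sol <- solve_scattering(sc, mat, fo)
  alpha <- (1 - sol$rho - sol$tau)[, 1]
  absorbed <- sum(sol$slot_area * alpha * sol$E[, 1])
  oracle <- oracle_path_trace(sc, rho_b1, tau_b1, rad,
                              n_photons = 16000L, seed = 9)
  se <- max(oracle$se, 0.005 * oracle$absorbed)
  expect_lt(abs(absorbed - oracle$absorbed), 2 * se)
})

test_that("energy closes exactly in closed-form scenes and without surface absorption", {
  rad <- test_noon_rad()
  mat <- material_library()
  # substrate only: analytic bookkeeping, closure at numerical precision
  sub <- facetize(canopy_scene(list(), c(0.2, 0.2)))
  expect_lt(energy_audit(sub, mat, rad)$closure_error, 1e-6)
  # no surface absorption (rho + tau = 1): everything must leave to the sky
  mirror <- material_library(leaf_reflectance = rep(0.5, 17),
                             leaf_transmittance = rep(0.5, 17),
                             substrate_reflectance = rep(1, 17),
                             stem_reflectance = rep(1, 17))
  sc <- facetize(tiny_canopy(0.8, seed = 7), 2e-4)
  fo <- direct_illumination(sc, rad,
                            transfer = trace_canopy(sc, n_gather = 64,
                                                    seed = 6))
  sol <- solve_scattering(sc, mirror, fo, tol = 1e-9, max_iters = 400L)
  e_in <- sum(planar_ed(rad)) * 0.04
  e_abs <- sum(sol$slot_area * rowSums((1 - sol$rho - sol$tau) * sol$E))
  e_sky <- sum(sol$slot_area * sol$escape_fraction * rowSums(sol$B))
  expect_lt(abs(e_abs) / e_in, 1e-9)
  expect_lt(abs(e_in - e_sky) / e_in, 0.02)   # audit tolerance
})

test_that("substrate transmittance behaves at the extremes and is monotone in LAI", {
  rad <- test_noon_rad()
  mat <- material_library()
  iops <- test_iops()
  sub <- facetize(canopy_scene(list(), c(0.2, 0.2)))
  sol <- canopy_transfer_solve(sub, rad, mat, iops)
  expect_equal(substrate_transmittance(sol, sub, rad), 100, tolerance = 1e-6)
  slab <- facetize(opaque_slab_scene())
  sol2 <- canopy_transfer_solve(slab, rad, mat, iops)
  expect_lte(substrate_transmittance(sol2, slab, rad), 1)
  # nested canopies: added leaf area can only darken the substrate
  pool <- make_fixtures(1, canopies = FALSE)$plant_pool
  base <- NULL; tt <- numeric(0)
  for (L in c(0.8, 1.8, 3)) {
    base <- assemble_canopy(pool, target_lai = L, seed = 31, base = base)
    fs <- facetize(base, 2e-4)
    s <- canopy_transfer_solve(fs, rad, mat, iops, seed = 31)
    tt <- c(tt, substrate_transmittance(s, fs, rad))
  }
  expect_true(all(diff(tt) < 0))
})

test_that("periodic translation of the scene leaves results unchanged", {
  pool <- make_fixtures(2, canopies = FALSE)$plant_pool
  sc <- assemble_canopy(pool, target_lai = 1.0, seed = 13)
  rad <- test_noon_rad()
  mat <- material_library()
  f1 <- facetize(sc, 2e-4)
  # rigid translation of the whole periodic structure: bitwise-equivalent
  # sampling, so per-facet results agree to rounding
  f2 <- f1
  f2$vertices[, 1] <- f2$vertices[, 1] + f1$tile[1] / 2
  s1 <- canopy_transfer_solve(f1, rad, mat, seed = 17)
  s2 <- canopy_transfer_solve(f2, rad, mat, seed = 17)
  expect_equal(leaf_irradiance(s2, f2)$par, leaf_irradiance(s1, f1)$par,
               tolerance = 1e-9)
  # wrapping plant positions across the boundary moves the plants relative
  # to the fixed substrate facet grid; the periodic physics is unchanged,
  # so canopy-aggregate results agree within Monte-Carlo tolerance
  shifted <- lapply(sc$plants, function(p) {
    attr(p, "position") <- (attr(p, "position") + c(0.1, 0)) %% 0.2
    p
  })
  f3 <- facetize(canopy_scene(shifted, sc$tile), 2e-4)
  s3 <- canopy_transfer_solve(f3, rad, mat, seed = 17)
  l1 <- leaf_irradiance(s1, f1); l3 <- leaf_irradiance(s3, f3)
  m1 <- sum(l1$par * l1$area) / sum(l1$area)
  m3 <- sum(l3$par * l3$area) / sum(l3$area)
  expect_equal(m3 / m1, 1, tolerance = 0.01)
  expect_equal(substrate_transmittance(s3, f3, rad),
               substrate_transmittance(s1, f1, rad), tolerance = 0.01)
})

test_that("the exponential transmittance fit recovers known curves", {
  lai <- seq(0.5, 8, length.out = 12)
  y <- 100 * exp(-0.29 * lai)
  fit <- fit_exponential_transmittance(lai, y)
  expect_equal(fit$b, 0.29, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # noisy points vs an independent Levenberg-Marquardt oracle
  set.seed(2)
  yn <- pmax(0.5, y + rnorm(12, 0, 2))
  fit2 <- fit_exponential_transmittance(lai, yn)
  or <- minpack.lm::nlsLM(yn ~ 100 * exp(-b * lai), start = list(b = 0.2))
  expect_equal(fit2$b, unname(coef(or)["b"]), tolerance = 1e-6)
  expect_error(fit_exponential_transmittance(c(1, 2), c(50, 20)), "3 points")
})
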
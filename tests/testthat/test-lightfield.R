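test_that("solar geometry matches an independent ephemeris and Snell refraction", {
  # equator, equinox, solar noon: sun overhead
  eq <- solar_position(0, 0, "2005-03-21", 12)
  expect_lt(eq$air_zenith, 1)
  # hours symmetric about noon give equal zeniths
  a <- solar_position(-30.3095, 115.0072, "2005-04-27", 9.3)
  b <- solar_position(-30.3095, 115.0072, "2005-04-27", 14.7)
  expect_equal(a$air_zenith, b$air_zenith, tolerance = 0.5)
  # reference site at solar noon vs the Cooper-declination oracle
  noon <- solar_position(-30.3095, 115.0072, "2005-04-27", 12)
  expect_equal(noon$air_zenith,
               oracle_solar_zenith(-30.3095, "2005-04-27", 12),
               tolerance = 1.5)
  # refraction is exactly Snell with n = 1.34; the refracted noon zenith is
  # near 30 degrees, consistent with the reported in-water sun angle
  expect_equal(sin(noon$water_zenith * pi / 180) * 1.34,
               sin(noon$air_zenith * pi / 180), tolerance = 1e-12)
  expect_gt(noon$water_zenith, 27); expect_lt(noon$water_zenith, 35)
})

test_that("clear-sky radiance has the right structure", {
  below <- solar_position(-30.3095, 115.0072, "2005-04-27", 23)
  expect_false(below$sun_up)
  expect_true(all(clear_sky_radiance(below)$radiance == 0))
  sun <- solar_position(-30.3095, 115.0072, "2005-04-27", 12)
  r <- clear_sky_radiance(sun)
  expect_equal(nrow(r$bands), 17L)
  # the direct-beam bin carries the largest single-bin share of irradiance
  per_bin <- rowSums(r$radiance) * r$bins$cw
  sun_bin <- findInterval(sun$air_zenith, r$bins$upper, left.open = TRUE) + 1L
  expect_equal(which.max(per_bin), sun_bin)
  expect_true(all(r$radiance >= 0))
})

test_that("azimuthal averaging conserves planar irradiance", {
  bins <- zenith_bins()
  # azimuthally uniform input is a fixed point
  arr <- array(rep(2, 18 * 8 * 17), c(18, 8, 17))
  out <- azimuthal_average(arr)
  expect_equal(max(abs(out$radiance - 2)), 0)
  # structured input: E_d conserved to 1e-12 relative
  set.seed(4)
  arr2 <- array(runif(18 * 8 * 17), c(18, 8, 17))
  out2 <- azimuthal_average(arr2)
  ed_in <- sapply(1:17, function(k) sum(rowMeans(arr2[, , k]) * bins$cw))
  expect_equal(planar_ed(out2), ed_in, tolerance = 1e-12)
  # single-azimuth beam at one zenith: ring with the same E_d
  arr3 <- array(0, c(18, 8, 17))
  arr3[7, 3, 5] <- 10
  out3 <- azimuthal_average(arr3)
  expect_equal(out3$radiance[7, 5], 10 / 8)
  expect_equal(planar_ed(out3)[5], 10 / 8 * bins$cw[7], tolerance = 1e-12)
})

test_that("water column transfer is Beer-Lambert in the scattering-free limit", {
  bins <- zenith_bins()
  iops0 <- water_iops(rep(0.3, 17), rep(0, 17))
  # one bin populated, in-water input compared after transmission step
  L <- matrix(0, 18, 17); L[5, ] <- 1
  rad <- directional_radiance(L, bins)
  surf <- propagate_water_column(rad, iops0, 0)     # transmission only
  deep <- propagate_water_column(rad, iops0, 3)
  # the refracted bin of bin 5 (centre 22.5 deg) is bin floor(16.7/5)+1 = 4
  j <- which(surf$radiance[, 1] > 0)
  mu <- cos(bins$centre[j] * pi / 180)
  expect_equal(deep$radiance[j, ], surf$radiance[j, ] * exp(-0.3 * 3 / mu),
               tolerance = 1e-9)
  # depth 0 is the identity after the air-water step
  expect_equal(surf$radiance, propagate_water_column(rad, iops0, 0)$radiance)
})

test_that("packaged reference IOPs give k_d(PAR) of about 0.2 over 4.5 m", {
  iops <- test_iops()
  sun <- solar_position(-30.3095, 115.0072, "2005-04-27", 12)
  r <- clear_sky_radiance(sun)
  ed <- sapply(c(0, 4.5), function(z) {
    to_par(planar_ed(propagate_water_column(r, iops, z)))
  })
  kd <- compute_kd_par(c(0, 4.5), ed)
  expect_equal(kd, 0.2, tolerance = 0.02)
})

test_that("k_d estimation matches closed forms and an independent regression", {
  z <- c(0, 4.5)
  expect_equal(compute_kd_par(z, 100 * exp(-0.2 * z)), 0.2, tolerance = 1e-12)
  expect_equal(compute_kd_par(c(0, 2, 5), c(7, 7, 7)), 0, tolerance = 1e-12)
  set.seed(1)
  z3 <- c(0, 2, 4.5)
  e3 <- 50 * exp(-0.31 * z3) * exp(rnorm(3, 0, 0.05))
  expect_equal(compute_kd_par(z3, e3), -oracle_ls_slope(z3, log(e3)),
               tolerance = 1e-9)
  expect_error(compute_kd_par(z, c(1, -1)), "positive")
})

test_that("k_d increases when absorption increases", {
  sun <- solar_position(-30.3095, 115.0072, "2005-04-27", 12)
  r <- clear_sky_radiance(sun)
  kd_of <- function(a_extra) {
    iops <- test_iops()
    iops$a <- iops$a + a_extra
    ed <- sapply(c(0, 4.5), function(z) {
      to_par(planar_ed(propagate_water_column(r, iops, z)))
    })
    compute_kd_par(c(0, 4.5), ed)
  }
  kds <- sapply(c(0, 0.05, 0.1, 0.2), kd_of)
  expect_true(all(diff(kds) > 0))
})

test_that("shading is a spectrally neutral multiplier and nothing else", {
  rad <- test_noon_rad()
  expect_equal(apply_shading(rad, 0)$radiance, rad$radiance)
  expect_equal(apply_shading(rad, 0.5)$radiance, rad$radiance * 0.5)
  expect_equal(apply_shading(rad, 0.95)$radiance, rad$radiance * 0.05)
  expect_error(apply_shading(rad, 1), "\\[0, 1\\)")
  expect_error(apply_shading(rad, -0.1), "\\[0, 1\\)")
  # shading-PAR commutation to 1e-12 relative
  p0 <- to_par(planar_ed(rad))
  for (s in c(0.1, 0.4, 0.85)) {
    expect_equal(to_par(planar_ed(apply_shading(rad, s))), (1 - s) * p0,
                 tolerance = 1e-12)
  }
})

test_that("the light chain is linear and diurnally symmetric", {
  iops <- test_iops()
  sun <- solar_position(-30.3095, 115.0072, "2005-04-27", 10)
  r <- clear_sky_radiance(sun)
  # linearity: scaling the boundary scales everything
  r2 <- directional_radiance(r$radiance * 3, r$bins, r$bands)
  expect_equal(propagate_water_column(r2, iops)$radiance,
               propagate_water_column(r, iops)$radiance * 3, tolerance = 1e-12)
  # hours mirrored about noon give identical radiance to 1e-9
  hrs <- diurnal_hours(-30.3095, "2005-04-27")
  ra <- clear_sky_radiance(solar_position(-30.3095, 0, "2005-04-27", hrs[3]))
  rb <- clear_sky_radiance(solar_position(-30.3095, 0, "2005-04-27", hrs[10]))
  expect_equal(ra$radiance, rb$radiance, tolerance = 1e-9)
})

test_that("diurnal hour centres are symmetric and span daylight", {
  h <- diurnal_hours(-30.3095, "2005-04-27")
  expect_equal(length(h), 12L)
  expect_equal(h + rev(h), rep(24, 12))   # symmetric about solar noon
  sun_first <- solar_position(-30.3095, 0, "2005-04-27", h[1])
  expect_true(sun_first$sun_up)
})
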
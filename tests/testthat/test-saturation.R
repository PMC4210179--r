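# Saturation metrics: % leaf area above E_k, H^A_sat, surfaces, isoclines.

fake_field <- function(par, area = rep(1, length(par))) {
  structure(data.frame(facet = seq_along(par), area = area, par = par),
            class = c("leaf_field", "data.frame"))
}

test_that("saturated fraction is inclusive and area-weighted", {
  expect_equal(saturated_fraction(fake_field(c(100, 120)), 50), 100)
  expect_equal(saturated_fraction(fake_field(c(0, 0, 0)), 50), 0)
  eps <- 1e-9
  expect_equal(saturated_fraction(fake_field(c(50 - eps, 50 + eps)), 50), 50)
  expect_equal(saturated_fraction(fake_field(50), 50), 100)  # inclusive
  # area weighting: a big saturated facet dominates
  expect_equal(saturated_fraction(fake_field(c(100, 10), area = c(3, 1)), 50),
               75)
  expect_error(saturated_fraction(fake_field(numeric(0))), "zero leaf area")
})

test_that("leaf PAR histograms normalise and shift one octave under halving", {
  f1 <- fake_field(123.4)
  h1 <- leaf_par_histogram(f1)
  expect_equal(sum(h1$percent_area), 100, tolerance = 1e-9)
  expect_equal(sum(h1$percent_area > 0), 1L)
  expect_equal(attr(h1, "ek_markers"), c(45, 55))
  # log2-spaced bins: halving all PAR moves mass exactly one bin left
  set.seed(3)
  par <- exp(runif(200, log(20), log(600)))
  breaks <- 2^seq(2, 11, by = 1)
  h <- leaf_par_histogram(fake_field(par), breaks)
  hh <- leaf_par_histogram(fake_field(par / 2), breaks / 2)
  expect_equal(h$percent_area, hh$percent_area, tolerance = 1e-12)
  expect_error(leaf_par_histogram(fake_field(c(1, 1e5)), breaks), "cover")
})

test_that("H^A_sat integrates hourly percentages with a 1200 ceiling", {
  h <- seq(6.5, 17.5, by = 1)
  expect_equal(hasat(saturation_series(h, rep(100, 12))), 1200)
  expect_equal(hasat(saturation_series(h, rep(50, 12))), 600)
  expect_equal(hasat(saturation_series(h, rep(0, 12))), 0)
  expect_error(saturation_series(h, rep(150, 12)))
})

test_that("top-of-canopy H_sat counts saturated hours", {
  h <- 1:12
  expect_equal(hsat_top(saturation_series(h, rep(0, 12), rep(300, 12)), 50), 12)
  expect_equal(hsat_top(saturation_series(h, rep(0, 12), rep(10, 12)), 50), 0)
  toc <- c(rep(10, 3), rep(80, 6), rep(10, 3))
  expect_equal(hsat_top(saturation_series(h, rep(0, 12), toc), 50), 6)
})

test_that("wave statistics are the plain mean and sample SD", {
  expect_equal(wave_average(rep(7, 14))$sd, 0)
  wa <- wave_average(c(40, 60))
  expect_equal(wa$mean, 50)
  expect_equal(wa$sd, 14.142, tolerance = 1e-3)   # sqrt(200)
  set.seed(1); x <- runif(14)
  expect_equal(wave_average(x)$mean, sum(x) / 14, tolerance = 1e-12)
  expect_error(wave_average(numeric(0)))
})

test_that("paired wave comparison matches the textbook paired t-test", {
  id <- compare_wave_treatments(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0); expect_equal(id$p, 1)
  # constant unit differences: zero variance, flagged limit case
  deg <- compare_wave_treatments(c(1, 2, 3), c(2, 3, 4))
  expect_equal(deg$mean_difference, -1)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  set.seed(2)
  lo <- runif(10); hi <- lo + rnorm(10, 0, 0.2)
  res <- compare_wave_treatments(lo, hi)
  tt <- t.test(lo - hi)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

# deterministic synthetic surface: H = (1200 - 120 L)(1 - s/100), exactly
# bilinear with clean isoclines
toy_surface <- function(lai = c(1, 2, 4, 6, 8),
                        shading = c(0, 20, 40, 60, 80)) {
  cells <- expand.grid(lai = lai, shading = shading)
  cells$hasat <- (1200 - 120 * cells$lai) * (1 - cells$shading / 100)
  build_hasat_surface(cells)
}

test_that("surface assembly validates bounds, completeness and monotonicity", {
  s <- toy_surface()
  expect_s3_class(s, "hasat_surface")
  expect_true(all(s$values >= 0 & s$values <= 1200))
  cells <- expand.grid(lai = c(1, 2), shading = c(0, 50))
  cells$hasat <- c(100, 90, 50, 45)
  expect_error(build_hasat_surface(cells[-2, ]), "missing grid cells")
  bad <- cells; bad$hasat <- c(100, 300, 50, 45)   # increases with LAI
  expect_error(build_hasat_surface(bad), "non-increasing in LAI")
  worse <- cells; worse$hasat <- c(100, 90, 150, 45)
  expect_error(build_hasat_surface(worse), "non-increasing in shading")
  over <- cells; over$hasat <- c(1300, 90, 50, 45)
  expect_error(build_hasat_surface(over), "outside")
  # a fully shaded column would be identically zero
  dark <- expand.grid(lai = c(1, 2), shading = c(0, 100))
  dark$hasat <- c(100, 90, 0, 0)
  sd0 <- build_hasat_surface(dark)
  expect_true(all(sd0$values[, "100"] == 0))
})

test_that("isoclines follow the closed form on a separable surface", {
  s <- toy_surface()
  iso <- extract_isoclines(s, levels = c(200, 400, 600))
  expect_gt(length(iso), 0)
  for (l in iso) {
    # points re-interpolate to the level within 1% of 1200
    vals <- mapply(function(x, y) canopylight:::interp_surface(s, x, y),
                   l$lai, l$shading)
    expect_lt(max(abs(vals - l$level)), 12)
    # closed form: s = 100 (1 - level / (1200 - 120 L))
    s_pred <- 100 * (1 - l$level / (1200 - 120 * l$lai))
    expect_lt(max(abs(l$shading - s_pred)), 2)
  }
  flat <- toy_surface()
  flat$values[] <- 500
  expect_error(extract_isoclines(flat), "degenerate")
  out <- extract_isoclines(s, levels = 5000)
  expect_equal(attr(out, "missing_levels"), 5000)
})

test_that("unshaded-LAI equivalence follows isoclines and flags extrapolation", {
  s <- toy_surface()
  # identity on the unshaded axis
  expect_equal(as.numeric(equivalent_unshaded_lai(s, 4, 0)), 4,
               tolerance = 1e-9)
  # closed form: H(2, 50) = (1200-240)*0.5 = 480 -> L* = (1200-480)/120 = 6
  eq <- equivalent_unshaded_lai(s, 2, 50)
  expect_equal(as.numeric(eq), 6, tolerance = 1e-9)
  expect_false(attr(eq, "extrapolated"))
  # severe shading maps beyond the grid and is flagged, never silent
  eq2 <- equivalent_unshaded_lai(s, 2, 80)
  expect_true(attr(eq2, "extrapolated"))
  expect_gt(as.numeric(eq2), 8)
})

test_that("the shading-equivalence error recovers constructed shifts", {
  a <- toy_surface()
  expect_equal(as.numeric(shading_equivalence_error(a, a)), 0)
  # b = a shifted by exactly 5 shading points
  cells <- expand.grid(lai = a$lai, shading = a$shading)
  cells$hasat <- (1200 - 120 * cells$lai) * (1 - (cells$shading - 5) / 100)
  cells$hasat <- pmin(cells$hasat, 1200)
  b <- build_hasat_surface(cells)
  err <- shading_equivalence_error(a, b)
  expect_equal(as.numeric(err), 5, tolerance = 0.1)
})

test_that("E_k surfaces bracket and hasat is a monotone functional", {
  h <- seq(6.5, 17.5, by = 1)
  lo <- saturation_series(h, rep(60, 12))
  hi <- saturation_series(h, c(rep(60, 6), rep(80, 6)))
  expect_gte(hasat(hi), hasat(lo))
  # thresholding a fixed field at growing E_k is non-increasing
  set.seed(9)
  f <- fake_field(exp(runif(300, log(5), log(400))))
  sf <- sapply(c(45, 50, 55), function(ek) saturated_fraction(f, ek))
  expect_true(all(diff(sf) <= 0))
})
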
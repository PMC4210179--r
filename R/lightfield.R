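# Boundary light field: solar geometry, clear-sky spectral model,
# plane-parallel water column, shading. All radiometry is azimuthally
# averaged: radiance depends on zenith angle and waveband only.

WATER_REFRACTIVE_INDEX <- 1.34

#' Zenith quadrature of the downward hemisphere
#'
#' Partition of zenith angle 0--90 degrees into `n` equal-angle bins.
#' For each bin the solid angle `domega = 2 pi (cos t1 - cos t2)` and the
#' exact cosine-weighted solid angle `cw = pi (cos^2 t1 - cos^2 t2)` are
#' tabulated; planar irradiance of a binned radiance field is
#' `sum(L * cw)`, which is exact for radiance constant within a bin.
#'
#' @param n Number of bins (default 18, i.e. 5 degree bins).
#' @return Data frame with columns `lower`, `upper`, `centre` (deg),
#'   `domega`, `cw` (sr).
#' @export
zenith_bins <- function(n = 18L) {
  stopifnot(n >= 1)
  edges <- seq(0, 90, length.out = n + 1L)
  t1 <- edges[-(n + 1L)] * pi / 180
  t2 <- edges[-1L] * pi / 180
  data.frame(
    lower = edges[-(n + 1L)],
    upper = edges[-1L],
    centre = (edges[-(n + 1L)] + edges[-1L]) / 2,
    domega = 2 * pi * (cos(t1) - cos(t2)),
    cw = pi * (cos(t1)^2 - cos(t2)^2)
  )
}

#' Azimuthally uniform directional spectral radiance
#'
#' The canopy's boundary condition: band-integrated radiance
#' (W m^-2 sr^-1 per band) on a zenith-bin by waveband grid, with no azimuth
#' dependence by construction.
#'
#' @param radiance Numeric matrix, `nrow(bins)` x `nrow(bands)`, >= 0.
#' @param bins Zenith quadrature from [zenith_bins()].
#' @param bands Band grid from [spectral_bands()].
#' @return An object of class `directional_radiance`.
#' @export
directional_radiance <- function(radiance, bins = zenith_bins(),
                                 bands = spectral_bands()) {
  radiance <- as.matrix(radiance)
  stopifnot(nrow(radiance) == nrow(bins), ncol(radiance) == nrow(bands))
  if (any(!is.finite(radiance)) || any(radiance < 0)) {
    stop("radiance must be finite and non-negative")
  }
  structure(list(radiance = radiance, bins = bins, bands = bands),
            class = "directional_radiance")
}

#' @export
print.directional_radiance <- function(x, ...) {
  ed <- planar_ed(x)
  cat("Directional radiance:", nrow(x$bins), "zenith bins x",
      nrow(x$bands), "bands\n")
  cat(sprintf("  E_d (planar, total) = %.4g W m^-2;  PAR = %.4g umol m^-2 s^-1\n",
              sum(ed), to_par(ed, x$bands)))
  invisible(x)
}

#' Planar downwelling irradiance per band
#'
#' `E_d(band) = sum_bins L * cw`, the cosine-weighted integral of the binned
#' radiance over the downward hemisphere.
#'
#' @param rad A [directional_radiance()].
#' @return Numeric vector, W m^-2 per band.
#' @export
planar_ed <- function(rad) {
  stopifnot(inherits(rad, "directional_radiance"))
  as.numeric(crossprod(rad$radiance, rad$bins$cw))
}

#' Solar position and refracted in-water zenith
#'
#' Low-precision solar ephemeris (NOAA formulation: fractional-year Fourier
#' series for declination and the equation of time), evaluated at local
#' apparent solar time, plus the Snell-refracted underwater zenith
#' `asin(sin(z)/1.34)`.
#'
#' @param latitude,longitude Degrees (south/west negative).
#' @param date A `Date` (or string coercible to one).
#' @param hour_solar Local apparent solar hour (12 = solar noon).
#' @return List with `air_zenith`, `water_zenith` (degrees), `declination`,
#'   `sun_up` (logical).
#' @export
solar_position <- function(latitude, longitude, date, hour_solar) {
  stopifnot(abs(latitude) <= 90)
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  # declination evaluated at local noon: constant over the day, which makes
  # the morning/afternoon zenith symmetry exact (exploited by the driver)
  g <- 2 * pi / 365 * (doy - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)   # radians
  ha <- (hour_solar - 12) * 15 * pi / 180
  phi <- latitude * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
  cosz <- min(1, max(-1, cosz))
  zen <- acos(cosz) * 180 / pi
  wzen <- asin(min(1, sin(zen * pi / 180) / WATER_REFRACTIVE_INDEX)) * 180 / pi
  list(air_zenith = zen, water_zenith = wzen,
       declination = decl * 180 / pi, sun_up = zen < 90)
}

#' Daylight hour centres for the diurnal design
#'
#' `n` time points at the centres of equal subdivisions of the daylight
#' period, in local apparent solar hours, symmetric about solar noon. Night
#' contributes zero light, so diurnal integrals run over these points only.
#'
#' @inheritParams solar_position
#' @param n Number of hourly intervals (default 12).
#' @return Numeric vector of solar hours, length `n`.
#' @export
diurnal_hours <- function(latitude, date, n = 12L) {
  sp <- solar_position(latitude, 0, date, 12)
  phi <- latitude * pi / 180
  decl <- sp$declination * pi / 180
  x <- -tan(phi) * tan(decl)
  if (x >= 1) stop("polar night: sun never rises on this date/latitude")
  x <- max(-1, x)
  h0 <- acos(x) * 180 / pi / 15      # half daylength, hours
  12 + (seq_len(n) - (n + 1) / 2) * (2 * h0 / n)
}

# Band-integrated extraterrestrial solar irradiance, W m^-2 per band:
# blackbody shape at 5772 K scaled to a 1361 W m^-2 solar constant.
extraterrestrial_bands <- function(bands = spectral_bands()) {
  planck <- function(lam) {   # lam in m; spectral radiance shape
    2 * PLANCK_H * LIGHT_C^2 / lam^5 / expm1(PLANCK_H * LIGHT_C / (lam * 1.380649e-23 * 5772))
  }
  tot <- integrate(function(l) planck(l * 1e-9), 10, 1e5, rel.tol = 1e-8,
                   subdivisions = 500L)$value
  vapply(seq_len(nrow(bands)), function(i) {
    integrate(function(l) planck(l * 1e-9), bands$lower[i], bands$upper[i],
              rel.tol = 1e-9)$value
  }, numeric(1)) / tot * 1361
}

# Kasten-Young relative air mass
air_mass <- function(zenith_deg) {
  1 / (cos(zenith_deg * pi / 180) +
         0.50572 * (96.07995 - zenith_deg)^(-1.6364))
}

#' Clear-sky spectral radiance above the water surface
#'
#' Two-component clear-sky model: a direct beam attenuated by Rayleigh and
#' Angstrom aerosol optical depths along the slant path, plus an isotropic
#' diffuse skylight term fed by half the Rayleigh-scattered and a quarter of
#' the aerosol-scattered flux. The direct beam is assigned to the zenith bin
#' containing the solar zenith; skylight is spread over all bins. Azimuthal
#' structure never arises because the direct beam is represented as an
#' azimuthally averaged ring (the canopy scene is periodic and orientation-
#' free, so only the zenith dependence matters).
#'
#' @param sun Solar geometry from [solar_position()].
#' @param bands,bins Grids.
#' @param aerosol_beta,aerosol_alpha Angstrom turbidity parameters.
#' @return Above-water [directional_radiance()]; all-zero when the sun is
#'   below the horizon.
#' @export
clear_sky_radiance <- function(sun, bands = spectral_bands(),
                               bins = zenith_bins(),
                               aerosol_beta = 0.03, aerosol_alpha = 1.3) {
  L <- matrix(0, nrow(bins), nrow(bands))
  if (!sun$sun_up || sun$air_zenith >= 89) {
    return(directional_radiance(L, bins, bands))
  }
  e0 <- extraterrestrial_bands(bands)
  m <- air_mass(sun$air_zenith)
  lam_um <- bands$centre / 1000
  tau_r <- 0.008735 * lam_um^(-4.08)
  tau_a <- aerosol_beta * lam_um^(-aerosol_alpha)
  mu0 <- cos(sun$air_zenith * pi / 180)
  e_direct <- e0 * mu0 * exp(-(tau_r + tau_a) * m)
  e_diffuse <- e0 * mu0 * (0.5 * (1 - exp(-tau_r * m)) * exp(-tau_a * m) +
                             0.25 * (1 - exp(-tau_a * m)))
  ib <- findInterval(sun$air_zenith, bins$upper, left.open = TRUE) + 1L
  ib <- min(ib, nrow(bins))
  L[ib, ] <- e_direct / bins$cw[ib]
  L <- L + matrix(e_diffuse / pi, nrow(bins), nrow(bands), byrow = TRUE)
  directional_radiance(L, bins, bands)
}

#' Azimuthally average a zenith x azimuth radiance field
#'
#' Collapses a radiance field tabulated over zenith bins and azimuth sectors
#' to the azimuthally uniform representation by the per-zenith mean over
#' azimuth. The cosine-weighted planar irradiance is conserved exactly
#' (the cosine weight depends on zenith only).
#'
#' @param radiance Array `nzenith x nazimuth x nband` (equal-width azimuth
#'   sectors) or matrix `nzenith x nazimuth` for a single band.
#' @param bins,bands Grids.
#' @return A [directional_radiance()].
#' @export
azimuthal_average <- function(radiance, bins = zenith_bins(),
                              bands = spectral_bands()) {
  if (is.matrix(radiance)) radiance <- array(radiance, c(dim(radiance), 1L))
  stopifnot(length(dim(radiance)) == 3, dim(radiance)[1] == nrow(bins))
  L <- apply(radiance, c(1, 3), mean)
  if (dim(radiance)[3] == 1L && nrow(bands) > 1L) {
    stop("band dimension of input does not match band grid")
  }
  directional_radiance(L, bins, bands)
}

#' Water inherent optical properties
#'
#' Band-resolved absorption and backscatter coefficients for the
#' plane-parallel water column. [reference_iops()] loads the packaged
#' reference set (clear coastal water: pure-water absorption plus a coloured
#' dissolved organic matter term, pure-seawater plus particulate
#' backscatter), chosen so that the 4.5 m column yields a diffuse PAR
#' attenuation k_d of about 0.2 m^-1.
#'
#' @param absorption,backscatter Numeric vectors per band, m^-1, >= 0.
#' @param depth Default water depth, m.
#' @param bands Band grid.
#' @return Object of class `water_iops`.
#' @export
water_iops <- function(absorption, backscatter, depth = 4.5,
                       bands = spectral_bands()) {
  stopifnot(length(absorption) == nrow(bands),
            length(backscatter) == nrow(bands),
            all(absorption >= 0), all(backscatter >= 0), depth >= 0)
  structure(list(a = absorption, bb = backscatter, depth = depth,
                 bands = bands), class = "water_iops")
}

#' @rdname water_iops
#' @param file Optional path to a CSV with columns `wavelength_nm`,
#'   `absorption_m1`, `backscatter_m1`; defaults to the packaged set.
#' @export
reference_iops <- function(file = NULL, depth = 4.5) {
  if (is.null(file)) {
    file <- system.file("extdata", "water_iops_reference.csv",
                        package = "canopylight", mustWork = TRUE)
  }
  d <- read.csv(file)
  bands <- spectral_bands()
  water_iops(resample_to_bands(d$wavelength_nm, d$absorption_m1, bands),
             resample_to_bands(d$wavelength_nm, d$backscatter_m1, bands),
             depth = depth, bands = bands)
}

# Unpolarised Fresnel transmittance air -> water at incidence theta (deg)
fresnel_transmittance <- function(theta_deg, n = WATER_REFRACTIVE_INDEX) {
  ti <- theta_deg * pi / 180
  tt <- asin(pmin(1, sin(ti) / n))
  rs <- (sin(ti - tt) / sin(ti + tt))^2
  rp <- (tan(ti - tt) / tan(ti + tt))^2
  r <- ifelse(theta_deg < 1e-6, ((n - 1) / (n + 1))^2, (rs + rp) / 2)
  1 - r
}

#' Propagate radiance across the surface and through the water column
#'
#' Plane-parallel transfer in two steps. (1) Air--water transmission: each
#' zenith bin's planar irradiance contribution is multiplied by the Fresnel
#' transmittance at its bin-centre incidence and reassigned to the bin
#' containing the Snell-refracted zenith. (2) Column transfer over `depth`
#' metres: per-direction beam attenuation `exp(-(a + b_b) z / cos t)` plus a
#' single-scattering source -- the flux scattered out of each beam, reduced
#' by absorption along its nominal path and re-emitted isotropically into
#' the downward hemisphere with efficiency 1/2. Depth 0 returns the
#' transmitted field unchanged; the operator is linear in the input
#' radiance.
#'
#' @param rad Above-water [directional_radiance()].
#' @param iops A [water_iops()].
#' @param depth Path length through the column, m (default `iops$depth`).
#' @return In-water [directional_radiance()] at the canopy top.
#' @export
propagate_water_column <- function(rad, iops, depth = iops$depth) {
  stopifnot(inherits(rad, "directional_radiance"), inherits(iops, "water_iops"),
            depth >= 0)
  bins <- rad$bins
  nb <- nrow(bins)
  # surface transmission with refraction
  Lw <- matrix(0, nb, nrow(rad$bands))
  tf <- fresnel_transmittance(bins$centre)
  wzen <- asin(pmin(1, sin(bins$centre * pi / 180) / WATER_REFRACTIVE_INDEX)) * 180 / pi
  for (i in seq_len(nb)) {
    e_i <- rad$radiance[i, ] * bins$cw[i] * tf[i]
    j <- findInterval(wzen[i], bins$upper, left.open = TRUE) + 1L
    j <- min(j, nb)
    Lw[j, ] <- Lw[j, ] + e_i / bins$cw[j]
  }
  if (depth == 0) return(directional_radiance(Lw, bins, rad$bands))
  mu <- cos(bins$centre * pi / 180)
  att_beam <- exp(-outer(1 / mu, iops$a + iops$bb) * depth)
  att_abs <- exp(-outer(1 / mu, iops$a) * depth)
  Lz <- Lw * att_beam
  # flux scattered out of each beam that survives absorption, isotropised down
  scat <- colSums(Lw * (att_abs - att_beam) * bins$cw)
  Lz <- Lz + matrix(0.5 * scat / pi, nb, length(scat), byrow = TRUE)
  directional_radiance(Lz, bins, rad$bands)
}

#' Diffuse attenuation coefficient of planar PAR irradiance
#'
#' Least-squares slope of `-log(E_d)` against depth; with exactly two depths
#' this is the two-point formula `log(E1/E2)/(z2 - z1)`.
#'
#' @param depths Numeric vector of depths, m (>= 2 values).
#' @param ed_par Planar downwelling PAR at those depths (> 0).
#' @return k_d in m^-1.
#' @export
compute_kd_par <- function(depths, ed_par) {
  stopifnot(length(depths) == length(ed_par), length(depths) >= 2)
  if (any(ed_par <= 0)) stop("irradiances must be positive")
  unname(-coef(lm(log(ed_par) ~ depths))[2])
}

#' Apply a spectrally neutral shading treatment
#'
#' Multiplies every (zenith bin, band) radiance value by `1 - fraction`;
#' nothing else changes. Mirrors neutral-density shade cloth over the
#' canopy.
#'
#' @param rad A [directional_radiance()].
#' @param fraction Shading fraction in `[0, 1)` (e.g. 0.5 for 50 percent).
#' @return Shaded [directional_radiance()].
#' @export
apply_shading <- function(rad, fraction) {
  stopifnot(inherits(rad, "directional_radiance"))
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop("shading fraction must lie in [0, 1)")
  }
  directional_radiance(rad$radiance * (1 - fraction), rad$bins, rad$bands)
}

#' Hourly top-of-canopy radiance series for a site
#'
#' Convenience wrapper: for each diurnal hour centre, run the clear-sky
#' model and the water-column transfer to the canopy-top depth.
#'
#' @param latitude,longitude Site coordinates, degrees.
#' @param date Date of simulation.
#' @param iops Water IOPs; depth taken from `iops$depth`.
#' @param n_hours Number of diurnal points (default 12).
#' @param bins,bands Grids.
#' @return List with `hours` (solar hours) and `radiance` (list of
#'   [directional_radiance()] per hour).
#' @export
toc_radiance_series <- function(latitude, longitude, date, iops,
                                n_hours = 12L, bins = zenith_bins(),
                                bands = spectral_bands()) {
  hours <- diurnal_hours(latitude, date, n_hours)
  rads <- lapply(hours, function(h) {
    sun <- solar_position(latitude, longitude, date, h)
    propagate_water_column(clear_sky_radiance(sun, bands, bins), iops)
  })
  list(hours = hours, radiance = rads)
}
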
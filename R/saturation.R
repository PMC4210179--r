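# Canopy-scale photosynthetic saturation metrics: % leaf area at or above
# the saturating irradiance E_k, the diurnal time integral H^A_sat, wave
# statistics, LAI x shading surfaces, isoclines and equivalence queries.

#' Percentage of leaf area at or above a saturating irradiance
#'
#' Area-weighted: `100 * sum(area of leaf facets with PAR >= E_k) /
#' total leaf area`. The comparison is inclusive.
#'
#' @param field A [leaf_irradiance()] field.
#' @param ek Saturating irradiance E_k, micromol quanta m^-2 s^-1
#'   (plausible range 45--55, midpoint 50).
#' @return Percentage in 0--100.
#' @export
saturated_fraction <- function(field, ek = 50) {
  stopifnot(inherits(field, "leaf_field"), ek > 0)
  ta <- sum(field$area)
  if (nrow(field) == 0 || ta <= 0) stop("leaf field has zero leaf area")
  100 * sum(field$area[field$par >= ek]) / ta
}

#' Area-fraction histogram of leaf-level PAR
#'
#' Distribution of leaf saturation state: the percentage of leaf area in
#' each PAR bin (fractions sum to 100). The conventional E_k markers at 45
#' and 55 are attached for plotting.
#'
#' @param field A [leaf_irradiance()] field.
#' @param breaks Bin edges covering the observed PAR range (default 24
#'   log2-spaced bins, padded).
#' @return Data frame with `lower`, `upper`, `mid`, `percent_area`;
#'   attribute `ek_markers = c(45, 55)`.
#' @export
leaf_par_histogram <- function(field, breaks = NULL) {
  stopifnot(inherits(field, "leaf_field"))
  if (is.null(breaks)) {
    lo <- max(min(field$par), 1e-3) / 2
    hi <- max(field$par) * 2 + 1e-3
    breaks <- 2^seq(log2(lo), log2(hi), length.out = 25L)
  }
  if (min(field$par) < breaks[1] || max(field$par) > breaks[length(breaks)]) {
    stop("breaks do not cover the observed PAR range")
  }
  bin <- findInterval(field$par, breaks, rightmost.closed = TRUE)
  frac <- vapply(seq_len(length(breaks) - 1L), function(i) {
    sum(field$area[bin == i])
  }, numeric(1)) / sum(field$area) * 100
  structure(data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                       mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                       percent_area = frac),
            ek_markers = c(45, 55))
}

#' Diurnal saturation series
#'
#' Hourly record of the canopy saturation state: percentage of leaf area at
#' or above E_k, and the top-of-canopy PAR, at each of the (nominally 12)
#' daylight hour points. Night contributes zero and is not stored.
#'
#' @param hours Solar-hour time points.
#' @param sat_percent Percentage of leaf area >= E_k per time point.
#' @param toc_par Top-of-canopy planar PAR per time point.
#' @return Object of class `saturation_series` (a data frame).
#' @export
saturation_series <- function(hours, sat_percent, toc_par = rep(NA_real_, length(hours))) {
  stopifnot(length(hours) == length(sat_percent),
            all(sat_percent >= 0 - 1e-9), all(sat_percent <= 100 + 1e-9))
  structure(data.frame(hour = hours, sat_percent = sat_percent,
                       toc_par = toc_par),
            class = c("saturation_series", "data.frame"))
}

#' Diurnally accumulated percentage of saturated leaf area, H^A_sat
#'
#' Time integral of the percentage of leaf area at or above E_k over the
#' day, by the rectangle rule with 1-hour widths over the 12 hourly
#' daylight points (night contributes zero). Units: % leaf area x hour;
#' a canopy fully saturated for 12 daylight hours scores exactly 1200.
#'
#' @param series A [saturation_series()].
#' @return H^A_sat in % leaf area x hour.
#' @export
hasat <- function(series) {
  stopifnot(inherits(series, "saturation_series"))
  sum(series$sat_percent)   # 1-hour rectangles
}

#' Daily hours of saturating top-of-canopy irradiance, H_sat
#'
#' Count of hourly samples whose top-of-canopy PAR is at or above E_k,
#' times 1 hour.
#'
#' @param series A [saturation_series()] with `toc_par` filled.
#' @param ek Saturating irradiance.
#' @return Hours (integer-valued numeric).
#' @export
hsat_top <- function(series, ek = 50) {
  stopifnot(inherits(series, "saturation_series"), all(is.finite(series$toc_par)))
  sum(series$toc_par >= ek)
}

#' Mean and standard deviation over movement snapshots
#'
#' Unweighted mean and sample standard deviation of a metric across the
#' canopy movement positions (the high-wave treatment averages 14).
#'
#' @param values Numeric vector of per-snapshot metric values.
#' @return List with `mean` and `sd` (`sd` is `NA` for a single snapshot).
#' @export
wave_average <- function(values) {
  if (length(values) == 0) stop("no snapshot values supplied")
  list(mean = mean(values), sd = if (length(values) >= 2) sd(values) else NA_real_)
}

#' Paired comparison of low- and high-wave treatments
#'
#' Standard paired t-test on matched (LAI, E_k) cells of the two wave
#' treatments.
#'
#' @param low,high Numeric vectors of paired metric values.
#' @return List with `mean_difference` (low - high), `t`, `p`,
#'   `degenerate` (TRUE when the differences have zero variance).
#' @export
compare_wave_treatments <- function(low, high) {
  stopifnot(length(low) == length(high), length(low) >= 2)
  d <- low - high
  if (sd(d) == 0) {
    return(list(mean_difference = mean(d),
                t = if (mean(d) == 0) 0 else Inf,
                p = if (mean(d) == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(low, high, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, degenerate = FALSE)
}

#' H^A_sat surface over the LAI x shading grid
#'
#' Assembles per-cell H^A_sat values (and optional per-cell SD across
#' movement snapshots) into a gridded surface, checking completeness, the
#' 0--1200 bounds, and the double monotonicity the physics implies:
#' increasing either LAI or shading cannot increase H^A_sat.
#'
#' @param cells Data frame with columns `lai`, `shading` (percent),
#'   `hasat`, optionally `sd`.
#' @param ek E_k the surface was computed at.
#' @param wave_mode "low" or "high".
#' @param check If `TRUE` (default) assert bounds and monotonicity.
#' @param tol Monotonicity tolerance in % leaf area x hour (default 0.1,
#'   i.e. less than 1e-4 of the 0--1200 range): the per-cell values are
#'   Monte-Carlo estimates, and cells holding almost no saturated area can
#'   wobble by a fraction of a unit between fixture realisations.
#' @return Object of class `hasat_surface`: matrix `values` (LAI rows x
#'   shading columns), axes, `ek`, `wave_mode`, optional `sd` matrix.
#' @export
build_hasat_surface <- function(cells, ek = 50, wave_mode = "low",
                                check = TRUE, tol = 0.1) {
  lai <- sort(unique(cells$lai)); sh <- sort(unique(cells$shading))
  full <- expand.grid(lai = lai, shading = sh)
  key <- paste(cells$lai, cells$shading)
  missing <- !(paste(full$lai, full$shading) %in% key)
  if (any(missing)) {
    stop("missing grid cells: ",
         paste(paste0("(", full$lai[missing], ", ", full$shading[missing], ")"),
               collapse = " "))
  }
  m <- matrix(NA_real_, length(lai), length(sh),
              dimnames = list(lai, sh))
  m[cbind(match(cells$lai, lai), match(cells$shading, sh))] <- cells$hasat
  sdm <- NULL
  if (!is.null(cells$sd)) {
    sdm <- m; sdm[] <- NA_real_
    sdm[cbind(match(cells$lai, lai), match(cells$shading, sh))] <- cells$sd
  }
  if (check) {
    if (any(m < -1e-9) || any(m > 1200 + 1e-9)) {
      stop("H^A_sat values outside [0, 1200]")
    }
    if (any(diff(m) > tol)) stop("H^A_sat not non-increasing in LAI")
    if (any(t(diff(t(m))) > tol)) stop("H^A_sat not non-increasing in shading")
  }
  structure(list(values = m, lai = lai, shading = sh, ek = ek,
                 wave_mode = wave_mode, sd = sdm),
            class = "hasat_surface")
}

#' @export
print.hasat_surface <- function(x, ...) {
  cat(sprintf("H^A_sat surface (E_k = %g, %s wave): %d LAI x %d shading levels, range %.0f--%.0f\n",
              x$ek, x$wave_mode, length(x$lai), length(x$shading),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.hasat_surface <- function(x, levels = c(50, 100, seq(200, 800, by = 100)),
                               ...) {
  graphics::filled.contour(
    x$lai, x$shading, x$values,
    xlab = "Leaf area index", ylab = "Shading (%)",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::contour(x$lai, x$shading, x$values, levels = levels,
                        add = TRUE)
    }, ...)
  invisible(x)
}

# bilinear interpolation on the surface grid
interp_surface <- function(surface, lai, shading) {
  gx <- surface$lai; gy <- surface$shading; z <- surface$values
  if (lai < min(gx) || lai > max(gx) || shading < min(gy) || shading > max(gy)) {
    stop("query point outside the surface grid")
  }
  i <- max(1L, min(findInterval(lai, gx), length(gx) - 1L))
  j <- max(1L, min(findInterval(shading, gy), length(gy) - 1L))
  tx <- (lai - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (shading - gy[j]) / (gy[j + 1] - gy[j])
  (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
    (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
}

#' Extract H^A_sat isoclines
#'
#' Marching-squares contours (linear interpolation on the grid, via
#' `grDevices::contourLines`) of the surface at the requested levels; the
#' conventional set is 50, 100, 200, then steps of 100 up to 800.
#'
#' @param surface A [build_hasat_surface()].
#' @param levels Contour levels.
#' @return List of contour polylines (`lai`, `shading`, `level`); levels
#'   outside the surface range yield no polyline and are flagged in the
#'   `missing_levels` attribute.
#' @export
extract_isoclines <- function(surface,
                              levels = c(50, 100, seq(200, 800, by = 100))) {
  stopifnot(inherits(surface, "hasat_surface"))
  rng <- range(surface$values)
  if (diff(rng) < 1e-9) stop("surface is degenerate (constant)")
  cl <- contourLines(surface$lai, surface$shading, surface$values,
                     levels = levels)
  out <- lapply(cl, function(l) {
    list(level = l$level, lai = l$x, shading = l$y)
  })
  found <- vapply(out, `[[`, numeric(1), "level")
  attr(out, "missing_levels") <- setdiff(levels, found)
  out
}

# monotone inverse along a decreasing profile y(x): find x with y(x)=target;
# linear extrapolation beyond the last knot when allowed
invert_monotone <- function(x, y, target) {
  stopifnot(length(x) == length(y))
  o <- order(x); x <- x[o]; y <- y[o]
  if (any(diff(y) > 1)) stop("profile is not non-increasing")
  y <- cummin(y)   # lower monotone envelope absorbs sampling wobble
  if (target > y[1] + 1e-9) {
    # brighter than the unshaded minimum-LAI cell: extrapolate below grid
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    return(structure(x[1] + (target - y[1]) / slope, extrapolated = TRUE))
  }
  if (target < y[length(y)] - 1e-9) {
    n <- length(y)
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    if (abs(slope) < 1e-12) {
      return(structure(Inf, extrapolated = TRUE))
    }
    return(structure(x[n] + (target - y[n]) / slope, extrapolated = TRUE))
  }
  # piecewise-linear inverse on the bracketing segment
  i <- max(which(y >= target - 1e-12))
  if (abs(y[i] - target) < 1e-12) return(structure(x[i], extrapolated = FALSE))
  i <- min(i, length(y) - 1L)
  t <- (target - y[i]) / (y[i + 1] - y[i])
  structure(x[i] + t * (x[i + 1] - x[i]), extrapolated = FALSE)
}

#' Unshaded-LAI equivalent of a (LAI, shading) state
#'
#' Follows the H^A_sat isocline through the query point to the unshaded
#' axis: the LAI whose unshaded H^A_sat equals the H^A_sat at
#' `(lai, shading)`. Queries whose isocline leaves the computed grid are
#' answered by linear extrapolation of the unshaded profile and flagged
#' with attribute `extrapolated = TRUE` (a severely shaded canopy can map
#' to an unrealistically large equivalent LAI).
#'
#' @param surface A [build_hasat_surface()].
#' @param lai,shading Query point (shading in percent), inside the grid.
#' @return Equivalent unshaded LAI (numeric, attribute `extrapolated`).
#' @export
equivalent_unshaded_lai <- function(surface, lai, shading) {
  stopifnot(inherits(surface, "hasat_surface"))
  target <- interp_surface(surface, lai, shading)
  unshaded <- surface$values[, which.min(surface$shading)]
  invert_monotone(surface$lai, unshaded, target)
}

#' Maximum shading-equivalence error between two surfaces
#'
#' For every grid cell of surface A, the shading shift that must be applied
#' to surface B (monotone interpolation along B's shading axis at the same
#' LAI) to reproduce A's value; returns the maximum absolute shift in
#' percentage points. Cells whose value lies outside B's range in that LAI
#' column are flagged and excluded.
#'
#' @param a,b [build_hasat_surface()] objects on identical grids.
#' @return Max |shift| in shading percentage points; attribute
#'   `excluded_cells` counts non-overlapping cells.
#' @export
shading_equivalence_error <- function(a, b) {
  stopifnot(identical(a$lai, b$lai), identical(a$shading, b$shading))
  shifts <- c(); excluded <- 0L
  for (i in seq_along(a$lai)) {
    colb <- b$values[i, ]
    for (j in seq_along(a$shading)) {
      va <- a$values[i, j]
      if (va > max(colb) + 1e-9 || va < min(colb) - 1e-9) {
        excluded <- excluded + 1L
        next
      }
      s_equiv <- invert_monotone(a$shading, colb, va)
      shifts <- c(shifts, abs(as.numeric(s_equiv) - a$shading[j]))
    }
  }
  if (length(shifts) == 0) stop("no overlapping cells between surfaces")
  structure(max(shifts), excluded_cells = excluded)
}
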
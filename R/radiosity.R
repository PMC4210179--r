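# Geometric-optics transfer through the periodic canopy: direct
# illumination, Lambertian inter-reflection/transmission (radiosity by
# Monte-Carlo-estimated exchange + Jacobi iterative gathering), energy
# audit and substrate transmittance.

#' Trace the geometric sampling of a canopy scene
#'
#' Precomputes everything about radiative exchange that depends on geometry
#' only: per-facet occlusion-resolved weights for every zenith bin of the
#' boundary radiance (`n_az` stratified azimuth samples per bin, seeded),
#' and a fixed set of cosine-sampled gather rays per facet face recording
#' the facet face they strike and the in-canopy path length. Because the
#' boundary radiance enters linearly, one trace serves every hour and
#' shading level on the same geometry.
#'
#' @param scene A facetized [canopy_scene()] (see [facetize()]).
#' @param bins Zenith quadrature of the boundary radiance.
#' @param n_az Azimuth samples per zenith bin for direct illumination.
#' @param n_gather Cosine-sampled gather rays per facet face.
#' @param seed Integer seed for all ray sampling.
#' @return Object of class `canopy_transfer`.
#' @export
trace_canopy <- function(scene, bins = zenith_bins(), n_az = 16L,
                         n_gather = 32L, seed = 1L) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (is.null(attr(scene, "facetized"))) {
    stop("scene must be facetized before optical transfer (see facetize())")
  }
  cos_lo <- cos(bins$lower * pi / 180)
  cos_hi <- cos(bins$upper * pi / 180)
  td <- cpp_trace_direct(scene$vertices, scene$faces, scene$tile[1],
                         scene$tile[2], cos_lo, cos_hi, as.integer(n_az),
                         as.integer(seed), 0)
  g <- cpp_gather_rays(scene$vertices, scene$faces, scene$tile[1],
                       scene$tile[2], as.integer(n_gather),
                       as.integer(seed), 0)
  zc <- (scene$vertices[scene$faces[, 1], 3] +
           scene$vertices[scene$faces[, 2], 3] +
           scene$vertices[scene$faces[, 3], 3]) / 3
  structure(list(w_up = td$w_up, w_dn = td$w_dn, hits = g$hits,
                 lens = g$lens, ztop = g$ztop, z_centroid = zc,
                 bins = bins, n_az = n_az, n_gather = n_gather,
                 seed = seed, n_facets = nrow(scene$faces)),
            class = "canopy_transfer")
}

#' First-order (direct) illumination of every facet face
#'
#' Folds the azimuthally averaged boundary radiance over the traced
#' occlusion weights: for each facet face and zenith bin, the unoccluded
#' cosine-weighted solid-angle fraction times the bin radiance, reduced by
#' within-canopy water absorption `exp(-a * path)` along the slant path to
#' the canopy top. Linear in the boundary radiance.
#'
#' @param scene Facetized [canopy_scene()].
#' @param rad Top-of-canopy [directional_radiance()].
#' @param iops Optional [water_iops()] for within-canopy absorption
#'   (`NULL` disables it, as in energy-audit mode).
#' @param transfer Optional precomputed [trace_canopy()] result.
#' @param ... Passed to [trace_canopy()] when `transfer` is missing.
#' @return Matrix `2*nfacets x nbands` of incident irradiance (W m^-2 per
#'   band); odd rows are +normal faces, even rows -normal faces. The
#'   transfer object is attached as an attribute.
#' @export
direct_illumination <- function(scene, rad, iops = NULL, transfer = NULL, ...) {
  stopifnot(inherits(rad, "directional_radiance"))
  if (is.null(transfer)) transfer <- trace_canopy(scene, rad$bins, ...)
  bins <- transfer$bins
  nf <- transfer$n_facets
  nb <- nrow(bins); nband <- nrow(rad$bands)
  mu <- cos(bins$centre * pi / 180)
  Edir <- matrix(0, 2L * nf, nband)
  up <- seq(1, 2L * nf, 2); dn <- seq(2, 2L * nf, 2)
  # slant path from facet to canopy top per zenith bin
  slant <- outer(pmax(transfer$ztop - transfer$z_centroid, 0), 1 / mu)
  for (b in seq_len(nband)) {
    att <- if (is.null(iops) || all(iops$a == 0)) 1
           else exp(-iops$a[b] * slant)
    wl <- bins$domega * rad$radiance[, b]
    Edir[up, b] <- (transfer$w_up * att) %*% wl
    Edir[dn, b] <- (transfer$w_dn * att) %*% wl
  }
  attr(Edir, "transfer") <- transfer
  Edir
}

#' Solve Lambertian multiple scattering in the canopy
#'
#' Jacobi iterative gathering over the Monte-Carlo-estimated exchange rays:
#' each face's exitant radiosity is `rho * (same-face incident) +
#' tau * (opposite-face incident)`; incident light is re-gathered along the
#' fixed cosine-sampled rays (attenuated by within-canopy water absorption
#' over the actual ray path) until the relative change in total absorbed
#' power drops below `tol` or `max_iters` is reached. The solution is
#' linear in the first-order input.
#'
#' @param scene Facetized [canopy_scene()].
#' @param materials A [material_library()].
#' @param first_order Matrix from [direct_illumination()] (its attached
#'   transfer is reused).
#' @param iops Optional [water_iops()]; `NULL` or zero absorption gives
#'   energy-audit mode.
#' @param tol Convergence tolerance on total absorbed power (default 1e-4).
#' @param max_iters Maximum Jacobi sweeps (default 20).
#' @return Object of class `radiosity_solution`: `E` (total incident, slot
#'   x band), `B` (exitant radiosity), iteration count, residual,
#'   convergence flag, plus per-slot areas and escape fractions used by the
#'   energy ledger.
#' @export
solve_scattering <- function(scene, materials, first_order, iops = NULL,
                             tol = 1e-4, max_iters = 20L) {
  transfer <- attr(first_order, "transfer")
  if (is.null(transfer)) stop("first_order must come from direct_illumination()")
  sm <- slot_materials(scene, materials)
  a_band <- if (is.null(iops)) rep(0, ncol(first_order)) else iops$a
  ns <- nrow(first_order)
  slot_area <- rep(scene$facet_area, each = 2L)
  sol <- cpp_jacobi_solve(transfer$hits, transfer$lens, first_order,
                          sm$rho, sm$tau, a_band, slot_area,
                          tol, as.integer(max_iters))
  esc <- rowMeans(transfer$hits == 0L)
  structure(list(E = sol$E, B = sol$B, iterations = sol$iterations,
                 residual = sol$residual, converged = sol$converged,
                 slot_area = slot_area, escape_fraction = esc,
                 first_order = first_order, rho = sm$rho, tau = sm$tau,
                 transfer = transfer),
            class = "radiosity_solution")
}

#' @export
print.radiosity_solution <- function(x, ...) {
  cat(sprintf("Radiosity solution: %d facet faces, %d iterations, residual %.2e%s\n",
              nrow(x$E), x$iterations, x$residual,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Full optical transfer for one boundary condition
#'
#' Convenience chain: direct illumination then multiple scattering.
#'
#' @inheritParams solve_scattering
#' @inheritParams direct_illumination
#' @return A `radiosity_solution`.
#' @export
canopy_transfer_solve <- function(scene, rad, materials = material_library(),
                                  iops = NULL, transfer = NULL,
                                  tol = 1e-4, max_iters = 20L, ...) {
  fo <- direct_illumination(scene, rad, iops, transfer, ...)
  solve_scattering(scene, materials, fo, iops, tol, max_iters)
}

#' Per-leaf-facet incident PAR field
#'
#' Reduces a radiosity solution to the leaf irradiance field: for every
#' leaf facet, its area and total incident PAR summed over both faces (the
#' strap leaves are thin, two-sided photosynthetic surfaces).
#'
#' @param solution A [solve_scattering()] result.
#' @param scene The scene it was computed on.
#' @param per_face If `TRUE`, report each face separately instead of the
#'   two-face sum.
#' @return Object of class `leaf_field`: data frame with `facet`, `area`
#'   (m^2) and `par` (micromol quanta m^-2 s^-1), spectral matrix attached.
#' @export
leaf_irradiance <- function(solution, scene, per_face = FALSE) {
  leaf <- which(scene$role == "leaf")
  if (length(leaf) == 0) stop("scene has no leaf facets")
  w <- photon_weights(spectral_bands())
  up <- solution$E[2L * leaf - 1L, , drop = FALSE]
  dn <- solution$E[2L * leaf, , drop = FALSE]
  if (per_face) {
    d <- data.frame(facet = rep(leaf, 2L),
                    face = rep(c("up", "dn"), each = length(leaf)),
                    area = rep(scene$facet_area[leaf], 2L),
                    par = c(as.numeric(up %*% w), as.numeric(dn %*% w)))
    spec <- rbind(up, dn)
  } else {
    d <- data.frame(facet = leaf, area = scene$facet_area[leaf],
                    par = as.numeric((up + dn) %*% w))
    spec <- up + dn
  }
  structure(d, spectral = spec, class = c("leaf_field", "data.frame"))
}

#' Energy-conservation audit of the optical solver
#'
#' With within-canopy water absorption forced to zero, solves the scene and
#' checks closure of the energy ledger over the tile:
#' `|E_in - E_out_sky - E_absorbed| / E_in`, where `E_in` is the planar
#' downwelling boundary irradiance times the tile area, `E_out_sky` sums
#' each face's radiosity times its cosine-weighted sky-escape fraction, and
#' `E_absorbed` sums `(1 - rho - tau) * incident * area` over faces.
#'
#' @param scene Facetized [canopy_scene()].
#' @param materials A [material_library()].
#' @param rad Boundary [directional_radiance()].
#' @param transfer Optional precomputed [trace_canopy()].
#' @param ... Passed to [trace_canopy()].
#' @return List with `closure_error` (fraction), the ledger components (W)
#'   and the solution.
#' @export
energy_audit <- function(scene, materials, rad, transfer = NULL, ...) {
  fo <- direct_illumination(scene, rad, iops = NULL, transfer = transfer, ...)
  sol <- solve_scattering(scene, materials, fo, iops = NULL)
  e_in <- sum(planar_ed(rad)) * prod(scene$tile)
  alpha <- 1 - sol$rho - sol$tau
  e_abs <- sum(sol$slot_area * rowSums(alpha * sol$E))
  e_sky <- sum(sol$slot_area * sol$escape_fraction * rowSums(sol$B))
  err <- abs(e_in - e_sky - e_abs) / e_in
  list(closure_error = err,
       ledger = c(incident = e_in, exitant_to_sky = e_sky,
                  absorbed_by_surfaces = e_abs,
                  absorbed_by_water = 0),
       solution = sol)
}

#' Percentage of top-of-canopy PAR transmitted to the substrate
#'
#' Area-weighted mean downwelling PAR incident on the substrate facets
#' (direct plus all scattered orders), as a percentage of the planar
#' top-of-canopy downwelling PAR.
#'
#' @param solution A [solve_scattering()] result.
#' @param scene The scene.
#' @param rad The boundary radiance used.
#' @return Percentage (0--100, can exceed 100 only by scattering noise).
#' @export
substrate_transmittance <- function(solution, scene, rad) {
  toc <- to_par(planar_ed(rad))
  if (toc <= 0) stop("zero incident top-of-canopy PAR")
  sub <- which(scene$role == "substrate")
  if (length(sub) == 0) stop("scene has no substrate facets")
  w <- photon_weights(spectral_bands())
  par_sub <- as.numeric(solution$E[2L * sub - 1L, , drop = FALSE] %*% w)
  area <- scene$facet_area[sub]
  100 * sum(par_sub * area) / sum(area) / toc
}

#' Fit the exponential transmittance-vs-LAI law
#'
#' Least squares fit of `y = 100 exp(-b LAI)` to (LAI, percent transmitted)
#' points by Gauss-Newton (`nls`, port algorithm), started from the
#' log-linear slope. Returns the decay coefficient and the coefficient of
#' determination of the points against the fitted curve.
#'
#' @param lai,percent Numeric vectors (>= 3 points, LAI >= 0).
#' @return List with `b`, `r_squared`, `fitted`.
#' @export
fit_exponential_transmittance <- function(lai, percent) {
  stopifnot(length(lai) == length(percent))
  if (length(lai) < 3) stop("need at least 3 points")
  if (any(lai < 0)) stop("LAI must be non-negative")
  b0 <- max(1e-6, -coef(lm(log(pmax(percent, 1e-6) / 100) ~ lai + 0))[1])
  fit <- nls(percent ~ 100 * exp(-b * lai), start = list(b = b0),
             algorithm = "port", lower = 0)
  b <- unname(coef(fit)["b"])
  fitted <- 100 * exp(-b * lai)
  r2 <- 1 - sum((percent - fitted)^2) / sum((percent - mean(percent))^2)
  list(b = b, r_squared = r2, fitted = fitted)
}
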
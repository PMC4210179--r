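# Surface optical properties: Lambertian reflectance/transmittance per band.

#' Material library for canopy surfaces
#'
#' Band-resolved Lambertian reflectance and transmittance for the three
#' scene materials: leaf, stem and substrate. Defaults are packaged
#' parametric stand-ins (labelled synthetic): a green-peaked,
#' absorptance-dominated leaf, a dark stem, and a sand substrate whose mean
#' reflectance over the grid is 0.33. Any spectrum can be replaced from a
#' 2-column CSV (`wavelength_nm`, value).
#'
#' @param leaf_reflectance,leaf_transmittance,substrate_reflectance,stem_reflectance
#'   Optional numeric vectors per band (or CSV file paths) overriding the
#'   packaged spectra.
#' @param bands Band grid.
#' @return Object of class `material_library`: matrices `rho`, `tau`
#'   (3 x nbands, rows leaf/stem/substrate).
#' @export
material_library <- function(leaf_reflectance = NULL,
                             leaf_transmittance = NULL,
                             substrate_reflectance = NULL,
                             stem_reflectance = NULL,
                             bands = spectral_bands()) {
  load_spec <- function(x, default_file) {
    if (is.null(x)) {
      x <- system.file("extdata", default_file, package = "canopylight",
                       mustWork = TRUE)
    }
    if (is.character(x)) {
      d <- read.csv(x)
      return(resample_to_bands(d[[1]], d[[2]], bands))
    }
    stopifnot(length(x) == nrow(bands))
    x
  }
  rho_leaf <- load_spec(leaf_reflectance, "leaf_reflectance_synthetic.csv")
  tau_leaf <- load_spec(leaf_transmittance, "leaf_transmittance_synthetic.csv")
  rho_sub <- load_spec(substrate_reflectance, "sand_reflectance_synthetic.csv")
  rho_stem <- if (is.null(stem_reflectance)) rep(0.08, nrow(bands))
              else load_spec(stem_reflectance, "")
  rho <- rbind(leaf = rho_leaf, stem = rho_stem, substrate = rho_sub)
  tau <- rbind(leaf = tau_leaf, stem = 0, substrate = 0)
  if (any(rho < 0) || any(tau < 0) || any(rho + tau > 1 + 1e-12)) {
    stop("materials must satisfy 0 <= rho, tau and rho + tau <= 1 per band")
  }
  structure(list(rho = rho, tau = tau, bands = bands),
            class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  cat("Material library (band means):\n")
  for (m in rownames(x$rho)) {
    cat(sprintf("  %-10s rho %.3f  tau %.3f  alpha %.3f\n", m,
                mean(x$rho[m, ]), mean(x$tau[m, ]),
                1 - mean(x$rho[m, ]) - mean(x$tau[m, ])))
  }
  invisible(x)
}

# per-slot (facet face) rho/tau matrices for the solver
slot_materials <- function(scene, materials) {
  idx <- scene$material             # 1 leaf, 2 stem, 3 substrate
  rho <- materials$rho[idx, , drop = FALSE]
  tau <- materials$tau[idx, , drop = FALSE]
  ns <- 2L * nrow(scene$faces)
  r <- matrix(0, ns, ncol(rho)); t <- matrix(0, ns, ncol(tau))
  r[seq(1, ns, 2), ] <- rho; r[seq(2, ns, 2), ] <- rho
  t[seq(1, ns, 2), ] <- tau; t[seq(2, ns, 2), ] <- tau
  # substrate under-face is optically dead
  sub <- which(scene$role == "substrate")
  r[2L * sub, ] <- 0; t[2L * sub, ] <- 0
  list(rho = r, tau = t)
}
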
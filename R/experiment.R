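# Factorial experiment driver: configuration, run enumeration, seeded
# fixtures, and the orchestration of the full LAI x structure x shading x
# hour design.

#' Read (or default) the experiment configuration
#'
#' Configuration is a hierarchical YAML file; [default_config()] returns
#' the packaged full factorial design: five
#' LAI treatments (1.27, 1.94, 3.15, 5.00, 7.65), one upright low-wave
#' structure plus 14 high-wave movement snapshots, nine shading levels (0,
#' 10, 25, 40, 50, 60, 70, 85, 95 percent) and 12 hourly diurnal intervals
#' -- 8100 runs in total.
#'
#' @param file Path to a YAML configuration.
#' @return Configuration list.
#' @export
read_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  validate_config(cfg)
}

#' @rdname read_config
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml",
                          package = "canopylight", mustWork = TRUE))
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg$site), is.list(cfg$design), is.list(cfg$optics))
  for (ax in c("lai", "shading")) {
    if (length(cfg$design[[ax]]) == 0) stop("empty design axis: ", ax)
  }
  if (cfg$design$n_hours < 1) stop("empty design axis: hours")
  if (length(cfg$design$wave_modes) == 0) stop("empty design axis: wave_modes")
  cfg$design$lai <- as.numeric(cfg$design$lai)
  cfg$design$shading <- as.numeric(cfg$design$shading)
  cfg
}

n_structures <- function(cfg) {
  n <- 0L
  if ("low" %in% cfg$design$wave_modes) n <- n + 1L
  if ("high" %in% cfg$design$wave_modes) n <- n + as.integer(cfg$design$n_snapshots)
  n
}

# documented per-run seed hash: reproducible for any subset of the design
run_seed <- function(master, lai, structure, shading, hour) {
  (as.numeric(master) * 1009 + round(lai * 100) * 30011 +
     structure * 131071 + round(shading) * 8191 + hour * 127) %% 2147483647
}

#' Enumerate the factorial run specifications
#'
#' Cartesian product of the design axes in documented order (LAI outermost,
#' then structure, shading, hour innermost). Structure 1 is the upright
#' low-wave canopy; structures 2..(1+n_snapshots) are the high-wave
#' movement snapshots.
#'
#' @param config Configuration list.
#' @return Data frame of runs with per-run seeds; the default design has
#'   5 x 15 x 9 x 12 = 8100 rows.
#' @export
enumerate_runs <- function(config = default_config()) {
  config <- validate_config(config)
  ns <- n_structures(config)
  if (ns == 0) stop("empty design axis: structures")
  g <- expand.grid(hour = seq_len(config$design$n_hours),
                   shading = config$design$shading,
                   structure = seq_len(ns),
                   lai = config$design$lai)
  g <- g[, c("lai", "structure", "shading", "hour")]
  g <- g[order(match(g$lai, config$design$lai), g$structure,
               match(g$shading, config$design$shading), g$hour), ]
  rownames(g) <- NULL
  g$wave_mode <- ifelse(g$structure == 1L & "low" %in% config$design$wave_modes,
                        "low", "high")
  g$seed <- run_seed(config$seed, g$lai, g$structure, g$shading, g$hour)
  g
}

#' Seeded synthetic fixture set
#'
#' Synthetic stand-ins for field-sampled plants: ten morphometric parameter
#' variants drawn around the package defaults, the five fixture canopies at
#' the treatment LAIs, and toy scenes used by oracle tests (substrate-only;
#' a single horizontal 10 cm^2 leaf; a continuous opaque slab; a 50-facet
#' random scene for the path-tracer cross-check).
#'
#' @param seed Integer master seed.
#' @param lai_targets Canopy LAI treatments.
#' @param tile Tile dimensions, m.
#' @param canopies If `FALSE`, skip assembling the five canopies.
#' @return List with `plant_pool`, `canopies` (named by LAI), `toys`.
#' @export
make_fixtures <- function(seed = 1L,
                          lai_targets = c(1.27, 1.94, 3.15, 5.00, 7.65),
                          tile = c(0.2, 0.2), canopies = TRUE) {
  pool <- with_seed(seed, {
    lapply(1:10, function(i) {
      jit <- function(range, f) range * runif(1, 1 - f, 1 + f)
      plant_params(
        stem_height = jit(c(0.30, 0.60), 0.12),
        branch_length = jit(c(0.03, 0.08), 0.15),
        leaf_length = jit(c(0.05, 0.12), 0.15),
        leaf_width = jit(c(0.006, 0.011), 0.1),
        seed = seed * 101L + i)
    })
  })
  cans <- list()
  if (canopies) {
    # built in ascending order, each extending the previous, so the
    # treatments are nested canopies
    ord <- order(lai_targets)
    base <- NULL
    for (L in lai_targets[ord]) {
      base <- assemble_canopy(pool, tile, L,
                              seed = as.integer(seed + round(L * 100)),
                              base = base)
      cans[[format(L)]] <- base
    }
    cans <- cans[format(lai_targets)]
  }
  list(plant_pool = pool, canopies = cans,
       toys = list(substrate_only = canopy_scene(list(), tile),
                   single_leaf = single_leaf_scene(tile = tile),
                   opaque_slab = opaque_slab_scene(tile = tile),
                   random50 = random_facet_scene(50L, tile = tile,
                                                 seed = seed)))
}

# minimal mesh object (same contract as generate_plant output)
bare_mesh <- function(vertices, faces, role) {
  areas <- triangle_areas(vertices, faces)
  skel <- list(nodes = matrix(0, 1, 3), edges = matrix(integer(0), 0, 2),
               rest_length = numeric(0), mass = 0.001)
  structure(list(vertices = vertices, faces = faces, role = role,
                 facet_bone = rep(0L, nrow(faces)), facet_area = areas,
                 leaf_area = sum(areas[role == "leaf"]),
                 skeleton = skel, params = NULL),
            class = "plant_mesh")
}

#' Toy scenes for oracle tests
#'
#' `single_leaf_scene`: one horizontal square leaf (default 10 cm^2) at
#' `height` over the tile centre. `opaque_slab_scene`: a stem-material slab
#' covering the whole tile (periodically continuous). `random_facet_scene`:
#' `n` randomly placed and oriented leaf triangles.
#'
#' @param area Leaf area, m^2.
#' @param height Height above the substrate, m.
#' @param tile Tile dimensions.
#' @param n Number of random facets.
#' @param seed Seed for the random scene.
#' @return A [canopy_scene()].
#' @export
single_leaf_scene <- function(area = 0.001, height = 0.1, tile = c(0.2, 0.2)) {
  s <- sqrt(area) / 2
  cx <- tile[1] / 2; cy <- tile[2] / 2
  v <- rbind(c(cx - s, cy - s, height), c(cx + s, cy - s, height),
             c(cx + s, cy + s, height), c(cx - s, cy + s, height))
  f <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  pl <- bare_mesh(v, f, rep("leaf", 2))
  attr(pl, "position") <- c(0, 0)
  canopy_scene(list(pl), tile)
}

#' @rdname single_leaf_scene
#' @export
opaque_slab_scene <- function(height = 0.3, tile = c(0.2, 0.2)) {
  v <- rbind(c(0, 0, height), c(tile[1], 0, height),
             c(tile[1], tile[2], height), c(0, tile[2], height))
  f <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  pl <- bare_mesh(v, f, rep("stem", 2))
  attr(pl, "position") <- c(0, 0)
  canopy_scene(list(pl), tile)
}

#' @rdname single_leaf_scene
#' @export
random_facet_scene <- function(n = 50L, tile = c(0.2, 0.2), seed = 1L) {
  with_seed(seed, {
    v <- matrix(0, 3 * n, 3); f <- matrix(0L, n, 3)
    for (i in seq_len(n)) {
      c0 <- c(runif(1, 0, tile[1]), runif(1, 0, tile[2]), runif(1, 0.05, 0.35))
      for (k in 1:3) {
        v[3 * (i - 1) + k, ] <- c0 + rnorm(3, 0, 0.012)
      }
      f[i, ] <- 3L * (i - 1L) + 1:3
    }
    pl <- bare_mesh(v, f, rep("leaf", n))
    attr(pl, "position") <- c(0, 0)
    canopy_scene(list(pl), tile)
  })
}

#' Run the factorial modelling experiment
#'
#' Executes the configured design and returns one row per run. The chain
#' per LAI treatment: assemble the fixture canopy; build the structure set
#' (upright, and/or movement snapshots from the wave simulation); facetize;
#' trace the geometry once per structure; then for each diurnal hour solve
#' the radiosity problem and reduce to metrics. Shading enters the optical
#' chain linearly, so shaded runs reuse the unshaded solution: leaf PAR
#' scales by `1 - s` exactly (equivalently, the saturation threshold is
#' `E_k / (1 - s)`). With `symmetry = TRUE` (default) only the unique
#' morning half of the symmetric diurnal hours is solved and the afternoon
#' is mirrored.
#'
#' @param config Configuration list (see [read_config()]).
#' @param symmetry Exploit diurnal symmetry (identical results either way).
#' @param progress Print per-treatment progress.
#' @return Data frame: one row per enumerated run with top-of-canopy PAR,
#'   saturated leaf-area percentages at E_k 45/50/55, substrate
#'   transmittance (percent) and solver diagnostics.
#' @export
run_experiment <- function(config = default_config(), symmetry = TRUE,
                           progress = FALSE) {
  config <- validate_config(config)
  runs <- enumerate_runs(config)
  site <- config$site
  iops <- reference_iops(depth = site$depth)
  materials <- material_library()
  bins <- zenith_bins(config$optics$zenith_bins)
  fx <- make_fixtures(config$seed, config$design$lai, canopies = FALSE)

  hours <- diurnal_hours(site$latitude, site$date, config$design$n_hours)
  nh <- length(hours)
  mirror <- nh + 1L - seq_len(nh)
  unique_hours <- if (symmetry) seq_len(ceiling(nh / 2)) else seq_len(nh)
  rad_by_hour <- lapply(seq_len(nh), function(i) {
    sun <- solar_position(site$latitude, site$longitude, site$date, hours[i])
    propagate_water_column(clear_sky_radiance(sun, bands = spectral_bands(),
                                              bins = bins), iops)
  })

  out <- list()
  base_scene <- NULL
  for (L in sort(config$design$lai)) {
    if (progress) message(sprintf("LAI %.2f ...", L))
    scene_up <- assemble_canopy(fx$plant_pool, c(0.2, 0.2), L,
                                seed = as.integer(config$seed + round(L * 100)),
                                base = base_scene)
    base_scene <- scene_up
    structures <- list()
    if ("low" %in% config$design$wave_modes) structures[["1"]] <- scene_up
    if ("high" %in% config$design$wave_modes) {
      forcing <- wave_forcing("high", amplitude = config$wave$amplitude,
                              period = config$wave$period,
                              drag = config$wave$drag)
      traj <- simulate_motion(scene_up, forcing,
                              duration = 4 * forcing$period,
                              dt = config$wave$dt %||% 1e-3)
      snaps <- extract_snapshots(traj, config$design$n_snapshots)
      off <- length(structures)
      for (k in seq_along(snaps)) {
        structures[[as.character(off + k)]] <- snaps[[k]]
      }
    }
    for (sname in names(structures)) {
      s_idx <- as.integer(sname)
      fscene <- facetize(structures[[sname]], config$optics$max_facet_area)
      tseed <- as.integer(run_seed(config$seed, L, s_idx, 0, 0) %% 2^31)
      transfer <- trace_canopy(fscene, bins, config$optics$n_az,
                               config$optics$n_gather, tseed)
      sols <- vector("list", nh)
      for (hi in unique_hours) {
        fo <- direct_illumination(fscene, rad_by_hour[[hi]], iops,
                                  transfer = transfer)
        sol <- solve_scattering(fscene, materials, fo, iops,
                                tol = config$optics$tol,
                                max_iters = config$optics$max_iters)
        lf <- leaf_irradiance(sol, fscene)
        sols[[hi]] <- list(
          field = lf,
          toc_par = to_par(planar_ed(rad_by_hour[[hi]])),
          substrate = substrate_transmittance(sol, fscene, rad_by_hour[[hi]]),
          iterations = sol$iterations, converged = sol$converged)
      }
      if (symmetry) for (hi in setdiff(seq_len(nh), unique_hours)) {
        sols[[hi]] <- sols[[mirror[hi]]]
      }
      for (sh in config$design$shading) {
        s_frac <- sh / 100
        for (hi in seq_len(nh)) {
          so <- sols[[hi]]
          sat <- vapply(c(45, 50, 55), function(ek) {
            saturated_fraction(so$field, ek / (1 - s_frac))
          }, numeric(1))
          out[[length(out) + 1L]] <- data.frame(
            lai = L, structure = s_idx,
            wave_mode = if (s_idx == 1L && "low" %in% config$design$wave_modes)
              "low" else "high",
            shading = sh, hour = hi,
            toc_par = so$toc_par * (1 - s_frac),
            sat_ek45 = sat[1], sat_ek50 = sat[2], sat_ek55 = sat[3],
            substrate_pct = so$substrate,
            iterations = so$iterations, converged = so$converged,
            seed = run_seed(config$seed, L, s_idx, sh, hi))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$lai, config$design$lai), res$structure,
                   match(res$shading, config$design$shading), res$hour), ]
  rownames(res) <- NULL
  if (nrow(res) != nrow(runs)) {
    warning(sprintf("result rows (%d) != enumerated runs (%d)",
                    nrow(res), nrow(runs)))
  }
  attr(res, "config") <- config
  attr(res, "hours") <- hours
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce experiment results to an H^A_sat surface
#'
#' Post-hoc aggregation of the factorial runs: for each (LAI,
#' shading) cell, per-structure diurnal H^A_sat values are averaged
#' (unweighted) over the movement snapshots of the requested wave mode,
#' with the across-snapshot standard deviation attached.
#'
#' @param results [run_experiment()] output.
#' @param ek One of 45, 50, 55.
#' @param wave_mode "low" or "high".
#' @return A [build_hasat_surface()] object.
#' @export
surface_from_results <- function(results, ek = 50, wave_mode = "low") {
  col <- paste0("sat_ek", ek)
  if (!col %in% names(results)) stop("E_k ", ek, " not present in results")
  r <- results[results$wave_mode == wave_mode, ]
  if (nrow(r) == 0) stop("no runs for wave mode ", wave_mode)
  cells <- do.call(rbind, lapply(split(r, list(r$lai, r$shading), drop = TRUE),
                                 function(d) {
    per_struct <- vapply(split(d, d$structure), function(s) {
      hasat(saturation_series(s$hour, s[[col]], s$toc_par))
    }, numeric(1))
    wa <- wave_average(per_struct)
    data.frame(lai = d$lai[1], shading = d$shading[1],
               hasat = wa$mean, sd = wa$sd)
  }))
  build_hasat_surface(cells, ek = ek, wave_mode = wave_mode)
}

#' Midday low-wave substrate transmittance per LAI
#'
#' Extracts the transmittance validation points (hour nearest solar noon,
#' upright structure, unshaded) from experiment results.
#'
#' @param results [run_experiment()] output.
#' @return Data frame `lai`, `percent`.
#' @export
transmittance_points <- function(results) {
  r <- results[results$wave_mode == "low" & results$shading == 0, ]
  nh <- max(r$hour)
  mid <- (nh + 1) / 2
  r <- r[abs(r$hour - mid) == min(abs(r$hour - mid)), ]
  agg <- aggregate(substrate_pct ~ lai, data = r, FUN = mean)
  data.frame(lai = agg$lai, percent = agg$substrate_pct)
}
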
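# Independent oracles used by the tests. These re-derive quantities by
# routes unrelated to the package's solvers: a brute-force forward photon
# tracer for radiative exchange, a second solar ephemeris, and closed-form
# formulas.

# --- simple second-opinion solar ephemeris (Cooper declination) ----------
oracle_solar_zenith <- function(latitude, date, hour_solar) {
  n <- as.integer(strftime(as.Date(date), "%j"))
  decl <- 23.45 * sin(2 * pi * (284 + n) / 365) * pi / 180
  ha <- (hour_solar - 12) * 15 * pi / 180
  phi <- latitude * pi / 180
  acos(pmin(1, pmax(-1,
    sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)))) * 180 / pi
}

# --- closed-form least-squares slope (for k_d regression) -----------------
oracle_ls_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# --- brute-force forward path tracer --------------------------------------
# Monte-Carlo photon transport through the periodic scene for ONE spectral
# band: photons are launched from the canopy top with the boundary
# radiance's cosine-weighted directional distribution, followed through
# Lambertian reflect/transmit events, and tallied when absorbed or when
# they escape upward. Periodicity is handled by testing the 3x3 tile
# neighbourhood of triangle copies. Completely independent of the grid/DDA
# radiosity kernel.
oracle_path_trace <- function(scene, rho_mat, tau_mat, rad_band,
                              n_photons = 20000L, seed = 1L,
                              n_batches = 10L) {
  v <- scene$vertices; f <- scene$faces
  tile <- scene$tile
  ztop <- max(v[, 3]) + 1e-6
  bins <- rad_band$bins
  L <- rad_band$radiance[, 1]
  # per-facet optical properties for this band
  rho <- rho_mat[scene$material]
  tau <- tau_mat[scene$material]
  # replicate triangles over the 3x3 neighbourhood
  shifts <- as.matrix(expand.grid(sx = (-1:1) * tile[1],
                                  sy = (-1:1) * tile[2]))
  A <- v[f[, 1], , drop = FALSE]
  E1 <- v[f[, 2], , drop = FALSE] - A
  E2 <- v[f[, 3], , drop = FALSE] - A
  nrm <- cbind(E1[, 2] * E2[, 3] - E1[, 3] * E2[, 2],
               E1[, 3] * E2[, 1] - E1[, 1] * E2[, 3],
               E1[, 1] * E2[, 2] - E1[, 2] * E2[, 1])
  nf <- nrow(f)
  repA <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    sweep(A, 2, c(shifts[s, 1], shifts[s, 2], 0), `+`)
  }))
  repE1 <- do.call(rbind, rep(list(E1), nrow(shifts)))
  repE2 <- do.call(rbind, rep(list(E2), nrow(shifts)))
  rep_id <- rep(seq_len(nf), times = nrow(shifts))

  hit_window <- function(o, d, skip) {
    # Moller-Trumbore against the 3x3 replicated triangles (vectorised)
    pvx <- d[2] * repE2[, 3] - d[3] * repE2[, 2]
    pvy <- d[3] * repE2[, 1] - d[1] * repE2[, 3]
    pvz <- d[1] * repE2[, 2] - d[2] * repE2[, 1]
    det <- repE1[, 1] * pvx + repE1[, 2] * pvy + repE1[, 3] * pvz
    tvx <- o[1] - repA[, 1]; tvy <- o[2] - repA[, 2]; tvz <- o[3] - repA[, 3]
    u <- (tvx * pvx + tvy * pvy + tvz * pvz) / det
    qx <- tvy * repE1[, 3] - tvz * repE1[, 2]
    qy <- tvz * repE1[, 1] - tvx * repE1[, 3]
    qz <- tvx * repE1[, 2] - tvy * repE1[, 1]
    w <- (d[1] * qx + d[2] * qy + d[3] * qz) / det
    tt <- (repE2[, 1] * qx + repE2[, 2] * qy + repE2[, 3] * qz) / det
    ok <- is.finite(tt) & abs(det) > 1e-14 & u >= -1e-9 & w >= -1e-9 &
      (u + w) <= 1 + 1e-9 & tt > 1e-7 & rep_id != skip
    if (!any(ok)) return(NULL)
    i <- which(ok)[which.min(tt[ok])]
    list(id = rep_id[i], t = tt[i])
  }

  # exact periodic tracing: march the segment tile by tile, wrapping the
  # origin at each boundary, and accept only hits inside the current tile
  # window (the 3x3 replicate covers facet overhang across boundaries)
  nearest_hit <- function(o, d, skip) {
    for (step in 1:500) {
      tx_exit <- if (abs(d[1]) > 1e-14) {
        if (d[1] > 0) (tile[1] - o[1]) / d[1] else -o[1] / d[1]
      } else Inf
      ty_exit <- if (abs(d[2]) > 1e-14) {
        if (d[2] > 0) (tile[2] - o[2]) / d[2] else -o[2] / d[2]
      } else Inf
      t_exit <- max(min(tx_exit, ty_exit), 1e-9)
      h <- hit_window(o, d, skip)
      if (!is.null(h) && h$t <= t_exit + 1e-9) {
        h$o_hit <- o + h$t * d
        return(h)
      }
      # out the top or bottom before the next tile boundary?
      z_exit <- o[3] + t_exit * d[3]
      if ((d[3] > 0 && z_exit > ztop) || (d[3] < 0 && z_exit < -1e-9)) {
        return(NULL)
      }
      o <- o + (t_exit + 1e-9) * d
      o[1] <- o[1] %% tile[1]; o[2] <- o[2] %% tile[2]
      skip <- -1L   # self-shadowing only matters on the first sub-segment
    }
    NULL
  }

  cosine_dir <- function(n_unit) {
    u1 <- runif(1); u2 <- runif(1)
    r <- sqrt(u1); zc <- sqrt(1 - u1)
    ref <- if (abs(n_unit[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(ref[2] * n_unit[3] - ref[3] * n_unit[2],
            ref[3] * n_unit[1] - ref[1] * n_unit[3],
            ref[1] * n_unit[2] - ref[2] * n_unit[1])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n_unit[2] * t1[3] - n_unit[3] * t1[2],
            n_unit[3] * t1[1] - n_unit[1] * t1[3],
            n_unit[1] * t1[2] - n_unit[2] * t1[1])
    r * cos(2 * pi * u2) * t1 + r * sin(2 * pi * u2) * t2 + zc * n_unit
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  e_in <- sum(L * bins$cw) * prod(tile)
  p_bin <- L * bins$cw / sum(L * bins$cw)
  per_photon <- e_in / n_photons
  batch <- rep(seq_len(n_batches), length.out = n_photons)
  abs_batch <- numeric(n_batches); sky_batch <- numeric(n_batches)
  for (ph in seq_len(n_photons)) {
    b <- sample.int(nrow(bins), 1, prob = p_bin)
    c1 <- cos(bins$lower[b] * pi / 180); c2 <- cos(bins$upper[b] * pi / 180)
    mu <- sqrt(c2^2 + runif(1) * (c1^2 - c2^2))   # cosine-weighted in bin
    phx <- runif(1, 0, 2 * pi)
    st <- sqrt(1 - mu^2)
    d <- c(st * cos(phx), st * sin(phx), -mu)
    o <- c(runif(1, 0, tile[1]), runif(1, 0, tile[2]), ztop)
    skip <- 0L
    for (bounce in 1:50) {
      h <- nearest_hit(o, d, skip)
      if (is.null(h)) {
        if (d[3] > 0) sky_batch[batch[ph]] <- sky_batch[batch[ph]] + per_photon
        break   # lost below (no substrate gap in fixture scenes)
      }
      o <- h$o_hit
      # wrap position back into the base tile
      o[1] <- o[1] %% tile[1]; o[2] <- o[2] %% tile[2]
      skip <- h$id
      u <- runif(1)
      n_unit <- nrm[h$id, ] / sqrt(sum(nrm[h$id, ]^2))
      # normal of the struck face (facing the incoming photon)
      m <- if (sum(n_unit * d) < 0) n_unit else -n_unit
      if (u < rho[h$id]) {
        d <- cosine_dir(m)
      } else if (u < rho[h$id] + tau[h$id]) {
        d <- cosine_dir(-m)
      } else {
        abs_batch[batch[ph]] <- abs_batch[batch[ph]] + per_photon
        break
      }
    }
  }
  tot_abs <- sum(abs_batch)
  se <- sd(abs_batch * n_batches) / sqrt(n_batches)
  list(absorbed = tot_abs, sky = sum(sky_batch), se = se, e_in = e_in)
}

# --- small shared fixtures -------------------------------------------------
test_iops <- function() reference_iops()

test_noon_rad <- function(bins = zenith_bins()) {
  sun <- solar_position(-30.3095, 115.0072, "2005-04-27", 12)
  propagate_water_column(clear_sky_radiance(sun, bins = bins), test_iops())
}

# single-band boundary radiance (band 1 carries everything)
one_band_rad <- function(level = 1, bins = zenith_bins()) {
  L <- matrix(0, nrow(bins), 17)
  L[, 1] <- level
  directional_radiance(L, bins)
}

tiny_canopy <- function(lai = 0.8, seed = 1L) {
  pool <- make_fixtures(seed, canopies = FALSE)$plant_pool
  assemble_canopy(pool, target_lai = lai, seed = seed)
}
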
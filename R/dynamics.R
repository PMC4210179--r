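# Wave-driven plant motion: point-mass/force skeleton dynamics in the
# style of cloth simulation -- semi-implicit Euler with per-edge distance
# constraint relaxation -- and snapshot extraction with rigid per-facet
# re-skinning.

#' Oscillatory wave forcing
#'
#' A deliberately simple wave-action force model: every skeleton point mass
#' feels a horizontal body force `amplitude * sin(2 pi t / period)` along
#' `direction`, plus linear drag `-drag * v`. Mode "low" is still water
#' (zero amplitude, the canopy stands in its upright rest pose); mode
#' "high" drives a vigorous cycle of forward and backward motion.
#'
#' @param mode "low" or "high".
#' @param amplitude Peak force per point mass, N (default 0.15 for
#'   high: tip excursions around 30 percent of plant height).
#' @param period Wave period, s.
#' @param direction Horizontal unit vector of the forcing.
#' @param drag Linear drag coefficient, kg s^-1.
#' @return Object of class `wave_forcing`.
#' @export
wave_forcing <- function(mode = c("low", "high"), amplitude = NULL,
                         period = 4, direction = c(1, 0), drag = 0.02) {
  mode <- match.arg(mode)
  if (is.null(amplitude)) amplitude <- if (mode == "low") 0 else 0.15
  if (mode == "low" && amplitude != 0) {
    stop("low wave mode implies zero amplitude")
  }
  stopifnot(period > 0, amplitude >= 0, drag >= 0)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(mode = mode, amplitude = amplitude, period = period,
                 direction = direction, drag = drag),
            class = "wave_forcing")
}

# one plant's skeleton through time; base node pinned (compiled core)
simulate_skeleton <- function(skel, forcing, duration, dt,
                              stiffness = 2, relax_iters = 8L,
                              save_every = 0L, constant_force = NULL) {
  cpp_simulate_skeleton(skel$nodes, skel$edges, skel$rest_length, skel$mass,
                        forcing$amplitude, forcing$period,
                        forcing$direction[1], forcing$direction[2],
                        forcing$drag, duration, dt, stiffness,
                        as.integer(relax_iters), as.integer(save_every),
                        !is.null(constant_force),
                        if (is.null(constant_force)) 0 else constant_force)
}

#' Simulate wave-driven canopy motion
#'
#' Integrates each plant's point-mass skeleton under the forcing with
#' semi-implicit Euler plus per-edge distance-constraint relaxation (edges
#' stay within 5 percent of rest length). The base node is pinned; a
#' shape-memory restoring force toward the upright rest pose supplies
#' bending stiffness. Low mode returns the upright equilibrium; high mode
#' settles into periodic swaying after the spin-up.
#'
#' @param scene A [canopy_scene()] (un-facetized; skeletons are taken from
#'   its plants).
#' @param forcing A [wave_forcing()].
#' @param duration Total simulated time, s; default spin-up of 3 periods
#'   plus one recorded period.
#' @param dt Time step, s. Must satisfy `dt < sqrt(mass/stiffness)`
#'   (default 1e-3 s is an order of magnitude inside the bound for the
#'   default stiffness 2 N m^-1 and 1 g masses).
#' @param stiffness Restoring stiffness toward the rest pose, N m^-1.
#' @return Object of class `canopy_trajectory`: per-plant frames, times,
#'   max edge strain per stored frame, the scene and forcing.
#' @export
simulate_motion <- function(scene, forcing, duration = 4 * forcing$period,
                            dt = 1e-3, stiffness = 2) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(forcing, "wave_forcing"))
  if (dt >= sqrt(min(unlist(lapply(scene$plants, function(p) p$skeleton$mass)))
                 / stiffness)) {
    stop("dt too large for the chosen stiffness (dt must be < sqrt(m/k))")
  }
  if (duration < forcing$period) stop("duration must cover at least one period")
  sims <- lapply(scene$plants, function(p) {
    simulate_skeleton(p$skeleton, forcing, duration, dt, stiffness)
  })
  structure(list(times = sims[[1]]$times,
                 plants = lapply(sims, `[[`, "frames"),
                 max_strain = do.call(pmax, lapply(sims, `[[`, "max_strain")),
                 scene = scene, forcing = forcing, duration = duration),
            class = "canopy_trajectory")
}

#' @export
print.canopy_trajectory <- function(x, ...) {
  cat(sprintf("Canopy trajectory: %d plants, %d stored frames over %.2f s, max edge strain %.3f%%\n",
              length(x$plants), length(x$times), x$duration,
              100 * max(x$max_strain)))
  invisible(x)
}

# rigid transform of facets bound to skeleton edges
reskin_plant <- function(plant, skel_now) {
  e <- plant$skeleton$edges
  rest <- plant$skeleton$nodes
  v <- plant$vertices
  out <- v
  for (edge_id in unique(plant$facet_bone)) {
    a0 <- rest[e[edge_id, 1], ]; b0 <- rest[e[edge_id, 2], ]
    a1 <- skel_now[e[edge_id, 1], ]; b1 <- skel_now[e[edge_id, 2], ]
    u <- b0 - a0; w <- b1 - a1
    lu <- sqrt(sum(u^2)); lw <- sqrt(sum(w^2))
    faces_here <- which(plant$facet_bone == edge_id)
    vid <- unique(as.vector(plant$faces[faces_here, ]))
    if (lu < 1e-12 || lw < 1e-12) next
    u <- u / lu; w <- w / lw
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    s <- sqrt(sum(cr^2)); cth <- sum(u * w)
    if (s < 1e-12) {
      R <- diag(3) * sign(cth)
    } else {
      k <- cr / s
      K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                  byrow = TRUE)
      R <- diag(3) + s * K + (1 - cth) * (K %*% K)
    }
    out[vid, ] <- sweep(t(R %*% t(sweep(v[vid, , drop = FALSE], 2, a0))),
                        2, a1, `+`)
  }
  plant$vertices <- out
  plant$facet_area <- triangle_areas(out, plant$faces)
  plant$leaf_area <- sum(plant$facet_area[plant$role == "leaf"])
  plant
}

#' Extract evenly phased canopy snapshots from a trajectory
#'
#' Takes `n` stored frames at evenly spaced phases `k/n` of the final
#' forcing period and rebuilds the canopy scene at each: every mesh facet
#' rides rigidly on its skeleton edge (rotation mapping the rest edge onto
#' the deformed edge), so facet areas are preserved exactly.
#'
#' @param traj A [simulate_motion()] result covering at least one full
#'   period after spin-up.
#' @param n Number of snapshots (>= 1); 14 for the high-wave design.
#' @return List of `n` [canopy_scene()] objects.
#' @export
extract_snapshots <- function(traj, n) {
  stopifnot(inherits(traj, "canopy_trajectory"))
  if (n < 1) stop("n must be at least 1")
  period <- traj$forcing$period
  t_end <- traj$times[length(traj$times)]
  t0 <- t_end - period
  if (t0 < 0) stop("trajectory does not cover a full period")
  phases <- t0 + (seq_len(n) - 1L) / n * period
  idx <- vapply(phases, function(p) which.min(abs(traj$times - p)), 0L)
  lapply(idx, function(i) {
    plants <- lapply(seq_along(traj$scene$plants), function(j) {
      p <- reskin_plant(traj$scene$plants[[j]], traj$plants[[j]][[i]])
      attr(p, "position") <- attr(traj$scene$plants[[j]], "position")
      p
    })
    canopy_scene(plants, traj$scene$tile)
  })
}
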
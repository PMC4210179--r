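# Parametric Amphibolis-like plant meshes and periodic-tile canopies.
#
# A plant is a vertical stem of several internodes; upper nodes carry short
# branches; branch tips (and the stem apex) carry clusters of strap leaves.
# Leaves are zero-thickness two-sided triangle strips; stems are thin
# ribbons that occlude light but do not count toward LAI.

MAT_LEAF <- 1L
MAT_STEM <- 2L
MAT_SUBSTRATE <- 3L

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

runif_range <- function(n, range) {
  if (length(range) == 1L) rep(range, n)
  else runif(n, range[1], range[2])
}
sample_count <- function(n, range) {
  if (length(range) == 1L) rep(as.integer(range), n)
  else as.integer(floor(runif(n, range[1], range[2] + 1 - 1e-9)))
}

#' Morphometric parameters of a model plant
#'
#' Ranges (2-vectors, sampled uniformly) or single fixed values for the
#' structural dimensions of an Amphibolis-like plant: a stem of several
#' internodes, 0 or more branches at the upper nodes, and clusters of strap
#' leaves at branch tips and the stem apex. Lengths are metres, the leaf
#' inclination is degrees from horizontal.
#'
#' Defaults describe a plant of stem height 0.3--0.6 m with 5--10
#' internodes, 2--4 branches per upper node, and branch-tip clusters of
#' 3--5 strap leaves of 5--12 cm by 0.6--1.1 cm. Leaves are steeply
#' inclined (55--85 degrees from horizontal) and each cluster fans over a
#' narrow azimuth range, giving the erect, clumped foliage of a branched
#' strap-leaf seagrass; with these defaults a 0.2 x 0.2 m tile holding
#' roughly 1--10 plants spans leaf area indices of about 1--8. The
#' inclination and clumping defaults are the package's one-time
#' calibration of canopy gap structure against the observed
#' light-extinction law (see the methods vignette).
#'
#' @param stem_height,n_internodes,branches_per_node,branch_length Ranges.
#' @param leaves_per_cluster,leaf_length,leaf_width,leaf_inclination Ranges.
#' @param cluster_fan Half-width (degrees) of the azimuth fan a leaf
#'   cluster spreads over; small values give the strongly clumped foliage
#'   of branch-tip strap-leaf clusters.
#' @param stem_diameter Ribbon width used for stem geometry, m.
#' @param seed Integer seed making the sampled plant reproducible.
#' @return Object of class `plant_params`.
#' @export
plant_params <- function(stem_height = c(0.30, 0.60),
                         n_internodes = c(5, 10),
                         branches_per_node = c(2, 4),
                         branch_length = c(0.03, 0.08),
                         leaves_per_cluster = c(3, 5),
                         leaf_length = c(0.05, 0.12),
                         leaf_width = c(0.006, 0.011),
                         leaf_inclination = c(55, 85),
                         cluster_fan = 12,
                         stem_diameter = 0.003,
                         seed = 1L) {
  p <- list(stem_height = stem_height, n_internodes = n_internodes,
            branches_per_node = branches_per_node,
            branch_length = branch_length,
            leaves_per_cluster = leaves_per_cluster,
            leaf_length = leaf_length, leaf_width = leaf_width,
            leaf_inclination = leaf_inclination,
            cluster_fan = cluster_fan,
            stem_diameter = stem_diameter, seed = as.integer(seed))
  for (f in c("stem_height", "branch_length", "leaf_length", "leaf_width",
              "stem_diameter")) {
    v <- p[[f]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("field '%s' must be finite and positive", f))
    }
  }
  for (f in c("n_internodes", "branches_per_node", "leaves_per_cluster")) {
    v <- p[[f]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("field '%s' must be a non-negative count", f))
    }
  }
  if (any(!is.finite(p$leaf_inclination)) || any(p$leaf_inclination < 0) ||
      any(p$leaf_inclination > 90)) {
    stop("field 'leaf_inclination' must lie in [0, 90] degrees")
  }
  structure(p, class = "plant_params")
}

triangle_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# accumulate mesh pieces in closures
new_mesh_builder <- function() {
  verts <- list(); faces <- list(); role <- list(); bone <- list()
  nv <- 0L
  add_quad <- function(p1, p2, p3, p4, r, b) {
    # two triangles of the (possibly non-planar) quad p1 p2 p3 p4
    verts[[length(verts) + 1L]] <<- rbind(p1, p2, p3, p4)
    faces[[length(faces) + 1L]] <<- rbind(nv + c(1L, 2L, 3L), nv + c(1L, 3L, 4L))
    role[[length(role) + 1L]] <<- rep(r, 2L)
    bone[[length(bone) + 1L]] <<- rep(b, 2L)
    nv <<- nv + 4L
  }
  build <- function() {
    list(vertices = do.call(rbind, verts), faces = do.call(rbind, faces),
         role = unlist(role), bone = unlist(bone))
  }
  list(add_quad = add_quad, build = build)
}

#' Generate a plant mesh from morphometric parameters
#'
#' Samples one plant from the parameter distributions (deterministically for
#' a fixed `seed`) and builds its triangle mesh together with the point-mass
#' skeleton used by the wave-motion integrator. The stem base sits at the
#' origin with z up.
#'
#' @param params A [plant_params()].
#' @return Object of class `plant_mesh`: `vertices` (n x 3, m), `faces`
#'   (m x 3 vertex indices), `role` ("leaf"/"stem" per facet), `leaf_area`
#'   (m^2), `skeleton` (nodes, edges, rest lengths, masses), `facet_bone`
#'   (skeleton edge each facet rides on, for re-skinning after motion).
#' @export
generate_plant <- function(params) {
  stopifnot(inherits(params, "plant_params"))
  with_seed(params$seed, {
    mb <- new_mesh_builder()
    s_nodes <- list(c(0, 0, 0)); s_edges <- list(); s_parent <- list()
    add_node <- function(p, parent) {
      s_nodes[[length(s_nodes) + 1L]] <<- p
      id <- length(s_nodes)
      s_edges[[length(s_edges) + 1L]] <<- c(parent, id)
      length(s_edges)   # edge id
    }
    height <- runif_range(1, params$stem_height)
    n_int <- max(1L, sample_count(1, params$n_internodes))
    dz <- height / n_int
    node_id <- 1L
    pos <- c(0, 0, 0)
    sd2 <- params$stem_diameter / 2

    add_ribbon <- function(p0, p1, half_width, bone) {
      d <- p1 - p0
      len <- sqrt(sum(d^2))
      if (len < 1e-9) return(invisible())
      d <- d / len
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      side <- c(d[2] * ref[3] - d[3] * ref[2],
                d[3] * ref[1] - d[1] * ref[3],
                d[1] * ref[2] - d[2] * ref[1])
      side <- side / sqrt(sum(side^2)) * half_width
      mb$add_quad(p0 - side, p0 + side, p1 + side, p1 - side, "stem", bone)
    }

    add_leaf <- function(origin, azimuth, incl_deg, len, wid, parent_node) {
      inc <- incl_deg * pi / 180
      d <- c(cos(azimuth) * cos(inc), sin(azimuth) * cos(inc), sin(inc))
      mid <- origin + d * len / 2
      tip <- origin + d * len
      mid_id <- add_node(mid, parent_node)
      e_mid <- length(s_edges)
      tip_id <- add_node(tip, mid_id)
      e_tip <- length(s_edges)
      # width axis: horizontal, perpendicular to the midrib azimuth
      w <- c(-sin(azimuth), cos(azimuth), 0) * wid / 2
      mb$add_quad(origin - w, origin + w, mid + w, mid - w, "leaf", e_mid)
      mb$add_quad(mid - w, mid + w, tip + w, tip - w, "leaf", e_tip)
      invisible()
    }

    add_cluster <- function(origin, parent_node) {
      n_lv <- sample_count(1, params$leaves_per_cluster)
      if (n_lv < 1L) return(invisible())
      # leaves of a cluster fan out around a common azimuth: the straps at
      # a branch tip overlap strongly (clumped foliage, not random stems)
      az0 <- runif(1, 0, 2 * pi)
      fan <- params$cluster_fan * pi / 180
      for (k in seq_len(n_lv)) {
        add_leaf(origin,
                 az0 + runif(1, -fan, fan),
                 runif_range(1, params$leaf_inclination),
                 runif_range(1, params$leaf_length),
                 runif_range(1, params$leaf_width),
                 parent_node)
      }
      invisible()
    }

    for (i in seq_len(n_int)) {
      nxt <- pos + c(runif(1, -0.004, 0.004), runif(1, -0.004, 0.004), dz)
      new_id <- add_node(nxt, node_id)
      e_id <- length(s_edges)
      add_ribbon(pos, nxt, sd2, e_id)
      # branches on the upper half of the stem
      if (i > n_int / 2) {
        nb <- sample_count(1, params$branches_per_node)
        for (b in seq_len(nb)) {
          az <- runif(1, 0, 2 * pi)
          el <- runif(1, 25, 60) * pi / 180
          bl <- runif_range(1, params$branch_length)
          bd <- c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
          btip <- nxt + bd * bl
          btip_id <- add_node(btip, new_id)
          be_id <- length(s_edges)
          add_ribbon(nxt, btip, sd2 * 0.6, be_id)
          add_cluster(btip, btip_id)
        }
      }
      pos <- nxt
      node_id <- new_id
    }
    add_cluster(pos, node_id)

    m <- mb$build()
    areas <- triangle_areas(m$vertices, m$faces)
    skel_nodes <- do.call(rbind, s_nodes)
    skel_edges <- do.call(rbind, s_edges)
    rest <- sqrt(rowSums((skel_nodes[skel_edges[, 2], , drop = FALSE] -
                            skel_nodes[skel_edges[, 1], , drop = FALSE])^2))
    structure(list(
      vertices = m$vertices, faces = m$faces, role = m$role,
      facet_bone = m$bone, facet_area = areas,
      leaf_area = sum(areas[m$role == "leaf"]),
      skeleton = list(nodes = skel_nodes, edges = skel_edges,
                      rest_length = rest,
                      mass = rep(0.001, nrow(skel_nodes))),
      params = params
    ), class = "plant_mesh")
  })
}

#' @export
print.plant_mesh <- function(x, ...) {
  cat(sprintf("Plant mesh: %d facets (%d leaf), leaf area %.4f m^2, height %.2f m\n",
              nrow(x$faces), sum(x$role == "leaf"), x$leaf_area,
              max(x$vertices[, 3])))
  invisible(x)
}

#' Assemble placed plants and a substrate into a periodic canopy scene
#'
#' Combines placed plant meshes with a horizontal substrate covering the
#' tile at z = 0. Scene semantics are periodic in x and y: the tile is
#' notionally repeated in all horizontal directions, and the ray tracer
#' wraps rays across tile boundaries.
#'
#' @param plants List of [generate_plant()] meshes, each optionally with a
#'   `position` attribute (x, y offset of the stem base inside the tile).
#' @param tile Tile dimensions c(x, y), m; default 0.2 x 0.2.
#' @return Object of class `canopy_scene` with combined `vertices`, `faces`,
#'   `role`, `material`, `plant_id`, `facet_area`, the `plants` list, the
#'   tile and the scene `lai`.
#' @export
canopy_scene <- function(plants = list(), tile = c(0.2, 0.2)) {
  stopifnot(all(tile > 0))
  verts <- list(); faces <- list(); role <- list(); plant_id <- list()
  nv <- 0L
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    pos <- attr(p, "position")
    if (is.null(pos)) pos <- c(0, 0)
    if (pos[1] < 0 || pos[1] >= tile[1] || pos[2] < 0 || pos[2] >= tile[2]) {
      stop("plant stem base must lie inside the tile")
    }
    v <- p$vertices
    v[, 1] <- v[, 1] + pos[1]; v[, 2] <- v[, 2] + pos[2]
    verts[[i]] <- v
    faces[[i]] <- p$faces + nv
    role[[i]] <- p$role
    plant_id[[i]] <- rep(i, nrow(p$faces))
    nv <- nv + nrow(v)
  }
  # substrate quad
  sx <- tile[1]; sy <- tile[2]
  verts[[length(verts) + 1L]] <- rbind(c(0, 0, 0), c(sx, 0, 0),
                                       c(sx, sy, 0), c(0, sy, 0))
  faces[[length(faces) + 1L]] <- rbind(nv + c(1L, 2L, 3L), nv + c(1L, 3L, 4L))
  role[[length(role) + 1L]] <- rep("substrate", 2L)
  plant_id[[length(plant_id) + 1L]] <- rep(0L, 2L)

  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  r <- unlist(role)
  scene <- structure(list(
    vertices = v, faces = f, role = r,
    material = c(leaf = MAT_LEAF, stem = MAT_STEM,
                 substrate = MAT_SUBSTRATE)[r],
    plant_id = unlist(plant_id),
    facet_area = triangle_areas(v, f),
    plants = plants, tile = tile
  ), class = "canopy_scene")
  scene$lai <- compute_lai(scene)
  scene
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("Canopy scene: %.2g x %.2g m tile, %d plants, %d facets, LAI %.3f\n",
              x$tile[1], x$tile[2], length(x$plants), nrow(x$faces), x$lai))
  invisible(x)
}

#' Leaf area index of a canopy scene
#'
#' One-sided leaf area per unit substrate area: the sum of leaf facet areas
#' divided by the tile area. Stems are optical occluders but are excluded
#' from LAI by the usual convention.
#'
#' @param scene A [canopy_scene()].
#' @return Dimensionless LAI.
#' @export
compute_lai <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  sum(scene$facet_area[scene$role == "leaf"]) / prod(scene$tile)
}

#' Merge two canopy scenes on the same tile
#'
#' Union of the plant sets (plants keep their positions); used for LAI
#' additivity and compositing fixtures.
#' @param a,b Scenes with identical tiles.
#' @return Combined [canopy_scene()].
#' @export
merge_scenes <- function(a, b) {
  stopifnot(all(a$tile == b$tile))
  canopy_scene(c(a$plants, b$plants), a$tile)
}

scale_leaf_width <- function(params, f) {
  params$leaf_width <- params$leaf_width * f
  params
}

#' Assemble a canopy of target leaf area index from a plant pool
#'
#' Draws plants cyclically from the parameter pool (with per-plant seeds
#' derived from `seed`) until the accumulated one-sided leaf area best
#' matches `target_lai * tile area`; as a last resort the leaf widths of all
#' chosen plants are uniformly rescaled by at most 5 percent so the achieved
#' LAI lands within 2 percent of the target. Stem bases are placed by seeded
#' uniform sampling with a minimum spacing (relaxed if the tile gets
#' crowded).
#'
#' @param plant_pool List of [plant_params()].
#' @param tile Tile dimensions, m.
#' @param target_lai Target LAI (>= 0).
#' @param seed Integer seed for plant sampling and placement.
#' @param min_spacing Minimum stem-base spacing, m.
#' @param base Optional existing [canopy_scene()] to extend: its plants are
#'   kept in place and new plants are added to reach the higher target, so
#'   a sequence of LAI treatments built incrementally is nested (the denser
#'   canopy contains the sparser one). Nesting makes the physically
#'   expected monotone effects of added leaf area -- lower transmittance,
#'   lower saturated fraction -- hold between treatments without
#'   Monte-Carlo caveats.
#' @return A [canopy_scene()] with `lai` within 2 percent of `target_lai`.
#' @export
assemble_canopy <- function(plant_pool, tile = c(0.2, 0.2), target_lai,
                            seed = 1L, min_spacing = 0.03, base = NULL) {
  stopifnot(target_lai >= 0, all(tile > 0))
  if (target_lai == 0 && is.null(base)) return(canopy_scene(list(), tile))
  if (length(plant_pool) == 0) stop("empty plant pool with positive target LAI")
  target_area <- target_lai * prod(tile)

  # grow the plant list until the target area is reached or overshot
  plants <- list(); areas <- numeric(0)
  n_base <- 0L
  if (!is.null(base)) {
    stopifnot(inherits(base, "canopy_scene"), all(base$tile == tile))
    if (base$lai > target_lai * (1 + 0.02)) {
      stop("base canopy already exceeds the target LAI")
    }
    plants <- base$plants
    areas <- vapply(plants, `[[`, numeric(1), "leaf_area")
    n_base <- length(plants)
  }
  i <- n_base
  repeat {
    i <- i + 1L
    if (i > 1000L) stop("target LAI unreachable with this pool (leafless plants?)")
    pp <- plant_pool[[(i - 1L) %% length(plant_pool) + 1L]]
    pp$seed <- as.integer((seed * 7919L + i * 104729L) %% 2147483647L)
    pl <- generate_plant(pp)
    if (pl$leaf_area <= 0) {
      if (all(areas == 0) && i > 10 * length(plant_pool)) {
        stop("target LAI unreachable with this pool (leafless plants?)")
      }
      next
    }
    plants[[length(plants) + 1L]] <- pl
    areas <- c(areas, pl$leaf_area)
    if (sum(areas) >= target_area) break
  }
  # fit the residual by resizing the final plant (leaf area is exactly
  # linear in the leaf length x width endpoint product, so this is exact),
  # staying within a sensible morphological range
  n <- length(areas)
  if (n == n_base) {
    # base alone already within reach of the target; nothing to resize
    if (abs(sum(areas) - target_area) > 0.02 * target_area) {
      stop("base canopy leaf area inconsistent with target")
    }
    return(base)
  }
  resid <- target_area - (sum(areas) - areas[n])
  g <- resid / areas[n]
  if (n - n_base > 1L && g < 0.1) {
    # residual too small for a credible plant: drop it and resize the new
    # last plant up by the (small) shortfall instead
    plants <- plants[-n]; areas <- areas[-n]
    n <- n - 1L
    resid <- target_area - (sum(areas) - areas[n])
    g <- resid / areas[n]
  }
  if (abs(g - 1) > 1e-9 && g >= 0.1 && g <= 3) {
    pp <- plants[[n]]$params
    pp$leaf_length <- pp$leaf_length * sqrt(g)
    pp$leaf_width <- pp$leaf_width * sqrt(g)
    plants[[n]] <- generate_plant(pp)
    areas[n] <- plants[[n]]$leaf_area
  }
  f <- target_area / sum(areas)
  if (abs(f - 1) > 0.05) {
    stop(sprintf(
      "cannot reach target LAI %.3g: residual width scaling %.3f exceeds 5%%",
      target_lai, f))
  }
  # regenerate with uniformly scaled leaf widths (leaf area is exactly
  # linear in width, so the achieved area matches the target)
  if (abs(f - 1) > 2e-3) {
    plants <- lapply(plants, function(pl) {
      generate_plant(scale_leaf_width(pl$params, f))
    })
  }
  # seeded placement with minimum spacing (base plants keep their spots)
  with_seed(seed + 777L, {
    pos <- matrix(NA_real_, length(plants), 2)
    for (k in seq_len(n_base)) pos[k, ] <- attr(plants[[k]], "position")
    spacing <- min_spacing
    for (k in seq_along(plants)) {
      if (k <= n_base) next
      ok <- FALSE
      for (try in 1:200) {
        cand <- c(runif(1, 0, tile[1] * 0.999), runif(1, 0, tile[2] * 0.999))
        if (k == 1L) { ok <- TRUE }
        else {
          # toroidal distance on the periodic tile
          dx <- abs(pos[1:(k - 1), 1] - cand[1]); dx <- pmin(dx, tile[1] - dx)
          dy <- abs(pos[1:(k - 1), 2] - cand[2]); dy <- pmin(dy, tile[2] - dy)
          ok <- all(sqrt(dx^2 + dy^2) >= spacing)
        }
        if (ok) break
        if (try %% 50 == 0) spacing <- spacing * 0.7
      }
      pos[k, ] <- cand
    }
    for (k in seq_along(plants)) attr(plants[[k]], "position") <- pos[k, ]
  })
  scene <- canopy_scene(plants, tile)
  if (abs(scene$lai - target_lai) > 0.02 * target_lai) {
    stop(sprintf("assembled LAI %.4f misses target %.4f by more than 2%%",
                 scene$lai, target_lai))
  }
  scene
}

#' Refine a scene so no facet exceeds a maximum area
#'
#' Longest-edge bisection until all leaf facet areas are at or below
#' `max_facet_area` (default 5e-5 m^2 = 0.5 cm^2, the leaf-surface
#' resolution of the irradiance field). The substrate is refined to twice
#' that limit and stems -- occluders whose own irradiance is never
#' analysed -- to eight times it. Bisection at edge midpoints preserves
#' total area per role exactly, and the operation is idempotent on an
#' already-refined scene.
#'
#' @param scene A [canopy_scene()].
#' @param max_facet_area Maximum leaf facet area, m^2.
#' @return Refined [canopy_scene()] (same class, plants list retained).
#' @export
facetize <- function(scene, max_facet_area = 5e-5) {
  stopifnot(inherits(scene, "canopy_scene"), max_facet_area > 0)
  v <- scene$vertices; f <- scene$faces
  role <- scene$role; pid <- scene$plant_id
  role_max <- function(r) {
    max_facet_area * c(leaf = 1, substrate = 2, stem = 8)[r]
  }
  areas <- triangle_areas(v, f)
  while (any(areas > role_max(role))) {
    big <- which(areas > role_max(role))
    keep <- setdiff(seq_len(nrow(f)), big)
    fb <- f[big, , drop = FALSE]
    p1 <- v[fb[, 1], , drop = FALSE]
    p2 <- v[fb[, 2], , drop = FALSE]
    p3 <- v[fb[, 3], , drop = FALSE]
    e12 <- rowSums((p2 - p1)^2); e23 <- rowSums((p3 - p2)^2)
    e31 <- rowSums((p1 - p3)^2)
    longest <- max.col(cbind(e12, e23, e31))
    # rotate so the longest edge is (a, b), opposite vertex c
    a <- p1; b <- p2; cc <- p3
    i2 <- longest == 2L; i3 <- longest == 3L
    a[i2, ] <- p2[i2, ]; b[i2, ] <- p3[i2, ]; cc[i2, ] <- p1[i2, ]
    a[i3, ] <- p3[i3, ]; b[i3, ] <- p1[i3, ]; cc[i3, ] <- p2[i3, ]
    mid <- (a + b) / 2
    nv0 <- nrow(v)
    nb <- length(big)
    v <- rbind(v, a, b, cc, mid)
    ia <- nv0 + seq_len(nb); ib <- ia + nb; ic <- ib + nb; im <- ic + nb
    newf <- rbind(cbind(ia, im, ic), cbind(im, ib, ic))
    f <- rbind(f[keep, , drop = FALSE], newf)
    role <- c(role[keep], rep(role[big], 2L))
    pid <- c(pid[keep], rep(pid[big], 2L))
    areas <- triangle_areas(v, f)
  }
  out <- scene
  out$vertices <- v; out$faces <- f; out$role <- role
  out$material <- c(leaf = MAT_LEAF, stem = MAT_STEM,
                    substrate = MAT_SUBSTRATE)[role]
  out$plant_id <- pid
  out$facet_area <- areas
  out$lai <- sum(areas[role == "leaf"]) / prod(out$tile)
  attr(out, "facetized") <- max_facet_area
  out
}
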
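test_that("plant generation is deterministic and additive in leaf area", {
  p <- plant_params(seed = 3)
  a <- generate_plant(p); b <- generate_plant(p)
  expect_identical(a$vertices, b$vertices)          # bitwise reproducible
  expect_identical(a$faces, b$faces)
  expect_equal(a$leaf_area, sum(a$facet_area[a$role == "leaf"]),
               tolerance = 1e-9)
  d <- generate_plant(plant_params(seed = 4))
  expect_false(isTRUE(all.equal(a$vertices, d$vertices)))
  # skeleton spans stem, branches and leaf midribs
  expect_gt(nrow(a$skeleton$nodes), 2 * sum(a$role == "leaf") / 4)
  expect_true(all(a$facet_bone >= 1))
})

test_that("degenerate and invalid plant parameters are handled", {
  p0 <- plant_params(branches_per_node = 0, leaves_per_cluster = 0)
  m <- generate_plant(p0)
  expect_true(all(m$role == "stem"))
  expect_equal(m$leaf_area, 0)
  expect_error(plant_params(leaf_length = -0.1), "leaf_length")
  expect_error(plant_params(stem_height = c(0.3, NaN)), "stem_height")
  expect_error(plant_params(leaf_inclination = c(-5, 30)), "leaf_inclination")
  expect_error(plant_params(branches_per_node = -1), "branches_per_node")
})

test_that("canopy assembly hits the treatment LAI targets", {
  pool <- make_fixtures(1, canopies = FALSE)$plant_pool
  # Table-style targets: one-sided leaf area = LAI * 0.04 m^2 within 2%
  sc1 <- assemble_canopy(pool, target_lai = 1.27, seed = 1)
  expect_equal(sum(sc1$facet_area[sc1$role == "leaf"]), 1.27 * 0.04,
               tolerance = 0.02)
  sc5 <- assemble_canopy(pool, target_lai = 7.65, seed = 1)
  expect_gte(sc5$lai, 7.50); expect_lte(sc5$lai, 7.80)
  # stem bases inside the tile
  for (p in sc5$plants) {
    pos <- attr(p, "position")
    expect_true(all(pos >= 0) && pos[1] < 0.2 && pos[2] < 0.2)
  }
  # empty pool with zero target: substrate-only scene
  sc0 <- assemble_canopy(list(), target_lai = 0)
  expect_equal(sc0$lai, 0)
  # leafless pool with positive target fails loudly
  bare <- plant_params(branches_per_node = 0, leaves_per_cluster = 0)
  expect_error(assemble_canopy(list(bare), target_lai = 1, seed = 1),
               "unreachable")
})

test_that("nested assembly extends a canopy without moving existing plants", {
  pool <- make_fixtures(1, canopies = FALSE)$plant_pool
  low <- assemble_canopy(pool, target_lai = 1.27, seed = 11)
  high <- assemble_canopy(pool, target_lai = 3.15, seed = 12, base = low)
  expect_equal(high$lai, 3.15, tolerance = 0.02 * 3.15)
  for (k in seq_along(low$plants)) {
    expect_identical(attr(high$plants[[k]], "position"),
                     attr(low$plants[[k]], "position"))
    expect_identical(high$plants[[k]]$vertices, low$plants[[k]]$vertices)
  }
  expect_error(assemble_canopy(pool, target_lai = 1.0, seed = 1, base = high),
               "exceeds")
})

test_that("LAI is one-sided leaf area per tile area and is additive", {
  expect_equal(compute_lai(canopy_scene(list(), c(0.2, 0.2))), 0)
  # one horizontal 10 cm^2 leaf on a 400 cm^2 tile
  sc <- single_leaf_scene(area = 0.001)
  expect_equal(compute_lai(sc), 0.025, tolerance = 1e-9)
  # fixture treatment C
  fx <- make_fixtures(1, lai_targets = 3.15)
  expect_equal(compute_lai(fx$canopies[["3.15"]]), 3.15, tolerance = 0.02)
  # additivity of merged scenes to 1e-9
  pool <- fx$plant_pool
  a <- assemble_canopy(pool, target_lai = 0.8, seed = 21)
  b <- assemble_canopy(pool, target_lai = 1.1, seed = 22)
  expect_equal(compute_lai(merge_scenes(a, b)),
               compute_lai(a) + compute_lai(b), tolerance = 1e-9)
})

test_that("facetization bounds leaf facet area and conserves area per role", {
  sc <- tiny_canopy(1.5, seed = 2)
  fs <- facetize(sc)   # default 0.5 cm^2
  expect_lte(max(fs$facet_area[fs$role == "leaf"]), 5e-5)
  for (r in unique(sc$role)) {
    expect_equal(sum(fs$facet_area[fs$role == r]),
                 sum(sc$facet_area[sc$role == r]),
                 tolerance = 1e-6 * sum(sc$facet_area[sc$role == r]))
  }
  # pigeonhole: facet count at least area / max_facet_area
  leaf_area <- sum(sc$facet_area[sc$role == "leaf"])
  expect_gte(sum(fs$role == "leaf"), ceiling(leaf_area / 5e-5))
  # idempotence
  fs2 <- facetize(fs)
  expect_equal(sort(fs2$facet_area), sort(fs$facet_area), tolerance = 1e-9)
  expect_error(facetize(sc, -1))
})

test_that("fixture regeneration is bitwise stable and toys are as described", {
  f1 <- make_fixtures(5, lai_targets = c(1.27, 1.94), tile = c(0.2, 0.2))
  f2 <- make_fixtures(5, lai_targets = c(1.27, 1.94), tile = c(0.2, 0.2))
  expect_identical(f1$canopies[["1.27"]]$vertices,
                   f2$canopies[["1.27"]]$vertices)
  expect_equal(f1$toys$single_leaf$lai,
               f1$toys$single_leaf$plants[[1]]$leaf_area / 0.04)
  expect_equal(f1$toys$substrate_only$lai, 0)
  expect_equal(sum(f1$toys$random50$role == "leaf"), 50L)
})
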
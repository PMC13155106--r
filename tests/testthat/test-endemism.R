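test_that("rasterization follows the half-open anchored convention", {
  g <- grid_spec(10)
  occ <- data.frame(otu_id = "s", latitude = -49.35, longitude = 70.22)
  cell <- rasterize(occ, g)$s
  expect_identical(cell, cell_of(-49.35, 70.22, g))
  rc <- cbind(cell %/% g$n_cols, cell %% g$n_cols)
  expect_equal(unname(rc[1, 1]), 4) # latitude band [-50, -40)
  expect_equal(unname(rc[1, 2]), 25) # longitude band [70, 80)
  # boundary point is lower-inclusive
  expect_identical(cell_of(-50, 70, g), cell_of(-49.99, 70.01, g))
  # two points in one cell collapse to a single cell
  occ2 <- data.frame(otu_id = c("s", "s"), latitude = c(-49, -41),
                     longitude = c(71, 79))
  expect_length(rasterize(occ2, g)$s, 1L)
  # poles and antimeridian
  expect_identical(cell_of(90, 0, g), cell_of(89.9, 0, g))
  expect_identical(cell_of(0, 180, g), cell_of(0, -180, g))
  expect_error(cell_of(91, 0, g), "invalid")
  expect_error(grid_spec(7), "divisor")
})

test_that("congruence score is the Jaccard index with its properties", {
  expect_equal(congruence_score(1:4, 1:4), 1)
  expect_equal(congruence_score(1L, 1:2), 0.5)
  expect_equal(congruence_score(c(1L, 3L), c(1L, 2L)), 1 / 3)
  expect_error(congruence_score(integer(0), 1L), "empty")
  set.seed(61)
  for (i in 1:20) {
    a <- sample(100, sample(8, 1))
    b <- sample(100, sample(8, 1))
    expect_equal(congruence_score(a, b), congruence_score(b, a))
    expect_identical(congruence_score(a, b) == 1, setequal(a, b))
  }
  # monotone decreasing as cells are added without species presences
  sp <- 1:3
  area <- 1:3
  prev <- congruence_score(sp, area)
  for (extra in 10:13) {
    area <- c(area, extra)
    cur <- congruence_score(sp, area)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("two coinciding species ranges yield one perfect area", {
  g <- grid_spec(30)
  block <- toy_block(g, 2, 3, 2, 2)
  raster <- list(sp1 = block, sp2 = block)
  areas <- search_areas(raster, g)
  expect_equal(length(areas), 1L)
  expect_identical(areas[[1]]$cells, block)
  expect_equal(areas[[1]]$total_score, 2)
  # a single species is never an area on its own
  expect_length(search_areas(list(sp1 = block), g), 0L)
  expect_error(search_areas(list(), g), "empty")
})

test_that("disjoint species ranges produce no shared area", {
  g <- grid_spec(30)
  raster <- list(sp1 = toy_block(g, 1, 1, 2, 2), sp2 = toy_block(g, 4, 8, 2, 2))
  expect_length(search_areas(raster, g), 0L)
})

test_that("search equals the exhaustive oracle on random toy grids", {
  g <- grid_spec(30)
  block <- toy_block(g, 2, 3, 3, 4) # 12-cell universe
  set.seed(71)
  for (rep in 1:15) {
    ns <- sample(2:3, 1)
    raster <- lapply(seq_len(ns), function(i) sort(sample(block, sample(2:6, 1))))
    names(raster) <- paste0("sp", seq_len(ns))
    want <- endemism_oracle_best(raster, g, block)
    got <- search_areas(raster, g)
    got_best <- if (length(got)) got[[1]]$total_score else 0
    expect_equal(got_best, want, tolerance = 1e-9)
  }
})

test_that("the heuristic search matches the oracle beyond the exact limit", {
  g <- grid_spec(30)
  block <- toy_block(g, 2, 3, 3, 4)
  set.seed(72)
  agree <- 0L
  for (rep in 1:8) {
    ns <- sample(2:3, 1)
    raster <- lapply(seq_len(ns), function(i) sort(sample(block, sample(3:6, 1))))
    names(raster) <- paste0("sp", seq_len(ns))
    want <- endemism_oracle_best(raster, g, block)
    got <- search_areas(raster, g, exact_limit = 0) # force the heuristic
    got_best <- if (length(got)) got[[1]]$total_score else 0
    expect_lte(got_best, want + 1e-9)
    if (abs(got_best - want) < 1e-9) agree <- agree + 1L
  }
  expect_gte(agree, 6L) # the heuristic may miss rare bridge-only optima
})

test_that("consensus merges overlapping areas sharing enough species", {
  mk <- function(cells, species) {
    structure(list(cells = sort(cells),
                   endemic_species = setNames(rep(1, length(species)), species),
                   total_score = length(species)), class = "endemicity_area")
  }
  g <- grid_spec(30)
  b1 <- toy_block(g, 2, 3, 2, 2)
  b2 <- c(b1[4], toy_block(g, 3, 5, 1, 2)) # shares one cell with b1
  raster <- list(s1 = b1, s2 = union(b1, b2), s3 = b2)
  a1 <- mk(b1, c("s1", "s2"))
  a2 <- mk(b2, c("s2", "s3"))
  merged <- consensus_areas(list(a1, a2), raster)
  expect_length(merged, 1L)
  expect_identical(merged[[1]]$cells, sort(union(b1, b2)))

  # disjoint species sets never merge
  a3 <- mk(b2, c("s3", "s4"))
  raster2 <- c(raster, list(s4 = b2))
  kept <- consensus_areas(list(a1, a3), raster2)
  expect_length(kept, 2L)

  # single area returned unchanged
  expect_identical(consensus_areas(list(a1), raster)[[1]]$cells, a1$cells)
})

test_that("planted zones are recovered at 10 degrees with a 2:1 species ratio", {
  cfg <- zone_test_config(seed = 7)
  pool <- simulate_reference_pool(cfg)
  g <- grid_spec(10)
  raster <- rasterize(pool$occurrences, g)
  areas <- consensus_areas(search_areas(raster, g), raster)
  expect_equal(length(areas), 2L)
  boxes <- lapply(cfg$endemicity_zones, zone_box_cells, grid = g)
  jac <- vapply(areas, function(a)
    max(vapply(boxes, cellset_jaccard, 0, x = a$cells)), 0)
  expect_true(all(jac >= 0.8))
  n_sp <- sort(vapply(areas, function(a) length(a$endemic_species), 0),
               decreasing = TRUE)
  expect_lt(abs(n_sp[1] / n_sp[2] - 2), 0.4)
})
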
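test_that("configuration validation names the offending field", {
  expect_error(simulation_config(known_fraction = 1.2), "known_fraction")
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulation_config(latitudinal_class_mix = c(arctic = 1)),
               "latitudinal_class_mix")
  mix <- c(cosmopolitan = 0.5, arctic = 0.6, antarctic = 0,
           northern_hemisphere = 0, southern_hemisphere = 0,
           low_latitudes = 0, other = 0)
  expect_error(simulation_config(latitudinal_class_mix = mix), "summing to 1")
  expect_error(simulation_config(endemicity_zones = list(list(lat_min = 10))),
               "endemicity_zones")
})

test_that("empty configuration yields an empty pool", {
  pool <- simulate_reference_pool(simulation_config(n_otus = 0, seed = 1))
  expect_equal(nrow(pool$ref), 0L)
  expect_equal(nrow(pool$occurrences), 0L)
  expect_length(pool$sequences, 0L)
})

test_that("an all-arctic class mix places every occurrence above 60 degrees", {
  mix <- c(cosmopolitan = 0, arctic = 1, antarctic = 0,
           northern_hemisphere = 0, southern_hemisphere = 0,
           low_latitudes = 0, other = 0)
  cfg <- simulation_config(n_otus = 50, known_fraction = 1,
                           latitudinal_class_mix = mix,
                           annotation_only_fraction = 0, seed = 1)
  pool <- simulate_reference_pool(cfg)
  expect_gt(nrow(pool$occurrences), 0L)
  expect_true(all(pool$occurrences$latitude >= 60))
})

test_that("seeds change coordinates but not pool shape; same seed is byte-identical", {
  cfg1 <- simulation_config(n_otus = 30, seed = 11)
  cfg2 <- simulation_config(n_otus = 30, seed = 12)
  p1 <- simulate_reference_pool(cfg1)
  p2 <- simulate_reference_pool(cfg2)
  expect_equal(nrow(p1$ref), nrow(p2$ref))
  expect_false(identical(p1$occurrences$latitude, p2$occurrences$latitude))

  p1b <- simulate_reference_pool(cfg1)
  expect_identical(p1[names(p1) != "config"], p1b[names(p1b) != "config"])
  i1 <- simulate_island_dataset(p1, cfg1)
  i1b <- simulate_island_dataset(p1b, cfg1)
  expect_identical(i1[names(i1) != "config"], i1b[names(i1b) != "config"])
})

test_that("zone OTUs concentrate occurrences inside their bounding box", {
  cfg <- zone_test_config(seed = 3)
  pool <- simulate_reference_pool(cfg)
  zones <- cfg$endemicity_zones
  for (zi in seq_along(zones)) {
    z <- zones[[zi]]
    ids <- pool$ref$id[!is.na(pool$ref$zone) & pool$ref$zone == zi]
    expect_length(ids, z$n_zone_otus)
    for (id in ids) {
      occ <- pool$occurrences[pool$occurrences$otu_id == id, ]
      inside <- occ$latitude >= z$lat_min & occ$latitude <= z$lat_max &
        occ$longitude >= z$lon_min & occ$longitude <= z$lon_max
      expect_gte(mean(inside), 0.8)
    }
  }
})

test_that("the field design yields 70 paired root and soil samples", {
  cfg <- simulation_config(n_otus = 10, seed = 2)
  pool <- simulate_reference_pool(cfg)
  isl <- simulate_island_dataset(pool, cfg)
  md <- isl$metadata
  expect_equal(nrow(md), 140L)
  expect_equal(sum(md$sample_type == "root"), 70L)
  expect_equal(sum(md$sample_type == "soil"), 70L)
  # every individual appears exactly once as root and once as soil
  expect_true(all(table(md$individual) == 2L))
  key <- with(md, paste(site, plant_species, individual, sample_type))
  expect_false(anyDuplicated(key) > 0)
})

test_that("known OTUs stay within 97% of their source; unknown stay below", {
  cfg <- simulation_config(n_otus = 20, known_fraction = 0.5, seed = 4)
  pool <- simulate_reference_pool(cfg)
  isl <- simulate_island_dataset(pool, cfg)
  tr <- isl$truth$otu
  for (i in which(tr$known)) {
    members <- names(isl$truth$asv_otu)[isl$truth$asv_otu == tr$planted_otu[i]]
    src <- pool$sequences[[tr$ref_id[i]]]
    for (mid in members) {
      s <- isl$asvs$sequences[match(mid, isl$asvs$ids)]
      expect_gte(global_identity(s, src), 0.97)
    }
  }
  for (i in which(!tr$known)) {
    members <- names(isl$truth$asv_otu)[isl$truth$asv_otu == tr$planted_otu[i]]
    s <- isl$asvs$sequences[match(members[1], isl$asvs$ids)]
    best <- max(vapply(pool$sequences, global_identity, 0, a = s))
    expect_lt(best, 0.97)
  }
})

test_that("private-haplotype off-switch plants no private ASVs", {
  cfg <- simulation_config(n_otus = 30, private_fraction = 0, seed = 6)
  pool <- simulate_reference_pool(cfg)
  isl <- simulate_island_dataset(pool, cfg)
  expect_false(any(isl$truth$otu$private))
  expect_false(any(isl$truth$asv_private))
  # every island ASV of a known OTU exists in the pool haplotype set
  tr <- isl$truth$otu
  for (i in which(tr$known)) {
    members <- names(isl$truth$asv_otu)[isl$truth$asv_otu == tr$planted_otu[i]]
    haps <- pool$haplotypes$sequence[pool$haplotypes$ref_id == tr$ref_id[i]]
    got <- isl$asvs$sequences[match(members, isl$asvs$ids)]
    expect_true(all(got %in% haps))
  }
})

test_that("environmental mean field is monotone, deterministic and longitude-free", {
  e0 <- env_from_location(c(10, 80), c(0, 0), noise_sd = 0)
  expect_lt(e0$mat[2], e0$mat[1])
  a <- env_from_location(45, 10, noise_sd = 1, seed = 9)
  b <- env_from_location(45, 10, noise_sd = 1, seed = 9)
  expect_identical(a, b)
  l1 <- env_from_location(0, 0, noise_sd = 0)
  l2 <- env_from_location(0, 120, noise_sd = 0)
  expect_identical(l1$mat, l2$mat)
  expect_error(env_from_location(95, 0), "latitude")
  # strictly decreasing in |lat| across the full range
  lats <- seq(0, 90, by = 5)
  expect_true(all(diff(env_from_location(lats, 0, 0)$mat) < 0))
})

test_that("synthetic inputs are written as plain-text files", {
  cfg <- simulation_config(n_otus = 8, seed = 5)
  pool <- simulate_reference_pool(cfg)
  isl <- simulate_island_dataset(pool, cfg)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(isl, pool, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "asv_sequences.fasta", "asv_table.tsv", "sample_metadata.tsv",
    "pool_taxonomy.tsv", "pool_occurrences.tsv", "pool_haplotypes.tsv",
    "pool_sequences.fasta", "config.json")))))
  tab <- read.delim(file.path(dir, "asv_table.tsv"), check.names = FALSE)
  expect_equal(nrow(tab), length(isl$asvs$ids))
  expect_equal(ncol(tab), 1L + nrow(isl$metadata))
})
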
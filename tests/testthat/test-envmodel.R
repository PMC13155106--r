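test_that("Moran eigenvectors are centered, orthogonal and rotation-invariant", {
  # three (near-)equidistant points
  coords <- cbind(c(0, 0, 0.866), c(-0.5, 0.5, 0))
  M <- mem_eigenvectors(coords)
  expect_gte(ncol(M), 1L)
  G <- crossprod(M)
  if (ncol(M) > 1L) {
    expect_lt(max(abs(G[upper.tri(G)])), 1e-9 * max(diag(G)))
  }
  expect_lt(max(abs(colSums(M))), 1e-6)

  set.seed(81)
  pts <- cbind(runif(20, -60, 60), runif(20, -150, 150))
  M1 <- mem_eigenvectors(pts)
  shifted <- cbind(pts[, 1], pts[, 2] + 15)
  M2 <- mem_eigenvectors(shifted)
  expect_equal(attr(M1, "values"), attr(M2, "values"), tolerance = 1e-6)

  expect_error(mem_eigenvectors(pts[1:2, ]), "at least 3")
  expect_error(mem_eigenvectors(rbind(pts, pts[1, ])), "duplicate")
})

test_that("Moran eigenvectors agree with the classical PCNM construction", {
  skip_if_not_installed("vegan")
  set.seed(82)
  pts <- cbind(runif(25, -60, 60), runif(25, -170, 170))
  M <- mem_eigenvectors(pts)
  d <- geosphere::distm(pts[, c(2, 1)], fun = geosphere::distHaversine)
  p <- vegan::pcnm(stats::as.dist(d), threshold = attr(M, "truncation"))
  pos <- p$values > max(p$values) * 1e-10
  expect_equal(ncol(M), sum(pos))
  expect_equal(attr(M, "values"), p$values[pos], tolerance = 1e-9)
  for (k in seq_len(min(3, ncol(M)))) {
    expect_gt(abs(stats::cor(M[, k], p$vectors[, k])), 0.999)
  }
})

test_that("adjusted R2 matches closed-form simple regression and edge cases", {
  x <- 1:5
  y <- c(1, 2, 3, 4, 6)
  r <- adjusted_r2(y, cbind(x))
  # hand computation: Sxy = 12, Sxx = 10, Syy = 14.8
  expect_equal(r$r2, 144 / 148, tolerance = 1e-12)
  expect_equal(r$adj_r2, 1 - (1 - 144 / 148) * 4 / 3, tolerance = 1e-12)

  # perfect multivariate fit
  set.seed(83)
  X <- matrix(rnorm(60), 20)
  Yp <- X %*% c(1, -2, 0.5)
  expect_equal(adjusted_r2(Yp, X)$r2, 1, tolerance = 1e-12)

  # a constant predictor explains nothing (and is flagged collinear)
  expect_warning(r0 <- adjusted_r2(y, matrix(1, 5)), "rank-deficient")
  expect_equal(r0$r2, 0)
  expect_error(adjusted_r2(y, cbind(x[1:4])), "row counts")
})

test_that("variance partition satisfies its identities on random inputs", {
  set.seed(84)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    E <- matrix(rnorm(n * 3), n)
    S <- matrix(rnorm(n * 2), n)
    Y <- rnorm(n)
    vp <- variance_partition(Y, E, S, n_perm = 3, seed = rep)
    expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
    expect_equal(vp$a + vp$b, vp$adj_r2_env, tolerance = 1e-9)
    expect_equal(vp$b + vp$c, vp$adj_r2_space, tolerance = 1e-9)
    expect_equal(vp$a + vp$b + vp$c, vp$adj_r2_full, tolerance = 1e-9)
  }
  expect_error(variance_partition(rnorm(10), matrix(rnorm(10)),
                                  matrix(rnorm(10)), n_perm = 0), "n_perm")
})

test_that("identical environment and space matrices share all explained variance", {
  set.seed(85)
  X <- matrix(rnorm(40 * 2), 40)
  Y <- X %*% c(1, 1) + rnorm(40, 0, 0.5)
  vp <- suppressWarnings(variance_partition(Y, X, X, n_perm = 3, seed = 1))
  expect_equal(vp$a, 0, tolerance = 1e-9)
  expect_equal(vp$c, 0, tolerance = 1e-9)
  expect_equal(vp$b, vp$adj_r2_full, tolerance = 1e-9)
})

test_that("variance partition agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(86)
  n <- 80
  E <- matrix(rnorm(n * 3), n)
  S <- matrix(rnorm(n * 4), n)
  Y <- 0.5 * E[, 1] - 0.3 * S[, 2] + rnorm(n)
  vp <- variance_partition(Y, E, S, n_perm = 3, seed = 1)
  ref <- vegan::varpart(Y, E, S)$part$indfract$Adj.R.square
  # vegan rows: [a] pure X1, [b] pure X2, [c] shared, [d] residual
  expect_equal(vp$a, ref[1], tolerance = 1e-10)
  expect_equal(vp$c, ref[2], tolerance = 1e-10)
  expect_equal(vp$b, ref[3], tolerance = 1e-10)
  expect_equal(vp$d, ref[4], tolerance = 1e-10)
})

test_that("design preparation transforms, standardizes and drops degenerates", {
  rec <- data.frame(abundance = c(1, 10, 100, rep(5, 9)),
                    latitude = c(seq(-60, 50, length.out = 11), 55),
                    mat = rnorm(12), precipitation = runif(12, 200, 900),
                    ph = runif(12, 4, 8), soc = runif(12, 1, 9),
                    study_id = "s1", primer = "p", sample_type = "soil")
  d <- prepare_design(rec)
  expect_equal(d$response[1:3], c(0, 1, 2))
  for (j in seq_len(ncol(d$predictors))) {
    expect_lt(abs(mean(d$predictors[, j])), 1e-9)
    expect_lt(abs(sd(d$predictors[, j]) - 1), 1e-9)
  }
  expect_true("latitude_sq" %in% colnames(d$predictors))

  rec0 <- rec
  rec0$mat <- 3
  expect_warning(d0 <- prepare_design(rec0), "zero variance")
  expect_false("mat" %in% colnames(d0$predictors))

  recz <- rec
  recz$abundance[1] <- 0
  expect_message(dz <- prepare_design(recz), "dropped 1")
  expect_equal(dz$n_dropped, 1L)
  expect_error(prepare_design(rec[1:5, ]), "fewer than")
})

test_that("a space-dominant generator yields pure space above pure environment", {
  mix <- c(cosmopolitan = 0.35, arctic = 0.10, antarctic = 0.10,
           northern_hemisphere = 0.15, southern_hemisphere = 0,
           low_latitudes = 0.20, other = 0.10)
  cfg <- simulation_config(n_otus = 60, known_fraction = 1,
                           latitudinal_class_mix = mix,
                           n_occurrences_per_otu = 40, seed = 7)
  pool <- simulate_reference_pool(cfg)
  occ <- pool$occurrences
  occ <- occ[!duplicated(occ[, c("latitude", "longitude")]), ]
  set.seed(87)
  occ <- occ[sample(nrow(occ), min(nrow(occ), 1200)), ]
  des <- prepare_design(occ)
  E <- des$predictors[, c("mat", "precipitation", "ph", "soc")]
  S <- mem_eigenvectors(occ[, c("latitude", "longitude")])
  S <- S[, seq_len(min(120, ncol(S))), drop = FALSE]
  vp <- variance_partition(des$response, E, S, n_perm = 19, seed = 2)
  expect_lt(vp$a, vp$c)
  expect_gt(vp$c, 0.05)
})

test_that("the mixed model recovers the planted effect directions", {
  skip_if_not_installed("lme4")
  cfg <- simulation_config(n_otus = 250, known_fraction = 1,
                           n_occurrences_per_otu = 30,
                           annotation_only_fraction = 0, seed = 19)
  pool <- simulate_reference_pool(cfg)
  des <- prepare_design(pool$occurrences)
  df <- data.frame(y = des$response, des$predictors, des$groups)
  fit <- lme4::lmer(
    y ~ latitude + latitude_sq + mat + precipitation + ph + soc +
      (1 | study_id) + (1 | primer) + (1 | sample_type), data = df)
  beta <- lme4::fixef(fit)
  expect_lt(beta[["mat"]], 0)
  expect_gt(beta[["soc"]], 0)
  expect_gt(beta[["ph"]], 0)
  expect_gt(beta[["latitude"]], 0)
})
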
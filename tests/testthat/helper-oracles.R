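# Independent oracles, coded separately from the package internals.

# Plain-matrix Needleman-Wunsch maximizing (matches, aligned pairs)
# lexicographically; identity = matches / alignment length.
nw_oracle <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  big <- m + n + 1
  S <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      diag <- S[i, j] + if (A[i] == B[j]) big + 1 else 1
      S[i + 1, j + 1] <- max(diag, S[i, j + 1], S[i + 1, j])
    }
  }
  sc <- S[m + 1, n + 1]
  M <- sc %/% big
  P <- sc %% big
  list(matches = M, align_length = m + n - P, identity = M / (m + n - P))
}

# Greedy centroid clustering re-implemented from the contract: decreasing
# total reads (ties by id), first centroid at >= threshold wins.
cluster_oracle <- function(ids, seqs, totals, threshold = 0.97) {
  ord <- order(-totals, ids)
  centroids <- integer(0)
  labels <- integer(length(ids))
  for (k in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (nw_oracle(seqs[k], seqs[centroids[ci]])$identity >= threshold) {
        labels[k] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids <- c(centroids, k)
      labels[k] <- length(centroids)
    }
  }
  labels
}

# Partition comparison independent of label names: canonical sets of ids.
partition_sets <- function(ids, labels) {
  unname(sort(vapply(split(ids, labels),
                     function(x) paste(sort(x), collapse = "|"), "")))
}

# Latitudinal rule oracle, straight transcription of the class legend.
lat_class_oracle <- function(m, M) {
  spans <- m < 0 && M > 0
  if ((M - m) > 60 && spans) return("cosmopolitan")
  if (m >= 60) return("arctic")
  if (M <= -50) return("antarctic")
  if (m >= 40 && M <= 60) return("northern_hemisphere")
  if (m >= -50 && M <= -40) return("southern_hemisphere")
  if (m >= -40 && M <= 40) return("low_latitudes")
  "other"
}

rand_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, pos) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# ---- toy-grid endemism oracle ----------------------------------------------

toy_block <- function(grid, r0, c0, nr, nc) {
  out <- integer(0)
  for (r in r0:(r0 + nr - 1)) {
    for (cc in c0:(c0 + nc - 1)) out <- c(out, r * grid$n_cols + cc)
  }
  sort(out)
}

toy_adjacency <- function(cells, grid) {
  n <- length(cells)
  A <- matrix(FALSE, n, n)
  r <- cells %/% grid$n_cols
  cc <- cells %% grid$n_cols
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(r[i] - r[j])
    dc <- min(abs(cc[i] - cc[j]), grid$n_cols - abs(cc[i] - cc[j]))
    A[i, j] <- (dr + dc) == 1
  }
  A
}

toy_connected <- function(idx, A) {
  if (length(idx) <= 1L) return(TRUE)
  seen <- idx[1L]
  repeat {
    nb <- idx[idx %in% which(apply(A[seen, , drop = FALSE], 2, any))]
    nb <- union(seen, nb)
    if (length(nb) == length(seen)) break
    seen <- nb
  }
  length(seen) == length(idx)
}

# Best total score over every connected subset of `cells`.
endemism_oracle_best <- function(raster, grid, cells,
                                 min_score = 0.5, min_species = 2) {
  A <- toy_adjacency(cells, grid)
  n <- length(cells)
  best <- 0
  for (m in seq_len(2^n - 1)) {
    idx <- which(as.logical(bitwAnd(m, 2^(0:(n - 1)))))
    if (!toy_connected(idx, A)) next
    cs <- cells[idx]
    sc <- vapply(raster, function(sp) {
      i <- length(intersect(sp, cs))
      i / (length(sp) + length(cs) - i)
    }, 0)
    sc <- sc[sc >= min_score]
    if (length(sc) < min_species) next
    if (sum(sc) > best) best <- sum(sc)
  }
  best
}

# Prim MST total weight oracle for haplotype networks.
mst_weight_oracle <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  w <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    w <- w + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  w
}

# Planted-zone test configuration: two zones (species ratio 2:1) on a
# diffuse background (no single-row southern band class).
zone_test_config <- function(seed = 7) {
  simulation_config(
    n_otus = 60, known_fraction = 1,
    endemicity_zones = list(
      list(lat_min = -70, lat_max = -50, lon_min = -80, lon_max = -60,
           n_zone_otus = 12),
      list(lat_min = 50, lat_max = 70, lon_min = 0, lon_max = 30,
           n_zone_otus = 6)),
    latitudinal_class_mix = c(cosmopolitan = 0.35, arctic = 0.10,
                              antarctic = 0.10, northern_hemisphere = 0.15,
                              southern_hemisphere = 0, low_latitudes = 0.20,
                              other = 0.10),
    n_occurrences_per_otu = 40, seed = seed)
}

zone_box_cells <- function(zone, grid) {
  eps <- 1e-9
  lats <- seq(zone$lat_min + eps, zone$lat_max - eps, by = grid$cell_size / 2)
  lons <- seq(zone$lon_min + eps, zone$lon_max - eps, by = grid$cell_size / 2)
  pts <- expand.grid(lat = lats, lon = lons)
  sort(unique(cell_of(pts$lat, pts$lon, grid)))
}

cellset_jaccard <- function(x, y) length(intersect(x, y)) / length(union(x, y))
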
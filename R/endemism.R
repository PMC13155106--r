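#' Specification of a world grid
#'
#' Cells are half-open `[lo, lo + size)` in both axes, anchored at -90
#' latitude and -180 longitude, so every valid coordinate maps to exactly
#' one cell; latitude 90 is clamped into the top row and longitude 180
#' wraps to -180. Adjacency is 4-neighbour with longitude wrap-around at
#' the antimeridian (no wrap across the poles).
#'
#' @param cell_size Cell edge in degrees; must divide 180.
#' @return Object of class `grid_spec` with `cell_size`, `n_rows`,
#'   `n_cols`.
#' @export
grid_spec <- function(cell_size = 10) {
  if (cell_size <= 0 || abs(180 / cell_size - round(180 / cell_size)) > 1e-9) {
    stop("grid_spec: cell_size must be a positive divisor of 180")
  }
  structure(list(cell_size = cell_size,
                 n_rows = as.integer(round(180 / cell_size)),
                 n_cols = as.integer(round(360 / cell_size))),
            class = "grid_spec")
}

#' Map coordinates to grid cells
#'
#' @param lat,lon Coordinate vectors.
#' @param grid A [grid_spec()].
#' @return Integer cell ids (`row * n_cols + col`, rows/cols 0-based).
#' @export
cell_of <- function(lat, lon, grid) {
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90) ||
      any(!is.finite(lon)) || any(lon < -180 | lon > 180)) {
    stop("cell_of: invalid coordinates")
  }
  lon <- ifelse(lon >= 180, lon - 360, lon)
  row <- pmin(floor((lat + 90) / grid$cell_size), grid$n_rows - 1L)
  col <- floor((lon + 180) / grid$cell_size)
  as.integer(row * grid$n_cols + col)
}

cell_rowcol <- function(cell, grid) {
  cbind(row = cell %/% grid$n_cols, col = cell %% grid$n_cols)
}

cell_neighbours <- function(cell, grid) {
  rc <- cell_rowcol(cell, grid)
  r <- rc[, "row"]; c <- rc[, "col"]
  nb <- rbind(
    cbind(r - 1L, c), cbind(r + 1L, c),
    cbind(r, (c - 1L) %% grid$n_cols), cbind(r, (c + 1L) %% grid$n_cols))
  ok <- nb[, 1L] >= 0L & nb[, 1L] < grid$n_rows
  unique(as.integer(nb[ok, 1L] * grid$n_cols + nb[ok, 2L]))
}

#' Rasterize occurrences onto the grid
#'
#' @param occurrences data.frame with `otu_id`, `latitude`, `longitude`.
#' @param grid A [grid_spec()].
#' @return Named list: species id -> sorted integer vector of occupied
#'   cells.
#' @export
rasterize <- function(occurrences, grid) {
  stopifnot(all(c("otu_id", "latitude", "longitude") %in% names(occurrences)))
  cells <- cell_of(occurrences$latitude, occurrences$longitude, grid)
  lapply(split(cells, occurrences$otu_id), function(x) sort(unique(x)))
}

#' Spatial congruence (Jaccard) of a species range with an area
#'
#' @param species_cells,area_cells Nonempty integer cell sets.
#' @return `|intersection| / |union|`, in \[0, 1\]; 1 iff the sets
#'   coincide.
#' @export
congruence_score <- function(species_cells, area_cells) {
  if (length(species_cells) == 0L || length(area_cells) == 0L) {
    stop("congruence_score: empty cell set")
  }
  i <- length(intersect(species_cells, area_cells))
  i / (length(species_cells) + length(area_cells) - i)
}

# Species scoring of an area; an inverted cell -> species index restricts
# evaluation to species overlapping the area (sound when min_score > 0,
# since a non-overlapping species scores 0).
area_scores <- function(cells, raster, min_score, index = NULL) {
  sub <- raster
  if (!is.null(index) && min_score > 0) {
    cand <- unique(unlist(index[as.character(cells)], use.names = FALSE))
    if (!length(cand)) return(setNames(numeric(0), character(0)))
    sub <- raster[cand]
  }
  sc <- vapply(sub, function(sp) congruence_score(sp, cells), 0)
  sc[sc >= min_score]
}

build_cell_index <- function(raster) {
  cells <- unlist(raster, use.names = FALSE)
  sp <- rep(names(raster), lengths(raster))
  split(sp, as.character(cells))
}

connected_components <- function(cells, grid) {
  remaining <- cells
  comps <- list()
  while (length(remaining)) {
    frontier <- remaining[1L]
    comp <- frontier
    remaining <- remaining[-1L]
    while (length(frontier)) {
      nb <- intersect(unlist(lapply(frontier, cell_neighbours, grid = grid)),
                      remaining)
      comp <- c(comp, nb)
      remaining <- setdiff(remaining, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

is_connected <- function(cells, grid) {
  length(connected_components(cells, grid)) <= 1L
}

# BFS shortest cell path between two cell sets (through any cells), used to
# bridge nearby components of a seed. Returns the intermediate cells or NULL
# when no path within max_gap exists.
bridge_path <- function(from_cells, to_cells, grid, max_gap) {
  frontier <- from_cells
  visited <- from_cells
  parent <- list()
  for (depth in seq_len(max_gap)) {
    nxt <- integer(0)
    for (f in frontier) {
      for (nb in setdiff(cell_neighbours(f, grid), visited)) {
        parent[[as.character(nb)]] <- f
        nxt <- c(nxt, nb)
        visited <- c(visited, nb)
        if (nb %in% to_cells) {
          # walk back, collecting intermediate cells only
          path <- integer(0)
          cur <- f
          while (!(cur %in% from_cells)) {
            path <- c(path, cur)
            cur <- parent[[as.character(cur)]]
          }
          return(path)
        }
      }
    }
    frontier <- setdiff(nxt, to_cells)
    if (!length(frontier)) break
  }
  NULL
}

# Make a seed connected by bridging components separated by short gaps
# (<= max_gap empty cells); distant components are left to their own seeds.
connectify <- function(cells, grid, max_gap = 2L) {
  comps <- connected_components(cells, grid)
  if (length(comps) <= 1L) return(list(sort(cells)))
  comps <- comps[order(-lengths(comps), vapply(comps, min, 0L))]
  merged <- comps[[1L]]
  out_rest <- list()
  rest <- comps[-1L]
  progress <- TRUE
  while (length(rest) && progress) {
    progress <- FALSE
    for (k in seq_along(rest)) {
      p <- bridge_path(merged, rest[[k]], grid, max_gap)
      if (!is.null(p) || length(intersect(merged, rest[[k]]))) {
        merged <- sort(unique(c(merged, p, rest[[k]])))
        rest <- rest[-k]
        progress <- TRUE
        break
      }
    }
  }
  c(list(merged), rest)
}

hill_climb <- function(cells, raster, grid, min_score, index = NULL,
                       max_iter = 500L) {
  total <- function(cs) sum(area_scores(cs, raster, min_score, index))
  cur <- sort(cells)
  cur_score <- total(cur)
  for (it in seq_len(max_iter)) {
    # candidate moves: add a frontier cell, or remove a cell keeping
    # connectivity; deterministic evaluation order
    adds <- sort(setdiff(unlist(lapply(cur, cell_neighbours, grid = grid)), cur))
    best_gain <- 0; best_set <- NULL
    for (a in adds) {
      s <- total(c(cur, a))
      if (s - cur_score > best_gain + 1e-12) {
        best_gain <- s - cur_score; best_set <- sort(c(cur, a))
      }
    }
    if (length(cur) > 1L) {
      for (r in cur) {
        cand <- setdiff(cur, r)
        if (!is_connected(cand, grid)) next
        s <- total(cand)
        if (s - cur_score > best_gain + 1e-12) {
          best_gain <- s - cur_score; best_set <- cand
        }
      }
    }
    if (is.null(best_set)) break
    cur <- best_set
    cur_score <- cur_score + best_gain
  }
  list(cells = cur, total_score = cur_score)
}

# Exact search by bitmask enumeration of every connected subset of the
# bounding box of the occupied cells (including empty bridge cells). Only
# used when the box has at most `limit` cells; returns locally maximal
# qualifying areas (the global optimum is always among them), or NULL when
# the instance is too large.
exact_search <- function(raster, grid, min_score, min_species, limit) {
  occ <- sort(unique(unlist(raster, use.names = FALSE)))
  rc <- cell_rowcol(occ, grid)
  r0 <- min(rc[, "row"]); r1 <- max(rc[, "row"])
  c0 <- min(rc[, "col"]); c1 <- max(rc[, "col"])
  n <- (r1 - r0 + 1) * (c1 - c0 + 1)
  if (n > limit || n > 20L) return(NULL)
  cells <- as.integer(vapply(c0:c1, function(cc) (r0:r1) * grid$n_cols + cc,
                             integer(r1 - r0 + 1)))
  idx_of <- function(cell) match(cell, cells)
  adj_mask <- integer(n)
  for (i in seq_len(n)) {
    nb <- idx_of(cell_neighbours(cells[i], grid))
    nb <- nb[!is.na(nb)]
    adj_mask[i] <- sum(bitwShiftL(1L, nb - 1L))
  }
  sp_mask <- vapply(raster, function(sp) {
    ii <- idx_of(sp); sum(bitwShiftL(1L, ii[!is.na(ii)] - 1L))
  }, 0L)
  sp_n <- lengths(raster)
  popcount <- function(m) { # 20-bit popcount
    k <- 0L
    while (m > 0L) { k <- k + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
    k
  }
  pc16 <- vapply(0:65535, popcount, 0L)
  pop <- function(m) pc16[bitwAnd(m, 65535L) + 1L] +
    pc16[bitwShiftR(m, 16L) + 1L]

  n_masks <- bitwShiftL(1L, n)
  totals <- rep(NA_real_, n_masks) # NA = disconnected / not evaluated
  nmemb <- rep(0L, n_masks)
  for (m in seq_len(n_masks - 1L)) {
    low <- bitwAnd(m, -m)
    comp <- low
    repeat {
      grow <- comp
      for (i in seq_len(n)) {
        if (bitwAnd(comp, bitwShiftL(1L, i - 1L)) != 0L) {
          grow <- bitwOr(grow, bitwAnd(adj_mask[i], m))
        }
      }
      if (grow == comp) break
      comp <- grow
    }
    if (comp != m) next
    asz <- pop(m)
    inter <- vapply(sp_mask, function(sm) pop(bitwAnd(sm, m)), 0L)
    sc <- inter / (sp_n + asz - inter)
    memb <- sc >= min_score
    totals[m + 1L] <- sum(sc[memb])
    nmemb[m + 1L] <- sum(memb)
  }
  out <- list()
  for (m in which(!is.na(totals) & nmemb >= min_species) - 1L) {
    tot <- totals[m + 1L]
    is_max <- TRUE
    for (i in seq_len(n)) {
      m2 <- bitwXor(m, bitwShiftL(1L, i - 1L))
      if (m2 == 0L) next
      t2 <- totals[m2 + 1L]
      if (!is.na(t2) && t2 > tot + 1e-12) { is_max <- FALSE; break }
    }
    if (!is_max) next
    cs <- cells[bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L) == 1L]
    sc <- area_scores(sort(cs), raster, min_score)
    out[[length(out) + 1L]] <- structure(
      list(cells = sort(cs), endemic_species = sc, total_score = sum(sc)),
      class = "endemicity_area")
  }
  out
}

#' Search for areas of endemism on a grid
#'
#' A deterministic heuristic in the spirit of grid-based endemicity
#' analysis: candidate areas are seeded from each species' occupied cell
#' set (components bridged across gaps of at most two cells, plus each
#' connected component separately; pairwise species unions are added as
#' seeds when at most 15 species are present), then hill-climbed by adding
#' frontier cells or removing cells (keeping connectivity) while the total
#' endemicity score strictly increases. The score of an area is the sum of
#' the [congruence_score()] of every species scoring at least `min_score`;
#' areas with fewer than `min_species` such members are discarded,
#' identical cell sets are deduplicated, and results are sorted by total
#' score (descending; ties by cell-set order).
#'
#' When the bounding box of all occupied cells holds at most `exact_limit`
#' cells, the search is exact instead: every connected subset of the box
#' (including unoccupied bridge cells) is enumerated and the locally
#' maximal qualifying areas are returned, so the globally best area is
#' guaranteed on such small instances.
#'
#' @param raster A [rasterize()] result.
#' @param grid The [grid_spec()].
#' @param min_score Minimum per-species congruence, default 0.5.
#' @param min_species Minimum endemic members per area, default 2.
#' @param exact_limit Bounding-box cell count up to which the exact
#'   enumeration is used, default 14 (at most 20).
#' @return List of objects of class `endemicity_area`, each with `cells`,
#'   `endemic_species` (named score vector), `total_score`.
#' @export
search_areas <- function(raster, grid, min_score = 0.5, min_species = 2,
                         exact_limit = 14) {
  if (length(raster) == 0L) stop("search_areas: empty raster")
  ex <- exact_search(raster, grid, min_score, min_species, exact_limit)
  if (!is.null(ex)) {
    if (!length(ex)) return(list())
    keys <- vapply(ex, function(a) paste(a$cells, collapse = ","), "")
    ex <- ex[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    return(ex[order(-vapply(ex, `[[`, 0, "total_score"), keys)])
  }
  seeds <- list()
  add_seed <- function(cells) {
    if (length(cells)) seeds[[length(seeds) + 1L]] <<- sort(unique(cells))
  }
  for (sp in names(raster)) {
    cc <- connectify(raster[[sp]], grid)
    for (x in cc) add_seed(x)
    comps <- connected_components(raster[[sp]], grid)
    if (length(comps) > 1L) for (x in comps) add_seed(x)
  }
  if (length(raster) >= 2L && length(raster) <= 15L) {
    nm <- names(raster)
    for (i in seq_along(nm)[-length(nm)]) {
      for (j in (i + 1L):length(nm)) {
        u <- union(raster[[nm[i]]], raster[[nm[j]]])
        for (x in connectify(u, grid)) add_seed(x)
      }
    }
  }
  seeds <- unique(seeds)
  index <- build_cell_index(raster)

  results <- list()
  for (sd in seeds) {
    hc <- hill_climb(sd, raster, grid, min_score, index)
    sc <- area_scores(hc$cells, raster, min_score, index)
    if (length(sc) < min_species) next
    results[[length(results) + 1L]] <- structure(
      list(cells = hc$cells, endemic_species = sc,
           total_score = sum(sc)), class = "endemicity_area")
  }
  if (!length(results)) return(list())
  keys <- vapply(results, function(a) paste(a$cells, collapse = ","), "")
  results <- results[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ord <- order(-vapply(results, `[[`, 0, "total_score"), keys)
  results[ord]
}

#' @export
print.endemicity_area <- function(x, ...) {
  cat(sprintf("<endemicity_area> %d cells, %d endemic species, total score %.3f\n",
              length(x$cells), length(x$endemic_species), x$total_score))
  invisible(x)
}

#' Merge overlapping candidate areas into consensus areas
#'
#' Two areas are linked when they share grid cells and the species overlap
#' `|S1 n S2| / min(|S1|, |S2|)` reaches `share_cutoff`; each connected
#' component of the resulting graph merges to one consensus area (union of
#' cells; the union of species is re-scored against the union of cells and
#' re-filtered at `min_score`/`min_species`).
#'
#' @param areas [search_areas()] output.
#' @param raster The [rasterize()] result the areas were found on.
#' @param share_cutoff Shared-species fraction, default 0.5.
#' @param min_score,min_species As in [search_areas()].
#' @return List of consensus `endemicity_area` objects, sorted by total
#'   score.
#' @export
consensus_areas <- function(areas, raster, share_cutoff = 0.5,
                            min_score = 0.5, min_species = 2) {
  n <- length(areas)
  if (n <= 1L) return(areas)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s1 <- names(areas[[i]]$endemic_species)
      s2 <- names(areas[[j]]$endemic_species)
      shared <- length(intersect(s1, s2)) / min(length(s1), length(s2))
      if (shared >= share_cutoff &&
          length(intersect(areas[[i]]$cells, areas[[j]]$cells)) > 0) {
        link[i, j] <- link[j, i] <- TRUE
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (link[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  for (g in unique(comp)) {
    group <- areas[comp == g]
    cells <- sort(unique(unlist(lapply(group, `[[`, "cells"))))
    sc <- area_scores(cells, raster[unique(unlist(lapply(group, function(a)
      names(a$endemic_species))))], min_score)
    if (length(sc) < min_species) next
    out[[length(out) + 1L]] <- structure(
      list(cells = cells, endemic_species = sc, total_score = sum(sc)),
      class = "endemicity_area")
  }
  ord <- order(-vapply(out, `[[`, 0, "total_score"),
               vapply(out, function(a) paste(a$cells, collapse = ","), ""))
  out[ord]
}

#' Tabulate endemicity areas
#'
#' @param areas List of `endemicity_area`.
#' @return data.frame (area id, species id, score) in the shape of a
#'   per-area endemic species listing.
#' @export
areas_table <- function(areas) {
  if (!length(areas)) {
    return(data.frame(area = integer(0), otu_id = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(areas), function(k) data.frame(
    area = k, otu_id = names(areas[[k]]$endemic_species),
    score = unname(areas[[k]]$endemic_species), stringsAsFactors = FALSE)))
}
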
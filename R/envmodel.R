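#' Moran eigenvector maps from sampling coordinates
#'
#' Builds the great-circle (haversine) distance matrix of the sampling
#' points, truncates it at the longest edge of the minimum spanning tree
#' (larger distances are replaced by four times the truncation threshold,
#' the standard principal-coordinates-of-neighbour-matrices construction),
#' double-centers -0.5 * D^2 and eigen-decomposes. Eigenvectors with
#' positive eigenvalues are returned in decreasing eigenvalue order; their
#' columns are centered and mutually orthogonal, and they describe spatial
#' variation from broad to fine scale.
#'
#' @param coords Two-column matrix or data.frame of (latitude, longitude)
#'   in degrees; at least three distinct points, no exact duplicates.
#' @param truncation Optional distance threshold (m); default the longest
#'   minimum-spanning-tree edge.
#' @return Numeric matrix (rows = points, columns = MEM_1, MEM_2, ...)
#'   with the eigenvalues as attribute `values` and the threshold as
#'   attribute `truncation`.
#' @export
mem_eigenvectors <- function(coords, truncation = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("mem_eigenvectors: coords must have 2 columns (lat, lon)")
  n <- nrow(coords)
  if (n < 3L) stop("mem_eigenvectors: need at least 3 points")
  d <- geosphere::distm(coords[, c(2L, 1L)], fun = geosphere::distHaversine)
  if (any(d[upper.tri(d)] == 0)) {
    stop("mem_eigenvectors: exact duplicate coordinates; deduplicate points first")
  }
  if (is.null(truncation)) truncation <- mst_longest_edge(d)
  w <- d
  w[w > truncation] <- 4 * truncation
  b <- -0.5 * w^2
  cent <- diag(n) - matrix(1 / n, n, n)
  g <- cent %*% b %*% cent
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  if (!any(pos)) stop("mem_eigenvectors: no positive eigenvalues")
  vec <- eig$vectors[, pos, drop = FALSE]
  colnames(vec) <- paste0("MEM_", seq_len(ncol(vec)))
  structure(vec, values = eig$values[pos], truncation = truncation)
}

# Longest edge of the minimum spanning tree of a distance matrix (Prim).
mst_longest_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  longest <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' Adjusted R-squared of a least-squares projection
#'
#' R2 is the explained sum of squares of the projection of (column
#' centered) `Y` on `X` over the total sum of squares, summed over
#' response columns; the adjustment is Ezekiel's
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` the number of
#' linearly independent non-constant predictors. Collinear columns are
#' dropped with a warning.
#'
#' @param Y Response vector or matrix.
#' @param X Predictor matrix (an intercept is always included).
#' @return List with `r2`, `adj_r2`, `rank`.
#' @export
adjusted_r2 <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("adjusted_r2: Y and X row counts differ")
  Xf <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xf)
  p <- qx$rank - 1L # predictors beyond the intercept
  if (qx$rank < ncol(Xf)) {
    warning("adjusted_r2: rank-deficient predictors; collinear columns dropped")
  }
  if (n <= p + 1L) stop("adjusted_r2: need rows > predictors + 1")
  Yc <- sweep(Y, 2L, colMeans(Y))
  tss <- sum(Yc^2)
  if (tss == 0) stop("adjusted_r2: response has zero variance")
  fit <- qr.fitted(qx, Y)
  fitc <- sweep(fit, 2L, colMeans(fit))
  r2 <- sum(fitc^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2 = r2, adj_r2 = adj, rank = p)
}

#' Partition response variation into environmental and spatial fractions
#'
#' Classic two-table variance partitioning on adjusted R2: with
#' `ab = adjR2(Y ~ E)`, `bc = adjR2(Y ~ S)` and `abc = adjR2(Y ~ E + S)`,
#' the pure environmental fraction is `a = abc - bc`, the pure spatial
#' fraction `c = abc - ab`, the shared fraction `b = ab + bc - abc` and
#' the residual `d = 1 - abc`. Significance of the pure fractions is
#' assessed by permuting the rows of `Y` and recomputing them, with the
#' add-one rule `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param Y Response vector/matrix (e.g. log10 abundance).
#' @param E Environmental predictor matrix.
#' @param S Spatial predictor matrix (e.g. [mem_eigenvectors()]).
#' @param n_perm Number of permutations (>= 1), default 1000.
#' @param seed Integer seed for the permutations.
#' @return Object of class `varpart_result`: fractions `a`, `b`, `c`, `d`,
#'   the three adjusted R2 values, and permutation p-values `p_env`,
#'   `p_space`.
#' @export
variance_partition <- function(Y, E, S, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("variance_partition: n_perm must be >= 1")
  Y <- as.matrix(Y); E <- as.matrix(E); S <- as.matrix(S)
  if (nrow(E) != nrow(Y) || nrow(S) != nrow(Y)) {
    stop("variance_partition: row counts of Y, E, S must agree")
  }
  # The three predictor sets are fixed across permutations: factor once,
  # then each (permuted) response costs only two triangular projections.
  n <- nrow(Y)
  qrs <- lapply(list(E = E, S = S, ES = cbind(E, S)), function(X) {
    qx <- qr(cbind(1, X))
    list(qx = qx, p = qx$rank - 1L)
  })
  if (qrs$ES$p < ncol(E) + ncol(S)) {
    warning("variance_partition: rank-deficient predictors; collinear columns dropped")
  }
  adj_of <- function(q, Yp, tss) {
    fit <- qr.fitted(q$qx, Yp)
    fitc <- sweep(fit, 2L, colMeans(fit))
    r2 <- sum(fitc^2) / tss
    1 - (1 - r2) * (n - 1) / (n - q$p - 1)
  }
  frac <- function(Yp) {
    Yc <- sweep(Yp, 2L, colMeans(Yp))
    tss <- sum(Yc^2)
    ab <- adj_of(qrs$E, Yp, tss)
    bc <- adj_of(qrs$S, Yp, tss)
    abc <- adj_of(qrs$ES, Yp, tss)
    c(a = abc - bc, b = ab + bc - abc, c = abc - ab, d = 1 - abc,
      ab = ab, bc = bc, abc = abc)
  }
  obs <- suppressWarnings(frac(Y))
  perm <- with_substream(seed, "varpart_perm", {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample(nrow(Y))
      f <- suppressWarnings(frac(Y[idx, , drop = FALSE]))
      c(f[["a"]], f[["c"]])
    }, c(0, 0))
  })
  structure(list(
    a = unname(obs[["a"]]), b = unname(obs[["b"]]), c = unname(obs[["c"]]),
    d = unname(obs[["d"]]),
    adj_r2_env = unname(obs[["ab"]]), adj_r2_space = unname(obs[["bc"]]),
    adj_r2_full = unname(obs[["abc"]]),
    p_env = (1 + sum(perm[1L, ] >= obs[["a"]])) / (1 + n_perm),
    p_space = (1 + sum(perm[2L, ] >= obs[["c"]])) / (1 + n_perm),
    n_perm = n_perm), class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("<varpart_result> adjusted R2 fractions\n")
  cat(sprintf("  pure environment (a): %6.3f  (p = %.4g)\n", x$a, x$p_env))
  cat(sprintf("  shared           (b): %6.3f\n", x$b))
  cat(sprintf("  pure space       (c): %6.3f  (p = %.4g)\n", x$c, x$p_space))
  cat(sprintf("  residual         (d): %6.3f\n", x$d))
  invisible(x)
}

#' Design matrix for the global abundance model
#'
#' Drops zero-abundance records (count reported), log10-transforms
#' abundance, standardizes the predictors (latitude, MAT, precipitation,
#' pH, SOC) to mean 0 / sd 1, and adds a quadratic latitude term (squared
#' standardized latitude, itself standardized). Zero-variance predictor
#' columns are dropped with a warning. Grouping labels (study, primer,
#' sample type) are carried through for mixed-model fitting.
#'
#' @param records Occurrence data.frame with columns `abundance`,
#'   `latitude`, `mat`, `precipitation`, `ph`, `soc`, and optionally
#'   `study_id`, `primer`, `sample_type`.
#' @param min_rows Minimum usable rows, default 10.
#' @return List of class `design_matrix`: `response` (log10 abundance),
#'   `predictors` (standardized matrix incl. `latitude_sq`), `groups`
#'   (data.frame of grouping labels), `n_dropped` (zero-abundance rows).
#' @export
prepare_design <- function(records, min_rows = 10) {
  need <- c("abundance", "latitude", "mat", "precipitation", "ph", "soc")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("prepare_design: missing columns: ",
                         paste(miss, collapse = ", "))
  keep <- records$abundance > 0
  n_dropped <- sum(!keep)
  if (n_dropped) message("prepare_design: dropped ", n_dropped,
                         " record(s) with zero abundance")
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < min_rows) {
    stop("prepare_design: fewer than ", min_rows, " usable rows")
  }
  std <- function(v, name) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warning("prepare_design: predictor `", name,
              "` has zero variance and was dropped")
      return(NULL)
    }
    (v - mean(v)) / s
  }
  cols <- list(latitude = std(rec$latitude, "latitude"))
  if (!is.null(cols$latitude)) {
    cols$latitude_sq <- std(cols$latitude^2, "latitude_sq")
  }
  for (v in c("mat", "precipitation", "ph", "soc")) {
    cols[[v]] <- std(rec[[v]], v)
  }
  cols <- Filter(Negate(is.null), cols)
  pred <- do.call(cbind, cols)
  groups <- rec[, intersect(c("study_id", "primer", "sample_type"),
                            names(rec)), drop = FALSE]
  structure(list(response = log10(rec$abundance), predictors = pred,
                 groups = groups, n_dropped = n_dropped),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d rows, predictors: %s\n",
              length(x$response), paste(colnames(x$predictors), collapse = ", ")))
  invisible(x)
}
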
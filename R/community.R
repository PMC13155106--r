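#' Rank-abundance quartiles of an OTU table
#'
#' Sorts OTUs by total reads (descending, ties broken by id ascending) and
#' splits the ranked curve into four contiguous groups of (near-)equal OTU
#' count: Q1 holds the most abundant quarter. When quartile sizes cannot be
#' equal, the extra OTUs go to the earlier quartiles, so sizes differ by at
#' most one.
#'
#' @param otus An [cluster_asvs()] `otu_set` (or any object with a `counts`
#'   matrix rownamed by OTU id).
#' @param known Optional named logical vector (OTU id -> known status) used
#'   to report the per-quartile fraction of known OTUs.
#' @return Object of class `quartile_assignment`: list with `assignment`
#'   (named factor Q1..Q4), `summary` (per-quartile data.frame: n OTUs,
#'   read share, known fraction).
#' @export
rank_quartiles <- function(otus, known = NULL) {
  counts <- if (inherits(otus, "otu_set")) otus$counts else as.matrix(otus)
  totals <- rowSums(counts)
  if (length(totals) < 4L) stop("rank_quartiles: need at least 4 OTUs")
  if (all(totals <= 0)) stop("rank_quartiles: OTU table has no reads")
  ids <- rownames(counts)
  ord <- order(-totals, ids)
  n <- length(ord)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, extra), rep(0L, 4L - extra))
  q <- factor(rep(paste0("Q", 1:4), times = sizes),
              levels = paste0("Q", 1:4))
  assignment <- setNames(q, ids[ord])[ids]
  names(assignment) <- ids

  grand <- sum(totals)
  share <- tapply(totals[ids][order(assignment)], sort(assignment), sum) / grand
  summ <- data.frame(
    quartile = paste0("Q", 1:4),
    n_otus = as.integer(sizes),
    read_share = as.numeric(share[paste0("Q", 1:4)]),
    stringsAsFactors = FALSE)
  if (!is.null(known)) {
    kf <- vapply(paste0("Q", 1:4), function(qq) {
      inq <- names(assignment)[assignment == qq]
      mean(known[inq], na.rm = TRUE)
    }, 0)
    summ$known_fraction <- unname(kf)
  }
  structure(list(assignment = assignment, summary = summ),
            class = "quartile_assignment")
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat("<quartile_assignment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pielou's evenness of a composition
#'
#' J = H / ln(S) where H is the Shannon entropy of the relative abundances
#' (renormalized to sum one) and S the number of categories with positive
#' abundance. Used at the taxonomic-order level on read relative abundance.
#'
#' @param abundances Nonnegative numeric vector (e.g. order -> relative read
#'   abundance); at least two positive entries.
#' @return Evenness in \[0, 1\]; 1 for a uniform composition.
#' @export
pielou_evenness <- function(abundances) {
  p <- abundances[abundances > 0]
  s <- length(p)
  if (s < 2L) stop("pielou_evenness: need at least 2 categories with positive abundance")
  p <- p / sum(p)
  -sum(p * log(p)) / log(s)
}

sample_relative_abundance <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/")
}

#' Select plant-associated OTUs
#'
#' An OTU is plant-associated when (a) its relative abundance exceeds
#' `ra_min` in at least one root sample, and (b) in at least one
#' (plant species, site) stratum it is detected (>= 1 read) in at least
#' `prevalence_min` of that stratum's root individuals. The prevalence
#' clause carries no abundance floor; the floor applies to clause (a)
#' only. Strata with zero root individuals are excluded from evaluation.
#'
#' @param otus An `otu_set` (or OTU x sample count matrix).
#' @param metadata Sample metadata data.frame with columns `sample_id`,
#'   `site`, `plant_species`, `sample_type`, `individual`.
#' @param ra_min Relative-abundance floor for clause (a); default 1e-4
#'   (i.e. 0.01%), applied strictly (`>`).
#' @param prevalence_min Minimum fraction of root individuals per stratum;
#'   default 0.5, applied inclusively (`>=`).
#' @return Character vector of selected OTU ids.
#' @export
select_plant_associated <- function(otus, metadata, ra_min = 0.0001,
                                    prevalence_min = 0.5) {
  counts <- if (inherits(otus, "otu_set")) otus$counts else as.matrix(otus)
  md <- check_metadata(metadata, colnames(counts))
  root_md <- md[md$sample_type == "root", , drop = FALSE]
  if (nrow(root_md) == 0L) return(character(0))
  root_counts <- counts[, root_md$sample_id, drop = FALSE]

  ra <- sample_relative_abundance(root_counts)
  cond_a <- apply(ra, 1L, max) > ra_min

  stratum <- interaction(root_md$plant_species, root_md$site, drop = TRUE)
  cond_b <- rep(FALSE, nrow(counts))
  for (st in levels(stratum)) {
    in_st <- stratum == st
    inds <- unique(root_md$individual[in_st])
    if (length(inds) == 0L) next
    detected <- root_counts[, in_st, drop = FALSE] > 0
    # one column per individual (root samples are per-individual)
    prev <- rowSums(detected) / length(inds)
    cond_b <- cond_b | (prev >= prevalence_min)
  }
  rownames(counts)[cond_a & cond_b]
}

#' Select non-plant-associated OTUs
#'
#' All OTUs outside the plant-associated set whose relative abundance
#' exceeds `ra_min` in at least one bulk-soil sample. The two selections
#' are disjoint by construction.
#'
#' @inheritParams select_plant_associated
#' @param plant_set Result of [select_plant_associated()].
#' @return Character vector of selected OTU ids.
#' @export
select_non_plant_associated <- function(otus, metadata, plant_set,
                                        ra_min = 0.0001) {
  counts <- if (inherits(otus, "otu_set")) otus$counts else as.matrix(otus)
  md <- check_metadata(metadata, colnames(counts))
  soil_md <- md[md$sample_type == "soil", , drop = FALSE]
  if (nrow(soil_md) == 0L) return(character(0))
  ra <- sample_relative_abundance(counts[, soil_md$sample_id, drop = FALSE])
  hit <- apply(ra, 1L, max) > ra_min
  setdiff(rownames(counts)[hit], plant_set)
}

check_metadata <- function(metadata, sample_ids) {
  need <- c("sample_id", "site", "plant_species", "sample_type", "individual")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (!all(sample_ids %in% metadata$sample_id)) {
    stop("metadata does not cover all samples in the OTU table")
  }
  key <- with(metadata, paste(site, plant_species, individual, sample_type))
  if (anyDuplicated(key)) stop("metadata rows are not unique over (site, plant_species, individual, sample_type)")
  metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
}

#' Order-level composition of an OTU table
#'
#' Sums read counts by taxonomic order and returns relative abundances,
#' the composition [pielou_evenness()] is computed on.
#'
#' @param counts OTU x sample count matrix (or `otu_set`).
#' @param orders Named character vector OTU id -> order (NA allowed,
#'   grouped as "unknown_order").
#' @return Named numeric vector of order relative read abundances.
#' @export
order_composition <- function(counts, orders) {
  if (inherits(counts, "otu_set")) counts <- counts$counts
  totals <- rowSums(counts)
  o <- orders[rownames(counts)]
  o[is.na(o)] <- "unknown_order"
  ab <- tapply(totals, o, sum)
  ab / sum(ab)
}
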
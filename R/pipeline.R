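#' Run the full island-biogeography pipeline
#'
#' Orchestrates the stages end to end on a synthetic study:
#' simulate -> cluster -> filter -> quartiles -> categorize -> match ->
#' biogeo -> haplonet -> endemism -> varpart. Any stage after clustering
#' can be skipped; later stages depending on a skipped one are skipped
#' too. Every analysis threshold surfaces as an argument with its
#' conventional default (0.97 identity, 0.005% rare-OTU floor, 0.01%
#' relative abundance, 50% prevalence and consensus cut-offs, 0.9
#' dominance, 0.5 congruence).
#'
#' @param config A [simulation_config()] (its `seed` drives every stage).
#' @param stages Character vector of stages to run.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as TSV/JSON and md5 checksums recorded in the manifest.
#' @param identity_threshold OTU clustering / matching identity threshold.
#' @param rare_min_fraction Global rare-OTU floor.
#' @param ra_min,prevalence_min Plant-associated selection thresholds.
#' @param grid_size Endemicity grid cell size (degrees).
#' @param min_score,min_species,share_cutoff Endemicity-area parameters.
#' @param n_perm Varpart permutations.
#' @param n_mem Number of broad-scale Moran eigenvectors used as spatial
#'   predictors.
#' @param varpart_max_records Record cap for the varpart stage (seeded
#'   subsample keeps the eigen-decomposition tractable).
#' @param len_ratio_min Length-ratio alignment prefilter.
#' @return Object of class `mycogeo_run`: a manifest (counts, per-stage
#'   outputs, checksums) with the stage results attached.
#' @export
run_pipeline <- function(config = simulation_config(),
                         stages = c("simulate", "cluster", "filter",
                                    "quartiles", "categorize", "match",
                                    "biogeo", "haplonet", "endemism",
                                    "varpart"),
                         out_dir = NULL,
                         identity_threshold = 0.97,
                         rare_min_fraction = 0.00005,
                         ra_min = 0.0001, prevalence_min = 0.5,
                         grid_size = 10, min_score = 0.5, min_species = 2,
                         share_cutoff = 0.5,
                         n_perm = 1000, n_mem = 120,
                         varpart_max_records = 1500,
                         len_ratio_min = 0.9) {
  stopifnot(inherits(config, "simulation_config"))
  t0 <- Sys.time()
  log_stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  res <- list()
  counts <- list()

  log_stage("simulate")
  res$pool <- simulate_reference_pool(config)
  res$island <- simulate_island_dataset(res$pool, config)
  counts$n_asvs <- length(res$island$asvs$ids)
  counts$n_samples <- nrow(res$island$metadata)

  if (!"cluster" %in% stages) stop("run_pipeline: the cluster stage cannot be skipped")
  log_stage("cluster")
  res$otus <- cluster_asvs(res$island$asvs, threshold = identity_threshold,
                           len_ratio_min = len_ratio_min)
  counts$n_otus_raw <- nrow(res$otus$otu)

  if ("filter" %in% stages) {
    log_stage("filter")
    res$otus <- filter_rare(res$otus, min_fraction = rare_min_fraction)
  }
  counts$n_otus <- nrow(res$otus$otu)

  if ("match" %in% stages) {
    log_stage("match")
    res$matches <- match_otus(res$otus, res$pool,
                              threshold = identity_threshold,
                              len_ratio_min = len_ratio_min)
    counts$n_known <- sum(res$matches$status == "known")
    counts$known_fraction <- counts$n_known / counts$n_otus
  }

  if ("quartiles" %in% stages) {
    log_stage("quartiles")
    known <- NULL
    if (!is.null(res$matches)) {
      known <- setNames(res$matches$status == "known", res$matches$otu_id)
    }
    res$quartiles <- rank_quartiles(res$otus, known = known)
    # per-quartile order-level evenness (taxonomy of matched references)
    if (!is.null(res$matches)) {
      orders <- setNames(
        res$pool$ref$order[match(res$matches$best_ref, res$pool$ref$id)],
        res$matches$otu_id)
      orders[res$matches$status != "known"] <- NA
      ev <- vapply(paste0("Q", 1:4), function(q) {
        ids <- names(res$quartiles$assignment)[res$quartiles$assignment == q]
        comp <- order_composition(res$otus$counts[ids, , drop = FALSE],
                                  orders)
        if (length(comp[comp > 0]) < 2L) NA_real_ else pielou_evenness(comp)
      }, 0)
      res$quartiles$summary$order_evenness <- unname(ev)
    }
  }

  if ("categorize" %in% stages) {
    log_stage("categorize")
    res$plant_set <- select_plant_associated(res$otus, res$island$metadata,
                                             ra_min = ra_min,
                                             prevalence_min = prevalence_min)
    res$non_plant_set <- select_non_plant_associated(
      res$otus, res$island$metadata, res$plant_set, ra_min = ra_min)
    counts$n_plant_associated <- length(res$plant_set)
    counts$n_non_plant_associated <- length(res$non_plant_set)
  }

  occ <- NULL
  if (!is.null(res$matches)) {
    keep <- res$matches$status == "known" & res$matches$in_occurrence_pool
    occ_list <- lapply(res$matches$otu_id[keep], occurrences_for,
                       matches = res$matches, pool = res$pool)
    occ <- do.call(rbind, occ_list)
    res$occurrences <- occ
  }

  if ("biogeo" %in% stages && !is.null(occ) && nrow(occ)) {
    log_stage("biogeo")
    res$biogeo <- geo_classification(occ)
  }

  if ("haplonet" %in% stages && !is.null(res$matches)) {
    log_stage("haplonet")
    res$networks <- haplotype_networks(res$otus, res$matches, res$pool)
    summ <- attr(res$networks, "summary")
    if (!is.null(summ)) {
      counts$n_networks <- nrow(summ)
      counts$n_private <- sum(summ$n_private > 0)
      counts$n_private_dominant <- sum(summ$dominant_private)
    }
  }

  if ("endemism" %in% stages && !is.null(occ) && nrow(occ)) {
    log_stage("endemism")
    grid <- grid_spec(grid_size)
    raster <- rasterize(occ, grid)
    cand <- search_areas(raster, grid, min_score = min_score,
                         min_species = min_species)
    res$areas <- consensus_areas(cand, raster, share_cutoff = share_cutoff,
                                 min_score = min_score,
                                 min_species = min_species)
    res$grid <- grid
    counts$n_consensus_areas <- length(res$areas)
  }

  if ("varpart" %in% stages && !is.null(occ) && nrow(occ) >= 30) {
    log_stage("varpart")
    vp_occ <- occ
    if (nrow(vp_occ) > varpart_max_records) {
      idx <- with_substream(config$seed, "varpart_subsample",
                            sample(nrow(vp_occ), varpart_max_records))
      vp_occ <- vp_occ[idx, , drop = FALSE]
    }
    vp_occ <- vp_occ[!duplicated(vp_occ[, c("latitude", "longitude")]), ,
                     drop = FALSE]
    des <- prepare_design(vp_occ)
    E <- des$predictors[, intersect(c("mat", "precipitation", "ph", "soc"),
                                    colnames(des$predictors)), drop = FALSE]
    S <- mem_eigenvectors(vp_occ[, c("latitude", "longitude")])
    S <- S[, seq_len(min(n_mem, ncol(S))), drop = FALSE]
    res$varpart <- variance_partition(des$response, E, S, n_perm = n_perm,
                                      seed = substream_seed(config$seed, "varpart"))
    res$design <- des
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    stages_run = stages,
    counts = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    manifest$files <- write_run_outputs(res, manifest, out_dir)
  }
  structure(c(manifest, list(results = res)), class = "mycogeo_run")
}

write_run_outputs <- function(res, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  put(data.frame(otu_id = res$otus$otu$id, res$otus$counts,
                 check.names = FALSE), "otu_table.tsv")
  put(data.frame(asv_id = names(res$otus$membership),
                 otu_id = unname(res$otus$membership)), "otu_membership.tsv")
  if (!is.null(res$matches)) put(res$matches, "matches.tsv")
  if (!is.null(res$quartiles)) put(res$quartiles$summary, "quartiles.tsv")
  if (!is.null(res$biogeo)) put(res$biogeo, "biogeo.tsv")
  if (!is.null(res$networks)) put(attr(res$networks, "summary"),
                                  "haplonet_summary.tsv")
  if (!is.null(res$areas)) put(areas_table(res$areas), "endemicity_areas.tsv")
  if (!is.null(res$varpart)) {
    p <- file.path(out_dir, "varpart.json")
    jsonlite::write_json(unclass(res$varpart)[c("a", "b", "c", "d",
                                                "p_env", "p_space")],
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest[c("seed", "config", "stages_run", "counts")],
                       p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  sums <- tools::md5sum(paths)
  data.frame(file = basename(names(sums)), md5 = unname(sums),
             stringsAsFactors = FALSE)
}

#' @export
print.mycogeo_run <- function(x, ...) {
  cat("<mycogeo_run>\n")
  cat("  stages:", paste(x$stages_run, collapse = " -> "), "\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.numeric(v) && v != round(v)) sprintf("%.4f", v) else v))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
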
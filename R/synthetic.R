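#' Configuration for the synthetic island metabarcoding study
#'
#' Parameterizes the paired generator of (i) a global reference pool
#' (annotated sequences, haplotypes and georeferenced occurrence records
#' with environmental covariates) and (ii) an island ASV dataset sampled
#' under the field design of the emulated study: three plant species
#' (two native, one introduced) sampled at four fellfield sites along a
#' two-point altitudinal transect, each individual contributing one root
#' and one paired bulk-soil sample. With the default `n_samples = 5`
#' replicates per (site x species x altitude) stratum the design yields 70
#' individuals, i.e. 140 samples.
#'
#' All randomness flows from `seed` through per-unit substreams, so an
#' identical seed and configuration reproduce byte-identical outputs.
#'
#' @param n_otus Number of island OTUs to plant.
#' @param n_asvs_per_otu Mean ASV count per OTU (geometric draw, >= 1).
#' @param known_fraction Fraction of island OTUs with a reference-pool
#'   match at >= 97% identity.
#' @param private_fraction Fraction of known OTUs carrying at least one
#'   island-private ASV (an ASV absent from the global haplotype set).
#' @param private_dominant_fraction Fraction of those private OTUs whose
#'   private ASVs carry more than 90% of the OTU's island reads.
#' @param endemicity_zones List of planted endemicity zones, each a list
#'   with `lat_min`, `lat_max`, `lon_min`, `lon_max`, `n_zone_otus`. Zone
#'   OTUs draw at least `zone_containment` of their occurrence points
#'   inside the zone's bounding box.
#' @param latitudinal_class_mix Named probability vector over
#'   [GEO_CLASSES], used to assign non-zone reference OTUs a latitudinal
#'   occurrence distribution.
#' @param n_samples Replicates per (site x species x altitude) stratum.
#' @param reads_per_sample Sequencing depth per sample (the study design
#'   does not fix one; 50,000 is a typical ITS2 soil library size).
#' @param rank_decay Geometric rank-abundance decay of OTU read shares.
#' @param seq_length_range Min/max reference sequence length (nt).
#' @param mutation_rate Per-site substitution rate used when deriving ASVs
#'   and haplotypes from a source sequence (no indels by default).
#' @param indel_rate Optional per-site indel rate (default 0, keeping
#'   within-OTU distances well-defined Hamming distances).
#' @param n_occurrences_per_otu Mean occurrence records per reference OTU.
#' @param zone_containment Fraction of a zone OTU's points inside its box.
#' @param annotation_only_fraction Fraction of reference OTUs present in
#'   the annotation pool only (taxonomy, no occurrence records).
#' @param plant_fraction Fraction of island OTUs planted as
#'   plant-associated; they are taken from the top abundance ranks so that
#'   a few percent of the richness carries most root reads.
#' @param root_leak Relative weight of root samples for soil OTUs (0 gives
#'   a noiseless root/soil separation).
#' @param n_global_haplotypes Mean global haplotypes per reference OTU.
#' @param env_noise_sd Named vector of independent noise s.d. for the four
#'   environmental covariates (`mat`, `precipitation`, `ph`, `soc`).
#' @param seed Integer master seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_otus = 500,
                              n_asvs_per_otu = 2,
                              known_fraction = 0.65,
                              private_fraction = 0.18,
                              private_dominant_fraction = 0.55,
                              endemicity_zones = list(),
                              latitudinal_class_mix = c(
                                cosmopolitan = 0.10, arctic = 0.15,
                                antarctic = 0.10, northern_hemisphere = 0.20,
                                southern_hemisphere = 0.10, low_latitudes = 0.25,
                                other = 0.10),
                              n_samples = 5,
                              reads_per_sample = 50000,
                              rank_decay = 0.98,
                              seq_length_range = c(150, 180),
                              mutation_rate = 0.01,
                              indel_rate = 0,
                              n_occurrences_per_otu = 30,
                              zone_containment = 0.95,
                              annotation_only_fraction = 0.1,
                              plant_fraction = 0.03,
                              root_leak = 0.02,
                              n_global_haplotypes = 3,
                              env_noise_sd = c(mat = 1, precipitation = 100,
                                               ph = 0.2, soc = 0.5),
                              seed = 1) {
  cfg <- list(
    n_otus = n_otus, n_asvs_per_otu = n_asvs_per_otu,
    known_fraction = known_fraction, private_fraction = private_fraction,
    private_dominant_fraction = private_dominant_fraction,
    endemicity_zones = endemicity_zones,
    latitudinal_class_mix = latitudinal_class_mix,
    n_samples = n_samples, reads_per_sample = reads_per_sample,
    rank_decay = rank_decay, seq_length_range = seq_length_range,
    mutation_rate = mutation_rate, indel_rate = indel_rate,
    n_occurrences_per_otu = n_occurrences_per_otu,
    zone_containment = zone_containment,
    annotation_only_fraction = annotation_only_fraction,
    plant_fraction = plant_fraction, root_leak = root_leak,
    n_global_haplotypes = n_global_haplotypes,
    env_noise_sd = env_noise_sd, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid configuration: `", field, "` must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  chk_posint <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min || v != round(v)) {
      stop("invalid configuration: `", field, "` must be an integer >= ", min,
           call. = FALSE)
    }
  }
  chk_posint("n_otus", min = 0)
  chk_posint("n_samples")
  chk_posint("reads_per_sample")
  if (cfg$n_asvs_per_otu < 1) {
    stop("invalid configuration: `n_asvs_per_otu` must be >= 1", call. = FALSE)
  }
  for (f in c("known_fraction", "private_fraction", "private_dominant_fraction",
              "zone_containment", "annotation_only_fraction", "plant_fraction",
              "root_leak")) chk_frac(f)
  mix <- cfg$latitudinal_class_mix
  if (is.null(names(mix)) || !setequal(names(mix), GEO_CLASSES)) {
    stop("invalid configuration: `latitudinal_class_mix` must be named by the ",
         "seven biogeographic classes", call. = FALSE)
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("invalid configuration: `latitudinal_class_mix` must be a probability ",
         "vector summing to 1", call. = FALSE)
  }
  if (cfg$rank_decay <= 0 || cfg$rank_decay > 1) {
    stop("invalid configuration: `rank_decay` must be in (0, 1]", call. = FALSE)
  }
  for (z in cfg$endemicity_zones) {
    need <- c("lat_min", "lat_max", "lon_min", "lon_max", "n_zone_otus")
    if (!all(need %in% names(z))) {
      stop("invalid configuration: `endemicity_zones` entries need fields ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (z$lat_min >= z$lat_max || z$lat_min < -90 || z$lat_max > 90 ||
        z$lon_min >= z$lon_max || z$lon_min < -180 || z$lon_max > 180) {
      stop("invalid configuration: `endemicity_zones` bounding box is invalid",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d OTUs (known fraction %.2f), ",
                     "%d zones, seed %d\n"),
              x$n_otus, x$known_fraction, length(x$endemicity_zones),
              as.integer(x$seed)))
  invisible(x)
}

# ---- low-level sequence helpers ----

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Per-site substitutions at `n_subs` distinct positions (and optional indels).
mutate_seq <- function(seq, n_subs, indel_rate = 0) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (n_subs > 0) {
    pos <- sample(length(v), min(n_subs, length(v)))
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
  }
  if (indel_rate > 0) {
    n_indel <- rbinom(1L, length(v), indel_rate)
    for (k in seq_len(n_indel)) {
      p <- sample(length(v), 1L)
      if (runif(1) < 0.5 && length(v) > 2L) v <- v[-p]
      else v <- append(v, sample(bases, 1L), after = p)
    }
  }
  paste(v, collapse = "")
}

# ---- environmental mean field ----

#' Environmental covariates from a location
#'
#' Deterministic latitudinal mean structure plus optional independent
#' noise: mean annual temperature decreases strictly with absolute
#' latitude, precipitation peaks near the equator, and soil pH and soil
#' organic carbon increase towards the poles (the covariate structure the
#' downstream abundance analyses assume). Longitude does not enter the
#' mean field.
#'
#' @param lat,lon Coordinate vectors (degrees); latitude in \[-90, 90\].
#' @param noise_sd Named vector (`mat`, `precipitation`, `ph`, `soc`) of
#'   noise standard deviations, or a single value recycled; 0 disables.
#' @param seed Optional integer seed for the noise draw.
#' @return data.frame with columns `mat` (deg C), `precipitation` (mm/yr),
#'   `ph`, `soc` (%).
#' @export
env_from_location <- function(lat, lon, noise_sd = 0, seed = NULL) {
  if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
    stop("env_from_location: latitude must lie in [-90, 90]")
  }
  a <- abs(lat)
  mu <- data.frame(
    mat = 28 - 0.55 * a,
    precipitation = 250 + 1800 * exp(-((a - 5) / 30)^2),
    ph = 5.2 + 0.018 * a,
    soc = 1.5 + 9 * (a / 90)^1.5
  )
  sds <- rep(0, 4)
  names(sds) <- names(mu)
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    sds[] <- noise_sd
  } else {
    sds[names(noise_sd)] <- noise_sd
  }
  if (any(sds > 0)) {
    draw <- function() {
      for (j in seq_along(mu)) {
        if (sds[j] > 0) mu[[j]] <<- mu[[j]] + rnorm(length(lat), 0, sds[j])
      }
    }
    if (is.null(seed)) draw() else with_substream(seed, "env", draw())
  }
  mu$precipitation <- pmax(mu$precipitation, 10)
  mu$soc <- pmax(mu$soc, 0.05)
  mu
}

biome_from_lat <- function(lat) {
  n <- length(lat)
  out <- character(n)
  a <- abs(lat)
  for (i in seq_len(n)) {
    out[i] <- if (lat[i] <= -60) "antarctic_no_vegetation"
    else if (a[i] >= 60) sample(c("tundra", "boreal_forest"), 1, prob = c(0.8, 0.2))
    else if (a[i] >= 50) sample(c("boreal_forest", "tundra", "wetland"), 1,
                                prob = c(0.7, 0.2, 0.1))
    else if (a[i] >= 35) sample(c("temperate_forest", "temperate_grassland",
                                  "montane"), 1, prob = c(0.5, 0.35, 0.15))
    else if (a[i] >= 23) sample(c("mediterranean", "desert", "montane"), 1,
                                prob = c(0.5, 0.35, 0.15))
    else sample(c("tropical_forest", "tropical_savanna", "wetland"), 1,
                prob = c(0.55, 0.35, 0.1))
  }
  out
}

# Latitude draws consistent with each biogeographic class definition.
lat_for_class <- function(class, n) {
  switch(class,
    cosmopolitan = {
      base <- runif(n, -65, 70)
      if (n >= 2L) {
        base[1L] <- runif(1, -65, -35)
        base[2L] <- runif(1, 35, 70)
      }
      base
    },
    arctic = runif(n, 60, 85),
    antarctic = runif(n, -85, -52),
    northern_hemisphere = runif(n, 40, 60),
    southern_hemisphere = runif(n, -50, -40),
    low_latitudes = runif(n, -40, 40),
    other = {
      base <- runif(n, -40, 8)
      base[1L] <- runif(1, -48, -42) # spans hemispheres, range <= 60
      base
    },
    stop("unknown latitudinal class: ", class))
}

FUNGAL_ORDERS <- c("Helotiales", "Pleosporales", "Hypocreales", "Agaricales",
                   "Mortierellales", "Tremellales", "Glomerales", "Russulales",
                   "Thelephorales", "Chaetothyriales", "Eurotiales",
                   "Capnodiales")
ORDER_PHYLUM <- c(
  Helotiales = "Ascomycota", Pleosporales = "Ascomycota",
  Hypocreales = "Ascomycota", Agaricales = "Basidiomycota",
  Mortierellales = "Mortierellomycota", Tremellales = "Basidiomycota",
  Glomerales = "Glomeromycota", Russulales = "Basidiomycota",
  Thelephorales = "Basidiomycota", Chaetothyriales = "Ascomycota",
  Eurotiales = "Ascomycota", Capnodiales = "Ascomycota")

# ---- reference pool ----

#' Simulate the global reference pool
#'
#' Generates one reference OTU per island "known" OTU the paired island
#' simulation will plant (`round(known_fraction * n_otus)` of them): an
#' annotated sequence, a small set of global haplotypes derived from it by
#' substitution, and a set of georeferenced occurrence records whose
#' latitudes follow the OTU's assigned biogeographic class (or planted
#' endemicity zone), with environmental covariates from
#' [env_from_location()] plus independent noise and a per-record abundance
#' combining a latitudinal trend, environmental effects (negative MAT,
#' positive SOC and pH) and a smooth spatial field.
#'
#' @param config A [simulation_config].
#' @return Object of class `reference_pool`: list with `ref` (per-reference
#'   data.frame incl. taxonomy, class, zone, `in_occurrence`), `sequences`
#'   (named character), `haplotypes` (data.frame `ref_id`, `hap_id`,
#'   `sequence`, `n_records`), `occurrences` (data.frame of occurrence
#'   records keyed by `otu_id`).
#' @export
simulate_reference_pool <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_config(config)
  n_known <- round(config$known_fraction * config$n_otus)
  zones <- config$endemicity_zones
  n_zone <- if (length(zones)) sum(vapply(zones, `[[`, 0, "n_zone_otus")) else 0
  if (n_zone > n_known) {
    stop("invalid configuration: `endemicity_zones` request more OTUs (",
         n_zone, ") than there are known OTUs (", n_known, ")")
  }
  empty_occ <- data.frame(
    otu_id = character(0), latitude = numeric(0), longitude = numeric(0),
    mat = numeric(0), precipitation = numeric(0), ph = numeric(0),
    soc = numeric(0), abundance = numeric(0), study_id = character(0),
    primer = character(0), sample_type = character(0), biome = character(0),
    stringsAsFactors = FALSE)
  if (n_known == 0L) {
    return(structure(list(
      ref = data.frame(id = character(0), class = character(0),
                       zone = integer(0), in_occurrence = logical(0),
                       stringsAsFactors = FALSE),
      sequences = character(0),
      haplotypes = data.frame(ref_id = character(0), hap_id = character(0),
                              sequence = character(0), n_records = integer(0),
                              stringsAsFactors = FALSE),
      occurrences = empty_occ, config = config), class = "reference_pool"))
  }
  ids <- sprintf("REF_%04d", seq_len(n_known))

  # class / zone assignment
  zone_of <- rep(NA_integer_, n_known)
  if (n_zone > 0) {
    k <- 1L
    for (zi in seq_along(zones)) {
      nz <- zones[[zi]]$n_zone_otus
      zone_of[k:(k + nz - 1L)] <- zi
      k <- k + nz
    }
  }
  class_of <- with_substream(config$seed, "pool_classes", {
    cls <- sample(GEO_CLASSES, n_known, replace = TRUE,
                  prob = config$latitudinal_class_mix[GEO_CLASSES])
    cls[!is.na(zone_of)] <- "zone"
    cls
  })
  in_occ <- with_substream(config$seed, "pool_in_occ", {
    v <- runif(n_known) >= config$annotation_only_fraction
    v[!is.na(zone_of)] <- TRUE
    v
  })

  # sequences + haplotypes
  seqs <- character(n_known)
  hap_rows <- vector("list", n_known)
  for (i in seq_len(n_known)) {
    with_substream(config$seed, paste0("pool_seq_", i), {
      len <- sample(config$seq_length_range[1]:config$seq_length_range[2], 1L)
      s <- rand_dna(len)
      seqs[i] <- s
      n_hap <- 1L + rpois(1L, max(config$n_global_haplotypes - 1, 0))
      haps <- s
      max_sub <- max(1L, floor(0.015 * len))
      while (length(haps) < n_hap) {
        cand <- mutate_seq(s, sample(max_sub, 1L))
        if (!cand %in% haps) haps <- c(haps, cand)
      }
      recs <- as.vector(rmultinom(1L, max(n_hap, 4L) * 3L,
                                  prob = 0.55^seq_along(haps)))
      recs <- pmax(recs, 1L)
      hap_rows[[i]] <- data.frame(
        ref_id = ids[i],
        hap_id = sprintf("%s_H%02d", ids[i], seq_along(haps)),
        sequence = haps, n_records = recs, stringsAsFactors = FALSE)
    })
  }
  names(seqs) <- ids

  # taxonomy
  tax <- with_substream(config$seed, "pool_tax", {
    ord <- sample(FUNGAL_ORDERS, n_known, replace = TRUE)
    data.frame(
      phylum = unname(ORDER_PHYLUM[ord]),
      class_tax = ifelse(runif(n_known) < 0.85, paste0(ord, "_class"), NA),
      order = ord,
      family = ifelse(runif(n_known) < 0.7, paste0(ord, "_fam"), NA),
      species = ifelse(runif(n_known) < 0.5,
                       sprintf("sp_%04d", seq_len(n_known)), NA),
      stringsAsFactors = FALSE)
  })

  # occurrence records
  occ_rows <- vector("list", n_known)
  studies <- sprintf("study_%03d", 1:40)
  primers <- c("gITS7_ITS4", "fITS7_ITS4", "ITS3_ITS4")
  for (i in seq_len(n_known)) {
    if (!in_occ[i]) next
    with_substream(config$seed, paste0("pool_occ_", i), {
      n_pts <- max(2L, rpois(1L, config$n_occurrences_per_otu))
      if (!is.na(zone_of[i])) {
        z <- zones[[zone_of[i]]]
        inside <- runif(n_pts) < config$zone_containment
        inside[1L] <- TRUE
        lat <- ifelse(inside, runif(n_pts, z$lat_min, z$lat_max),
                      runif(n_pts, -60, 70))
        lon <- ifelse(inside, runif(n_pts, z$lon_min, z$lon_max),
                      runif(n_pts, -180, 180))
      } else {
        lat <- lat_for_class(class_of[i], n_pts)
        lon <- runif(n_pts, -180, 180)
      }
      lon[lon >= 180] <- lon[lon >= 180] - 360
      env <- env_from_location(lat, lon, noise_sd = config$env_noise_sd)
      # log10 abundance: weak environmental effects (negative MAT, positive
      # SOC/pH/latitude), a strong smooth spatial field and wide noise, so
      # the partitioned variance is space-dominant with a small shared and
      # a smaller pure-environment fraction.
      sf <- sin(lon * pi / 90) * cos(lat * pi / 60) +
        0.6 * cos(lon * pi / 120 + 1)
      y <- 0.6 + 0.012 * lat - 0.04 * env$mat + 0.06 * env$soc +
        0.10 * env$ph + 0.9 * sf + rnorm(n_pts, 0, 0.8)
      occ_rows[[i]] <- data.frame(
        otu_id = ids[i], latitude = lat, longitude = lon,
        mat = env$mat, precipitation = env$precipitation, ph = env$ph,
        soc = env$soc, abundance = 10^y,
        study_id = sample(studies, n_pts, replace = TRUE),
        primer = sample(primers, n_pts, replace = TRUE, prob = c(.5, .3, .2)),
        sample_type = sample(c("soil", "litter", "root"), n_pts,
                             replace = TRUE, prob = c(.7, .15, .15)),
        biome = biome_from_lat(lat), stringsAsFactors = FALSE)
    })
  }
  occ <- if (length(occ_rows)) do.call(rbind, occ_rows) else NULL
  if (is.null(occ)) occ <- empty_occ
  rownames(occ) <- NULL

  structure(list(
    ref = cbind(data.frame(id = ids, class = class_of, zone = zone_of,
                           in_occurrence = in_occ, stringsAsFactors = FALSE),
                tax),
    sequences = seqs,
    haplotypes = do.call(rbind, hap_rows),
    occurrences = occ,
    config = config), class = "reference_pool")
}

#' @export
print.reference_pool <- function(x, ...) {
  cat(sprintf("<reference_pool> %d reference OTUs, %d haplotypes, %d occurrence records\n",
              nrow(x$ref), nrow(x$haplotypes), nrow(x$occurrences)))
  invisible(x)
}

# ---- island dataset ----

study_design <- function(n_samples) {
  strata <- rbind(
    expand.grid(site = paste0("S", 1:4), plant_species = "poa_kerguelensis",
                altitude = c("low", "high"), stringsAsFactors = FALSE),
    expand.grid(site = paste0("S", 1:2), plant_species = "poa_annua",
                altitude = "low", stringsAsFactors = FALSE),
    expand.grid(site = paste0("S", 3:4), plant_species = "pringlea_antiscorbutica",
                altitude = c("low", "high"), stringsAsFactors = FALSE))
  ind <- strata[rep(seq_len(nrow(strata)), each = n_samples), ]
  ind$individual <- sprintf("IND_%03d", seq_len(nrow(ind)))
  md <- rbind(transform(ind, sample_type = "root"),
              transform(ind, sample_type = "soil"))
  md$sample_id <- paste(md$individual, md$sample_type, sep = "_")
  rownames(md) <- NULL
  md[, c("sample_id", "site", "plant_species", "altitude", "sample_type",
         "individual")]
}

#' Simulate the island ASV dataset
#'
#' Plants `n_otus` island OTUs: known ones reuse global haplotypes of their
#' paired reference-pool OTU (guaranteeing >= 97% identity to the source),
#' unknown ones are rejection-sampled random sequences below 97% identity
#' to every pool sequence. A configurable subset of known OTUs carries an
#' island-private ASV (absent from the pool haplotype set), dominant
#' (> 90% of the OTU's island reads) for the configured sub-fraction.
#' OTU read totals follow a geometric rank-abundance law (top quartile
#' carries ~the whole library), assigned to OTUs in a seeded random
#' permutation so that abundance rank is independent of known status;
#' plant-associated OTUs are drawn from the top ranks and concentrated in
#' the root samples of their host species.
#'
#' @param pool A [simulate_reference_pool()] result built from a compatible
#'   configuration (same `n_otus` and `known_fraction`).
#' @param config The [simulation_config].
#' @param max_attempts Rejection-sampling bound per unknown OTU.
#' @return Object of class `island_dataset`: list with `asvs` ([asv_set]),
#'   `metadata` (sample metadata data.frame), `truth` (planted ground
#'   truth: per-OTU data.frame and `asv_otu` map) and `config`.
#' @export
simulate_island_dataset <- function(pool, config, max_attempts = 50L) {
  stopifnot(inherits(pool, "reference_pool"), inherits(config, "simulation_config"))
  validate_config(config)
  n <- config$n_otus
  n_known <- round(config$known_fraction * n)
  if (nrow(pool$ref) < n_known) {
    stop("pool is incompatible with config: it contains ", nrow(pool$ref),
         " reference OTUs but ", n_known, " known island OTUs are requested")
  }
  md <- study_design(config$n_samples)
  if (n == 0L) {
    stop("invalid configuration: `n_otus` must be >= 1 for an island dataset")
  }

  # planted flags -----------------------------------------------------------
  n_private <- round(config$private_fraction * n_known)
  n_dominant <- round(config$private_dominant_fraction * n_private)
  flags <- with_substream(config$seed, "island_flags", {
    priv <- sort(sample(seq_len(n_known), n_private))
    dom <- if (n_private) sort(sample(priv, n_dominant)) else integer(0)
    sigma <- rep(NA_real_, n)
    sigma[priv] <- runif(n_private, 0.15, 0.55)
    sigma[dom] <- runif(n_dominant, 0.94, 0.985)
    list(priv = priv, dom = dom, sigma = sigma)
  })

  # per-OTU ASV sequences ----------------------------------------------------
  pool_seqs <- unname(pool$sequences)
  hap_by_ref <- split(pool$haplotypes$sequence, pool$haplotypes$ref_id)
  otu_seq_list <- vector("list", n)
  private_of <- vector("list", n)
  ref_of <- rep(NA_character_, n)
  p_geo <- 1 / config$n_asvs_per_otu
  for (i in seq_len(n)) {
    with_substream(config$seed, paste0("island_otu_", i), {
      k <- 1L + rgeom(1L, p_geo)
      if (i <= n_known) {
        rid <- pool$ref$id[i]
        ref_of[i] <- rid
        haps <- hap_by_ref[[rid]]
        take <- haps[sample(length(haps), min(k, length(haps)))]
        is_priv <- i %in% flags$priv
        if (is_priv) {
          base <- pool$sequences[[rid]]
          max_sub <- max(1L, floor(0.015 * nchar(base)))
          repeat {
            cand <- mutate_seq(base, sample(max_sub, 1L), config$indel_rate)
            if (!cand %in% haps) break
          }
          take <- c(cand, take[!take %in% cand])
        }
        otu_seq_list[[i]] <- take
        private_of[[i]] <- if (is_priv) 1L else integer(0)
      } else {
        # unknown OTU: rejection-check below 97% identity to every pool seq
        len <- sample(config$seq_length_range[1]:config$seq_length_range[2], 1L)
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          cand <- rand_dna(len)
          if (length(pool_seqs) == 0L) { ok <- TRUE; break }
          best <- .identity_best(cand, pool_seqs, 0.9)
          if (is.na(best[["identity"]]) || best[["identity"]] < 0.97) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("generation error: could not draw an unknown OTU ",
                      "sequence below the identity threshold after ",
                      max_attempts, " attempts")
        seqsK <- cand
        max_sub <- max(1L, floor(0.015 * len))
        while (length(seqsK) < k) {
          m <- mutate_seq(cand, sample(max_sub, 1L), config$indel_rate)
          if (!m %in% seqsK) seqsK <- c(seqsK, m)
        }
        otu_seq_list[[i]] <- seqsK
        private_of[[i]] <- integer(0)
      }
    })
  }

  # abundance ranks, plant status -------------------------------------------
  shares <- config$rank_decay^(seq_len(n) - 1)
  shares <- shares / sum(shares)
  rank_of <- with_substream(config$seed, "island_ranks", sample(n))
  otu_share <- shares[rank_of]
  n_plant <- max(0L, round(config$plant_fraction * n))
  plant <- rank_of <= n_plant
  hosts <- unique(md$plant_species)
  host_of <- with_substream(config$seed, "island_hosts",
                            sample(hosts, n, replace = TRUE))
  host_of[!plant] <- NA_character_

  # sample weights ------------------------------------------------------------
  # Soil OTUs reach root samples only through sparse accidental carry-over
  # (insufficient root cleaning): a per-(OTU, root sample) Bernoulli gate at
  # 8% keeps such OTUs below the 50%-of-individuals prevalence rule.
  is_root <- md$sample_type == "root"
  leak_gate <- with_substream(config$seed, "island_leak",
                              matrix(runif(n * sum(is_root)) < 0.08,
                                     nrow = n))
  w <- matrix(0, nrow = n, ncol = nrow(md))
  for (i in seq_len(n)) {
    if (plant[i]) {
      wi <- ifelse(is_root & md$plant_species == host_of[i], 1,
                   ifelse(is_root, 0.02, 0.10))
    } else {
      wi <- ifelse(is_root, config$root_leak, 1)
      wi[is_root] <- wi[is_root] * leak_gate[i, ]
    }
    w[i, ] <- otu_share[i] * wi
  }

  # per-OTU ASV proportions ---------------------------------------------------
  asv_prop <- vector("list", n)
  for (i in seq_len(n)) {
    k <- length(otu_seq_list[[i]])
    pr <- 0.6^(seq_len(k) - 1)
    if (length(private_of[[i]])) {
      sig <- flags$sigma[i]
      rest <- pr[-1] / sum(pr[-1])
      pr <- if (k > 1L) c(sig, (1 - sig) * rest) else 1
    }
    asv_prop[[i]] <- pr / sum(pr)
  }

  # flatten to ASV level ------------------------------------------------------
  otu_index <- rep(seq_len(n), lengths(otu_seq_list))
  asv_seqs <- unlist(otu_seq_list, use.names = FALSE)
  asv_ids <- sprintf("ASV_%05d", seq_along(asv_seqs))
  asv_w <- w[otu_index, , drop = FALSE] *
    unlist(asv_prop, use.names = FALSE)
  counts <- with_substream(config$seed, "island_counts", {
    m <- matrix(0L, nrow = length(asv_ids), ncol = nrow(md))
    for (j in seq_len(nrow(md))) {
      pj <- asv_w[, j]
      if (sum(pj) <= 0) next
      m[, j] <- as.integer(rmultinom(1L, config$reads_per_sample, pj))
    }
    m
  })
  colnames(counts) <- md$sample_id

  is_private_asv <- logical(length(asv_ids))
  for (i in which(lengths(private_of) > 0)) {
    is_private_asv[which(otu_index == i)[private_of[[i]]]] <- TRUE
  }

  planted <- sprintf("P_%04d", seq_len(n))
  truth_otu <- data.frame(
    planted_otu = planted,
    ref_id = ref_of,
    known = seq_len(n) <= n_known,
    rank = rank_of,
    share = otu_share,
    plant = plant,
    host_species = host_of,
    private = seq_len(n) %in% flags$priv,
    dominant_private = seq_len(n) %in% flags$dom,
    private_share_target = flags$sigma,
    n_asvs = lengths(otu_seq_list),
    stringsAsFactors = FALSE)

  structure(list(
    asvs = asv_set(asv_ids, asv_seqs, counts, origin = "island"),
    metadata = md,
    truth = list(otu = truth_otu,
                 asv_otu = setNames(planted[otu_index], asv_ids),
                 asv_private = setNames(is_private_asv, asv_ids)),
    config = config), class = "island_dataset")
}

#' @export
print.island_dataset <- function(x, ...) {
  cat(sprintf("<island_dataset> %d planted OTUs, %d ASVs, %d samples\n",
              nrow(x$truth$otu), length(x$asvs$ids), nrow(x$metadata)))
  invisible(x)
}

#' Write the synthetic inputs to plain-text files
#'
#' Writes the ASV FASTA, the ASV count table, the sample metadata, the pool
#' taxonomy/haplotypes/occurrences and the configuration JSON into a
#' directory, mirroring the file formats a real study would start from.
#'
#' @param dataset An [simulate_island_dataset()] result.
#' @param pool The paired [simulate_reference_pool()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(dataset, pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_fasta(dataset$asvs, file.path(dir, "asv_sequences.fasta"))
  write_tsv(data.frame(asv_id = dataset$asvs$ids, dataset$asvs$counts,
                       check.names = FALSE),
            file.path(dir, "asv_table.tsv"))
  write_tsv(dataset$metadata, file.path(dir, "sample_metadata.tsv"))
  write_tsv(pool$ref, file.path(dir, "pool_taxonomy.tsv"))
  write_tsv(pool$occurrences, file.path(dir, "pool_occurrences.tsv"))
  write_tsv(pool$haplotypes, file.path(dir, "pool_haplotypes.tsv"))
  if (length(pool$sequences)) {
    x <- Biostrings::DNAStringSet(pool$sequences)
    Biostrings::writeXStringSet(x, file.path(dir, "pool_sequences.fasta"))
  }
  cfg <- dataset$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
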
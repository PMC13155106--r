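#' Latitudinal biogeographic class of an occurrence set
#'
#' Classifies an OTU from the minimum (m) and maximum (M) latitude of its
#' occurrence records, evaluating the rules in precedence order:
#' cosmopolitan if the latitudinal range exceeds 60 degrees and spans both
#' hemispheres (m < 0 < M); else arctic if m >= 60; else antarctic if
#' M <= -50; else northern hemisphere if 40 <= m and M <= 60; else
#' southern hemisphere if -50 <= m and M <= -40; else low latitudes if
#' -40 <= m and M <= 40; else other. Band boundaries are inclusive.
#'
#' @param latitudes Numeric vector of occurrence latitudes (>= 1 value), or
#'   a data.frame with a `latitude` column.
#' @return One of [GEO_CLASSES].
#' @export
classify_latitudinal <- function(latitudes) {
  if (is.data.frame(latitudes)) latitudes <- latitudes$latitude
  if (length(latitudes) == 0L || any(!is.finite(latitudes))) {
    stop("classify_latitudinal: need at least one finite latitude")
  }
  if (any(latitudes < -90 | latitudes > 90)) {
    stop("classify_latitudinal: latitude outside [-90, 90]")
  }
  m <- min(latitudes); M <- max(latitudes)
  if ((M - m) > 60 && m < 0 && M > 0) return("cosmopolitan")
  if (m >= 60) return("arctic")
  if (M <= -50) return("antarctic")
  if (m >= 40 && M <= 60) return("northern_hemisphere")
  if (m >= -50 && M <= -40) return("southern_hemisphere")
  if (m >= -40 && M <= 40) return("low_latitudes")
  "other"
}

#' Ubiquity index: number of distinct plant biomes occupied
#'
#' Ranges from 1 (single biome) to 11 (all ten plant biomes plus the
#' unvegetated Antarctic category).
#'
#' @param occurrences data.frame with a `biome` column, or a character
#'   vector of biome labels from [BIOME_LABELS].
#' @return Integer count of distinct biomes.
#' @export
ubiquity_index <- function(occurrences) {
  biomes <- if (is.data.frame(occurrences)) occurrences$biome else occurrences
  if (length(biomes) == 0L) stop("ubiquity_index: empty occurrence list")
  bad <- setdiff(unique(biomes), BIOME_LABELS)
  if (length(bad)) stop("ubiquity_index: unknown biome label(s): ",
                        paste(bad, collapse = ", "))
  length(unique(biomes))
}

#' Tundra specificity percentage
#'
#' Percentage of an OTU's occurrence records falling in a cold tundra
#' biome or on the unvegetated Antarctic continent.
#'
#' @param occurrences data.frame with a `biome` column or character vector.
#' @param tundra_labels Biome labels counted as tundra; the Antarctic
#'   category is always included.
#' @return Percentage in \[0, 100\].
#' @export
tundra_specificity <- function(occurrences, tundra_labels = "tundra") {
  biomes <- if (is.data.frame(occurrences)) occurrences$biome else occurrences
  if (length(biomes) == 0L) stop("tundra_specificity: empty occurrence list")
  cold <- union(tundra_labels, "antarctic_no_vegetation")
  100 * mean(biomes %in% cold)
}

#' Per-OTU biogeographic summary table
#'
#' Applies [classify_latitudinal()], [ubiquity_index()] and
#' [tundra_specificity()] to each OTU of an occurrence table.
#'
#' @param occurrences data.frame with columns `otu_id`, `latitude`, `biome`.
#' @param tundra_labels Passed to [tundra_specificity()].
#' @return data.frame: `otu_id`, `class`, `lat_min`, `lat_max`, `n_records`,
#'   `ubiquity`, `tundra_pct`.
#' @export
geo_classification <- function(occurrences, tundra_labels = "tundra") {
  stopifnot(all(c("otu_id", "latitude", "biome") %in% names(occurrences)))
  parts <- split(occurrences, occurrences$otu_id)
  rows <- lapply(parts, function(d) {
    data.frame(otu_id = d$otu_id[1L],
               class = classify_latitudinal(d$latitude),
               lat_min = min(d$latitude), lat_max = max(d$latitude),
               n_records = nrow(d),
               ubiquity = ubiquity_index(d),
               tundra_pct = tundra_specificity(d, tundra_labels),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
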
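#' Match one OTU representative against the reference pool
#'
#' Computes the best global identity of the representative over all pool
#' sequences (exhaustive alignment; optional length-ratio prefilter) and
#' calls the OTU `known` when the best identity meets the threshold in at
#' least one pool. The pool is split into an occurrence pool (references
#' with georeferenced records) and an annotation pool (all references,
#' taxonomy only), mirroring an environmental-occurrence database versus a
#' curated annotation database.
#'
#' @param sequence Representative nucleotide sequence.
#' @param pool A [simulate_reference_pool()]-shaped `reference_pool`.
#' @param threshold Identity threshold, default 0.97 (inclusive).
#' @param strict Exclusive reading (`> threshold`) when `TRUE`.
#' @param len_ratio_min Optional length-ratio prefilter (see
#'   [cluster_asvs()]); pairs below the ratio are skipped.
#' @return List of class `match_result`: `best_ref`, `best_identity`,
#'   `status` ("known"/"unknown"), `pools` (character subset of
#'   `c("occurrence_pool", "annotation_pool")`).
#' @export
match_otu <- function(sequence, pool, threshold = 0.97, strict = FALSE,
                      len_ratio_min = NULL) {
  stopifnot(inherits(pool, "reference_pool"))
  lr <- if (is.null(len_ratio_min)) 0 else as.numeric(len_ratio_min)
  ids <- names(pool$sequences)
  if (length(ids) == 0L) {
    warning("match_otu: empty reference pool; OTU called unknown")
    return(structure(list(best_ref = NA_character_, best_identity = NA_real_,
                          status = "unknown", pools = character(0)),
                     class = "match_result"))
  }
  ord <- order(ids) # deterministic argmax tie-break by id
  seqs <- unname(pool$sequences[ord])
  best <- .identity_best(sequence, seqs, lr)
  idx <- as.integer(best[["index"]])
  bid <- best[["identity"]]
  hit <- function(x) if (isTRUE(strict)) isTRUE(x > threshold) else isTRUE(x >= threshold)
  pools <- character(0)
  best_ref <- NA_character_
  if (idx > 0L) {
    best_ref <- ids[ord][idx]
    if (hit(bid)) {
      pools <- "annotation_pool"
      occ_ids <- pool$ref$id[pool$ref$in_occurrence]
      if (length(occ_ids)) {
        occ_in <- which(ids[ord] %in% occ_ids)
        if (length(occ_in)) {
          bo <- .identity_best(sequence, seqs[occ_in], lr)
          if (hit(bo[["identity"]])) pools <- c("occurrence_pool", pools)
        }
      }
    }
  }
  structure(list(best_ref = best_ref,
                 best_identity = if (idx > 0L) unname(bid) else NA_real_,
                 status = if (length(pools)) "known" else "unknown",
                 pools = pools),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s (best %s at %.4f; pools: %s)\n", x$status,
              ifelse(is.na(x$best_ref), "-", x$best_ref),
              ifelse(is.na(x$best_identity), NA, x$best_identity),
              if (length(x$pools)) paste(x$pools, collapse = "+") else "none"))
  invisible(x)
}

#' Match every OTU of a table against the pool
#'
#' @param otus An `otu_set` with representative sequences.
#' @inheritParams match_otu
#' @return data.frame with one row per OTU: `otu_id`, `best_ref`,
#'   `best_identity`, `status`, `in_occurrence_pool`, `in_annotation_pool`.
#' @export
match_otus <- function(otus, pool, threshold = 0.97, strict = FALSE,
                       len_ratio_min = NULL) {
  stopifnot(inherits(otus, "otu_set"))
  res <- lapply(otus$otu$id, function(oid) {
    m <- match_otu(otus$rep_sequences[[oid]], pool, threshold, strict,
                   len_ratio_min)
    data.frame(otu_id = oid, best_ref = m$best_ref,
               best_identity = m$best_identity, status = m$status,
               in_occurrence_pool = "occurrence_pool" %in% m$pools,
               in_annotation_pool = "annotation_pool" %in% m$pools,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Occurrence records of a known OTU, re-keyed to the island OTU id
#'
#' @param otu_id Island OTU id.
#' @param matches The [match_otus()] table.
#' @param pool The `reference_pool`.
#' @return data.frame of the matched reference's occurrence records with
#'   `otu_id` replaced by the island OTU id; zero rows when the OTU is
#'   known in the annotation pool only.
#' @export
occurrences_for <- function(otu_id, matches, pool) {
  row <- matches[matches$otu_id == otu_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("occurrences_for: OTU ", otu_id, " not in match table")
  if (row$status != "known") {
    stop("occurrences_for: OTU ", otu_id, " is unknown; no occurrences can be looked up")
  }
  occ <- pool$occurrences[pool$occurrences$otu_id == row$best_ref, , drop = FALSE]
  if (!isTRUE(row$in_occurrence_pool)) {
    occ <- occ[0, , drop = FALSE]
  }
  if (nrow(occ)) occ$otu_id <- otu_id
  rownames(occ) <- NULL
  occ
}
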
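#' Construct a set of amplicon sequence variants (ASVs)
#'
#' Bundles ASV identifiers, nucleotide sequences, a read-count matrix and an
#' origin label into the container used by the clustering and haplotype
#' stages. Sequences must be over the strict A/C/G/T alphabet; ambiguous
#' bases (N) are rejected at load because denoised amplicon variants carry
#' none.
#'
#' @param ids Character vector of unique ASV identifiers.
#' @param sequences Character vector of A/C/G/T sequences, same length.
#' @param counts Integer matrix of read counts, one row per ASV (rownames
#'   are set to `ids`), one column per sample.
#' @param origin Either a single label or one per ASV, each `"island"` or
#'   `"global"`.
#' @return An object of class `asv_set`: a list with elements `ids`,
#'   `sequences`, `counts`, `origin`.
#' @export
asv_set <- function(ids, sequences, counts, origin = "island") {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (anyDuplicated(ids)) {
    stop("duplicate ASV ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(sequences) != length(ids)) stop("ids and sequences differ in length")
  if (any(nchar(sequences) == 0L)) stop("empty ASV sequence")
  if (any(grepl("[^ACGT]", sequences))) {
    stop("ASV sequences must use the A/C/G/T alphabet only (no ambiguous bases)")
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != length(ids)) stop("counts must have one row per ASV")
  if (any(counts < 0)) stop("negative read counts")
  rownames(counts) <- ids
  origin <- rep_len(match.arg(origin, c("island", "global"), several.ok = FALSE), length(ids))
  structure(list(ids = ids, sequences = sequences, counts = counts, origin = origin),
            class = "asv_set")
}

#' @export
print.asv_set <- function(x, ...) {
  cat(sprintf("<asv_set> %d ASVs x %d samples, %s total reads\n",
              length(x$ids), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Global pairwise identity of two nucleotide sequences
#'
#' Identity over the entire length of both sequences: an optimal global
#' (Needleman--Wunsch) alignment maximizing the number of matching columns
#' (match +1, mismatch 0, gap 0, end gaps penalized like internal gaps) is
#' computed, and among match-optimal alignments the shortest one is taken.
#' The returned value is `matches / alignment length`.
#'
#' @param a,b Nonempty nucleotide strings.
#' @return Fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' global_identity("ACGT", "ACGA")      # 0.75
#' global_identity("ACGTACGT", "ACGTCGT") # 0.875
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: sequences must be nonempty")
  unname(.nw_stats(a, b)[["identity"]])
}

#' Cluster ASVs into OTUs by greedy centroid clustering at fixed identity
#'
#' ASVs are processed by decreasing total reads (ties broken by id,
#' ascending); each ASV joins the first existing centroid whose global
#' identity to it meets the threshold, otherwise it founds a new OTU whose
#' centroid is its own sequence. The procedure is fully deterministic.
#'
#' @param asvs An [asv_set].
#' @param threshold Identity threshold, default 0.97.
#' @param strict If `TRUE`, require identity strictly above the threshold
#'   (the exclusive reading of "> 97%"); default inclusive.
#' @param len_ratio_min Optional length prefilter: centroid/ASV pairs whose
#'   length ratio (shorter/longer) is below this value are skipped without
#'   alignment. `NULL` disables. Any value at or below the identity
#'   threshold is conservative, since identity cannot exceed the ratio.
#' @return An object of class `otu_set`: list with `otu` (data.frame of id,
#'   representative, n_asvs, total_reads), `membership` (named character,
#'   ASV id -> OTU id), `counts` (OTU x sample matrix), `rep_sequences`
#'   (named character), and the input `asvs`.
#' @export
cluster_asvs <- function(asvs, threshold = 0.97, strict = FALSE,
                         len_ratio_min = NULL) {
  stopifnot(inherits(asvs, "asv_set"))
  n <- length(asvs$ids)
  totals <- rowSums(asvs$counts)
  ord <- order(-totals, asvs$ids)
  lr <- if (is.null(len_ratio_min)) 0 else as.numeric(len_ratio_min)

  centroid_seq <- character(0)
  assignment <- integer(n) # per processed ASV (in ord), OTU index
  members <- list()
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- asvs$sequences[i]
    hit <- if (length(centroid_seq)) {
      .identity_first(s, centroid_seq, threshold, isTRUE(strict), lr)
    } else 0L
    if (hit == 0L) {
      centroid_seq <- c(centroid_seq, s)
      hit <- length(centroid_seq)
      members[[hit]] <- integer(0)
    }
    members[[hit]] <- c(members[[hit]], i)
    assignment[k] <- hit
  }

  n_otu <- length(centroid_seq)
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otu))
  membership <- character(n)
  counts <- matrix(0, nrow = n_otu, ncol = ncol(asvs$counts),
                   dimnames = list(otu_ids, colnames(asvs$counts)))
  representative <- character(n_otu)
  for (g in seq_len(n_otu)) {
    idx <- members[[g]]
    membership[idx] <- otu_ids[g]
    counts[g, ] <- if (length(idx) > 1L) colSums(asvs$counts[idx, , drop = FALSE]) else asvs$counts[idx, ]
    representative[g] <- pick_representative(asvs$ids[idx], asvs)
  }
  names(membership) <- asvs$ids
  rep_seq <- asvs$sequences[match(representative, asvs$ids)]
  names(rep_seq) <- otu_ids

  structure(list(
    otu = data.frame(id = otu_ids, representative = representative,
                     n_asvs = lengths(members), total_reads = rowSums(counts),
                     row.names = NULL, stringsAsFactors = FALSE),
    membership = membership,
    counts = counts,
    rep_sequences = rep_seq,
    threshold = threshold,
    asvs = asvs
  ), class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("<otu_set> %d OTUs from %d ASVs (identity threshold %.2f)\n",
              nrow(x$otu), length(x$membership), x$threshold))
  invisible(x)
}

#' Representative ASV of an OTU
#'
#' The member with maximal total reads; ties are broken by the
#' lexicographically smallest sequence, then the smallest id.
#'
#' @param members Character vector of member ASV ids (nonempty).
#' @param asvs The [asv_set] the members belong to.
#' @return A single ASV id.
#' @export
pick_representative <- function(members, asvs) {
  if (length(members) == 0L) stop("pick_representative: empty OTU")
  idx <- match(members, asvs$ids)
  if (anyNA(idx)) stop("pick_representative: unknown member id")
  totals <- rowSums(asvs$counts[idx, , drop = FALSE])
  o <- order(-totals, asvs$sequences[idx], asvs$ids[idx])
  members[o[1L]]
}

#' Remove OTUs below a global relative-abundance floor
#'
#' Drops OTUs whose total reads fall below `min_fraction` of the grand total
#' of the table; the grand total is computed before any OTU is removed.
#' The default floor of 0.005% matches common practice for removing index
#' bleed-through and tag-switching artefacts.
#'
#' @param otus An [otu_set].
#' @param min_fraction Minimum share of the grand total, default 5e-5.
#' @return The filtered `otu_set` (counts of survivors unchanged).
#' @export
filter_rare <- function(otus, min_fraction = 0.00005) {
  stopifnot(inherits(otus, "otu_set"))
  grand <- sum(otus$counts)
  if (grand <= 0) stop("filter_rare: all-zero OTU table")
  keep <- rowSums(otus$counts) / grand >= min_fraction
  subset_otu_set(otus, keep)
}

subset_otu_set <- function(otus, keep) {
  kept_ids <- otus$otu$id[keep]
  otus$otu <- otus$otu[keep, , drop = FALSE]
  rownames(otus$otu) <- NULL
  otus$counts <- otus$counts[keep, , drop = FALSE]
  otus$rep_sequences <- otus$rep_sequences[kept_ids]
  otus$membership <- otus$membership[otus$membership %in% kept_ids]
  otus
}

#' Read / write ASV sequences as FASTA
#'
#' Thin wrappers around Biostrings for the package's on-disk formats.
#'
#' @param asvs An [asv_set] (for writing).
#' @param path File path.
#' @return `write_asv_fasta` returns `path` invisibly; `read_fasta` returns
#'   a named character vector of sequences.
#' @export
write_asv_fasta <- function(asvs, path) {
  x <- Biostrings::DNAStringSet(setNames(asvs$sequences, asvs$ids))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname write_asv_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
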
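#' Hamming distance between two haplotype sequences
#'
#' For equal-length sequences, the count of differing positions. When
#' lengths differ the sequences are implicitly padded by the same global
#' alignment used for [global_identity()], and the distance is the number
#' of non-identical alignment columns (mismatch plus gap columns).
#'
#' @param a,b Nonempty nucleotide strings.
#' @return Nonnegative integer.
#' @export
pairwise_hamming <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_hamming: sequences must be nonempty")
  if (nchar(a) == nchar(b)) {
    va <- charToRaw(a); vb <- charToRaw(b)
    return(sum(va != vb))
  }
  st <- .nw_stats(a, b)
  as.integer(st[["align_length"]] - st[["matches"]])
}

#' Build a minimum spanning haplotype network
#'
#' A minimum spanning network over the haplotypes: pairwise distances are
#' processed by increasing weight and, at each weight level, every edge
#' joining two components that were still separate before that level is
#' retained (so tied alternative connections are all kept, as in
#' statistical-parsimony style networks). Edges above `connection_limit`
#' are dropped, which may leave several components.
#'
#' @param haplotypes data.frame with columns `hap_id`, `sequence`,
#'   `island_reads` (numeric), `global_records` (numeric). One row per
#'   haplotype; >= 1 row.
#' @param otu_id Optional label stored on the network.
#' @param connection_limit Integer distance cutoff or `NULL` (none).
#' @return Object of class `haplotype_network`: list with `otu_id`, `nodes`
#'   (the input data.frame), `edges` (data.frame `from`, `to`, `distance`),
#'   and the private-haplotype summary fields filled by [detect_private()].
#' @export
build_network <- function(haplotypes, otu_id = NA_character_,
                          connection_limit = NULL) {
  stopifnot(is.data.frame(haplotypes), nrow(haplotypes) >= 1L,
            all(c("hap_id", "sequence", "island_reads", "global_records")
                %in% names(haplotypes)))
  if (anyDuplicated(haplotypes$hap_id)) stop("build_network: duplicate haplotype ids")
  n <- nrow(haplotypes)
  edges <- data.frame(from = character(0), to = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (n > 1L) {
    pairs <- t(utils::combn(n, 2L))
    d <- apply(pairs, 1L, function(p)
      pairwise_hamming(haplotypes$sequence[p[1L]], haplotypes$sequence[p[2L]]))
    keep <- rep(TRUE, length(d))
    if (!is.null(connection_limit)) keep <- d <= connection_limit
    pairs <- pairs[keep, , drop = FALSE]
    d <- d[keep]
    if (length(d)) {
      comp <- seq_len(n) # union-find (path halving not needed at this scale)
      find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
      sel <- logical(length(d))
      for (w in sort(unique(d))) {
        lev <- which(d == w)
        before <- vapply(seq_len(n), find, 1L) # components before this level
        add <- lev[before[pairs[lev, 1L]] != before[pairs[lev, 2L]]]
        sel[add] <- TRUE
        for (e in add) {
          r1 <- find(pairs[e, 1L]); r2 <- find(pairs[e, 2L])
          if (r1 != r2) comp[r1] <- r2
        }
      }
      edges <- data.frame(from = haplotypes$hap_id[pairs[sel, 1L]],
                          to = haplotypes$hap_id[pairs[sel, 2L]],
                          distance = d[sel], stringsAsFactors = FALSE)
      edges <- edges[order(edges$distance, edges$from, edges$to), ]
      rownames(edges) <- NULL
    }
  }
  net <- structure(list(otu_id = otu_id, nodes = haplotypes, edges = edges,
                        private_set = NULL, private_read_share = NULL,
                        dominant_private = NULL),
                   class = "haplotype_network")
  if (sum(haplotypes$island_reads) > 0) net <- detect_private(net)
  net
}

#' Detect island-private haplotypes and read-share dominance
#'
#' A haplotype is island-private when it carries island reads but has no
#' record in the global occurrence data of the matched reference (the
#' "private allele" of population genetics). The private read share is the
#' fraction of the OTU's island reads carried by private haplotypes, and
#' the OTU is flagged dominant-private when that share strictly exceeds
#' 0.9.
#'
#' @param network A [build_network()] result (called automatically there;
#'   re-callable after editing node counts).
#' @param dominance_threshold Strict dominance cutoff, default 0.9.
#' @return The network with `private_set`, `private_read_share` and
#'   `dominant_private` filled.
#' @export
detect_private <- function(network, dominance_threshold = 0.9) {
  stopifnot(inherits(network, "haplotype_network"))
  nd <- network$nodes
  total_island <- sum(nd$island_reads)
  if (total_island <= 0) {
    stop("detect_private: OTU has zero island reads")
  }
  priv <- nd$island_reads > 0 & nd$global_records == 0
  share <- sum(nd$island_reads[priv]) / total_island
  network$private_set <- nd$hap_id[priv]
  network$private_read_share <- share
  network$dominant_private <- share > dominance_threshold
  network
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %s: %d haplotypes, %d edges, %d private (share %s%s)\n",
              ifelse(is.na(x$otu_id), "(unnamed)", x$otu_id),
              nrow(x$nodes), nrow(x$edges), length(x$private_set),
              if (is.null(x$private_read_share)) "-" else
                sprintf("%.3f", x$private_read_share),
              if (isTRUE(x$dominant_private)) ", dominant" else ""))
  invisible(x)
}

#' Haplotype networks for every known OTU of an island dataset
#'
#' For each OTU called known in the occurrence pool, merges its island
#' ASVs with the global haplotypes of the matched reference (identical
#' sequences collapse to one node carrying both island reads and global
#' record counts) and builds the network.
#'
#' @param otus An `otu_set` (island ASVs clustered).
#' @param matches [match_otus()] table.
#' @param pool The `reference_pool` (for global haplotypes).
#' @param connection_limit Passed to [build_network()].
#' @return List of `haplotype_network`, named by OTU id, plus an attribute
#'   `summary` data.frame (otu_id, n_haplotypes, n_private, share,
#'   dominant).
#' @export
haplotype_networks <- function(otus, matches, pool, connection_limit = NULL) {
  stopifnot(inherits(otus, "otu_set"))
  keep <- matches$status == "known" & matches$in_occurrence_pool
  nets <- list()
  for (oid in matches$otu_id[keep]) {
    rid <- matches$best_ref[matches$otu_id == oid]
    members <- names(otus$membership)[otus$membership == oid]
    island_seq <- otus$asvs$sequences[match(members, otus$asvs$ids)]
    island_reads <- rowSums(otus$asvs$counts[members, , drop = FALSE])
    gh <- pool$haplotypes[pool$haplotypes$ref_id == rid, , drop = FALSE]
    nodes <- data.frame(hap_id = members, sequence = island_seq,
                        island_reads = as.numeric(island_reads),
                        global_records = 0, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(gh))) {
      hit <- match(gh$sequence[k], nodes$sequence)
      if (!is.na(hit)) {
        nodes$global_records[hit] <- nodes$global_records[hit] + gh$n_records[k]
      } else {
        nodes <- rbind(nodes, data.frame(
          hap_id = gh$hap_id[k], sequence = gh$sequence[k], island_reads = 0,
          global_records = gh$n_records[k], stringsAsFactors = FALSE))
      }
    }
    nets[[oid]] <- build_network(nodes, otu_id = oid,
                                 connection_limit = connection_limit)
  }
  summ <- do.call(rbind, lapply(nets, function(nw) data.frame(
    otu_id = nw$otu_id, n_haplotypes = nrow(nw$nodes),
    n_private = length(nw$private_set),
    private_read_share = nw$private_read_share,
    dominant_private = nw$dominant_private, stringsAsFactors = FALSE)))
  if (!is.null(summ)) rownames(summ) <- NULL
  attr(nets, "summary") <- summ
  nets
}
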
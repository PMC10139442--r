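#' One-to-one ortholog calling from pairwise similarity scores
#'
#' Ortholog pairs are reciprocal best hits by bitscore, after which any gene
#' that is the best hit of two or more genes of the other species is removed
#' as a putative duplicate. Ties for a gene's best hit make that gene
#' ambiguous: it has no unique best hit and cannot enter a pair.
#'
#' @name orthology
NULL

# Max-aggregate duplicate (gene_a, gene_b) rows, returning a data.table.
aggregate_scores <- function(records) {
  stopifnot(all(c("gene_a", "gene_b", "bitscore") %in% names(records)))
  if (any(records$bitscore < 0)) stop("bitscore must be non-negative")
  dt <- data.table::as.data.table(records)
  dt[, list(bitscore = max(bitscore)), by = c("gene_a", "gene_b")]
}

# Unique best hit per 'from' gene; genes whose top score is tied get NA.
best_hits <- function(dt, from, to) {
  ans <- dt[, {
    top <- max(bitscore)
    tied <- sum(bitscore == top)
    list(best = if (tied == 1L) .SD[[to]][bitscore == top] else NA_character_)
  }, by = from]
  data.table::setnames(ans, c("gene", "best"))
  ans
}

#' Reciprocal best-hit ortholog pairs
#'
#' Returns pairs where each gene is the other's unique best hit, then applies
#' [exclude_multi_best()] so genes that are the best hit of several genes of
#' the other species (putative duplicates) are dropped. Output is sorted by
#' `gene_a`.
#'
#' @param records data.frame with `gene_a`, `gene_b`, `bitscore`; multiple
#'   HSPs per pair are max-aggregated first
#' @return data.frame with columns `gene_a`, `gene_b`
#' @export
reciprocal_best_pairs <- function(records) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  if (NROW(records) == 0L) return(empty)
  dt <- aggregate_scores(records)
  ba <- best_hits(dt, "gene_a", "gene_b")
  bb <- best_hits(dt, "gene_b", "gene_a")
  a_best <- setNames(ba$best, ba$gene)
  b_best <- setNames(bb$best, bb$gene)
  cand <- ba[!is.na(ba$best), ]
  keep <- !is.na(b_best[cand$best]) & b_best[cand$best] == cand$gene
  pairs <- data.frame(gene_a = cand$gene[keep], gene_b = cand$best[keep],
                      stringsAsFactors = FALSE)
  pairs <- exclude_multi_best(pairs, records)
  pairs[order(pairs$gene_a), , drop = FALSE]
}

#' Remove pairs containing a gene that is the best hit of several genes
#'
#' A gene that is the (unique) best hit of two or more distinct genes of the
#' other species could be a duplicated gene; every candidate pair containing
#' such a gene is removed.
#'
#' @param pairs candidate pairs from the reciprocal-best step
#' @param records the similarity records used to form them
#' @return filtered pairs
#' @export
exclude_multi_best <- function(pairs, records) {
  if (NROW(pairs) == 0L) return(pairs)
  dt <- aggregate_scores(records)
  ba <- best_hits(dt, "gene_a", "gene_b")
  bb <- best_hits(dt, "gene_b", "gene_a")
  multi_b <- names(which(table(ba$best[!is.na(ba$best)]) >= 2L))
  multi_a <- names(which(table(bb$best[!is.na(bb$best)]) >= 2L))
  keep <- !(pairs$gene_a %in% multi_a) & !(pairs$gene_b %in% multi_b)
  pairs[keep, , drop = FALSE]
}

#' Attach per-species and mean exonic lengths to ortholog pairs
#'
#' Exonic length is the length of the union of a gene's exon intervals
#' (overlaps are not double-counted); `mean_len` is the arithmetic mean of
#' the two species' lengths — the effective length used downstream for
#' cross-species count correction.
#'
#' @param pairs data.frame `gene_a`, `gene_b`
#' @param genes_A,genes_B gene-model tables (see [write_gff3()])
#' @return data.frame `pair_id`, `gene_a`, `gene_b`, `len_a`, `len_b`,
#'   `mean_len`; `pair_id` is the species-A gene id
#' @export
attach_lengths <- function(pairs, genes_A, genes_B) {
  exon_len <- function(genes) {
    ex <- genes[genes$feature == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- genes[genes$feature == "CDS", , drop = FALSE]
    vapply(split(ex, ex$gene_id), function(g) {
      union_length(cbind(g$start, g$end))
    }, 0)
  }
  la <- exon_len(genes_A)
  lb <- exon_len(genes_B)
  missing_a <- setdiff(pairs$gene_a, names(la))
  missing_b <- setdiff(pairs$gene_b, names(lb))
  if (length(missing_a) || length(missing_b)) {
    stop("genes without exon annotation: ",
         paste(c(missing_a, missing_b), collapse = ", "))
  }
  len_a <- unname(la[pairs$gene_a])
  len_b <- unname(lb[pairs$gene_b])
  zero <- len_a == 0 | len_b == 0
  if (any(zero)) {
    stop("zero exonic length for gene(s): ",
         paste(unique(c(pairs$gene_a[zero & len_a == 0],
                        pairs$gene_b[zero & len_b == 0])), collapse = ", "))
  }
  data.frame(
    pair_id = pairs$gene_a, gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    len_a = len_a, len_b = len_b, mean_len = (len_a + len_b) / 2,
    stringsAsFactors = FALSE
  )
}
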
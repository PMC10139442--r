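#' TE insertion-site classification
#'
#' The gene region runs from the first CDS base to the last CDS base (UTRs
#' are unannotated in one species, so CDS bounds are the common currency).
#' Six strand-aware regions are derived from it: CDS, 2,000-bp upstream of
#' the first CDS, introns (gaps between CDS intervals), 2,000-bp downstream
#' of the last CDS, the first 200 bp of that window (possible 3'UTR), and
#' the 200-2,000-bp remainder. A TE overlapping a region by >= 1 bp yields an
#' insertion record; a TE may hit several regions and several genes. Flanks
#' are truncated at chromosome ends only.
#'
#' @name te_annotation
NULL

#' Gene-relative region intervals for one gene
#'
#' @param cds 2-column matrix of CDS intervals (0-based half-open)
#' @param strand `"+"` or `"-"`
#' @param chrom_len chromosome length for truncation (default `Inf`)
#' @return named list of 2-column interval matrices:
#'   CDS, UP2000, INTRON, DOWN2000, DOWN200, DOWN200_2000
#' @export
build_regions <- function(cds, strand = "+", chrom_len = Inf) {
  stopifnot(is.matrix(cds), ncol(cds) == 2L, nrow(cds) >= 1L)
  cds <- merge_intervals(cds)
  rs <- cds[1L, 1L]
  re <- cds[nrow(cds), 2L]
  iv <- function(s, e) {
    s <- max(0, s)
    e <- min(chrom_len, e)
    if (e <= s) {
      matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    } else {
      matrix(c(s, e), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    }
  }
  introns <- if (nrow(cds) > 1L) {
    m <- cbind(start = cds[-nrow(cds), 2L], end = cds[-1L, 1L])
    m[m[, 2L] > m[, 1L], , drop = FALSE]
  } else {
    matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  if (strand == "+") {
    list(
      CDS = cds,
      UP2000 = iv(rs - 2000, rs),
      INTRON = introns,
      DOWN2000 = iv(re, re + 2000),
      DOWN200 = iv(re, re + 200),
      DOWN200_2000 = iv(re + 200, re + 2000)
    )
  } else {
    list(
      CDS = cds,
      UP2000 = iv(re, re + 2000),
      INTRON = introns,
      DOWN2000 = iv(rs - 2000, rs),
      DOWN200 = iv(rs - 200, rs),
      DOWN200_2000 = iv(rs - 2000, rs - 200)
    )
  }
}

# All region intervals for a gene table, as one long data.frame.
region_table <- function(genes, chrom_lens = NULL) {
  cds <- genes[genes$feature == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in gene table")
  parts <- lapply(split(cds, cds$gene_id), function(g) {
    cl <- if (is.null(chrom_lens)) Inf else chrom_lens[[g$chrom[1L]]] %||% Inf
    regs <- build_regions(cbind(g$start, g$end), g$strand[1L], cl)
    do.call(rbind, lapply(names(regs), function(r) {
      m <- regs[[r]]
      if (nrow(m) == 0L) return(NULL)
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L], region = r,
                 start = m[, 1L], end = m[, 2L], stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Classify TE insertions into gene-relative regions
#'
#' Emits one record per (gene, TE, region) with at least 1 bp of overlap
#' between the TE interval and a region interval. TEs on other chromosomes
#' simply never overlap.
#'
#' @param genes gene-model table (CDS features required)
#' @param tes TE table (`te_id`, `chrom`, `start`, `end`, `te_type`)
#' @param chrom_lens optional named list/vector of chromosome lengths
#' @return data.frame `gene_id`, `te_id`, `te_type`, `region`
#' @export
classify_te_insertions <- function(genes, tes, chrom_lens = NULL) {
  empty <- data.frame(gene_id = character(0), te_id = character(0),
                      te_type = character(0), region = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tes) == 0L) return(empty)
  regs <- region_table(genes, chrom_lens)
  if (nrow(regs) == 0L) return(empty)
  # 0-based half-open -> IRanges 1-based closed
  reg_gr <- GenomicRanges::GRanges(
    regs$chrom, IRanges::IRanges(regs$start + 1, regs$end)
  )
  te_gr <- GenomicRanges::GRanges(
    tes$chrom, IRanges::IRanges(tes$start + 1, tes$end)
  )
  hits <- GenomicRanges::findOverlaps(te_gr, reg_gr, minoverlap = 1L)
  if (length(hits) == 0L) return(empty)
  out <- data.frame(
    gene_id = regs$gene_id[S4Vectors::subjectHits(hits)],
    te_id = tes$te_id[S4Vectors::queryHits(hits)],
    te_type = tes$te_type[S4Vectors::queryHits(hits)],
    region = regs$region[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$gene_id, out$te_id, out$region), , drop = FALSE]
}

#' Species-specific insertion sets over ortholog pairs
#'
#' For one (region, TE type) combination, partitions the ortholog pairs into
#' `only_A` (focal species has >= 1 qualifying insertion, comparator none),
#' `only_B`, `both` and `neither`. An optional conserved-TE filter restricts
#' which species-A TEs qualify.
#'
#' @param records_A,records_B outputs of [classify_te_insertions()] per species
#' @param pairs ortholog pairs (`pair_id`, `gene_a`, `gene_b`)
#' @param region region label (one of CDS, UP2000, INTRON, DOWN2000,
#'   DOWN200, DOWN200_2000)
#' @param te_type TE class, or `"any"` for all classes
#' @param conserved_filter optional character vector of species-A TE ids that
#'   qualify (e.g. conserved TEs); others are ignored on the A side
#' @return list of pair-id character vectors: `only_A`, `only_B`, `both`,
#'   `neither`
#' @export
species_specific_insertions <- function(records_A, records_B, pairs, region,
                                        te_type = "any",
                                        conserved_filter = NULL) {
  if (!region %in% TE_REGIONS) stop("unknown region: ", region)
  qual <- function(rec, filter = NULL) {
    r <- rec[rec$region == region, , drop = FALSE]
    if (!identical(te_type, "any")) r <- r[r$te_type == te_type, , drop = FALSE]
    if (!is.null(filter)) r <- r[r$te_id %in% filter, , drop = FALSE]
    unique(r$gene_id)
  }
  ga <- qual(records_A, conserved_filter)
  gb <- qual(records_B)
  in_a <- pairs$gene_a %in% ga
  in_b <- pairs$gene_b %in% gb
  list(
    only_A = pairs$pair_id[in_a & !in_b],
    only_B = pairs$pair_id[!in_a & in_b],
    both = pairs$pair_id[in_a & in_b],
    neither = pairs$pair_id[!in_a & !in_b]
  )
}

#' Per-region, per-type counts of TE-inserted genes
#'
#' Summary of [classify_te_insertions()] output: how many distinct genes
#' carry at least one insertion of each TE class in each region.
#'
#' @param records insertion records
#' @return data.frame `region`, `te_type`, `n_genes`
#' @export
insertion_summary <- function(records) {
  grid <- expand.grid(region = TE_REGIONS, te_type = TE_TYPES,
                      stringsAsFactors = FALSE)
  grid$n_genes <- mapply(function(r, t) {
    length(unique(records$gene_id[records$region == r & records$te_type == t]))
  }, grid$region, grid$te_type)
  grid
}
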
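# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: per-base labelling instead of interval
# algebra, per-position counting instead of overlap arithmetic, lchoose-based
# enumeration instead of dhyper, numeric convolution instead of the
# sum-of-NB identity, and exhaustive best-hit enumeration for orthology.

# --- orthology ---------------------------------------------------------------

# Enumerate best-hit relations from a score table and apply the pairing and
# multi-best rules literally.
oracle_ortholog_pairs <- function(records) {
  agg <- aggregate(bitscore ~ gene_a + gene_b, data = records, FUN = max)
  best_of <- function(df, from, to) {
    out <- list()
    for (g in unique(df[[from]])) {
      sub <- df[df[[from]] == g, ]
      top <- max(sub$bitscore)
      winners <- sub[[to]][sub$bitscore == top]
      out[[g]] <- if (length(winners) == 1L) winners else NA_character_
    }
    out
  }
  ba <- best_of(agg, "gene_a", "gene_b")
  bb <- best_of(agg, "gene_b", "gene_a")
  pairs <- list()
  for (a in names(ba)) {
    b <- ba[[a]]
    if (is.na(b)) next
    if (!is.na(bb[[b]]) && bb[[b]] == a) pairs[[a]] <- b
  }
  # multi-best exclusion: target of >= 2 unique best hits
  count_targets <- function(lst) table(unlist(lst[!is.na(lst)]))
  multi_b <- names(which(count_targets(ba) >= 2L))
  multi_a <- names(which(count_targets(bb) >= 2L))
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(gene_a = names(pairs),
                   gene_b = unlist(pairs, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df <- df[!(df$gene_a %in% multi_a) & !(df$gene_b %in% multi_b), , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$gene_a), , drop = FALSE]
}

# --- TE region classification ------------------------------------------------

# Label every base of the TE by direct condition checks and report the set of
# regions it touches.
oracle_te_regions <- function(cds, strand, te_start, te_end) {
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  rs <- min(cds[, 1L])
  re <- max(cds[, 2L])
  b <- seq(te_start, te_end - 1)
  in_cds <- rep(FALSE, length(b))
  for (i in seq_len(nrow(cds))) {
    in_cds <- in_cds | (b >= cds[i, 1L] & b < cds[i, 2L])
  }
  in_region <- b >= rs & b < re
  hits <- character(0)
  if (any(in_cds)) hits <- c(hits, "CDS")
  if (any(in_region & !in_cds)) hits <- c(hits, "INTRON")
  if (strand == "+") {
    up <- b >= rs - 2000 & b < rs
    d2000 <- b >= re & b < re + 2000
    d200 <- b >= re & b < re + 200
    d200_2000 <- b >= re + 200 & b < re + 2000
  } else {
    up <- b >= re & b < re + 2000
    d2000 <- b >= rs - 2000 & b < rs
    d200 <- b >= rs - 200 & b < rs
    d200_2000 <- b >= rs - 2000 & b < rs - 200
  }
  up <- up & b >= 0
  d2000 <- d2000 & b >= 0
  d200 <- d200 & b >= 0
  d200_2000 <- d200_2000 & b >= 0
  if (any(up)) hits <- c(hits, "UP2000")
  if (any(d2000)) hits <- c(hits, "DOWN2000")
  if (any(d200)) hits <- c(hits, "DOWN200")
  if (any(d200_2000)) hits <- c(hits, "DOWN200_2000")
  sort(hits)
}

# --- boundary support --------------------------------------------------------

# Count uncovered window positions one by one.
oracle_boundary_uncovered <- function(win_start, win_end, blocks) {
  if (win_end <= win_start) return(0L)
  pos <- seq(win_start, win_end - 1)
  covered <- rep(FALSE, length(pos))
  if (nrow(blocks) > 0L) {
    for (i in seq_len(nrow(blocks))) {
      covered <- covered | (pos >= blocks[i, 1L] & pos < blocks[i, 2L])
    }
  }
  sum(!covered)
}

# --- Fisher ------------------------------------------------------------------

# Exhaustive hypergeometric enumeration via lchoose (no dhyper).
oracle_fisher_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; r2 <- n21 + n22; c1 <- n11 + n21
  if (r1 == 0 || r2 == 0 || c1 == 0 || n12 + n22 == 0) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) -
    lchoose(r1 + r2, c1)
  d <- exp(logp)
  min(1, sum(d[d <= d[support == n11] * (1 + 1e-7)]))
}

# --- NB exact test -----------------------------------------------------------

# Conditional split distribution built by numeric convolution of the
# per-replicate pmfs (no sum-of-NB closed form). Returns the two-sided
# p-value for observed group-A total `sa` out of total `s`.
oracle_nb_exact_p <- function(sa, s, n1, n2, phi, mu = 10) {
  pmf1 <- if (phi == 0) dpois(0:s, mu) else dnbinom(0:s, size = 1 / phi, mu = mu)
  convn <- function(p, n) {
    out <- c(1, rep(0, s))
    for (i in seq_len(n)) {
      out <- convolve(out, rev(p), type = "open")[1:(s + 1)]
    }
    pmax(out, 0)
  }
  pa <- convn(pmf1, n1)
  pb <- convn(pmf1, n2)
  d <- pa[1:(s + 1)] * pb[(s:0) + 1]
  d <- d / sum(d)
  min(1, sum(d[d <= d[sa + 1] * (1 + 1e-7)]))
}

# --- misc --------------------------------------------------------------------

# Random similarity table for property tests.
random_score_table <- function(na, nb, density = 0.5) {
  grid <- expand.grid(gene_a = sprintf("a%02d", seq_len(na)),
                      gene_b = sprintf("b%02d", seq_len(nb)),
                      stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < density, , drop = FALSE]
  grid$bitscore <- round(runif(nrow(grid), 10, 500))
  grid
}

# Small deterministic gene-model table builder.
make_gene <- function(gene_id, chrom, strand, cds) {
  do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               feature = c("CDS", "exon"),
               start = cds[i, 1L], end = cds[i, 2L], stringsAsFactors = FALSE)
  }))
}

make_te <- function(te_id, chrom, start, end, te_type = "DNA") {
  data.frame(te_id = te_id, chrom = chrom, start = start, end = end,
             te_type = te_type, strand = "+", stringsAsFactors = FALSE)
}
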
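#' TE-by-expression enrichment tests
#'
#' For each condition (stage x direction x focal species) and each
#' (insertion region x TE type), ortholog pairs are cross-classified into a
#' 2x2 table: rows are "TE of this type in this region only in the focal
#' species" vs "no such TE in either species" (pairs with the TE in both
#' species, or only in the other species, are excluded), columns are "DEG in
#' the stated direction" vs "other". Fisher's exact test is applied and
#' p-values are BH-corrected within each condition across the region x type
#' scan. Pairs with any CDS TE in either species are excluded from non-CDS
#' universes, and the 200-2,000-bp downstream scan additionally excludes
#' pairs with any TE within 200 bp downstream.
#'
#' @name association
NULL

#' Universe of ortholog pairs eligible for one region's tests
#'
#' `CDS`: all pairs. `UP2000`/`INTRON`/`DOWN2000`/`DOWN200`: pairs where
#' neither species has any TE (any type) overlapping CDS. `DOWN200_2000`:
#' additionally excludes pairs where either species has any TE within 200 bp
#' downstream.
#'
#' @param region region label
#' @param records_A,records_B insertion records per species (all TE types)
#' @param pairs ortholog pairs
#' @return character vector of pair ids
#' @export
build_universe <- function(region, records_A, records_B, pairs) {
  if (!region %in% TE_REGIONS) stop("unknown region: ", region)
  if (region == "CDS") return(pairs$pair_id)
  hit <- function(rec, reg) unique(rec$gene_id[rec$region == reg])
  cds_a <- pairs$gene_a %in% hit(records_A, "CDS")
  cds_b <- pairs$gene_b %in% hit(records_B, "CDS")
  keep <- !cds_a & !cds_b
  if (region == "DOWN200_2000") {
    d2_a <- pairs$gene_a %in% hit(records_A, "DOWN200")
    d2_b <- pairs$gene_b %in% hit(records_B, "DOWN200")
    keep <- keep & !d2_a & !d2_b
  }
  pairs$pair_id[keep]
}

#' Build one TE x DEG contingency table
#'
#' `N11` = TE-only-in-focal and DEG in the stated direction, `N12` =
#' TE-only-in-focal and other, `N21` = without TE in both species and DEG in
#' direction, `N22` = without TE and other.
#'
#' @param universe eligible pair ids
#' @param only_focal pairs with the insertion only in the focal species
#'   (must be a subset of `universe`)
#' @param direction_set pairs that are DEGs in the stated direction
#' @param neither pairs without the insertion in both species; defaults to
#'   `universe` minus `only_focal` (valid when both/only-other pairs were
#'   already removed from `universe`)
#' @return named integer vector `N11`, `N12`, `N21`, `N22`
#' @export
build_te_deg_table <- function(universe, only_focal, direction_set,
                               neither = NULL) {
  if (length(setdiff(only_focal, universe))) {
    stop("only_focal is not a subset of the universe")
  }
  neither <- neither %||% setdiff(universe, only_focal)
  if (length(setdiff(neither, universe))) {
    stop("neither is not a subset of the universe")
  }
  if (length(intersect(neither, only_focal))) {
    stop("only_focal and neither overlap")
  }
  if (length(neither) == 0L) stop("no comparison group: 'neither' set is empty")
  c(
    N11 = length(intersect(only_focal, direction_set)),
    N12 = length(setdiff(only_focal, direction_set)),
    N21 = length(intersect(neither, direction_set)),
    N22 = length(setdiff(neither, direction_set))
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p: sum of hypergeometric probabilities (margins fixed) of all
#' tables whose probability is <= the observed one, with a 1 + 1e-7 relative
#' tolerance. The odds ratio is the sample cross-product ratio, with 0.5
#' added to every cell iff any cell is zero (Haldane-Anscombe); this is not
#' the conditional MLE. A zero margin yields `p = 1`, `odds_ratio = 1`,
#' flagged degenerate.
#'
#' @param tab numeric vector/table `c(N11, N12, N21, N22)`
#' @return list: `p`, `odds_ratio`, `degenerate`
#' @export
fisher_exact <- function(tab) {
  tab <- as.numeric(tab)
  if (length(tab) != 4L || any(tab < 0) || any(tab != round(tab))) {
    stop("need 4 non-negative integers (N11, N12, N21, N22)")
  }
  n11 <- tab[1L]; n12 <- tab[2L]; n21 <- tab[3L]; n22 <- tab[4L]
  r1 <- n11 + n12; r2 <- n21 + n22; c1 <- n11 + n21; c2 <- n12 + n22
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(p = 1, odds_ratio = 1, degenerate = TRUE))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  d <- dhyper(support, r1, r2, c1)
  p <- sum(d[d <= d[support == n11] * (1 + 1e-7)])
  if (any(tab == 0)) tab <- tab + 0.5
  list(
    p = min(1, p),
    odds_ratio = (tab[1L] * tab[4L]) / (tab[2L] * tab[3L]),
    degenerate = FALSE
  )
}

# Direction set: pairs called DEG in the stated direction for the focal
# species ("higher" = expressed higher in focal).
direction_set <- function(deg_results, stage, direction, focal) {
  d <- deg_results[deg_results$stage == stage, , drop = FALSE]
  want <- if (focal == "A") {
    if (direction == "higher") "higher_in_A" else "higher_in_B"
  } else {
    if (direction == "higher") "higher_in_B" else "higher_in_A"
  }
  unique(d$pair_id[d$direction == want])
}

#' Scan TE insertions against DEG direction
#'
#' One Fisher test per (stage x direction x region x TE type) for a focal
#' species; BH correction is applied within each condition
#' (stage x focal x direction) across the region x type scan. The conserved
#' filter restricts qualifying focal-species TEs (used when the focal
#' species is the one with population data).
#'
#' @param deg_results combined [call_degs()] output
#' @param records_A,records_B insertion records per species
#' @param pairs ortholog pairs
#' @param focal focal species, `"A"` or `"B"`
#' @param conserved_filter optional TE-id vector restricting focal TEs
#'   (only applied when `focal == "A"`)
#' @param stages,directions,regions,te_types scan grid (defaults: all)
#' @param alpha significance flag threshold on BH-q (default 0.05)
#' @return data.frame of [fisher_exact()] results with table cells and a
#'   `significant` flag
#' @export
run_te_deg_scan <- function(deg_results, records_A, records_B, pairs,
                            focal = "A", conserved_filter = NULL,
                            stages = unique(deg_results$stage),
                            directions = c("higher", "lower"),
                            regions = TE_REGIONS, te_types = TE_TYPES,
                            alpha = 0.05) {
  universes <- lapply(setNames(regions, regions), build_universe,
                      records_A = records_A, records_B = records_B,
                      pairs = pairs)
  set_cache <- list()
  for (region in regions) {
    for (tt in te_types) {
      set_cache[[paste(region, tt)]] <- species_specific_insertions(
        records_A, records_B, pairs, region, tt,
        conserved_filter = if (focal == "A") conserved_filter else NULL
      )
    }
  }
  rows <- list()
  for (stage in stages) {
    for (direction in directions) {
      dset <- direction_set(deg_results, stage, direction, focal)
      for (region in regions) {
        uni <- universes[[region]]
        for (tt in te_types) {
          sets <- set_cache[[paste(region, tt)]]
          only_focal <- intersect(if (focal == "A") sets$only_A else sets$only_B, uni)
          neither <- intersect(sets$neither, uni)
          if (length(uni) == 0L || (length(only_focal) + length(neither)) == 0L) {
            warning("empty universe for ", region, "/", tt)
            rows[[length(rows) + 1L]] <- data.frame(
              stage = stage, direction = direction, focal = focal,
              region = region, te_type = tt,
              N11 = NA_integer_, N12 = NA_integer_, N21 = NA_integer_,
              N22 = NA_integer_, odds_ratio = NA_real_, p = NA_real_,
              degenerate = NA, stringsAsFactors = FALSE
            )
            next
          }
          tab <- build_te_deg_table(uni, only_focal,
                                    intersect(dset, uni), neither)
          ft <- fisher_exact(tab)
          rows[[length(rows) + 1L]] <- data.frame(
            stage = stage, direction = direction, focal = focal,
            region = region, te_type = tt,
            N11 = tab[["N11"]], N12 = tab[["N12"]], N21 = tab[["N21"]],
            N22 = tab[["N22"]], odds_ratio = ft$odds_ratio, p = ft$p,
            degenerate = ft$degenerate, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (grp in split(seq_len(nrow(out)),
                    paste(out$stage, out$focal, out$direction))) {
    out$q[grp] <- p.adjust(out$p[grp], method = "BH")
  }
  out$significant <- !is.na(out$q) & out$q < alpha
  rownames(out) <- NULL
  out
}

#' Scan TE insertions against expression-profile clusters
#'
#' For each (cluster x region x TE type): `N11` = in-cluster pairs with the
#' TE only in the focal species, `N12` = in-cluster pairs without it in both
#' species, `N21`/`N22` = the same outside the cluster. The universe is the
#' clusterable-gene set restricted by [build_universe()] for the region
#' tested. BH correction is applied across the whole scan.
#'
#' @param assignments data.frame `pair_id`, `cluster`
#' @param records_A,records_B insertion records
#' @param pairs ortholog pairs
#' @param universe_base clusterable pair ids (TPM mean/variance filter)
#' @param focal focal species
#' @param conserved_filter optional focal TE-id filter
#' @param regions,te_types scan grid
#' @param alpha significance threshold on q
#' @return data.frame of results
#' @export
run_cluster_te_scan <- function(assignments, records_A, records_B, pairs,
                                universe_base = assignments$pair_id,
                                focal = "A", conserved_filter = NULL,
                                regions = TE_REGIONS, te_types = TE_TYPES,
                                alpha = 0.05) {
  clusters <- sort(unique(assignments$cluster))
  if (length(clusters) == 0L) stop("no cluster assignments")
  rows <- list()
  for (region in regions) {
    uni <- intersect(universe_base,
                     build_universe(region, records_A, records_B, pairs))
    for (tt in te_types) {
      sets <- species_specific_insertions(
        records_A, records_B, pairs, region, tt,
        conserved_filter = if (focal == "A") conserved_filter else NULL
      )
      only_focal <- intersect(if (focal == "A") sets$only_A else sets$only_B, uni)
      neither <- intersect(sets$neither, uni)
      for (cl in clusters) {
        in_cl <- intersect(assignments$pair_id[assignments$cluster == cl], uni)
        tab <- c(
          N11 = length(intersect(in_cl, only_focal)),
          N12 = length(intersect(in_cl, neither)),
          N21 = length(setdiff(only_focal, in_cl)),
          N22 = length(setdiff(neither, in_cl))
        )
        ft <- fisher_exact(tab)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, focal = focal, region = region, te_type = tt,
          N11 = tab[["N11"]], N12 = tab[["N12"]], N21 = tab[["N21"]],
          N22 = tab[["N22"]], odds_ratio = ft$odds_ratio, p = ft$p,
          degenerate = ft$degenerate, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}
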
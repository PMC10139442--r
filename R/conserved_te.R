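#' Conserved-TE calling from boundary-spanning read evidence
#'
#' A reference-genome TE is present in a population when at least one
#' properly and uniquely mapped read from one of its lines continuously
#' spans a TE boundary: within the 20-bp window (10 bp inside + 10 bp
#' outside the boundary) at most 4 positions may be uncovered ("a gap of
#' below 5 bp in the total 20 bp"). Either boundary suffices. Read pairs
#' with an unmapped mate, or with both mates entirely inside annotated
#' repeats, are excluded first. A TE present in every population is
#' conserved.
#'
#' @name conserved_te
NULL

# Merged repeat intervals per chromosome, for containment queries.
repeat_index <- function(repeats) {
  lapply(split(repeats[, c("start", "end")], repeats$chrom), function(d) {
    merge_intervals(cbind(d$start, d$end))
  })
}

# Is [s, e) fully inside one merged repeat interval on chrom?
inside_repeats <- function(chrom, s, e, idx) {
  m <- idx[[chrom]]
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  i <- findInterval(s, m[, 1L])
  i >= 1L && e <= m[i, 2L] && s >= m[i, 1L]
}

#' Filter read pairs for the conservation analysis
#'
#' Keeps a pair iff both mates are mapped, the pair is proper and unique,
#' and NOT both mates' full extents lie inside annotated repeat intervals.
#'
#' @param aln alignment-block table: `read_id`, `mate`, `line_id`,
#'   `population`, `chrom`, `blocks` (`"s-e,s-e"`, 0-based half-open),
#'   `mapped`, `proper_pair`, `unique`
#' @param repeats repeat/TE annotation table (`chrom`, `start`, `end`)
#' @return filtered alignment table (both mates of surviving pairs)
#' @export
filter_read_pairs <- function(aln, repeats) {
  if (nrow(aln) == 0L) return(aln)
  idx <- repeat_index(repeats)
  dt <- data.table::as.data.table(aln)
  # per-row mate extent (NA when unmapped)
  ext <- matrix(NA_real_, nrow(dt), 2L)
  has <- dt$mapped & nzchar(dt$blocks) & !is.na(dt$blocks)
  if (any(has)) {
    ext[has, ] <- t(vapply(dt$blocks[has], function(s) {
      b <- decode_blocks(s)
      c(min(b[, 1L]), max(b[, 2L]))
    }, c(0, 0)))
  }
  # fully-inside-a-repeat flag, vectorized per chromosome
  in_rep <- rep(FALSE, nrow(dt))
  for (ch in unique(dt$chrom[has])) {
    m <- idx[[ch]]
    if (is.null(m) || nrow(m) == 0L) next
    rows <- which(has & dt$chrom == ch)
    i <- findInterval(ext[rows, 1L], m[, 1L])
    ok <- i >= 1L
    in_rep[rows[ok]] <- ext[rows[ok], 2L] <= m[i[ok], 2L]
  }
  pair_key <- paste(dt$population, dt$line_id, dt$read_id, sep = "\r")
  g <- data.table::data.table(
    pair_key = pair_key, mapped = dt$mapped & has, proper = dt$proper_pair,
    uniq = dt$unique, in_rep = in_rep
  )
  stat <- g[, list(n = .N, all_mapped = all(mapped), all_proper = all(proper),
                   all_uniq = all(uniq), all_in_rep = all(in_rep)),
            by = "pair_key"]
  good <- stat$pair_key[stat$n == 2L & stat$all_mapped & stat$all_proper &
                          stat$all_uniq & !stat$all_in_rep]
  as.data.frame(dt[pair_key %in% good])
}

#' Boundary support from one mate's aligned blocks
#'
#' For each TE boundary a 20-bp window (10 bp inside, 10 bp outside) is
#' examined; `uncovered_bp` counts window positions not covered by the
#' mate's blocks, and the boundary is supported iff `uncovered_bp <= 4`.
#' TEs shorter than 10 bp have the inside half truncated to the TE extent
#' and are flagged.
#'
#' @param te_start,te_end TE interval (0-based half-open)
#' @param blocks 2-column matrix of the mate's aligned intervals
#' @return list with `left` and `right`, each
#'   `list(uncovered_bp, supported, truncated)`
#' @export
boundary_support <- function(te_start, te_end, blocks) {
  win <- function(ws, we) {
    width <- we - ws
    covered <- if (nrow(blocks) == 0L) 0 else {
      sum(pmax(0, pmin(blocks[, 2L], we) - pmax(blocks[, 1L], ws)))
    }
    uncovered <- width - covered
    list(uncovered_bp = uncovered, supported = uncovered <= 4,
         truncated = width < 20)
  }
  list(
    left = win(te_start - 10, min(te_start + 10, te_end)),
    right = win(max(te_end - 10, te_start), te_end + 10)
  )
}

# Candidate (window x mate-alignment) hits for a set of TEs: returns a
# data.table of te index, alignment row, boundary.
boundary_hits <- function(tes, aln) {
  mapped <- aln[aln$mapped, , drop = FALSE]
  if (nrow(mapped) == 0L || nrow(tes) == 0L) return(NULL)
  ext <- t(vapply(mapped$blocks, function(s) {
    b <- decode_blocks(s)
    if (nrow(b) == 0L) c(NA_real_, NA_real_) else c(min(b[, 1L]), max(b[, 2L]))
  }, c(0, 0)))
  ok <- !is.na(ext[, 1L])
  mapped <- mapped[ok, , drop = FALSE]
  ext <- ext[ok, , drop = FALSE]
  win <- data.frame(
    te = rep(seq_len(nrow(tes)), 2L),
    boundary = rep(c("left", "right"), each = nrow(tes)),
    chrom = rep(tes$chrom, 2L),
    start = c(tes$start - 10, pmax(tes$end - 10, tes$start)),
    end = c(pmin(tes$start + 10, tes$end), tes$end + 10)
  )
  win_gr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start + 1, win$end))
  aln_gr <- GenomicRanges::GRanges(mapped$chrom, IRanges::IRanges(ext[, 1L] + 1, ext[, 2L]))
  hits <- GenomicRanges::findOverlaps(win_gr, aln_gr)
  if (length(hits) == 0L) return(NULL)
  data.frame(
    te = win$te[S4Vectors::queryHits(hits)],
    boundary = win$boundary[S4Vectors::queryHits(hits)],
    row = S4Vectors::subjectHits(hits),
    mapped_row = TRUE
  ) -> out
  attr(out, "mapped") <- mapped
  out
}

#' Is a TE present in one population?
#'
#' Present iff at least one mate alignment from at least one line of the
#' population supports the left or the right boundary (see
#' [boundary_support()]). Input should already be pair-filtered.
#'
#' @param te one-row TE table (or list with `chrom`, `start`, `end`)
#' @param aln_pop filtered alignments of one population
#' @param min_lines minimum number of distinct supporting lines (default 1)
#' @return logical
#' @export
call_population_presence <- function(te, aln_pop, min_lines = 1L) {
  te_df <- data.frame(chrom = te$chrom, start = te$start, end = te$end)
  h <- boundary_hits(te_df, aln_pop)
  if (is.null(h)) return(FALSE)
  mapped <- attr(h, "mapped")
  lines <- character(0)
  for (i in seq_len(nrow(h))) {
    b <- decode_blocks(mapped$blocks[h$row[i]])
    bs <- boundary_support(te$start, te$end, b)[[h$boundary[i]]]
    if (bs$supported) lines <- union(lines, mapped$line_id[h$row[i]])
    if (length(lines) >= min_lines) return(TRUE)
  }
  length(lines) >= min_lines
}

#' Conserved-TE calls across populations
#'
#' Filters read pairs (both-mates-mapped, proper, unique, not both inside
#' repeats), evaluates per-population presence for every TE, and calls a TE
#' conserved iff it is present in all populations.
#'
#' @param tes TE table
#' @param aln alignment-block table over all populations
#' @param populations character vector of all surveyed populations
#' @param repeats repeat annotation used for the both-mates-in-repeat filter
#'   (defaults to `tes`)
#' @param min_lines minimum supporting lines per population (default 1)
#' @return list: `presence` (logical matrix TEs x populations), `calls`
#'   (data.frame `te_id`, `conserved`), `conserved` (TE-id vector)
#' @export
conserved_set <- function(tes, aln, populations, repeats = tes, min_lines = 1L) {
  if (length(populations) == 0L) stop("need >= 1 population")
  filtered <- filter_read_pairs(aln, repeats)
  presence <- matrix(FALSE, nrow(tes), length(populations),
                     dimnames = list(tes$te_id, populations))
  for (p in populations) {
    sub <- filtered[filtered$population == p, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("population with zero usable reads: ", p)
      next
    }
    h <- boundary_hits(tes, sub)
    if (is.null(h)) next
    mapped <- attr(h, "mapped")
    sup_lines <- vector("list", nrow(tes))
    for (i in seq_len(nrow(h))) {
      ti <- h$te[i]
      if (length(sup_lines[[ti]]) >= min_lines) next
      b <- decode_blocks(mapped$blocks[h$row[i]])
      bs <- boundary_support(tes$start[ti], tes$end[ti], b)[[h$boundary[i]]]
      if (bs$supported) sup_lines[[ti]] <- union(sup_lines[[ti]], mapped$line_id[h$row[i]])
    }
    presence[, p] <- vapply(sup_lines, length, 0L) >= min_lines
  }
  conserved <- rowSums(presence) == length(populations)
  list(
    presence = presence,
    calls = data.frame(te_id = tes$te_id, conserved = unname(conserved),
                       stringsAsFactors = FALSE),
    conserved = tes$te_id[conserved]
  )
}
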
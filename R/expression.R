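#' Cross-species expression normalization and differential expression
#'
#' Counts are first corrected to the ortholog pair's mean exonic length so
#' the two species' libraries are comparable, lowly expressed pairs are
#' removed (corrected CPM < 1 in every sample), library scaling uses TMM, and
#' each developmental stage is tested with a common-dispersion
#' negative-binomial exact test. Multiple testing is controlled per stage
#' with Benjamini-Hochberg; the significance threshold for interspecific
#' DEGs is FDR < 1e-5.
#'
#' @name expression
NULL

#' Length-correct a count matrix to ortholog mean exonic length
#'
#' `corrected[g, s] = counts[g, s] * 1000 / mean_len(g)` — counts per
#' kilobase of the pair's mean exonic length, making rows comparable across
#' species despite differing annotations.
#'
#' @param counts non-negative matrix, rownames = pair ids
#' @param pairs output of [attach_lengths()]
#' @return numeric matrix of the same shape
#' @export
length_correct <- function(counts, pairs) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  ml <- setNames(pairs$mean_len, pairs$pair_id)
  missing <- setdiff(rownames(counts), names(ml))
  if (length(missing)) {
    stop("no ortholog pair (mean_len) for gene(s): ",
         paste(head(missing, 10L), collapse = ", "))
  }
  counts * 1000 / ml[rownames(counts)]
}

#' Corrected counts-per-million
#'
#' Scales each corrected column to sum 1e6.
#'
#' @param corrected matrix from [length_correct()]
#' @return CPM matrix
#' @export
corrected_cpm <- function(corrected) {
  cs <- colSums(corrected)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(corrected)[cs == 0], collapse = ", "))
  }
  sweep(corrected, 2L, cs, "/") * 1e6
}

#' Filter lowly expressed ortholog pairs
#'
#' A pair is kept iff its corrected CPM is >= 1 in at least one sample;
#' pairs below 1 in all samples are dropped here and re-enter downstream as
#' non-DEGs.
#'
#' @param corrected matrix from [length_correct()]
#' @return character vector of kept pair ids
#' @export
filter_low_expression <- function(corrected) {
  cpm <- corrected_cpm(corrected)
  rownames(cpm)[rowSums(cpm >= 1) > 0L]
}

#' TMM library scaling factors
#'
#' Trimmed mean of M-values: per-gene log2 ratios vs a reference sample are
#' trimmed by 30% on M and 5% on average log intensity A, then averaged with
#' inverse approximate-binomial-variance weights. Factors are rescaled to
#' geometric mean 1. Genes with a zero in either sample are excluded from the
#' trim set.
#'
#' @param counts matrix after low-expression filtering (may be non-integer)
#' @param ref reference column name or index; default: column whose upper
#'   quartile of scaled counts is closest to the mean upper quartile
#' @return named numeric vector of factors, one per sample
#' @export
tmm_factors <- function(counts, ref = NULL) {
  stopifnot(ncol(counts) >= 2L)
  libsize <- colSums(counts)
  if (is.null(ref)) {
    uq <- apply(sweep(counts, 2L, libsize, "/"), 2L, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(counts))
    if (is.na(ref)) stop("reference sample not found")
  }
  r <- counts[, ref]
  nr <- libsize[ref]
  one <- function(x, n) {
    use <- x > 0 & r > 0
    if (sum(use) < 10L) {
      warning("fewer than 10 usable genes for TMM; returning unit factor")
      return(1)
    }
    xs <- x[use] / n
    rs <- r[use] / nr
    M <- log2(xs / rs)
    A <- 0.5 * log2(xs * rs)
    w <- (n - x[use]) / (n * x[use]) + (nr - r[use]) / (nr * r[use])
    keepM <- rank(M, ties.method = "first")
    keepA <- rank(A, ties.method = "first")
    nuse <- sum(use)
    loM <- floor(nuse * 0.30) + 1L
    hiM <- nuse - floor(nuse * 0.30)
    loA <- floor(nuse * 0.05) + 1L
    hiA <- nuse - floor(nuse * 0.05)
    keep <- keepM >= loM & keepM <= hiM & keepA >= loA & keepA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) 1 else one(counts[, j], libsize[j])
  }, 0)
  f <- f / geometric_mean(f)
  setNames(f, colnames(counts))
}

#' Method-of-moments common negative-binomial dispersion
#'
#' On factor-adjusted counts, computes per gene and per group
#' `max(0, (s^2 - m) / m^2)` and pools as the median over genes of the
#' group-mean estimate. Simple and adequate for a 4-replicate design; no
#' empirical-Bayes shrinkage.
#'
#' @param counts matrix (possibly length-corrected, non-integer)
#' @param groups factor/vector of group labels per column
#' @param factors optional per-sample scaling factors (e.g. TMM); effective
#'   library size = colSums * factors
#' @return list with element `phi` (>= 0)
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) stop("need >= 2 replicates per group")
  eff <- colSums(counts) * (factors %||% rep(1, ncol(counts)))
  adj <- sweep(counts, 2L, eff / geometric_mean(eff), "/")
  phi_g <- matrix(NA_real_, nrow(counts), nlevels(groups))
  for (k in seq_len(nlevels(groups))) {
    sub <- adj[, groups == levels(groups)[k], drop = FALSE]
    m <- rowMeans(sub)
    s2 <- apply(sub, 1L, var)
    phi_g[, k] <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), NA_real_)
  }
  phi <- median(rowMeans(phi_g, na.rm = TRUE), na.rm = TRUE)
  list(phi = max(0, phi, na.rm = TRUE))
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Counts are scaled to equal pseudo-libraries (the geometric mean of the
#' effective sizes), summed per group, and the two-sided p-value is the sum
#' of conditional probabilities, given the total, of group-A totals whose
#' probability does not exceed the observed one (with a 1 + 1e-7 relative
#' tolerance). Group sums are NB with size `n/phi`; at `phi = 0` the
#' conditional law is binomial.
#'
#' @param counts_a,counts_b numeric count vectors for the two groups
#' @param phi common dispersion (>= 0)
#' @param factors effective library sizes (or relative factors) for
#'   `c(counts_a, counts_b)`; default equal
#' @return two-sided p-value
#' @export
nb_exact_test <- function(counts_a, counts_b, phi, factors = NULL) {
  if (any(c(counts_a, counts_b) < 0)) stop("negative counts")
  if (phi < 0) stop("phi must be >= 0")
  n1 <- length(counts_a)
  n2 <- length(counts_b)
  y <- c(counts_a, counts_b)
  f <- factors %||% rep(1, n1 + n2)
  stopifnot(length(f) == n1 + n2)
  pseudo <- y * geometric_mean(f) / f
  sa <- round(sum(pseudo[seq_len(n1)]))
  sb <- round(sum(pseudo[n1 + seq_len(n2)]))
  s <- sa + sb
  if (s == 0) return(1)
  a <- 0:s
  if (phi == 0) {
    d <- dbinom(a, s, n1 / (n1 + n2))
  } else {
    mu <- s / (n1 + n2)
    d <- dnbinom(a, size = n1 / phi, mu = n1 * mu) *
      dnbinom(s - a, size = n2 / phi, mu = n2 * mu)
    d <- d / sum(d)
  }
  min(1, sum(d[d <= d[sa + 1L] * (1 + 1e-7)]))
}

#' Call interspecific differentially expressed genes for one stage
#'
#' Runs the full per-stage chain: length correction, corrected-CPM < 1
#' filter, TMM, common-dispersion estimate, per-gene NB exact test, BH
#' adjustment within the stage, and a direction call
#' (`higher_in_A`/`higher_in_B`) for pairs with `q < alpha`. Pairs removed by
#' the expression filter are appended with `direction = "ns"` and NA
#' statistics.
#'
#' @param counts matrix, rownames = pair ids, one column per sample
#' @param meta data.frame `sample_id`, `species` (A/B), `stage`, `replicate`
#' @param pairs output of [attach_lengths()]
#' @param stage stage label to test (e.g. `"L4"`)
#' @param alpha FDR threshold for the direction call (default 1e-5)
#' @return data.frame `pair_id`, `stage`, `logFC` (log2 A/B), `logCPM`, `p`,
#'   `q`, `direction`
#' @export
call_degs <- function(counts, meta, pairs, stage, alpha = 1e-5) {
  if (!stage %in% meta$stage) stop("stage not in metadata: ", stage)
  sel <- meta$stage == stage
  sm <- meta[sel, , drop = FALSE]
  m <- counts[, sm$sample_id, drop = FALSE]
  corrected <- length_correct(m, pairs)
  kept <- filter_low_expression(corrected)
  dropped <- setdiff(rownames(m), kept)
  ck <- corrected[kept, , drop = FALSE]
  tmm <- tmm_factors(ck)
  eff <- colSums(ck) * tmm
  disp <- estimate_common_dispersion(ck, sm$species, factors = tmm)
  ia <- which(sm$species == "A")
  ib <- which(sm$species == "B")
  geo <- geometric_mean(eff)
  pseudo <- sweep(ck, 2L, geo / eff, "*")
  sa <- rowSums(pseudo[, ia, drop = FALSE])
  sb <- rowSums(pseudo[, ib, drop = FALSE])
  p <- vapply(seq_along(kept), function(g) {
    nb_exact_test(ck[g, ia], ck[g, ib], disp$phi, factors = eff[c(ia, ib)])
  }, 0)
  q <- p.adjust(p, method = "BH")
  logFC <- log2((sa / length(ia) + 0.5) / (sb / length(ib) + 0.5))
  logCPM <- log2(((sa + sb) / (length(ia) + length(ib)) + 0.5) / geo * 1e6)
  direction <- ifelse(q < alpha,
                      ifelse(logFC > 0, "higher_in_A", "higher_in_B"), "ns")
  out <- data.frame(
    pair_id = kept, stage = stage, logFC = logFC, logCPM = logCPM,
    p = p, q = q, direction = direction, stringsAsFactors = FALSE
  )
  if (length(dropped)) {
    out <- rbind(out, data.frame(
      pair_id = dropped, stage = stage, logFC = NA_real_, logCPM = NA_real_,
      p = NA_real_, q = NA_real_, direction = "ns", stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Transcripts per million with per-species gene lengths
#'
#' `rate = count / length(species of sample)`; each column is scaled so TPM
#' sums to 1e6.
#'
#' @param counts matrix, rownames = pair ids
#' @param meta sample metadata (`sample_id`, `species`)
#' @param pairs output of [attach_lengths()] (uses `len_a`/`len_b`)
#' @return TPM matrix
#' @export
compute_tpm <- function(counts, meta, pairs) {
  la <- setNames(pairs$len_a, pairs$pair_id)
  lb <- setNames(pairs$len_b, pairs$pair_id)
  missing <- setdiff(rownames(counts), pairs$pair_id)
  if (length(missing)) {
    stop("no lengths for gene(s): ", paste(head(missing, 10L), collapse = ", "))
  }
  if (any(la[rownames(counts)] <= 0) || any(lb[rownames(counts)] <= 0)) {
    stop("non-positive exonic length")
  }
  sp <- setNames(meta$species, meta$sample_id)[colnames(counts)]
  rate <- counts
  rate[, sp == "A"] <- counts[, sp == "A", drop = FALSE] / la[rownames(counts)]
  rate[, sp == "B"] <- counts[, sp == "B", drop = FALSE] / lb[rownames(counts)]
  cs <- colSums(rate)
  if (any(cs == 0)) stop("all-zero sample column in TPM computation")
  sweep(rate, 2L, cs, "/") * 1e6
}

#' PCA variance fractions and sample scores
#'
#' Rows (genes) are optionally log2(x+1)-transformed and centered; the
#' variance fractions are the eigenvalue shares of the sample covariance.
#'
#' @param mat genes x samples matrix (typically corrected CPM)
#' @param log apply log2(x + 1) first (default TRUE)
#' @return list: `fractions` (length = number of components, sums to 1),
#'   `scores` (samples x components)
#' @export
pca_variance_explained <- function(mat, log = TRUE) {
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  x <- if (log) log2(mat + 1) else mat
  x <- x - rowMeans(x)
  if (max(abs(x)) == 0) stop("no variance across samples")
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  list(fractions = ev / sum(ev), scores = pc$x)
}
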
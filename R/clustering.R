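#' Expression-profile clustering of interspecific DEGs
#'
#' Genes that are interspecific DEGs in at least one stage and have TPM mean
#' and variance above 1 are summarized as Z-scored per-condition mean TPM
#' profiles (4 conditions: species x stage) and clustered with k-means; the
#' number of clusters is chosen by the gap statistic with the 1-SE rule, up
#' to 20 clusters by default.
#'
#' @name clustering
NULL

#' Select genes eligible for profile clustering
#'
#' Keeps ortholog pairs that are DEGs in at least one stage (direction not
#' `"ns"`) and whose TPM mean and variance across all samples both exceed 1.
#'
#' @param tpm TPM matrix (all samples)
#' @param deg_results combined [call_degs()] output over stages
#' @return character vector of pair ids
#' @export
select_clusterable_genes <- function(tpm, deg_results) {
  deg_ids <- unique(deg_results$pair_id[deg_results$direction != "ns"])
  m <- rowMeans(tpm)
  v <- apply(tpm, 1L, var)
  keep <- rownames(tpm)[m > 1 & v > 1]
  sort(intersect(deg_ids, keep))
}

#' Z-scored per-condition mean TPM profiles
#'
#' For each kept gene, the mean TPM of every (species, stage) condition is
#' computed (order: A-L4, A-YA, B-L4, B-YA) and the 4-vector is Z-scored
#' with the n-1 denominator. Zero-variance profiles are dropped with a
#' message.
#'
#' @param tpm TPM matrix
#' @param kept pair ids from [select_clusterable_genes()]
#' @param meta sample metadata
#' @return matrix (genes x 4), rownames = pair ids, colnames = conditions
#' @export
zscore_profiles <- function(tpm, kept, meta) {
  cond <- paste(meta$species, meta$stage, sep = "-")
  levels <- c("A-L4", "A-YA", "B-L4", "B-YA")
  levels <- levels[levels %in% cond]
  sub <- tpm[kept, , drop = FALSE]
  prof <- vapply(levels, function(cl) {
    rowMeans(sub[, meta$sample_id[cond == cl], drop = FALSE])
  }, numeric(length(kept)))
  if (length(kept) == 1L) prof <- matrix(prof, nrow = 1L, dimnames = list(kept, levels))
  sds <- apply(prof, 1L, sd)
  zero <- sds == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-variance profile(s)")
    prof <- prof[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  (prof - rowMeans(prof)) / sds
}

# k-means++ seeding: D^2-weighted center choices.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    pick <- if (all(d2 == 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    centers[j + 1L] <- pick
    nd <- rowSums((x - matrix(x[pick, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' k-means with k-means++ restarts
#'
#' Lloyd iterations from `n_restarts` k-means++ seedings; the restart with
#' the smallest total within-cluster sum of squares wins. Deterministic for
#' a fixed seed; the caller's RNG state is untouched. Empty clusters trigger
#' a fresh seeding of that restart.
#'
#' @param x numeric matrix (observations x features)
#' @param k number of clusters (1 <= k <= nrow(x))
#' @param n_restarts random restarts (default 10)
#' @param seed integer seed
#' @return list: `cluster` (assignments), `centers`, `tot_withinss`
#' @export
kmeans_profiles <- function(x, k, n_restarts = 10, seed = 1) {
  x <- as.matrix(x)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds number of observations")
  if (k == 1L) {
    ctr <- colMeans(x)
    return(list(cluster = rep(1L, nrow(x)), centers = matrix(ctr, 1L),
                tot_withinss = sum(sweep(x, 2L, ctr)^2)))
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (attempt in 1:20) {
        init <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stop("k-means failed to produce ", k, " non-empty clusters")
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    list(cluster = best$cluster, centers = best$centers,
         tot_withinss = best$tot.withinss)
  })
}

#' Gap statistic for choosing the number of clusters
#'
#' For each k in 1..kmax, `logW` is the log within-cluster dispersion of the
#' best k-means fit; B reference datasets are drawn uniformly over the
#' per-dimension range of the data (original feature space, or the
#' PCA-rotated box when `reference = "pca"`). `gap(k) = mean_b logW_b -
#' logW`, `se(k) = sd_b(logW_b) * sqrt(1 + 1/B)`, and the chosen k is the
#' smallest with `gap(k) >= gap(k+1) - se(k+1)` (1-SE rule), else kmax.
#'
#' @param x observations x features matrix
#' @param kmax maximum k (default 20; clamped to nrow(x) with a warning)
#' @param B reference draws (>= 10, default 100)
#' @param n_restarts k-means restarts per fit
#' @param seed integer seed
#' @param reference `"range"` (default) or `"pca"` box
#' @return list: `table` (data.frame k, logW, E_logW, gap, se), `k_chosen`
#' @export
gap_statistic <- function(x, kmax = 20, B = 100, n_restarts = 10, seed = 1,
                          reference = c("range", "pca")) {
  reference <- match.arg(reference)
  x <- as.matrix(x)
  if (B < 10) stop("B must be >= 10")
  if (kmax > nrow(x)) {
    warning("kmax exceeds number of observations; clamped")
    kmax <- nrow(x)
  }
  if (reference == "pca") {
    ctr <- colMeans(x)
    vmat <- svd(sweep(x, 2L, ctr))$v
    xr <- sweep(x, 2L, ctr) %*% vmat
  } else {
    xr <- x
    vmat <- NULL
    ctr <- NULL
  }
  rng <- apply(xr, 2L, range)
  logw <- function(y, k, s) log(kmeans_profiles(y, k, n_restarts, s)$tot_withinss)
  logW <- vapply(1:kmax, function(k) logw(x, k, derive_seed(seed, paste0("gapW", k))), 0)
  logWb <- matrix(0, B, kmax)
  for (b in seq_len(B)) {
    ref <- with_seed(derive_seed(seed, paste0("gapref", b)), {
      apply(rng, 2L, function(r) runif(nrow(x), r[1L], r[2L]))
    })
    if (!is.null(vmat)) ref <- sweep(ref %*% t(vmat), 2L, ctr, "+")
    for (k in 1:kmax) {
      logWb[b, k] <- logw(ref, k, derive_seed(seed, paste0("gapB", b, "k", k)))
    }
  }
  gap <- colMeans(logWb) - logW
  se <- apply(logWb, 2L, sd) * sqrt(1 + 1 / B)
  k_chosen <- kmax
  for (k in seq_len(kmax - 1L)) {
    if (gap[k] >= gap[k + 1L] - se[k + 1L]) {
      k_chosen <- k
      break
    }
  }
  list(
    table = data.frame(k = 1:kmax, logW = logW, E_logW = colMeans(logWb),
                       gap = gap, se = se),
    k_chosen = k_chosen
  )
}

#' Cluster DEG expression profiles end to end
#'
#' Convenience wrapper: select genes, Z-score profiles, choose k by the gap
#' statistic, and fit the final k-means.
#'
#' @inheritParams gap_statistic
#' @param tpm TPM matrix
#' @param deg_results combined DE table
#' @param meta sample metadata
#' @return list: `assignments` (data.frame pair_id, cluster), `gap`
#'   (gap-statistic result), `k`, `profiles`
#' @export
cluster_deg_profiles <- function(tpm, deg_results, meta, kmax = 20, B = 100,
                                 n_restarts = 10, seed = 1) {
  kept <- select_clusterable_genes(tpm, deg_results)
  if (length(kept) < 2L) stop("fewer than 2 clusterable genes")
  prof <- zscore_profiles(tpm, kept, meta)
  gap <- gap_statistic(prof, kmax = min(kmax, nrow(prof)), B = B,
                       n_restarts = n_restarts, seed = derive_seed(seed, "gap"))
  fit <- kmeans_profiles(prof, gap$k_chosen, n_restarts, derive_seed(seed, "final-km"))
  list(
    assignments = data.frame(pair_id = rownames(prof), cluster = fit$cluster,
                             stringsAsFactors = FALSE),
    gap = gap, k = gap$k_chosen, profiles = prof
  )
}
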
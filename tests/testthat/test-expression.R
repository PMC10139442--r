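mk_pairs <- function(ids, mean_len, len_a = mean_len, len_b = mean_len) {
  data.frame(pair_id = ids, gene_a = ids, gene_b = sub("^gA", "gB", ids),
             len_a = len_a, len_b = len_b, mean_len = mean_len,
             stringsAsFactors = FALSE)
}

test_that("length correction follows counts * 1000 / mean_len and is linear", {
  counts <- matrix(c(100, 100, 0, 8), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  pairs <- mk_pairs(c("g1", "g2"), c(1000, 2000))
  got <- length_correct(counts, pairs)
  expect_equal(got["g1", "s1"], 100)
  expect_equal(got["g2", "s1"], 50)
  expect_equal(got["g2", "s2"], 4)
  expect_equal(length_correct(2 * counts, pairs), 2 * got)
  expect_equal(unname(got["g1", "s2"] / got["g1", "s1"]), 0)
  expect_error(length_correct(matrix(1, 1, 1, dimnames = list("gX", "s")),
                              pairs), "gX")
})

test_that("low-expression filter drops only all-sample-below-1 genes", {
  # 3 genes x 2 samples; craft corrected values whose CPMs are known
  corrected <- rbind(
    lowlow = c(0.4, 0.4),
    lowhigh = c(0.4, 2),
    big = c(999999.2, 999997.6)
  )
  colnames(corrected) <- c("s1", "s2")
  cpm <- corrected_cpm(corrected)
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6))
  kept <- filter_low_expression(corrected)
  expect_true("lowhigh" %in% kept)
  expect_true("big" %in% kept)
  expect_false("lowlow" %in% kept)
  # the 2-gene toy: columns (1, 999999) keep both
  toy <- rbind(g1 = c(1, 1), g2 = c(999999, 999999))
  expect_setequal(filter_low_expression(toy), c("g1", "g2"))
  expect_error(corrected_cpm(rbind(c(0, 1))), "all-zero")
})

test_that("TMM factors: identity, 2x scaling recovery, unit geometric mean", {
  set.seed(7)
  base <- rnbinom(3000, mu = 200, size = 10)
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)

  m2 <- cbind(s1 = base, s2 = rnbinom(3000, mu = 2 * 200, size = 10),
              s3 = rnbinom(3000, mu = 200, size = 10))
  rownames(m2) <- paste0("g", seq_len(nrow(m2)))
  f <- tmm_factors(m2)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # doubling the library, no DE: effective sizes colSums*f should agree with
  # the 2x design within 1%
  eff <- colSums(m2) * f
  expect_equal(unname(eff["s2"] / eff["s1"]), 2, tolerance = 0.01)
  expect_warning(tmm_factors(m2[1:5, 1:2]), "fewer than 10")
})

test_that("common dispersion: zero variance, Poisson and NB regimes", {
  const <- matrix(rep(c(10, 20), each = 4), 2, 4, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  groups <- rep("A", 4)
  expect_equal(estimate_common_dispersion(const, groups)$phi, 0)
  expect_error(estimate_common_dispersion(const, c("A", "A", "A", "B")),
               "replicates")

  set.seed(11)
  pois <- matrix(rpois(2000 * 8, 100), 2000, 8)
  rownames(pois) <- paste0("g", 1:2000)
  grp <- rep(c("A", "B"), each = 4)
  expect_lte(estimate_common_dispersion(pois, grp)$phi, 0.01)

  nb <- matrix(rnbinom(2000 * 8, mu = 100, size = 1 / 0.2), 2000, 8)
  rownames(nb) <- paste0("g", 1:2000)
  phi <- estimate_common_dispersion(nb, grp)$phi
  expect_gte(phi, 0.1)
  expect_lte(phi, 0.3)
})

test_that("NB exact test matches its oracles on small cases", {
  # symmetric mode case
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.1), 1)
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0), 1)
  # phi = 0 equals the conditional binomial two-sided tail
  p <- nb_exact_test(c(2, 0), c(9, 9), phi = 0)
  d <- dbinom(0:20, 20, 0.5)
  expect_equal(p, sum(d[d <= d[3] * (1 + 1e-7)]), tolerance = 1e-12)
  # phi > 0 equals the brute-force convolution over all splits
  for (case in list(c(sa = 3, s = 17), c(sa = 10, s = 20), c(sa = 0, s = 9))) {
    sa <- case[["sa"]]; s <- case[["s"]]
    mine <- nb_exact_test(c(sa, 0), c(s - sa, 0, 0, 0), phi = 0.1)
    want <- oracle_nb_exact_p(sa, s, n1 = 2, n2 = 4, phi = 0.1)
    expect_equal(mine, want, tolerance = 1e-10)
  }
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), 0.1), "negative")
})

test_that("call_degs recovers planted effects and respects label symmetry", {
  cfg <- sim_config(seed = 5, n_genes = 400, frac_pair = 1,
                    nb_mean_log_range = c(log(100), log(500)),
                    nb_dispersion = 0.05)
  g <- simulate_genome_pair(cfg)
  pairs <- attach_lengths(g$ortholog_truth[, c("gene_a", "gene_b")],
                          g$genes_A, g$genes_B)
  truth <- plan_deg_truth(cfg, g$ortholog_truth)
  sim <- simulate_counts(cfg, g$ortholog_truth, truth)
  de <- call_degs(sim$counts, sim$meta, pairs, "L4")
  planted <- truth$pair_id[truth$direction != "ns"]
  hit <- de$pair_id[de$direction != "ns"]
  expect_gte(length(intersect(hit, planted)) / length(planted), 0.7)
  dirs <- merge(de[de$direction != "ns", c("pair_id", "direction")],
                truth, by = "pair_id")
  expect_true(all(dirs$direction.x == dirs$direction.y))

  # swapping species labels flips every direction call
  meta_sw <- sim$meta
  meta_sw$species <- ifelse(sim$meta$species == "A", "B", "A")
  de_sw <- call_degs(sim$counts, meta_sw, pairs, "L4")
  m <- merge(de, de_sw, by = "pair_id")
  flip <- c(higher_in_A = "higher_in_B", higher_in_B = "higher_in_A",
            ns = "ns")
  expect_equal(unname(flip[m$direction.x]), m$direction.y)
  expect_error(call_degs(sim$counts, sim$meta, pairs, "L9"), "stage")
})

test_that("BH q-values are nondecreasing in p rank within stage", {
  cfg <- sim_config(seed = 6, n_genes = 200, frac_pair = 1)
  g <- simulate_genome_pair(cfg)
  pairs <- attach_lengths(g$ortholog_truth[, c("gene_a", "gene_b")],
                          g$genes_A, g$genes_B)
  sim <- simulate_counts(cfg, g$ortholog_truth)
  de <- call_degs(sim$counts, sim$meta, pairs, "YA")
  tested <- de[!is.na(de$p), ]
  ord <- order(tested$p)
  expect_true(all(diff(tested$q[ord]) >= -1e-12))
})

test_that("TPM uses per-species lengths and sums to 1e6", {
  counts <- matrix(c(100, 200), 2, 1, dimnames = list(c("g1", "g2"), "sA"))
  meta <- data.frame(sample_id = "sA", species = "A", stage = "L4",
                     replicate = 1)
  pairs <- mk_pairs(c("g1", "g2"), c(1500, 2500), len_a = c(1000, 2000),
                    len_b = c(2000, 3000))
  tpm <- compute_tpm(counts, meta, pairs)
  expect_equal(unname(tpm[, 1L]), c(5e5, 5e5))
  # single gene -> 1e6
  tpm1 <- compute_tpm(counts[1, , drop = FALSE], meta, pairs)
  expect_equal(unname(tpm1[1, 1]), 1e6)
  # per-species lengths actually differ: a B sample uses len_b
  metaB <- data.frame(sample_id = "sB", species = "B", stage = "L4",
                      replicate = 1)
  colnames(counts) <- "sB"
  tpmB <- compute_tpm(counts, metaB, pairs)
  rateB <- c(100 / 2000, 200 / 3000)
  expect_equal(unname(tpmB[, 1L]), rateB / sum(rateB) * 1e6)
  expect_equal(unname(colSums(tpmB)), 1e6, tolerance = 1e-9)
})

test_that("PCA fractions match a direct eigen oracle", {
  # samples on a line in gene space -> PC1 carries everything
  line <- cbind(s1 = c(0, 0), s2 = c(1, 2), s3 = c(2, 4))
  got <- pca_variance_explained(line, log = FALSE)
  expect_equal(got$fractions[1L], 1, tolerance = 1e-12)

  set.seed(3)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  got2 <- pca_variance_explained(abs(m), log = TRUE)
  x <- log2(abs(m) + 1)
  x <- x - rowMeans(x)
  ev <- sort(eigen(crossprod(x) / 1, symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_equal(got2$fractions, (ev / sum(ev))[seq_along(got2$fractions)],
               tolerance = 1e-8)
  expect_equal(sum(got2$fractions), 1, tolerance = 1e-12)
  expect_error(pca_variance_explained(m[, 1, drop = FALSE]), "2 samples")
})
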
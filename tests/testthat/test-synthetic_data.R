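test_that("genome pair generation is seed-deterministic and well spaced", {
  cfg <- sim_config(seed = 1, n_genes = 10)
  g1 <- simulate_genome_pair(cfg)
  g2 <- simulate_genome_pair(cfg)
  expect_identical(g1, g2)
  expect_equal(length(unique(g1$genes_A$gene_id)), 10L)
  expect_equal(length(unique(g1$genes_B$gene_id)), 10L)
  expect_gte(nrow(g1$ortholog_truth), 9L)

  # byte-identical GFF3 on reseed
  f1 <- tempfile(); f2 <- tempfile()
  write_gff3(g1$genes_A, f1)
  write_gff3(simulate_genome_pair(cfg)$genes_A, f2)
  expect_identical(readLines(f1), readLines(f2))

  # default layout: adjacent gene regions > 4,000 bp apart
  cds <- g1$genes_A[g1$genes_A$feature == "CDS", ]
  spans <- do.call(rbind, lapply(split(cds, cds$gene_id), function(x) {
    data.frame(chrom = x$chrom[1], start = min(x$start), end = max(x$end))
  }))
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L) {
      expect_true(all(s$start[-1L] - s$end[-nrow(s)] > 4000))
    }
  }
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("decoy blocks exercise the multi-best exclusion", {
  cfg <- sim_config(seed = 2, n_genes = 200, frac_pair = 0.9)
  g <- simulate_genome_pair(cfg)
  expect_lt(nrow(g$ortholog_truth), 200L)
  got <- reciprocal_best_pairs(g$similarity)
  expect_setequal(got$gene_a, g$ortholog_truth$gene_a)
  # the decoy genes never pair
  decoys <- setdiff(unique(g$genes_A$gene_id), g$ortholog_truth$gene_a)
  expect_gt(length(decoys), 0L)
  expect_length(intersect(got$gene_a, decoys), 0L)
})

test_that("TE landscape respects rates, regions and impossibility", {
  cfg0 <- sim_config(seed = 3, n_genes = 20,
                     te_rates = default_te_rates(0, 0))
  g <- simulate_genome_pair(cfg0)
  land0 <- simulate_te_landscape(cfg0, g$genes_A, g$genes_B)
  expect_equal(nrow(land0$tes_A), 0L)
  expect_equal(nrow(land0$tes_B), 0L)

  # rate 1 for intronic DNA in species A only: every multi-CDS A gene hit
  rates <- default_te_rates(0, 0)
  rates$rate_A[rates$region == "INTRON" & rates$te_type == "DNA"] <- 1
  cfg1 <- sim_config(seed = 3, n_genes = 20, te_rates = rates,
                     n_cds_range = c(2, 4))
  land1 <- simulate_te_landscape(cfg1, g$genes_A, g$genes_B)
  expect_setequal(unique(land1$placements_A$gene_id),
                  unique(g$genes_A$gene_id))
  expect_true(all(land1$placements_A$region == "INTRON"))
  expect_equal(nrow(land1$tes_B), 0L)

  # single-CDS genes make intron placement impossible -> skipped with log
  cfg2 <- sim_config(seed = 4, n_genes = 5, te_rates = rates,
                     n_cds_range = c(1, 1))
  g2 <- simulate_genome_pair(cfg2)
  expect_message(
    land2 <- simulate_te_landscape(cfg2, g2$genes_A, g2$genes_B),
    "skipped"
  )
  expect_equal(nrow(land2$tes_A), 0L)
})

test_that("planted TE region labels agree with the classifier", {
  cfg <- sim_config(seed = 9, n_genes = 150)
  g <- simulate_genome_pair(cfg)
  land <- simulate_te_landscape(cfg, g$genes_A, g$genes_B)
  for (side in c("A", "B")) {
    planted <- land[[paste0("placements_", side)]]
    rec <- classify_te_insertions(g[[paste0("genes_", side)]],
                                  land[[paste0("tes_", side)]])
    merged <- merge(planted, rec,
                    by = c("gene_id", "te_id", "te_type", "region"))
    expect_equal(nrow(merged), nrow(planted))
  }
})

test_that("count simulation: Poisson limit, null model, library factors", {
  cfg <- sim_config(seed = 5, n_genes = 800, frac_pair = 1, nb_dispersion = 0,
                    frac_deg = 0, frac_stage = 0, lib_factor_sd = 0)
  g <- simulate_genome_pair(cfg)
  sim <- simulate_counts(cfg, g$ortholog_truth)
  # phi = 0: per-gene variance tracks the mean on average (Poisson)
  sub <- sim$counts[, sim$meta$species == "A" & sim$meta$stage == "L4"]
  m <- rowMeans(sim$counts)
  v <- apply(sim$counts, 1L, var)
  expect_equal(mean(v / m), 1, tolerance = 0.1)
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")

  # null model: no true DEGs
  cfg0 <- sim_config(seed = 5, n_genes = 50, logfc_effect = 0,
                     te_effect_beta = 1)
  g0 <- simulate_genome_pair(cfg0)
  s0 <- simulate_counts(cfg0, g0$ortholog_truth)
  expect_equal(nrow(s0$ground_truth$deg), 0L)

  # a doubled library factor doubles the column sum within 5%
  lib <- simulate_counts(cfg, g$ortholog_truth)$ground_truth$lib_factors
  cfgl <- sim_config(seed = 5, n_genes = 800, frac_pair = 1,
                     nb_dispersion = 0, frac_deg = 0, frac_stage = 0,
                     lib_factor_sd = 0.4)
  siml <- simulate_counts(cfgl, g$ortholog_truth)
  fl <- siml$ground_truth$lib_factors
  cs <- colSums(siml$counts)
  ratio <- (cs / fl) / mean(cs / fl)
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("population reads recover the planted conservation pattern", {
  cfg <- sim_config(seed = 7, n_genes = 40, conservation_prob = 1)
  g <- simulate_genome_pair(cfg)
  land <- simulate_te_landscape(cfg, g$genes_A, g$genes_B)
  pops <- colnames(land$conservation_map)
  reads <- simulate_population_reads(cfg, land$tes_A, land$conservation_map)
  cs <- conserved_set(land$tes_A, reads, pops)
  expect_setequal(cs$conserved, land$tes_A$te_id)

  # empty conservation map -> empty conserved set
  cm0 <- land$conservation_map & FALSE
  reads0 <- simulate_population_reads(cfg, land$tes_A, cm0)
  cs0 <- conserved_set(land$tes_A, reads0, pops)
  expect_length(cs0$conserved, 0L)
  expect_true(all(!cs0$presence))

  # one-side-unmapped decoys are removed by the pair filter
  decoy <- reads0[grepl("_oneside$", reads0$read_id), ]
  expect_gt(nrow(decoy), 0L)
  filtered <- filter_read_pairs(reads0, land$tes_A)
  expect_length(intersect(filtered$read_id, decoy$read_id), 0L)
  expect_error(sim_config(read_length = 10), "read_length")
})

test_that("simulate_to_dir is byte-deterministic across runs", {
  cfg <- sim_config(seed = 11, n_genes = 30)
  d1 <- file.path(tempdir(), "simdet1")
  d2 <- file.path(tempdir(), "simdet2")
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
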
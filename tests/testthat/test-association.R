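# Five-pair fixture for universe filters: pair ids p1..p5
#   p1: no TEs anywhere
#   p2: CDS TE in species B only
#   p3: DOWN200 TE in species A only
#   p4: UP2000 TE in both species
#   p5: no TEs anywhere
universe_fixture <- function() {
  pairs <- data.frame(pair_id = paste0("p", 1:5),
                      gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                      stringsAsFactors = FALSE)
  recA <- data.frame(
    gene_id = c("a3", "a3", "a4"), te_id = c("tA1", "tA1", "tA2"),
    te_type = "DNA", region = c("DOWN200", "DOWN2000", "UP2000"),
    stringsAsFactors = FALSE
  )
  recB <- data.frame(
    gene_id = c("b2", "b4"), te_id = c("tB1", "tB2"), te_type = "DNA",
    region = c("CDS", "UP2000"), stringsAsFactors = FALSE
  )
  list(pairs = pairs, recA = recA, recB = recB)
}

test_that("universe filters reproduce the hand enumeration", {
  fx <- universe_fixture()
  # CDS tests use every pair
  expect_setequal(build_universe("CDS", fx$recA, fx$recB, fx$pairs),
                  paste0("p", 1:5))
  # other regions drop pairs with a CDS TE in either species (p2)
  for (r in c("UP2000", "INTRON", "DOWN2000", "DOWN200")) {
    expect_setequal(build_universe(r, fx$recA, fx$recB, fx$pairs),
                    c("p1", "p3", "p4", "p5"))
  }
  # DOWN200_2000 additionally drops the DOWN200 carrier p3
  expect_setequal(build_universe("DOWN200_2000", fx$recA, fx$recB, fx$pairs),
                  c("p1", "p4", "p5"))
  # no TEs anywhere: every universe is every pair
  none <- fx$recA[0, ]
  for (r in c("CDS", "UP2000", "INTRON", "DOWN2000",
              "DOWN200", "DOWN200_2000")) {
    expect_setequal(build_universe(r, none, none, fx$pairs), paste0("p", 1:5))
  }
  expect_error(build_universe("PROMOTER", none, none, fx$pairs), "unknown")
})

test_that("contingency construction does the stated set arithmetic", {
  universe <- paste0("u", 1:20)
  only_focal <- paste0("u", 1:6)
  direction <- c(paste0("u", 1:4), paste0("u", 7:9))
  tab <- build_te_deg_table(universe, only_focal, direction)
  expect_equal(unname(tab), c(4L, 2L, 3L, 11L))
  # empty direction column
  tab0 <- build_te_deg_table(universe, only_focal, character(0))
  expect_equal(unname(tab0[c("N11", "N21")]), c(0L, 0L))
  # degenerate: no comparison group
  expect_error(build_te_deg_table(universe, universe, direction),
               "comparison group")
  expect_error(build_te_deg_table(universe, c("zz", only_focal), direction),
               "subset")
})

test_that("fisher_exact matches enumeration and handles degeneracy", {
  got <- fisher_exact(c(3, 1, 1, 3))
  expect_equal(got$p, 34 / 70, tolerance = 1e-12)
  expect_equal(got$odds_ratio, 9)
  got2 <- fisher_exact(c(5, 5, 5, 5))
  expect_equal(got2$p, 1)
  expect_equal(got2$odds_ratio, 1)
  # zero margin
  gotd <- fisher_exact(c(0, 0, 3, 7))
  expect_true(gotd$degenerate)
  expect_equal(gotd$p, 1)
  # Haldane correction only when a zero cell exists
  gotz <- fisher_exact(c(0, 4, 5, 3))
  expect_equal(gotz$odds_ratio, (0.5 * 3.5) / (4.5 * 5.5))
  # random tables vs lchoose enumeration and stats::fisher.test
  set.seed(91)
  for (i in 1:200) {
    tab <- as.numeric(sample(0:25, 4, replace = TRUE))
    mine <- fisher_exact(tab)
    expect_equal(mine$p, oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    m <- matrix(tab, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(mine$p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
    }
  }
  expect_error(fisher_exact(c(-1, 1, 1, 1)), "non-negative")
})

test_that("TE-DEG scan recovers a planted enrichment and BH groups correctly", {
  set.seed(14)
  n <- 1200
  pairs <- data.frame(pair_id = sprintf("p%04d", 1:n),
                      gene_a = sprintf("a%04d", 1:n),
                      gene_b = sprintf("b%04d", 1:n), stringsAsFactors = FALSE)
  # direction truth: 25% higher_in_A per stage
  dirn <- sample(c("higher_in_A", "ns"), n, replace = TRUE, prob = c(0.25, 0.75))
  de <- do.call(rbind, lapply(c("L4", "YA"), function(st) {
    data.frame(pair_id = pairs$pair_id, stage = st, logFC = 0, logCPM = 5,
               p = 0.5, q = 0.5, direction = dirn, stringsAsFactors = FALSE)
  }))
  # intronic DNA TEs enriched in higher_in_A genes (odds ratio 3)
  base_odds <- 0.15 / 0.85
  p_hi <- base_odds * 3 / (1 + base_odds * 3)
  has_te <- ifelse(dirn == "higher_in_A", runif(n) < p_hi, runif(n) < 0.15)
  recA <- data.frame(gene_id = pairs$gene_a[has_te],
                     te_id = paste0("t", which(has_te)), te_type = "DNA",
                     region = "INTRON", stringsAsFactors = FALSE)
  recB <- recA[0, ]
  res <- run_te_deg_scan(de, recA, recB, pairs, focal = "A",
                         stages = "L4", te_types = c("DNA", "LINE"))
  row <- res[res$region == "INTRON" & res$te_type == "DNA" &
               res$direction == "higher", ]
  expect_gt(row$odds_ratio, 1)
  expect_lt(row$q, 0.05)
  expect_true(row$significant)
  # cells partition the universe
  expect_equal(row$N11 + row$N12 + row$N21 + row$N22, n)
  # BH grouping: q within (stage, focal, direction) equals p.adjust by hand
  grp <- res[res$direction == "higher", ]
  expect_equal(grp$q, p.adjust(grp$p, "BH"))

  # permuting DEG labels destroys the signal
  de_perm <- de
  de_perm$direction <- sample(de$direction)
  res_p <- run_te_deg_scan(de_perm, recA, recB, pairs, focal = "A",
                           stages = "L4", te_types = "DNA",
                           regions = "INTRON")
  expect_gte(res_p$q[1L], 0.05)
})

test_that("conserved filter changes only_focal membership in the scan", {
  fx <- universe_fixture()
  de <- data.frame(pair_id = fx$pairs$pair_id, stage = "L4", logFC = 1,
                   logCPM = 5, p = 0.01, q = 0.01,
                   direction = c("higher_in_A", "ns", "higher_in_A", "ns", "ns"),
                   stringsAsFactors = FALSE)
  res_all <- run_te_deg_scan(de, fx$recA, fx$recB, fx$pairs,
                             regions = "DOWN200", te_types = "DNA",
                             directions = "higher")
  expect_equal(res_all$N11[1L], 1L)  # p3 carries the DOWN200 TE and is a DEG
  res_f <- run_te_deg_scan(de, fx$recA, fx$recB, fx$pairs,
                           conserved_filter = "none_conserved",
                           regions = "DOWN200", te_types = "DNA",
                           directions = "higher")
  expect_equal(res_f$N11[1L], 0L)
})

test_that("planted odds ratios in {2, 3, 5} are recovered within 30%", {
  n <- 3000
  universe <- sprintf("u%04d", 1:n)
  base_rate <- 0.12
  for (or_true in c(2, 3, 5)) {
    ok_runs <- 0L
    for (run in 1:20) {
      set.seed(3000 * or_true + run)
      dirn <- runif(n) < 0.3
      odds <- base_rate / (1 - base_rate)
      p_dir <- odds * or_true / (1 + odds * or_true)
      bearing <- runif(n) < ifelse(dirn, p_dir, base_rate)
      tab <- build_te_deg_table(universe, universe[bearing],
                                universe[dirn])
      ft <- fisher_exact(tab)
      or_ok <- abs(log(ft$odds_ratio) - log(or_true)) <= log(1.3)
      # q across a 30-test scan is at worst p * 30 (BH upper bound)
      detected <- min(1, ft$p * 30) < 0.05
      if (or_ok && detected) ok_runs <- ok_runs + 1L
      expect_gte(sum(bearing), 300)
    }
    expect_gte(ok_runs / 20, 0.9)
  }
})

test_that("cluster-TE scan flags a planted cluster association", {
  set.seed(15)
  n <- 600
  pairs <- data.frame(pair_id = sprintf("p%03d", 1:n),
                      gene_a = sprintf("a%03d", 1:n),
                      gene_b = sprintf("b%03d", 1:n), stringsAsFactors = FALSE)
  cl <- sample(1:3, n, replace = TRUE)
  # TE-bearing genes concentrated in cluster 2
  has_te <- runif(n) < ifelse(cl == 2L, 0.5, 0.08)
  recA <- data.frame(gene_id = pairs$gene_a[has_te],
                     te_id = paste0("t", which(has_te)), te_type = "DNA",
                     region = "INTRON", stringsAsFactors = FALSE)
  assign <- data.frame(pair_id = pairs$pair_id, cluster = cl,
                       stringsAsFactors = FALSE)
  res <- run_cluster_te_scan(assign, recA, recA[0, ], pairs,
                             regions = "INTRON", te_types = "DNA")
  sig <- res[res$cluster == 2L, ]
  expect_lt(sig$q, 0.05)
  expect_gt(sig$odds_ratio, 1)
  # row/column cells cover the universe for each cluster row
  expect_equal(unique(res$N11 + res$N12 + res$N21 + res$N22), n)
})
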
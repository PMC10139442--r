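#' Synthetic pipeline inputs with known ground truth
#'
#' Emulates, post-mapping, everything the pipeline consumes: a pair of
#' genomes with one-to-one orthologous gene models plus decoy duplicates, TE
#' insertions of five classes in six gene-relative regions with configurable
#' species-specificity and population conservation, negative-binomial counts
#' with species/stage effects and optional TE-linked boosts, and read
#' alignment blocks that do or do not span TE boundaries. Nucleotide
#' sequence, sequencing error and mapper behaviour are not simulated.
#'
#' @name synthetic_data
NULL

#' Default per-gene TE insertion rates
#'
#' One row per (region, TE type) giving the per-gene insertion probability
#' in each species. Regions `DOWN200` and `DOWN200_2000` are placed inside
#' their sub-window, so they also produce `DOWN2000` overlaps, as on a real
#' genome.
#'
#' @param rate_A,rate_B default probability for every combination
#' @param regions placeable regions
#' @return data.frame `region`, `te_type`, `rate_A`, `rate_B`
#' @export
default_te_rates <- function(rate_A = 0.03, rate_B = 0.03,
                             regions = c("CDS", "UP2000", "INTRON",
                                         "DOWN200", "DOWN200_2000")) {
  grid <- expand.grid(region = regions, te_type = TE_TYPES,
                      stringsAsFactors = FALSE)
  grid$rate_A <- rate_A
  grid$rate_B <- rate_B
  grid
}

#' Simulation configuration
#'
#' Defaults mirror the study design this pipeline emulates: 4 replicates per
#' species per stage (16 RNA-seq samples), stages L4 and young adult, 8
#' resequenced populations, 150-bp reads, and an interspecific log2
#' fold-change of 2 for true DEGs at FDR 1e-5.
#'
#' @param seed master seed; every stream derives from it
#' @param n_genes genes per species (>= 1)
#' @param n_samples_per_group replicates per (species, stage)
#' @param stages,species group labels (species A = focal)
#' @param nb_mean_log_range natural-log range of baseline NB means
#' @param nb_dispersion common NB dispersion phi (>= 0; 0 = Poisson)
#' @param frac_deg fraction of pairs with a true species effect
#' @param logfc_effect |log2 fold change| of true DEGs
#' @param frac_stage fraction of pairs with a stage effect
#' @param stage_logfc |log2 fold change| of the stage effect
#' @param te_rates data.frame from [default_te_rates()]
#' @param te_effect_beta multiplicative species-A expression boost attached
#'   to TE-boosted genes (1 = none)
#' @param te_boost_region,te_boost_type which planted insertions receive the
#'   boost (defaults: intronic DNA transposons)
#' @param te_enrichment optional list(`region`, `te_type`, `odds_ratio`)
#'   biasing species-A placements of that combination toward true
#'   higher-in-A DEGs with the given odds
#' @param n_populations populations carrying the focal species
#' @param lines_per_population isofemale lines per population
#' @param read_length read length in bp (>= 20)
#' @param conservation_prob probability a focal TE is present in each
#'   population (1 = conserved everywhere)
#' @param lib_factor_sd log-normal sd of library-size factors
#' @param frac_pair fraction of genes forming true one-to-one pairs
#'   (remainder become duplicated-best-hit decoys, in blocks of two per
#'   species)
#' @param len_b_factor species-B total exonic length = shared transcript
#'   length x this factor (extra non-coding exon), exercising length
#'   correction
#' @param crowding if TRUE genes are packed closely so 2,000-bp flanks can
#'   collide; default keeps all adjacent gene regions > 4,000 bp apart
#' @param n_cds_range,cds_len_range,intron_len_range,te_len_range structural
#'   ranges in bp
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000,
                       n_samples_per_group = 4,
                       stages = c("L4", "YA"),
                       species = c("A", "B"),
                       nb_mean_log_range = c(log(20), log(500)),
                       nb_dispersion = 0.05,
                       frac_deg = 0.3,
                       logfc_effect = 2,
                       frac_stage = 0.2,
                       stage_logfc = 1,
                       te_rates = default_te_rates(),
                       te_effect_beta = 1,
                       te_boost_region = "INTRON",
                       te_boost_type = "DNA",
                       te_enrichment = NULL,
                       n_populations = 8,
                       lines_per_population = 7,
                       read_length = 150,
                       conservation_prob = 1,
                       lib_factor_sd = 0.15,
                       frac_pair = 0.95,
                       len_b_factor = 1.25,
                       crowding = FALSE,
                       n_cds_range = c(2, 4),
                       cds_len_range = c(150, 600),
                       intron_len_range = c(60, 400),
                       te_len_range = c(100, 1200)) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (read_length < 20) stop("read_length must be >= 20")
  probs <- c(frac_deg, frac_stage, frac_pair, conservation_prob,
             te_rates$rate_A, te_rates$rate_B)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Gene placement grid: one chromosome per 100 genes, 1-Mb slots (10-kb slots
# under crowding).
gene_grid <- function(n_genes, crowding) {
  per_chrom <- 100L
  spacing <- if (crowding) 10000 else 1e6
  chrom <- paste0("chr", (seq_len(n_genes) - 1L) %/% per_chrom + 1L)
  slot <- (seq_len(n_genes) - 1L) %% per_chrom
  list(chrom = chrom, start = slot * spacing + 10000, spacing = spacing)
}

#' Simulate a pair of genomes with one-to-one orthologous gene models
#'
#' True pairs share an identical CDS structure (the "shared transcript");
#' species B gains an extra non-coding exon so the two annotated exonic
#' lengths differ by `len_b_factor`. Decoy genes come in blocks of two per
#' species arranged so one B gene is the best hit of two A genes,
#' exercising the multi-best exclusion rule; decoys form no true pair.
#' Also returns the pairwise bitscore table the orthology stage consumes.
#'
#' @param config [sim_config()]
#' @return list: `genes_A`, `genes_B` (gene-model tables), `ortholog_truth`
#'   (`pair_id`, `gene_a`, `gene_b`), `similarity` (`gene_a`, `gene_b`,
#'   `bitscore`), `chrom_lens`
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  n_decoy_blocks <- floor(n * (1 - config$frac_pair) / 2)
  n_true <- n - 2L * n_decoy_blocks
  with_seed(derive_seed(config$seed, "genome"), {
    grid <- gene_grid(n, config$crowding)
    build_gene <- function(gid, chrom, start, strand, extra_exon = 0) {
      k <- sample(config$n_cds_range[1L]:config$n_cds_range[2L], 1L)
      cds_len <- sample(config$cds_len_range[1L]:config$cds_len_range[2L], k,
                        replace = TRUE)
      intron_len <- if (k > 1L) {
        sample(config$intron_len_range[1L]:config$intron_len_range[2L],
               k - 1L, replace = TRUE)
      } else integer(0)
      s <- start
      rows <- list()
      for (i in seq_len(k)) {
        e <- s + cds_len[i]
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, strand = strand, feature = "CDS",
          start = s, end = e, stringsAsFactors = FALSE
        )
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, strand = strand, feature = "exon",
          start = s, end = e, stringsAsFactors = FALSE
        )
        if (i < k) s <- e + intron_len[i]
      }
      last_end <- rows[[length(rows)]]$end
      if (extra_exon > 0) {
        # extra annotated (non-coding) exon just downstream of the last CDS
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = chrom, strand = strand, feature = "exon",
          start = last_end, end = last_end + extra_exon,
          stringsAsFactors = FALSE
        )
      }
      do.call(rbind, rows)
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    genes_A <- list()
    genes_B <- list()
    pairs <- list()
    sim_rows <- list()
    hi_score <- function() round(runif(1L, 400, 800), 1)
    for (i in seq_len(n_true)) {
      ga <- sprintf("gA%04d", i)
      gb <- sprintf("gB%04d", i)
      gene_a <- build_gene(ga, grid$chrom[i], grid$start[i], strands[i])
      cds_total <- sum(gene_a$end[gene_a$feature == "CDS"] -
                         gene_a$start[gene_a$feature == "CDS"])
      extra <- round((config$len_b_factor - 1) * cds_total)
      # species B shares the transcript structure, plus an extra exon
      gene_b <- gene_a
      gene_b$gene_id <- gb
      if (extra > 0) {
        le <- max(gene_a$end)
        gene_b <- rbind(gene_b, data.frame(
          gene_id = gb, chrom = grid$chrom[i], strand = strands[i],
          feature = "exon", start = le, end = le + extra,
          stringsAsFactors = FALSE
        ))
      }
      genes_A[[ga]] <- gene_a
      genes_B[[gb]] <- gene_b
      pairs[[i]] <- data.frame(pair_id = ga, gene_a = ga, gene_b = gb,
                               stringsAsFactors = FALSE)
      top <- hi_score()
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, bitscore = top, stringsAsFactors = FALSE
      )
      # background off-target hit, well below the true score
      other <- if (i > 1L) sprintf("gB%04d", i - 1L) else sprintf("gB%04d", min(n_true, i + 1L))
      if (other != gb) {
        sim_rows[[length(sim_rows) + 1L]] <- data.frame(
          gene_a = ga, gene_b = other, bitscore = round(top * runif(1L, 0.05, 0.3), 1),
          stringsAsFactors = FALSE
        )
      }
    }
    # decoy blocks: dA1, dA2 both best-hit dB1 (dB1's best = dA1); dB2's
    # best is dA2 but dA2's best is dB1 -> no reciprocal pair survives
    for (bidx in seq_len(n_decoy_blocks)) {
      i1 <- n_true + 2L * bidx - 1L
      i2 <- n_true + 2L * bidx
      da1 <- sprintf("gA%04d", i1); da2 <- sprintf("gA%04d", i2)
      db1 <- sprintf("gB%04d", i1); db2 <- sprintf("gB%04d", i2)
      genes_A[[da1]] <- build_gene(da1, grid$chrom[i1], grid$start[i1], strands[i1])
      genes_A[[da2]] <- build_gene(da2, grid$chrom[i2], grid$start[i2], strands[i2])
      genes_B[[db1]] <- build_gene(db1, grid$chrom[i1], grid$start[i1], strands[i1])
      genes_B[[db2]] <- build_gene(db2, grid$chrom[i2], grid$start[i2], strands[i2])
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        gene_a = c(da1, da2, da2), gene_b = c(db1, db1, db2),
        bitscore = c(320, 310, 250), stringsAsFactors = FALSE
      )
    }
    genes_A <- do.call(rbind, unname(genes_A))
    genes_B <- do.call(rbind, unname(genes_B))
    rownames(genes_A) <- rownames(genes_B) <- NULL
    chroms <- unique(grid$chrom)
    chrom_lens <- setNames(
      rep(100 * grid$spacing + 2e5, length(chroms)), chroms
    )
    list(
      genes_A = genes_A, genes_B = genes_B,
      ortholog_truth = do.call(rbind, pairs),
      similarity = do.call(rbind, sim_rows),
      chrom_lens = as.list(chrom_lens)
    )
  })
}

#' Plan the true DEG assignment
#'
#' Deterministic given the config seed, so TE placement (which may be
#' enriched in true DEGs) and count simulation agree on the planted truth.
#' A true DEG carries its species effect in both stages with a single
#' direction.
#'
#' @param config [sim_config()]
#' @param ortholog_truth pair table from [simulate_genome_pair()]
#' @return data.frame `pair_id`, `is_deg`, `direction`
#'   (`higher_in_A`/`higher_in_B`/`ns`)
#' @export
plan_deg_truth <- function(config, ortholog_truth) {
  with_seed(derive_seed(config$seed, "deg-truth"), {
    n <- nrow(ortholog_truth)
    is_deg <- runif(n) < config$frac_deg & config$logfc_effect != 0
    dirn <- ifelse(is_deg,
                   ifelse(runif(n) < 0.5, "higher_in_A", "higher_in_B"), "ns")
    data.frame(pair_id = ortholog_truth$pair_id, is_deg = is_deg,
               direction = dirn, stringsAsFactors = FALSE)
  })
}

# Pick a placement interval for a TE intended for `region` of one gene.
# Returns c(start, end) or NULL when the region does not exist.
place_te_in_region <- function(regs, region, te_len_range) {
  iv <- regs[[region]]
  if (is.null(iv) || nrow(iv) == 0L) return(NULL)
  row <- iv[sample.int(nrow(iv), 1L), ]
  width <- row[2L] - row[1L]
  len <- min(sample(te_len_range[1L]:te_len_range[2L], 1L), width)
  start <- row[1L] + if (width > len) sample.int(width - len + 1L, 1L) - 1L else 0L
  c(start, start + len)
}

#' Simulate TE landscapes for both species
#'
#' Places TEs per (region, TE type) rate row and per species, fully inside
#' the intended region interval so the planted label is recoverable.
#' Impossible requests (e.g. intron of a single-CDS gene) are skipped with a
#' message. When `config$te_enrichment` is set, species-A placements of that
#' (region, type) are biased toward true higher-in-A DEGs with the requested
#' odds ratio while keeping the marginal rate. The conservation map marks,
#' for each species-A TE, the populations carrying it
#' (`conservation_prob` per population; 1 = all).
#'
#' @param config [sim_config()]
#' @param genes_A,genes_B gene-model tables
#' @param deg_truth optional [plan_deg_truth()] output (computed on demand
#'   when enrichment is requested)
#' @return list: `tes_A`, `tes_B` (TE tables), `placements_A`,
#'   `placements_B` (planted `gene_id`, `te_id`, `te_type`, `region`),
#'   `conservation_map` (logical matrix TEs x populations)
#' @export
simulate_te_landscape <- function(config, genes_A, genes_B, deg_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$te_rates
  enr <- config$te_enrichment
  if (!is.null(enr) && is.null(deg_truth)) {
    stop("te_enrichment requires deg_truth (see plan_deg_truth)")
  }
  higher_a <- if (!is.null(deg_truth)) {
    deg_truth$pair_id[deg_truth$direction == "higher_in_A"]
  } else character(0)
  with_seed(derive_seed(config$seed, "te-landscape"), {
    one_species <- function(genes, rate_col, id_prefix, enrich) {
      cds <- genes[genes$feature == "CDS", , drop = FALSE]
      by_gene <- split(cds, cds$gene_id)
      tes <- list()
      plc <- list()
      skipped <- 0L
      k <- 0L
      for (gid in names(by_gene)) {
        g <- by_gene[[gid]]
        regs <- build_regions(cbind(g$start, g$end), g$strand[1L])
        for (ri in seq_len(nrow(rates))) {
          rate <- rates[[rate_col]][ri]
          region <- rates$region[ri]
          if (enrich && region == enr$region && rates$te_type[ri] == enr$te_type) {
            # odds-ratio-biased rate keeping the same order of magnitude
            odds <- rate / (1 - rate)
            rate <- if (gid %in% higher_a) {
              (odds * enr$odds_ratio) / (1 + odds * enr$odds_ratio)
            } else rate
          }
          if (rate <= 0 || runif(1L) >= rate) next
          pos <- place_te_in_region(regs, region, config$te_len_range)
          if (is.null(pos)) {
            skipped <- skipped + 1L
            next
          }
          k <- k + 1L
          te_id <- sprintf("%s%05d", id_prefix, k)
          tes[[k]] <- data.frame(
            te_id = te_id, chrom = g$chrom[1L], start = pos[1L], end = pos[2L],
            te_type = rates$te_type[ri], strand = "+", stringsAsFactors = FALSE
          )
          plc[[k]] <- data.frame(
            gene_id = gid, te_id = te_id, te_type = rates$te_type[ri],
            region = region, stringsAsFactors = FALSE
          )
        }
      }
      if (skipped > 0L) {
        message(skipped, " placement(s) skipped: region absent for gene")
      }
      empty_te <- data.frame(te_id = character(0), chrom = character(0),
                             start = numeric(0), end = numeric(0),
                             te_type = character(0), strand = character(0))
      empty_plc <- data.frame(gene_id = character(0), te_id = character(0),
                              te_type = character(0), region = character(0))
      list(tes = if (k > 0L) do.call(rbind, tes) else empty_te,
           placements = if (k > 0L) do.call(rbind, plc) else empty_plc)
    }
    a <- one_species(genes_A, "rate_A", "teA", enrich = !is.null(enr))
    b <- one_species(genes_B, "rate_B", "teB", enrich = FALSE)
    pops <- paste0("pop", seq_len(config$n_populations))
    cm <- matrix(runif(nrow(a$tes) * length(pops)) < config$conservation_prob,
                 nrow = nrow(a$tes), ncol = length(pops),
                 dimnames = list(a$tes$te_id, pops))
    list(tes_A = a$tes, tes_B = b$tes,
         placements_A = a$placements, placements_B = b$placements,
         conservation_map = cm)
  })
}

#' Simulate negative-binomial counts with planted effects
#'
#' Counts are drawn on the pair's shared transcript: a per-pair baseline
#' mean (log-uniform), a species effect `2^(+/- logfc_effect)` for true
#' DEGs, a stage effect for a fraction of pairs, a multiplicative
#' `te_effect_beta` in species A for TE-boosted genes, and per-sample
#' library factors. `phi = 0` gives Poisson counts.
#'
#' @param config [sim_config()]
#' @param ortholog_truth pair table
#' @param deg_truth defaults to [plan_deg_truth()]
#' @param te_boost_genes pair ids receiving the species-A TE boost
#' @return list: `counts` (integer matrix pairs x samples), `meta`
#'   (`sample_id`, `species`, `stage`, `replicate`), `ground_truth`
#'   (list: `deg`, `te_boost_genes`, `lib_factors`)
#' @export
simulate_counts <- function(config, ortholog_truth,
                            deg_truth = plan_deg_truth(config, ortholog_truth),
                            te_boost_genes = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  n <- nrow(ortholog_truth)
  reps <- config$n_samples_per_group
  meta <- expand.grid(
    replicate = seq_len(reps), stage = config$stages, species = config$species,
    stringsAsFactors = FALSE
  )[, c("species", "stage", "replicate")]
  meta$sample_id <- paste(meta$species, meta$stage, meta$replicate, sep = "_")
  meta <- meta[, c("sample_id", "species", "stage", "replicate")]
  with_seed(derive_seed(config$seed, "counts"), {
    base <- exp(runif(n, config$nb_mean_log_range[1L], config$nb_mean_log_range[2L]))
    stage_gene <- runif(n) < config$frac_stage
    stage_dir <- ifelse(runif(n) < 0.5, 1, -1)
    lib <- exp(rnorm(nrow(meta), 0, config$lib_factor_sd))
    sp_mult <- matrix(1, n, nrow(meta))
    deg_sign <- ifelse(deg_truth$direction == "higher_in_A", 1,
                       ifelse(deg_truth$direction == "higher_in_B", -1, 0))
    boost <- ortholog_truth$pair_id %in% te_boost_genes
    counts <- matrix(0L, n, nrow(meta),
                     dimnames = list(ortholog_truth$pair_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- base
      if (meta$species[j] == "A") {
        mu <- mu * 2^(deg_sign * config$logfc_effect)
        mu <- mu * ifelse(boost, config$te_effect_beta, 1)
      }
      if (meta$stage[j] == config$stages[2L]) {
        mu <- mu * ifelse(stage_gene, 2^(stage_dir * config$stage_logfc), 1)
      }
      mu <- mu * lib[j]
      counts[, j] <- if (config$nb_dispersion == 0) {
        rpois(n, mu)
      } else {
        rnbinom(n, size = 1 / config$nb_dispersion, mu = mu)
      }
    }
    deg_out <- do.call(rbind, lapply(config$stages, function(st) {
      data.frame(pair_id = deg_truth$pair_id, stage = st,
                 direction = deg_truth$direction, stringsAsFactors = FALSE)
    }))
    deg_out <- deg_out[deg_out$direction != "ns", , drop = FALSE]
    list(
      counts = counts, meta = meta,
      ground_truth = list(deg = deg_out, te_boost_genes = te_boost_genes,
                          lib_factors = setNames(lib, meta$sample_id))
    )
  })
}

#' Simulate population read-alignment blocks around TE boundaries
#'
#' For every TE present in a population (per the conservation map), one line
#' contributes a proper, unique read pair whose spanning mate continuously
#' covers >= 10 bp on both sides of a boundary. For absent TEs the emitted
#' reads stop at, or gap >= 5 bp across, the boundary, so no support exists.
#' Decoy pairs (one mate unmapped; both mates inside the TE) are added to
#' exercise the pair filter — the unmapped-mate decoy's mapped mate spans a
#' boundary, so skipping the filter would create false presence calls.
#'
#' @param config [sim_config()]
#' @param tes_A species-A TE table
#' @param conservation_map logical matrix (TEs x populations)
#' @return alignment-block table (see [filter_read_pairs()])
#' @export
simulate_population_reads <- function(config, tes_A, conservation_map) {
  stopifnot(inherits(config, "sim_config"))
  if (config$read_length < 20) stop("read_length must be >= 20")
  rl <- config$read_length
  pops <- colnames(conservation_map)
  half <- floor(rl / 2)
  # all TE boundary positions per chromosome: non-spanning reads must not
  # accidentally support any of them, or absent TEs would look present
  bounds <- split(c(tes_A$start, tes_A$end), rep(tes_A$chrom, 2L))
  supports_any <- function(blocks, chrom) {
    bs <- bounds[[chrom]]
    if (is.null(bs)) return(FALSE)
    covered <- 0
    for (i in seq_len(nrow(blocks))) {
      covered <- covered + pmax(0, pmin(blocks[i, 2L], bs + 10) -
                                   pmax(blocks[i, 1L], bs - 10))
    }
    any(covered >= 16)
  }
  # first offset in `tries` whose single block is support-free, else NA
  clean_offset <- function(pos, tries, chrom, width = rl) {
    for (off in tries) {
      if (!supports_any(cbind(pos + off, pos + off + width), chrom)) {
        return(off)
      }
    }
    NA_real_
  }
  rows <- vector("list", 0L)
  add <- function(read_id, mate, line, pop, chrom, blocks, mapped = TRUE,
                  proper = TRUE, uniq = TRUE) {
    rows[[length(rows) + 1L]] <<- list(
      read_id = read_id, mate = mate, line_id = line, population = pop,
      chrom = chrom, blocks = blocks, mapped = mapped, proper_pair = proper,
      unique = uniq
    )
  }
  with_seed(derive_seed(config$seed, "population-reads"), {
    for (ti in seq_len(nrow(tes_A))) {
      te <- list(te_id = tes_A$te_id[ti], chrom = tes_A$chrom[ti],
                 start = tes_A$start[ti], end = tes_A$end[ti])
      # support-free placements depend on the TE only; hoist out of the
      # population loop
      offL <- clean_offset(te$start, -c(400, 700, 1000, 1300, 1600), te$chrom)
      if (is.na(offL)) offL <- -400
      offR <- clean_offset(te$end, c(250, 550, 850, 1150, 1450), te$chrom)
      if (is.na(offR)) offR <- 250
      anchor_off <- clean_offset(te$start, -c(400, 700, 1000, 1300, 1600),
                                 te$chrom)
      anchor <- if (is.na(anchor_off)) NULL else {
        cbind(te$start + anchor_off, te$start + anchor_off + rl)
      }
      stop_len <- NA_real_
      for (L in c(rl, 60, 25)) {
        if (!supports_any(cbind(te$start - L, te$start), te$chrom)) {
          stop_len <- L
          break
        }
      }
      gap_blocks <- rbind(c(te$start - half, te$start - 3),
                          c(te$start + 2, te$start + half))
      gap_ok <- !supports_any(gap_blocks, te$chrom)
      for (pop in pops) {
        line <- paste0(pop, "_line1")
        present <- conservation_map[ti, pop]
        if (present) {
          # spanning pairs at both boundaries; either suffices for presence,
          # and redundancy keeps recovery noise-free when a flanking repeat
          # swallows one of the anchor mates
          rid <- paste0("rd_", te$te_id, "_", pop, "_spanL")
          add(rid, 1L, line, pop, te$chrom,
              encode_blocks(cbind(te$start - half, te$start + half)))
          add(rid, 2L, line, pop, te$chrom,
              encode_blocks(cbind(te$start + offL, te$start + offL + rl)))
          rid_r <- paste0("rd_", te$te_id, "_", pop, "_spanR")
          add(rid_r, 1L, line, pop, te$chrom,
              encode_blocks(cbind(te$end - half, te$end + half)))
          add(rid_r, 2L, line, pop, te$chrom,
              encode_blocks(cbind(te$end + offR, te$end + offR + rl)))
        } else {
          # read stopping exactly at the boundary: zero coverage inside;
          # shortened (or skipped) when its body would span another TE edge
          if (!is.na(stop_len) && !is.null(anchor)) {
            rid <- paste0("rd_", te$te_id, "_", pop, "_stop")
            add(rid, 1L, line, pop, te$chrom,
                encode_blocks(cbind(te$start - stop_len, te$start)))
            add(rid, 2L, line, pop, te$chrom, encode_blocks(anchor))
          }
          # gapped read: blocks leave a 5-bp hole across the boundary
          if (gap_ok && !is.null(anchor)) {
            rid2 <- paste0("rd_", te$te_id, "_", pop, "_gap")
            add(rid2, 1L, line, pop, te$chrom, encode_blocks(gap_blocks))
            add(rid2, 2L, line, pop, te$chrom, encode_blocks(anchor))
          }
          # decoy: mapped mate spans the right boundary but its mate is
          # unmapped -> the pair must be filtered out
          rid3 <- paste0("rd_", te$te_id, "_", pop, "_oneside")
          add(rid3, 1L, line, pop, te$chrom,
              encode_blocks(cbind(te$end - half, te$end + half)))
          add(rid3, 2L, line, pop, te$chrom, "", mapped = FALSE)
        }
        # repeat-internal decoy pair (both mates inside the TE)
        if (te$end - te$start >= 2 * rl) {
          rid4 <- paste0("rd_", te$te_id, "_", pop, "_internal")
          add(rid4, 1L, line, pop, te$chrom,
              encode_blocks(cbind(te$start + 1, te$start + 1 + rl)))
          add(rid4, 2L, line, pop, te$chrom,
              encode_blocks(cbind(te$end - 1 - rl, te$end - 1)))
        }
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(read_id = character(0), mate = integer(0),
                        line_id = character(0), population = character(0),
                        chrom = character(0), blocks = character(0),
                        mapped = logical(0), proper_pair = logical(0),
                        unique = logical(0), stringsAsFactors = FALSE))
    }
    out <- as.data.frame(data.table::rbindlist(rows))
    rownames(out) <- NULL
    out
  })
}

#' Write all simulated inputs to a directory
#'
#' Emits the on-disk forms every stage consumes: GFF3 gene models, TE BED
#' and RepeatMasker `.out`, counts and metadata TSV, similarity TSV,
#' alignment-block TSV, and ground-truth TSVs. Byte-deterministic for a
#' fixed config.
#'
#' @param config [sim_config()]
#' @param dir output directory (created if needed)
#' @return list of generated objects, invisibly (paths in `$paths`)
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome_pair(config)
  deg_truth <- plan_deg_truth(config, genome$ortholog_truth)
  land <- simulate_te_landscape(config, genome$genes_A, genome$genes_B,
                                deg_truth = deg_truth)
  boosted <- if (config$te_effect_beta != 1) {
    unique(land$placements_A$gene_id[
      land$placements_A$region == config$te_boost_region &
        land$placements_A$te_type == config$te_boost_type
    ])
  } else character(0)
  cnt <- simulate_counts(config, genome$ortholog_truth, deg_truth, boosted)
  reads <- simulate_population_reads(config, land$tes_A, land$conservation_map)
  p <- function(f) file.path(dir, f)
  paths <- list(
    genes_A = p("genes_A.gff3"), genes_B = p("genes_B.gff3"),
    tes_A_bed = p("tes_A.bed"), tes_B_bed = p("tes_B.bed"),
    tes_A_out = p("tes_A.out"), tes_B_out = p("tes_B.out"),
    counts = p("counts.tsv"), meta = p("samples.tsv"),
    similarity = p("similarity.tsv"), alignments = p("alignments.tsv"),
    truth_deg = p("truth_deg.tsv"), truth_pairs = p("truth_pairs.tsv"),
    truth_placements = p("truth_placements_A.tsv"),
    truth_conservation = p("truth_conservation.tsv")
  )
  write_gff3(genome$genes_A, paths$genes_A)
  write_gff3(genome$genes_B, paths$genes_B)
  write_te_bed(land$tes_A, paths$tes_A_bed)
  write_te_bed(land$tes_B, paths$tes_B_bed)
  write_rm_out(land$tes_A, paths$tes_A_out)
  write_rm_out(land$tes_B, paths$tes_B_out)
  write_counts_tsv(cnt$counts, paths$counts)
  write_tsv(cnt$meta, paths$meta)
  write_tsv(genome$similarity, paths$similarity)
  write_tsv(reads, paths$alignments)
  write_tsv(cnt$ground_truth$deg, paths$truth_deg)
  write_tsv(genome$ortholog_truth, paths$truth_pairs)
  write_tsv(land$placements_A, paths$truth_placements)
  cons <- data.frame(te_id = rownames(land$conservation_map),
                     land$conservation_map, row.names = NULL)
  write_tsv(cons, paths$truth_conservation)
  invisible(list(config = config, genome = genome, landscape = land,
                 expression = cnt, reads = reads, deg_truth = deg_truth,
                 paths = paths))
}
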
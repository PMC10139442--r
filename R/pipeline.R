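#' End-to-end pipeline orchestration
#'
#' Runs orthology, per-stage differential expression, clustering, TE
#' insertion classification, conserved-TE calling and the association scans
#' from a single configuration, writing fixed-name TSV outputs and a
#' machine-readable run report. All randomness derives from one seed.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory
#' @param seed master seed
#' @param simulate if TRUE, inputs are generated with [simulate_to_dir()]
#'   using `sim` (a [sim_config()]); otherwise `inputs` must name existing
#'   files (`counts`, `meta`, `similarity`, `genes_A`, `genes_B`, `tes_A`,
#'   `tes_B`, `alignments`)
#' @param sim optional [sim_config()] for simulation mode
#' @param inputs named list of input paths (non-simulation mode)
#' @param alpha_deg DEG FDR threshold (default 1e-5)
#' @param alpha_assoc significance flag threshold for association q-values
#' @param alpha_assoc_report report filter: rows with q below this are
#'   echoed in the run report (default 0.1)
#' @param kmax,gap_B gap-statistic parameters
#' @param use_conserved_filter apply the conserved-TE filter to focal
#'   (species A) insertions in the association scans
#' @param min_lines minimum supporting lines per population
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE, sim = NULL,
                            inputs = NULL, alpha_deg = 1e-5,
                            alpha_assoc = 0.05, alpha_assoc_report = 0.1,
                            kmax = 20, gap_B = 100,
                            use_conserved_filter = TRUE, min_lines = 1L) {
  stopifnot(alpha_deg > 0, alpha_deg < 1, alpha_assoc > 0, alpha_assoc < 1,
            kmax >= 1)
  if (simulate && is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Stage order: orthology -> expression (each stage) -> clustering ->
#' TE annotation -> conserved TEs -> association. Any stage failure aborts
#' with a stage-named error; outputs written so far are retained.
#' Idempotent for a fixed config and seed.
#'
#' @param config [pipeline_config()]
#' @return list with all stage results and `report` (row counts per stage)
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inp <- stage("inputs", {
    if (config$simulate) {
      sim <- simulate_to_dir(config$sim, file.path(config$out_dir, "inputs"))
      list(
        counts = sim$expression$counts, meta = sim$expression$meta,
        similarity = sim$genome$similarity,
        genes_A = sim$genome$genes_A, genes_B = sim$genome$genes_B,
        tes_A = sim$landscape$tes_A, tes_B = sim$landscape$tes_B,
        alignments = sim$reads,
        populations = colnames(sim$landscape$conservation_map)
      )
    } else {
      f <- config$inputs
      aln <- read_tsv(f$alignments)
      list(
        counts = read_counts_tsv(f$counts), meta = read_tsv(f$meta),
        similarity = read_tsv(f$similarity),
        genes_A = read_gff3(f$genes_A), genes_B = read_gff3(f$genes_B),
        tes_A = if (grepl("\\.out$", f$tes_A)) read_rm_out(f$tes_A) else read_te_bed(f$tes_A),
        tes_B = if (grepl("\\.out$", f$tes_B)) read_rm_out(f$tes_B) else read_te_bed(f$tes_B),
        alignments = aln,
        populations = sort(unique(aln$population))
      )
    }
  })
  out <- function(f) file.path(config$out_dir, f)

  pairs <- stage("orthology", {
    rb <- reciprocal_best_pairs(inp$similarity)
    attach_lengths(rb, inp$genes_A, inp$genes_B)
  })
  write_tsv(pairs, out("orthologs.tsv"))

  counts <- inp$counts[rownames(inp$counts) %in% pairs$pair_id, , drop = FALSE]
  stages <- unique(inp$meta$stage)
  de <- stage("expression", {
    do.call(rbind, lapply(stages, function(st) {
      call_degs(counts, inp$meta, pairs, st, alpha = config$alpha_deg)
    }))
  })
  write_tsv(de, out("de.tsv"))
  tpm <- stage("expression", compute_tpm(counts, inp$meta, pairs))
  write_counts_tsv(tpm, out("tpm.tsv"))
  pca <- stage("expression", {
    pca_variance_explained(corrected_cpm(length_correct(counts, pairs)))
  })
  write_tsv(data.frame(component = seq_along(pca$fractions),
                       fraction = pca$fractions), out("pca.tsv"))

  clust <- stage("clustering", {
    cluster_deg_profiles(tpm, de, inp$meta, kmax = config$kmax,
                         B = config$gap_B,
                         seed = derive_seed(config$seed, "clustering"))
  })
  write_tsv(clust$assignments, out("clusters.tsv"))
  write_tsv(clust$gap$table, out("gap.tsv"))

  records <- stage("te_annotation", {
    list(A = classify_te_insertions(inp$genes_A, inp$tes_A),
         B = classify_te_insertions(inp$genes_B, inp$tes_B))
  })
  write_tsv(records$A, out("insertions_A.tsv"))
  write_tsv(records$B, out("insertions_B.tsv"))

  cons <- stage("conserved_te", {
    if (nrow(inp$alignments) > 0L && nrow(inp$tes_A) > 0L) {
      conserved_set(inp$tes_A, inp$alignments, inp$populations,
                    min_lines = config$min_lines)
    } else {
      list(presence = NULL, calls = NULL, conserved = character(0))
    }
  })
  if (!is.null(cons$calls)) write_tsv(cons$calls, out("conserved.tsv"))

  filt <- if (config$use_conserved_filter) cons$conserved else NULL
  assoc <- stage("association", {
    run_te_deg_scan(de, records$A, records$B, pairs, focal = "A",
                    conserved_filter = filt, alpha = config$alpha_assoc)
  })
  write_tsv(assoc, out("te_deg_association.tsv"))
  cl_assoc <- stage("association", {
    run_cluster_te_scan(clust$assignments, records$A, records$B, pairs,
                        universe_base = clust$assignments$pair_id,
                        focal = "A", conserved_filter = filt,
                        alpha = config$alpha_assoc)
  })
  write_tsv(cl_assoc, out("cluster_te_association.tsv"))

  report <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("texpress")),
    n_ortholog_pairs = nrow(pairs),
    n_genes_tested = sum(!is.na(de$p)) / length(stages),
    n_degs = sapply(stages, function(st) {
      sum(de$stage == st & de$direction != "ns")
    }),
    n_clustered = nrow(clust$assignments), k_chosen = clust$k,
    n_tes_A = nrow(inp$tes_A), n_tes_B = nrow(inp$tes_B),
    n_conserved = length(cons$conserved),
    n_assoc_tests = nrow(assoc),
    assoc_reported = sum(!is.na(assoc$q) & assoc$q < config$alpha_assoc_report)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(pairs = pairs, de = de, tpm = tpm, pca = pca, clustering = clust,
       insertions = records, conserved = cons, association = assoc,
       cluster_association = cl_assoc, report = report, inputs = inp)
}
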
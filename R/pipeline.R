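#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the stages end to end on a simulated cohort: simulate
#' (panel + cohort) -> write/read round trip -> QC (call rate, MAF, rare
#' flag, relatedness pruning, ancestry PCs) -> single-variant association
#' (logistic + Fisher, inflation lambda, Bonferroni threshold, QQ/Manhattan
#' tables) -> gene kernel burden scan and per-individual NS burden ->
#' optional matched-permutation gene-set enrichment, GWA-interval
#' construction/overlap and tissue enrichment. Per-stage tables are written
#' as tab-separated files under `out_dir` together with a machine-readable
#' JSON summary; every table's md5 digest is recorded, so equal seeds yield
#' verifiably identical runs.
#'
#' @param config A [sim_config()] describing the cohort.
#' @param out_dir Output directory (created if needed).
#' @param gene_sets Optional named list of character vectors: candidate gene
#'   sets tested for enrichment at the variant and gene level.
#' @param leads Optional tibble of lead SNPs (`id`, `chrom`, `pos`) from
#'   which GWA intervals are built on the simulated panel.
#' @param expression Optional gene x tissue expression table (see
#'   [normalize_expression()]).
#' @param params List of analysis parameters; see Defaults.
#' @section Defaults: `call_rate_min = 0.99`, `rare_maf = 0.01`,
#'   `ibd_max = 0.1875`, `n_pcs = 2`, `skat_weights = c(1, 25)`,
#'   `permutations = 1000`, `r2_threshold = 0.5`, `interval_flank = 250000`,
#'   `overlap_pad = 500000`, `alpha = 0.05`, `top_n = 30`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("exocohort_"),
                         gene_sets = NULL, leads = NULL, expression = NULL,
                         params = list()) {
  defaults <- list(call_rate_min = 0.99, rare_maf = 0.01, ibd_max = 0.1875,
                   n_pcs = 2L, skat_weights = c(1, 25), permutations = 1000L,
                   r2_threshold = 0.5, interval_flank = 250000,
                   overlap_pad = 500000, alpha = 0.05, top_n = 30L)
  params <- utils::modifyList(defaults, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[exocohort] ", sprintf(...))
  written <- character()
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written[[name]] <<- path
    path
  }
  summary <- list(seed = config$seed, params = params)

  log_stage("simulate: seed %d, %d cases / %d controls", config$seed,
            config$n_cases, config$n_controls)
  panel <- simulate_haplotypes(config)
  cohort <- simulate_cohort(panel, config)
  prefix <- file.path(out_dir, "cohort")
  files <- write_cohort(cohort$genotypes, cohort$samples, cohort$variants, prefix)
  loaded <- read_cohort(files["vcf"], files["pheno"])
  genotypes <- loaded$genotypes
  samples <- loaded$samples
  variants <- dplyr::left_join(
    loaded$variants,
    cohort$variants[c("variant_id", "block", "p_anc", "is_causal")],
    by = "variant_id")
  summary$simulate <- list(n_samples = nrow(genotypes),
                           n_variants = ncol(genotypes))

  log_stage("qc: call rate >= %g, rare MAF < %g, IBD <= %g",
            params$call_rate_min, params$rare_maf, params$ibd_max)
  genotypes <- filter_call_rate(genotypes, params$call_rate_min)
  n_after_call_rate <- ncol(genotypes)
  mafs_now <- compute_maf(genotypes)$maf
  if (sum(!is.na(mafs_now) & mafs_now >= 0.05) >= 200L) {
    pruned <- prune_related(genotypes, samples, threshold = params$ibd_max)
  } else {
    log_stage("qc: too few common variants for relatedness pruning; skipped")
    pruned <- list(genotypes = genotypes, samples = samples, removed = character())
  }
  genotypes <- pruned$genotypes
  samples <- pruned$samples
  variants <- variant_qc(variants, genotypes, samples,
                         rare_threshold = params$rare_maf)
  samples <- add_ancestry_pcs(samples, genotypes, params$n_pcs)
  save_tsv(variants[c("variant_id", "call_rate", "maf_cases", "maf_controls",
                      "maf_all", "is_rare")], "qc_variants")
  writeLines(pruned$removed, file.path(out_dir, "removed_samples.txt"))
  summary$qc <- list(n_variants_after_call_rate = n_after_call_rate,
                     n_rare = sum(variants$is_rare, na.rm = TRUE),
                     removed_samples = pruned$removed)

  log_stage("assoc: logistic with %d PCs + Fisher over %d variants",
            params$n_pcs, ncol(genotypes))
  assoc <- assoc_scan(genotypes, samples, variants, test = "both",
                      n_covariates = params$n_pcs)
  logi <- dplyr::filter(assoc, .data$test == "logistic")
  n_ns <- sum(is_ns_class(variants$csq_class))
  bonf <- bonferroni_threshold(params$alpha, max(n_ns, 1L))
  common_p <- logi$p_value[!is.na(logi$p_value) & !is.na(logi$maf_all) &
                             logi$maf_all >= 0.05]
  lambda <- if (length(common_p) >= 100) genomic_lambda(common_p) else NA_real_
  tables <- qq_manhattan_tables(logi, threshold = bonf)
  save_tsv(assoc[c("variant_id", "test", "odds_ratio", "beta", "p_value",
                   "n_used", "flag")], "single_variant")
  save_tsv(tables$qq, "qq")
  if (!is.null(tables$manhattan)) save_tsv(tables$manhattan, "manhattan")
  summary$single_variant <- list(n_tests = nrow(logi),
                                 bonferroni_threshold = bonf, lambda = lambda,
                                 n_significant = sum(logi$p_value < bonf, na.rm = TRUE))

  log_stage("burden: kernel test per gene, Beta(%g,%g) weights",
            params$skat_weights[1], params$skat_weights[2])
  burden <- skat_scan(genotypes, samples, variants,
                      n_covariates = params$n_pcs,
                      weights_beta = params$skat_weights)
  save_tsv(burden, "gene_burden")
  ns_burden <- per_individual_ns_burden(genotypes, variants)
  is_case <- case_mask(samples)[match(ns_burden$sample_id, samples$sample_id)]
  burden_cmp <- compare_burden(ns_burden$burden[is_case],
                               ns_burden$burden[!is_case])
  save_tsv(burden_cmp, "ns_burden_comparison")
  summary$burden <- list(n_genes = nrow(burden),
                         min_p = min(burden$p_value, na.rm = TRUE),
                         ns_burden = as.list(burden_cmp[1, c("mean_cases",
                                                             "mean_controls",
                                                             "p_value")]))

  if (!is.null(gene_sets)) {
    log_stage("enrich: %d gene set(s), R = %d", length(gene_sets),
              params$permutations)
    stats <- gene_ns_stats(logi, universe = unique(variants$gene))
    enr <- purrr::imap_dfr(gene_sets, function(set, nm) {
      vfit <- matched_permutation_test(stats, set, R = params$permutations,
                                       seed = sub_seed(config$seed, paste0("enr_v_", nm)),
                                       set_name = paste0(nm, "/variant"))
      gstats <- dplyr::mutate(stats, score = -log10(
        pmax(burden$p_value[match(.data$gene, burden$gene)], 1e-300, na.rm = FALSE)))
      gstats$score[is.na(gstats$score)] <- 0
      gfit <- matched_permutation_test(gstats, set, R = params$permutations,
                                       seed = sub_seed(config$seed, paste0("enr_g_", nm)),
                                       set_name = paste0(nm, "/gene"))
      dplyr::bind_rows(tidy(vfit), tidy(gfit))
    })
    save_tsv(enr, "geneset_enrichment")
    summary$enrichment <- enr
  }

  if (!is.null(leads)) {
    log_stage("intervals: %d lead(s), r2 > %g, flank %g bp", nrow(leads),
              params$r2_threshold, params$interval_flank)
    ivs <- build_intervals(leads, panel, r2_threshold = params$r2_threshold,
                           flank = params$interval_flank)
    save_tsv(ivs, "gwa_intervals")
    gm <- gene_models(cohort$variants)
    top <- burden |>
      dplyr::filter(!is.na(.data$p_value)) |>
      dplyr::arrange(.data$p_value, .data$gene) |>
      utils::head(min(params$top_n, nrow(burden)))
    ov <- interval_overlap_test(top$gene,
                                extend_intervals(ivs, params$overlap_pad), gm,
                                R = params$permutations,
                                seed = sub_seed(config$seed, "overlap"))
    summary$intervals <- list(intervals = nrow(ivs),
                              genes_in_intervals = length(genes_in_intervals(gm, ivs)),
                              overlap = as.list(tidy(ov)[1, ]))
  }

  if (!is.null(expression)) {
    log_stage("tissue: %d tissue(s)", ncol(expression) - 1L)
    gm <- gene_models(cohort$variants)
    expr_norm <- normalize_expression(expression)
    top <- topn_genes(logi, min(params$top_n,
                                sum(gene_ns_stats(logi)$ns_snv_count > 0)))
    top <- intersect(top, expr_norm$gene)
    if (length(top)) {
      tis <- tissue_set_test(expr_norm, top, gm, R = params$permutations,
                             seed = sub_seed(config$seed, "tissue"))
      save_tsv(tis, "tissue_enrichment")
      summary$tissue <- tis
    }
  }

  digests <- tools::md5sum(unlist(written))
  names(digests) <- names(written)
  summary$digests <- as.list(digests)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage("done: outputs in %s", out_dir)
  invisible(summary)
}

#' Render a human-readable report from a pipeline summary
#'
#' Formats the pipeline summary as text, including Table-style listings of
#' nominally associated variants within supplied candidate gene sets when an
#' association table is given.
#'
#' @param summary Summary list from [run_pipeline()].
#' @param assoc Optional single-variant association tibble (with variant
#'   annotation columns) used to render the candidate-variant tables.
#' @param gene_sets Optional named list of candidate gene sets.
#' @param alpha Nominal significance threshold for the listings.
#' @return Character vector of report lines.
#' @export
make_report <- function(summary, assoc = NULL, gene_sets = NULL, alpha = 0.05) {
  lines <- c("== exocohort pipeline report ==",
             sprintf("seed: %s", summary$seed),
             sprintf("samples: %d, variants: %d",
                     summary$simulate$n_samples, summary$simulate$n_variants),
             sprintf("variants after call-rate filter: %d (rare: %d)",
                     summary$qc$n_variants_after_call_rate, summary$qc$n_rare),
             sprintf("samples removed for relatedness: %s",
                     if (length(summary$qc$removed_samples))
                       paste(summary$qc$removed_samples, collapse = ", ")
                     else "none"),
             sprintf("single-variant tests: %d, Bonferroni threshold %.3g, lambda %.3f",
                     summary$single_variant$n_tests,
                     summary$single_variant$bonferroni_threshold,
                     summary$single_variant$lambda),
             sprintf("variants below threshold: %d",
                     summary$single_variant$n_significant),
             sprintf("gene burden: %d genes, min p = %.3g",
                     summary$burden$n_genes, summary$burden$min_p),
             sprintf("NS burden per individual: cases %.1f vs controls %.1f (p = %.2g)",
                     summary$burden$ns_burden$mean_cases,
                     summary$burden$ns_burden$mean_controls,
                     summary$burden$ns_burden$p_value))
  if (!is.null(assoc) && !is.null(gene_sets)) {
    for (nm in names(gene_sets)) {
      hits <- assoc |>
        dplyr::filter(.data$test == "logistic",
                      .data$gene %in% gene_sets[[nm]],
                      is_ns_class(.data$csq_class),
                      !is.na(.data$p_value), .data$p_value < alpha) |>
        dplyr::arrange(.data$p_value)
      lines <- c(lines, "",
                 sprintf("-- suggestive NS variants (p < %g) in set '%s' --", alpha, nm))
      if (nrow(hits) == 0) {
        lines <- c(lines, "no variants pass")
      } else {
        lines <- c(lines,
                   "variant\tchrom\tpos\tgene\talleles\tmaf_cases\tmaf_controls\tOR\tp",
                   sprintf("%s\t%s\t%d\t%s\t%s/%s\t%.4g\t%.4g\t%.3g\t%.3g",
                           hits$variant_id, hits$chrom, hits$pos, hits$gene,
                           hits$ref, hits$alt, hits$maf_cases,
                           hits$maf_controls, hits$odds_ratio, hits$p_value))
      }
    }
  }
  lines
}
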
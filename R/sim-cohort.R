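#' Simulate a diploid case/control cohort from a haplotype panel
#'
#' Pairs haplotypes drawn within each sample's subpopulation into diploid
#' genotypes and assigns disease status from an additive logistic model:
#' `logit P(case) = baseline_logit[subpop] + sum over causal variants of
#' log(causal_or) * genotype`. Candidate individuals are consumed until the
#' requested numbers of cases and controls are reached; if the panel is
#' exhausted, further haplotype batches are generated from the same
#' configuration (each individual always receives fresh haplotypes, so
#' cohort members are unrelated by construction). If the quotas remain
#' unreachable after a bounded number of batches the function fails with a
#' diagnostic reporting the achieved counts.
#'
#' Variants are labelled non-synonymous with probability `ns_fraction`
#' (a fraction `stop_fraction` of those as stop gain/loss) and belong to the
#' contiguous genes laid down by [simulate_haplotypes()]. Genotypes are set
#' missing completely at random at rate `missing_rate`. If
#' `config$related_pair_pi_hat` is set, one extra cryptically related sample
#' is appended via [inject_related_pair()].
#'
#' @param panel A `hap_panel` from [simulate_haplotypes()].
#' @param config The same [sim_config()] used to build the panel.
#' @param max_batches Maximum number of additional haplotype batches drawn
#'   when the panel does not yield the requested quotas.
#' @return A list with `genotypes` (integer matrix, samples x variants, values
#'   0/1/2/NA), `samples` (tibble: `sample_id`, `status` in
#'   case/control, `subpop`, `related_to`) and `variants` (tibble: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `csq_class`, plus simulation truth
#'   `p_anc`, `block`, `is_causal`).
#' @examples
#' cfg <- sim_config(n_cases = 15, n_controls = 15, n_genes = 8, seed = 3)
#' cohort <- simulate_cohort(simulate_haplotypes(cfg), cfg)
#' table(cohort$samples$status)
#' @export
simulate_cohort <- function(panel, config, max_batches = 25L) {
  stopifnot(inherits(panel, "hap_panel"), inherits(config, "sim_config"))
  if (nrow(panel$haplotypes) < 2L) stop("panel is empty", call. = FALSE)

  variants <- with_sub_seed(config$seed, "variants", {
    v <- panel$variants
    m <- nrow(v)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    csq <- ifelse(stats::runif(m) < config$ns_fraction,
                  ifelse(stats::runif(m) < config$stop_fraction, "STOP", "NS"),
                  "SYN")
    dplyr::mutate(v, ref = ref, alt = alt, csq_class = csq,
                  is_causal = .data$gene %in% config$causal_gene_set)
  })

  beta <- ifelse(variants$is_causal, log(config$causal_or), 0)
  causal_idx <- which(beta != 0)
  base_logit <- rep(config$baseline_logit, length.out = config$n_subpops)

  with_sub_seed(config$seed, "cohort", {
    n_goal <- c(control = config$n_controls, case = config$n_cases)
    got <- c(control = 0L, case = 0L)
    geno_rows <- vector("list", sum(n_goal))
    status <- character(sum(n_goal))
    subpop <- integer(sum(n_goal))
    filled <- 0L

    consume_batch <- function(haps, hap_subpop) {
      for (sp in unique(hap_subpop)) {
        idx <- sample(which(hap_subpop == sp))      # shuffle within subpop
        n_pairs <- length(idx) %/% 2L
        if (n_pairs == 0L) next
        for (i in seq_len(n_pairs)) {
          if (all(got >= n_goal)) return(invisible(NULL))
          g <- haps[idx[2L * i - 1L], ] + haps[idx[2L * i], ]
          eta <- base_logit[sp] +
            (if (length(causal_idx)) sum(beta[causal_idx] * g[causal_idx]) else 0)
          st <- if (stats::runif(1) < stats::plogis(eta)) "case" else "control"
          if (got[st] < n_goal[st]) {
            got[st] <<- got[st] + 1L
            filled <<- filled + 1L
            geno_rows[[filled]] <<- g
            status[filled] <<- st
            subpop[filled] <<- sp
          }
        }
      }
      invisible(NULL)
    }

    consume_batch(panel$haplotypes, panel$hap_subpop)
    batch <- 0L
    while (!all(got >= n_goal) && batch < max_batches) {
      batch <- batch + 1L
      extra <- panel_redraw(panel, sub_seed(config$seed, paste0("extra_batch", batch)))
      consume_batch(extra, panel$hap_subpop)
    }
    if (!all(got >= n_goal)) {
      stop(sprintf(paste0("could not reach requested cohort size after %d extra ",
                          "batches: got %d/%d cases and %d/%d controls ",
                          "(is the disease model prevalence compatible?)"),
                   max_batches, got["case"], n_goal["case"],
                   got["control"], n_goal["control"]), call. = FALSE)
    }

    genotypes <- do.call(rbind, geno_rows)
    storage.mode(genotypes) <- "integer"
    rownames(genotypes) <- sprintf("S%04d", seq_len(nrow(genotypes)))
    colnames(genotypes) <- variants$variant_id

    if (config$missing_rate > 0) {
      miss <- stats::runif(length(genotypes)) < config$missing_rate
      genotypes[miss] <- NA_integer_
    }

    samples <- tibble::tibble(sample_id = rownames(genotypes),
                              status = status, subpop = subpop,
                              related_to = NA_character_)

    if (!is.null(config$related_pair_pi_hat)) {
      inj <- inject_related_pair(genotypes, config$related_pair_pi_hat,
                                 seed = sub_seed(config$seed, "related"))
      genotypes <- inj$genotypes
      tmpl <- which(samples$sample_id == inj$template_id)
      samples <- dplyr::bind_rows(samples, tibble::tibble(
        sample_id = inj$new_id, status = samples$status[tmpl],
        subpop = samples$subpop[tmpl], related_to = inj$template_id))
    }

    list(genotypes = genotypes, samples = samples, variants = variants)
  })
}

#' Append a cryptically related sample to a genotype matrix
#'
#' Adds one sample whose genotype at each variant is copied from a template
#' sample with probability `target_pi_hat` and re-drawn from the cohort's
#' allele frequencies (Hardy-Weinberg) otherwise. Copying a whole genotype
#' corresponds to sharing both alleles identical-by-descent at that site, so
#' the expected method-of-moments relatedness of the pair is `target_pi_hat`.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param target_pi_hat Target relatedness in `[0, 1]`.
#' @param seed Integer seed.
#' @param template Template `sample_id`; default draws one at random.
#' @return List with the augmented `genotypes`, `template_id`, `new_id` and
#'   the logical `copy_mask` used (simulation truth, one entry per variant).
#' @export
inject_related_pair <- function(genotypes, target_pi_hat, seed = 1L,
                                template = NULL) {
  assert_genotypes(genotypes)
  assert_scalar_prop(target_pi_hat, "target_pi_hat", 0, 1)
  if (nrow(genotypes) < 1L) stop("need at least one sample", call. = FALSE)
  withr::with_seed(seed, {
    template_id <- template %||% sample(rownames(genotypes), 1L)
    if (!template_id %in% rownames(genotypes)) {
      stop("template sample not found: ", template_id, call. = FALSE)
    }
    p_hat <- colMeans(genotypes, na.rm = TRUE) / 2
    p_hat[is.nan(p_hat)] <- 0
    m <- ncol(genotypes)
    copy_mask <- stats::runif(m) < target_pi_hat
    fresh <- stats::rbinom(m, 2L, p_hat)
    g_new <- ifelse(copy_mask, genotypes[template_id, ], fresh)
    new_id <- paste0(template_id, "_rel")
    out <- rbind(genotypes, matrix(as.integer(g_new), nrow = 1,
                                   dimnames = list(new_id, colnames(genotypes))))
    list(genotypes = out, template_id = template_id, new_id = new_id,
         copy_mask = copy_mask)
  })
}

#' Derive a gene model table from a variant table
#'
#' Gene extent is the span of the gene's variants padded by 100 bp on each
#' side; the CDS length is proportional to the number of variants the gene
#' carries (150 bp of coding sequence per simulated variant, floor 300 bp),
#' so that length- and count-matched null sampling is exercised over a
#' log-spread range of gene sizes.
#'
#' @param variants Variant tibble with `gene`, `chrom`, `pos`.
#' @return Tibble with `gene`, `chrom`, `start`, `end`, `cds_len`
#'   (1-based inclusive coordinates).
#' @export
gene_models <- function(variants) {
  variants |>
    dplyr::group_by(.data$gene, .data$chrom) |>
    dplyr::summarise(start = min(.data$pos) - 100L,
                     end = max(.data$pos) + 100L,
                     cds_len = max(300L, 150L * dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write a simulated cohort to disk
#'
#' Emits a multi-sample VCF 4.2 (unphased GT, INFO keys `GENE` and
#' `CSQ_CLASS`), a tab-separated phenotype/covariate file (`sample_id`,
#' `status` coded 1 = control / 2 = case, `subpop`), and a tab-separated gene
#' model table. The files round-trip losslessly through [read_cohort()].
#'
#' @param genotypes,samples,variants A cohort as from [simulate_cohort()].
#' @param out_prefix Path prefix; writes `<prefix>.vcf`, `<prefix>.pheno.tsv`
#'   and `<prefix>.genes.tsv`.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(genotypes, samples, variants, out_prefix) {
  assert_genotypes(genotypes)
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir, call. = FALSE)

  vcf_path <- paste0(out_prefix, ".vcf")
  pheno_path <- paste0(out_prefix, ".pheno.tsv")
  genes_path <- paste0(out_prefix, ".genes.tsv")

  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(genotypes), ncol = ncol(genotypes))
  ok <- !is.na(genotypes)
  gt[ok] <- gt_code[as.character(genotypes[ok])]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exocohort",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class: NS, SYN or STOP">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  info <- sprintf("GENE=%s;CSQ_CLASS=%s", variants$gene, variants$csq_class)
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  pheno <- data.frame(sample_id = samples$sample_id,
                      status = ifelse(case_mask(samples), 2L, 1L),
                      subpop = if ("subpop" %in% names(samples)) samples$subpop else 1L)
  utils::write.table(pheno, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(gene_models(variants)), genes_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(c(vcf = vcf_path, pheno = pheno_path, genes = genes_path))
}
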
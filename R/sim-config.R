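#' Configuration for a synthetic case/control exome cohort
#'
#' Collects every parameter of the cohort generator in one validated object.
#' The defaults describe the study design the package is organized around:
#' a 228-case / 884-control exome cohort of roughly 5,000 coding SNVs in 500
#' genes, a rare-heavy site frequency spectrum (80% of variants with ancestral
#' frequency below 1%), two subpopulations under the Balding-Nichols model,
#' block LD, and an additive logistic disease model.
#'
#' @param n_cases,n_controls Number of affected / unaffected samples to draw.
#' @param n_genes Number of genes; variants are assigned to genes in
#'   contiguous runs whose lengths are drawn log-uniformly with mean
#'   `variants_per_gene`, so the total variant count is close to (not exactly)
#'   `n_genes * variants_per_gene`.
#' @param variants_per_gene Mean number of variants per gene.
#' @param maf_spectrum List with elements `rare_frac` (fraction of variants in
#'   the rare band), `rare_range` and `common_range` (frequency bands; within
#'   each band ancestral frequencies are drawn log-uniformly, skewing the
#'   spectrum toward rare alleles).
#' @param n_subpops Number of subpopulations; samples are split evenly.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`. With `fst = 0`
#'   all subpopulations share the ancestral frequencies exactly.
#' @param ld_block_len Number of consecutive variants per LD block. Blocks are
#'   mutually independent; within a block adjacent variants are correlated.
#' @param recomb_prob Per-adjacent-variant decay of the latent ancestry
#'   process in `[0, 1]`: 0 gives perfect within-block LD, 1 gives
#'   independent variants.
#' @param causal_gene_set Character vector of gene names whose variants carry
#'   the causal odds ratio.
#' @param causal_or Per-allele odds ratio (>= 1) applied to every variant of
#'   every causal gene.
#' @param baseline_logit Intercept of the disease model, on the logit scale.
#'   May be a vector of length `n_subpops` to give subpopulations different
#'   baseline disease rates (used to provoke stratification confounding).
#' @param related_pair_pi_hat If non-`NULL`, after sampling the cohort one
#'   extra sample is appended that shares this expected fraction of its
#'   genome identical-by-descent with a template sample.
#' @param ns_fraction Fraction of variants labelled non-synonymous; a small
#'   fraction of those (`stop_fraction`) are labelled stop gain/loss.
#' @param stop_fraction Fraction of NS variants labelled `STOP`.
#' @param missing_rate Per-genotype missingness probability (missing
#'   completely at random), so that call-rate QC is exercised.
#' @param n_haplotypes Number of phased haplotypes to simulate in the panel;
#'   default accommodates the requested cohort with a 30% margin.
#' @param seed Integer seed; all randomness flows from it through
#'   deterministically derived per-operation sub-seeds, so identical
#'   configurations reproduce byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, n_genes = 20, seed = 7)
#' cfg$fst
#' @export
sim_config <- function(n_cases = 228L,
                       n_controls = 884L,
                       n_genes = 500L,
                       variants_per_gene = 10,
                       maf_spectrum = list(rare_frac = 0.8,
                                           rare_range = c(5e-4, 0.01),
                                           common_range = c(0.01, 0.3)),
                       n_subpops = 2L,
                       fst = 0,
                       ld_block_len = 20L,
                       recomb_prob = 0.1,
                       causal_gene_set = character(),
                       causal_or = 1,
                       baseline_logit = 0,
                       related_pair_pi_hat = NULL,
                       ns_fraction = 0.225,
                       stop_fraction = 0.015,
                       missing_rate = 0.002,
                       n_haplotypes = NULL,
                       seed = 1L) {
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  n_genes <- assert_count(n_genes, "n_genes")
  n_subpops <- assert_count(n_subpops, "n_subpops")
  ld_block_len <- assert_count(ld_block_len, "ld_block_len")
  if (!is.numeric(variants_per_gene) || variants_per_gene < 1) {
    stop("`variants_per_gene` must be >= 1", call. = FALSE)
  }
  assert_scalar_prop(fst, "fst", 0, 1, hi_open = TRUE)
  assert_scalar_prop(recomb_prob, "recomb_prob", 0, 1)
  assert_scalar_prop(ns_fraction, "ns_fraction", 0, 1)
  assert_scalar_prop(stop_fraction, "stop_fraction", 0, 1)
  assert_scalar_prop(missing_rate, "missing_rate", 0, 1)
  if (!is.numeric(causal_or) || any(causal_or < 1)) {
    stop("`causal_or` must be >= 1", call. = FALSE)
  }
  if (!is.null(related_pair_pi_hat)) {
    assert_scalar_prop(related_pair_pi_hat, "related_pair_pi_hat", 0, 1)
  }
  if (!length(baseline_logit) %in% c(1L, n_subpops)) {
    stop("`baseline_logit` must have length 1 or n_subpops", call. = FALSE)
  }
  stopifnot(is.list(maf_spectrum),
            all(c("rare_frac", "rare_range", "common_range") %in% names(maf_spectrum)))
  assert_scalar_prop(maf_spectrum$rare_frac, "maf_spectrum$rare_frac", 0, 1)
  for (rg in c("rare_range", "common_range")) {
    r <- maf_spectrum[[rg]]
    if (length(r) != 2L || any(r <= 0) || any(r > 0.5) || r[1] > r[2]) {
      stop(sprintf("`maf_spectrum$%s` must be an increasing pair in (0, 0.5]", rg),
           call. = FALSE)
    }
  }
  if (is.null(n_haplotypes)) {
    n_haplotypes <- 2L * ceiling(1.3 * (n_cases + n_controls))
  }
  n_haplotypes <- assert_count(n_haplotypes, "n_haplotypes", min = 2L)
  # keep an even number per subpopulation so haplotypes pair into individuals
  n_haplotypes <- as.integer(2 * n_subpops * ceiling(n_haplotypes / (2 * n_subpops)))
  seed <- assert_count(seed, "seed", min = 0L)

  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    n_genes = n_genes, variants_per_gene = variants_per_gene,
    maf_spectrum = maf_spectrum,
    n_subpops = n_subpops, fst = fst,
    ld_block_len = ld_block_len, recomb_prob = recomb_prob,
    causal_gene_set = as.character(causal_gene_set), causal_or = causal_or,
    baseline_logit = baseline_logit,
    related_pair_pi_hat = related_pair_pi_hat,
    ns_fraction = ns_fraction, stop_fraction = stop_fraction,
    missing_rate = missing_rate,
    n_haplotypes = n_haplotypes,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d cases / %d controls, %d subpop(s), Fst = %g\n",
              x$n_cases, x$n_controls, x$n_subpops, x$fst))
  cat(sprintf("  genome: %d genes, ~%g variants/gene, LD blocks of %d (recomb %g)\n",
              x$n_genes, x$variants_per_gene, x$ld_block_len, x$recomb_prob))
  cat(sprintf("  disease: baseline logit %s, OR %g at %d causal gene(s)\n",
              paste(format(x$baseline_logit), collapse = "/"),
              x$causal_or[1], length(x$causal_gene_set)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# mean of exp(U(0, log b)) equals (b - 1) / log(b); invert for a target mean
log_uniform_upper <- function(mean_size) {
  if (mean_size <= 1.0001) return(1)
  stats::uniroot(function(b) (b - 1) / log(b) - mean_size,
                 lower = 1 + 1e-9, upper = 1e9, tol = 1e-9)$root
}

# draw contiguous gene sizes (in variants), log-uniform with the target mean
draw_gene_sizes <- function(n_genes, variants_per_gene) {
  b <- log_uniform_upper(variants_per_gene)
  pmax(1L, as.integer(round(exp(stats::runif(n_genes, 0, log(b))))))
}
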
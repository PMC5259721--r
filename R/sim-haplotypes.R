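#' Simulate a phased haplotype panel with subpopulation structure and block LD
#'
#' Draws an ancestral frequency for every variant from the configured site
#' frequency spectrum, diverges it into per-subpopulation frequencies under
#' the Balding-Nichols construction `Beta(p(1-F)/F, (1-p)(1-F)/F)` (with
#' `F = fst`; for `F = 0` the ancestral frequency is used exactly), and builds
#' phased 0/1 haplotypes with linkage disequilibrium confined to blocks of
#' `ld_block_len` consecutive variants.
#'
#' Within a block each haplotype carries a latent ancestry score following a
#' stationary AR(1) process with autocorrelation `1 - recomb_prob`; the allele
#' at a variant is the indicator that the latent quantile falls below the
#' subpopulation frequency. Marginal allele frequencies are therefore exact at
#' every `recomb_prob`, while `recomb_prob = 0` makes equal-frequency variants
#' of a block perfectly correlated (r-squared 1) and `recomb_prob = 1` makes
#' all variants independent. Blocks are mutually independent, so block
#' boundaries are ground truth for LD-interval construction.
#'
#' @param config A [sim_config()].
#' @return An object of class `hap_panel`: a list with `haplotypes` (integer
#'   0/1 matrix, haplotypes x variants), `variants` (tibble with `variant_id`,
#'   `chrom`, `pos`, `block`, `gene`, `p_anc`), `hap_subpop` (subpopulation
#'   index per haplotype), `subpop_freq` (subpopulations x variants frequency
#'   matrix) and the generating `config`.
#' @examples
#' panel <- simulate_haplotypes(sim_config(n_cases = 20, n_controls = 20,
#'                                         n_genes = 10, seed = 1))
#' dim(panel$haplotypes)
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sub_seed(config$seed, "haplotypes", {
    sizes <- draw_gene_sizes(config$n_genes, config$variants_per_gene)
    m <- sum(sizes)
    if (m < 1L) stop("configuration yields zero variants", call. = FALSE)
    gene <- rep(sprintf("g%04d", seq_len(config$n_genes)), sizes)

    block <- rep(seq_len(ceiling(m / config$ld_block_len)),
                 each = config$ld_block_len)[seq_len(m)]
    gap <- stats::runif(m, 200, 1500)
    gap[c(FALSE, diff(block) != 0)] <- 30000            # spacer between blocks
    pos <- as.integer(cumsum(gap)) + 10000L

    spec <- config$maf_spectrum
    rare <- stats::runif(m) < spec$rare_frac
    draw_band <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
    p_anc <- numeric(m)
    p_anc[rare] <- draw_band(sum(rare), spec$rare_range)
    p_anc[!rare] <- draw_band(sum(!rare), spec$common_range)

    k <- config$n_subpops
    subpop_freq <- matrix(rep(p_anc, each = k), nrow = k)
    if (config$fst > 0) {
      f <- config$fst
      subpop_freq[] <- stats::rbeta(k * m,
                                    rep(p_anc, each = k) * (1 - f) / f,
                                    (1 - rep(p_anc, each = k)) * (1 - f) / f)
    }

    h <- config$n_haplotypes
    hap_subpop <- rep(seq_len(k), each = h %/% k)[seq_len(h)]
    haps <- build_haplotypes(subpop_freq, hap_subpop, block,
                             1 - config$recomb_prob)
    variant_id <- sprintf("v%05d", seq_len(m))
    colnames(haps) <- variant_id

    structure(list(
      haplotypes = haps,
      variants = tibble::tibble(variant_id = variant_id, chrom = "1",
                                pos = pos, block = block, gene = gene,
                                p_anc = p_anc),
      hap_subpop = hap_subpop,
      subpop_freq = subpop_freq,
      config = config
    ), class = "hap_panel")
  })
}

# latent AR(1) ancestry process per block; draws from the current RNG state
build_haplotypes <- function(subpop_freq, hap_subpop, block, phi) {
  h <- length(hap_subpop)
  m <- ncol(subpop_freq)
  haps <- matrix(0L, nrow = h, ncol = m)
  for (b in unique(block)) {
    idx <- which(block == b)
    z <- stats::rnorm(h)
    for (j in seq_along(idx)) {
      if (j > 1L) z <- phi * z + sqrt(1 - phi^2) * stats::rnorm(h)
      pv <- subpop_freq[, idx[j]][hap_subpop]
      haps[, idx[j]] <- as.integer(stats::pnorm(z) < pv)
    }
  }
  haps
}

# fresh haplotypes on an existing panel's variant structure (used when the
# cohort sampler exhausts the panel before filling its case/control quotas)
panel_redraw <- function(panel, seed) {
  haps <- withr::with_seed(seed, build_haplotypes(
    panel$subpop_freq, panel$hap_subpop, panel$variants$block,
    1 - panel$config$recomb_prob))
  colnames(haps) <- panel$variants$variant_id
  haps
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d variants, %d subpop(s), %d LD block(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$hap_subpop)), max(x$variants$block)))
  invisible(x)
}
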
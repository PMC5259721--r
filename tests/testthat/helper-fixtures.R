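# shared fixtures: all built in code, no files

# Hardy-Weinberg genotype matrix at given allele frequencies
hwe_genotypes <- function(n, freqs, seed = 1) {
  withr::with_seed(seed, {
    m <- length(freqs)
    g <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
    dimnames(g) <- list(sprintf("s%04d", seq_len(n)), sprintf("v%05d", seq_len(m)))
    g
  })
}

sample_table <- function(y, ids = NULL) {
  tibble::tibble(sample_id = ids %||% sprintf("s%04d", seq_along(y)),
                 status = ifelse(y == 1, "case", "control"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-sided Fisher p by exhaustive hypergeometric enumeration (independent
# oracle for the packaged test)
enum_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n2 <- sum(tab[, 2]); k <- sum(tab[1, ])
  x <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(x, m, n2, k)
  sum(pr[pr <= stats::dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
}

# small cohort used by several suites
small_cohort <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cases = 40, n_controls = 60, n_genes = 25, seed = seed,
         missing_rate = 0.01),
    list(...))
  cfg <- do.call(sim_config, args)
  c(simulate_cohort(simulate_haplotypes(cfg), cfg), list(config = cfg))
}
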
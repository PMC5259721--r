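# Method-of-moments relatedness from identity-by-state counts.
#
# For a variant with alternate-allele frequency p (q = 1 - p), the
# probabilities of observing IBS state s between two outbred individuals
# given their IBD state z are the classical ones:
#   P(IBS0|IBD0) = 2 p^2 q^2
#   P(IBS1|IBD0) = 4 p^3 q + 4 p q^3      P(IBS1|IBD1) = 2 p q
#   P(IBS2|IBD0) = p^4 + q^4 + 4 p^2 q^2  P(IBS2|IBD1) = p^2 + q^2
#   P(IBS2|IBD2) = 1
# Solving the moment equations in order gives P(IBD=0), P(IBD=1), P(IBD=2)
# and pi-hat = P(IBD=1)/2 + P(IBD=2).

ibs_expectations <- function(p) {
  q <- 1 - p
  list(e00 = 2 * p^2 * q^2,
       e10 = 4 * p^3 * q + 4 * p * q^3,
       e20 = p^4 + q^4 + 4 * p^2 * q^2,
       e11 = 2 * p * q,
       e21 = p^2 + q^2)
}

pi_hat_from_counts <- function(n_ibs0, n_ibs1, n_ibs2, s00, s10, s20, s11, s21, n) {
  p0 <- n_ibs0 / s00
  p1 <- (n_ibs1 - p0 * s10) / s11
  p2 <- (n_ibs2 - p0 * s20 - p1 * s21) / n
  out <- p1 / 2 + p2
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Method-of-moments IBD estimate for a sample pair
#'
#' Estimates the expected genome fraction shared identical-by-descent,
#' `pi_hat = P(IBD=1)/2 + P(IBD=2)`, from observed identity-by-state counts
#' and population allele frequencies (estimated from the full cohort unless
#' supplied). Only variants with cohort MAF at or above `min_maf` and called
#' in both samples are informative; fewer than `min_variants` of them is an
#' error, because the estimator is unreliable below that floor.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param pair Character vector of two sample ids.
#' @param min_maf Minimum cohort MAF for a variant to be used.
#' @param min_variants Minimum number of informative variants.
#' @param freqs Optional per-variant alternate-allele frequencies; default
#'   estimates them from `genotypes`.
#' @return The clipped `pi_hat` estimate in `[0, 1]`, with the number of
#'   variants used in attribute `"n_variants"`.
#' @export
ibd_estimate <- function(genotypes, pair, min_maf = 0.05, min_variants = 200L,
                         freqs = NULL) {
  assert_genotypes(genotypes)
  if (length(pair) != 2L || !all(pair %in% rownames(genotypes))) {
    stop("`pair` must name two samples present in the matrix", call. = FALSE)
  }
  mafs <- compute_maf(genotypes)
  p <- freqs %||% mafs$alt_freq
  use <- !is.na(mafs$maf) & mafs$maf >= min_maf
  g1 <- genotypes[pair[1], use]
  g2 <- genotypes[pair[2], use]
  p <- p[use]
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_variants) {
    stop(sprintf("only %d informative variants (MAF >= %g, called in both); need %d",
                 sum(ok), min_maf, min_variants), call. = FALSE)
  }
  g1 <- g1[ok]; g2 <- g2[ok]; p <- p[ok]
  ibs <- 2L - abs(g1 - g2)
  e <- ibs_expectations(p)
  out <- pi_hat_from_counts(sum(ibs == 0L), sum(ibs == 1L), sum(ibs == 2L),
                            sum(e$e00), sum(e$e10), sum(e$e20),
                            sum(e$e11), sum(e$e21), length(p))
  attr(out, "n_variants") <- length(p)
  out
}

# all-pairs pi-hat via indicator-matrix products; assumes informative variants
# have been pre-selected. Returns a symmetric matrix with NA diagonal.
pairwise_pi_hat <- function(genotypes, min_maf = 0.05) {
  mafs <- compute_maf(genotypes)
  use <- !is.na(mafs$maf) & mafs$maf >= min_maf
  g <- genotypes[, use, drop = FALSE]
  p <- mafs$alt_freq[use]
  a0 <- (!is.na(g) & g == 0L) * 1
  a1 <- (!is.na(g) & g == 1L) * 1
  a2 <- (!is.na(g) & g == 2L) * 1
  cc <- a0 + a1 + a2
  ibs2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  ibs0 <- tcrossprod(a0, a2); ibs0 <- ibs0 + t(ibs0)
  n_both <- tcrossprod(cc)
  ibs1 <- n_both - ibs2 - ibs0
  e <- ibs_expectations(p)
  wsum <- function(w) tcrossprod(cc * rep(w, each = nrow(cc)), cc)
  s00 <- wsum(e$e00); s10 <- wsum(e$e10); s20 <- wsum(e$e20)
  s11 <- wsum(e$e11); s21 <- wsum(e$e21)
  pi <- pi_hat_from_counts(ibs0, ibs1, ibs2, s00, s10, s20, s11, s21, n_both)
  diag(pi) <- NA_real_
  dimnames(pi) <- list(rownames(genotypes), rownames(genotypes))
  pi
}

#' Prune related samples by pairwise IBD
#'
#' Scans all sample pairs and, for every pair with `pi_hat` strictly above
#' the threshold (default 0.1875, halfway between second- and third-degree
#' relatives), removes one member. The removal rule is deterministic: drop
#' the member with the lower genotype call rate, breaking ties by
#' lexicographic sample id. Pairs are resolved from the strongest down, and
#' the output is guaranteed (and re-checked) to contain no pair above the
#' threshold.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param samples Sample tibble with `sample_id`.
#' @param threshold Strict `pi_hat` threshold for removal.
#' @param min_maf Minimum cohort MAF for informative variants.
#' @param min_variants Minimum number of informative variants; below this
#'   floor the estimator's sampling noise would spill past the threshold and
#'   the function refuses to prune.
#' @return List with the pruned `genotypes` and `samples` and the character
#'   vector `removed`.
#' @export
prune_related <- function(genotypes, samples, threshold = 0.1875,
                          min_maf = 0.05, min_variants = 200L) {
  assert_genotypes(genotypes)
  mafs <- compute_maf(genotypes)$maf
  n_inf <- sum(!is.na(mafs) & mafs >= min_maf)
  if (n_inf < min_variants) {
    stop(sprintf("only %d informative variants (MAF >= %g); need %d to prune reliably",
                 n_inf, min_maf, min_variants), call. = FALSE)
  }
  pi <- pairwise_pi_hat(genotypes, min_maf = min_maf)
  call_rate <- rowMeans(!is.na(genotypes))
  removed <- character()
  active <- rownames(genotypes)
  repeat {
    sub <- pi[active, active, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    hits <- which(sub > threshold, arr.ind = TRUE)
    if (nrow(hits) == 0L) break
    vals <- sub[hits]
    ord <- order(-vals, rownames(sub)[hits[, 1]], colnames(sub)[hits[, 2]])
    i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
    a <- rownames(sub)[i]; b <- colnames(sub)[j]
    drop_id <- if (call_rate[a] < call_rate[b]) a
               else if (call_rate[b] < call_rate[a]) b
               else max(a, b)   # tie: lexicographically later id dropped, keeping the first
    removed <- c(removed, drop_id)
    active <- setdiff(active, drop_id)
  }
  list(genotypes = genotypes[active, , drop = FALSE],
       samples = samples[samples$sample_id %in% active, , drop = FALSE],
       removed = removed)
}
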
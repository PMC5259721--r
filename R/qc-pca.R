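#' Ancestry principal components from a genotype matrix
#'
#' Mean-centres each variant and scales it by `sqrt(2 p (1 - p))` (the
#' binomial standard deviation at its allele frequency), imputes missing
#' calls to the variant mean, and returns the leading eigenvectors of the
#' sample covariance as per-sample ancestry coordinates. Monomorphic variants
#' are dropped. Components are unit-norm and mutually orthogonal; the sign of
#' any component is arbitrary.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param n_components Number of components to return.
#' @return Tibble with `sample_id` and `PC1` ... `PCk`, in genotype row
#'   order; eigenvalues and their proportion of total variance are in
#'   attributes `"eigenvalues"` and `"var_explained"`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_cases = 30, n_controls = 30, n_genes = 40, fst = 0.1,
#'                   seed = 2)
#' cohort <- simulate_cohort(simulate_haplotypes(cfg), cfg)
#' pcs <- pca_ancestry(cohort$genotypes)
#' }
#' @export
pca_ancestry <- function(genotypes, n_components = 2L) {
  assert_genotypes(genotypes)
  n_components <- assert_count(n_components, "n_components")
  n <- nrow(genotypes)
  if (n < n_components + 1L) {
    stop("need at least n_components + 1 samples", call. = FALSE)
  }
  f <- compute_maf(genotypes)$alt_freq
  keep <- !is.na(f) & f > 0 & f < 1
  if (!any(keep)) stop("no polymorphic variants available", call. = FALSE)
  g <- genotypes[, keep, drop = FALSE]
  f <- f[keep]
  x <- sweep(g, 2L, 2 * f, "-")
  x <- sweep(x, 2L, sqrt(2 * f * (1 - f)), "/")
  x[is.na(x)] <- 0                       # mean imputation after centring
  if (all(abs(x) < 1e-12)) stop("degenerate genotype matrix: zero variance", call. = FALSE)
  cov_s <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov_s, symmetric = TRUE)
  vecs <- eig$vectors[, seq_len(n_components), drop = FALSE]
  colnames(vecs) <- paste0("PC", seq_len(n_components))
  out <- tibble::as_tibble(vecs)
  out <- tibble::add_column(out, sample_id = rownames(genotypes), .before = 1)
  attr(out, "eigenvalues") <- eig$values[seq_len(n_components)]
  attr(out, "var_explained") <- eig$values[seq_len(n_components)] /
    sum(pmax(eig$values, 0))
  out
}

#' Attach ancestry PCs to a sample table
#'
#' Convenience wrapper: runs [pca_ancestry()] and left-joins the coordinates
#' onto the sample table, so downstream association tests find their
#' covariate columns.
#'
#' @param samples Sample tibble with `sample_id`.
#' @param genotypes Samples x variants genotype matrix.
#' @param n_components Number of components.
#' @return The sample tibble with `PC1` ... `PCk` columns added (replacing
#'   any existing ones).
#' @export
add_ancestry_pcs <- function(samples, genotypes, n_components = 2L) {
  pcs <- pca_ancestry(genotypes, n_components)
  old <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  samples <- samples[setdiff(names(samples), old)]
  dplyr::left_join(samples, pcs, by = "sample_id")
}
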
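#' Filter variants on genotype call rate
#'
#' Retains variants called (non-missing) in at least `min_rate` of samples,
#' the classical "base calls in at least 99% of samples" site filter.
#' Variant order is preserved and the operation is idempotent.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param min_rate Minimum fraction of called samples, in `(0, 1]`; the
#'   comparison is `call_rate >= min_rate`.
#' @return The filtered genotype matrix, with the removed variant ids in
#'   attribute `"removed"`.
#' @export
filter_call_rate <- function(genotypes, min_rate = 0.99) {
  assert_genotypes(genotypes)
  assert_scalar_prop(min_rate, "min_rate", 0, 1, lo_open = FALSE)
  rate <- colMeans(!is.na(genotypes))
  keep <- rate >= min_rate
  out <- genotypes[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(genotypes)[!keep]
  out
}

#' Minor allele frequency per variant
#'
#' MAF is the minor-allele count among called genotypes divided by twice the
#' number of called samples in the subset, folded so that values never exceed
#' 0.5. Variants with no called genotype in the subset get `NA` (undefined,
#' deliberately not 0).
#'
#' @param genotypes Samples x variants genotype matrix (alt-allele counts).
#' @param subset Optional sample selector: character ids or logical/integer
#'   index into the rows. Default uses all samples.
#' @return Tibble with `variant_id`, `maf` (folded), `alt_freq` (unfolded
#'   alternate-allele frequency) and `n_called`.
#' @examples
#' g <- matrix(c(0L, 1L, 1L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' compute_maf(g)
#' @export
compute_maf <- function(genotypes, subset = NULL) {
  assert_genotypes(genotypes)
  if (!is.null(subset)) {
    genotypes <- genotypes[subset, , drop = FALSE]
    if (nrow(genotypes) == 0L) stop("empty sample subset", call. = FALSE)
  }
  n_called <- unname(colSums(!is.na(genotypes)))
  alt <- unname(colSums(genotypes, na.rm = TRUE))
  f <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  tibble::tibble(variant_id = colnames(genotypes),
                 maf = pmin(f, 1 - f),
                 alt_freq = f,
                 n_called = as.integer(n_called))
}

#' Annotate a variant table with QC statistics
#'
#' Adds per-variant call rate, overall/case/control MAF, and the rare flag to
#' a variant table, for the samples and genotypes supplied.
#'
#' @param variants Variant tibble with `variant_id`.
#' @param genotypes Samples x variants genotype matrix.
#' @param samples Sample tibble with `sample_id` and `status`.
#' @param rare_threshold Control-MAF rarity threshold passed to [flag_rare()].
#' @return The variant tibble with `call_rate`, `maf_all`, `maf_cases`,
#'   `maf_controls` and `is_rare` columns.
#' @export
variant_qc <- function(variants, genotypes, samples, rare_threshold = 0.01) {
  assert_genotypes(genotypes)
  variants <- variants[variants$variant_id %in% colnames(genotypes), , drop = FALSE]
  g <- genotypes[, variants$variant_id, drop = FALSE]
  is_case <- case_mask(samples)[match(rownames(g), samples$sample_id)]
  variants$call_rate <- colMeans(!is.na(g))
  variants$maf_all <- compute_maf(g)$maf
  variants$maf_cases <- compute_maf(g, subset = which(is_case))$maf
  variants$maf_controls <- compute_maf(g, subset = which(!is_case))$maf
  flag_rare(variants, threshold = rare_threshold)
}

#' Flag rare variants by control minor allele frequency
#'
#' A variant is rare when its control MAF is strictly below the threshold
#' (default 1%). An undefined control MAF yields an `NA` flag rather than a
#' silent `FALSE`. Idempotent.
#'
#' @param variants Variant tibble with a `maf_controls` column.
#' @param threshold Strict upper bound on control MAF.
#' @return The variant tibble with (re)computed logical `is_rare`.
#' @export
flag_rare <- function(variants, threshold = 0.01) {
  if (!"maf_controls" %in% names(variants)) {
    stop("`variants` must carry a maf_controls column", call. = FALSE)
  }
  assert_scalar_prop(threshold, "threshold", 0, 0.5)
  dplyr::mutate(variants, is_rare = .data$maf_controls < threshold)
}
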
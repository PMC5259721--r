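#' Per-individual non-synonymous burden
#'
#' Counts, for every sample, the NS sites at which it carries at least one
#' alternate allele (`mode = "site"`, the default) or its total NS alternate
#' allele count (`mode = "allele"`). Missing genotypes contribute nothing.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param variants Optional variant tibble with `variant_id` and `csq_class`;
#'   when supplied, the count is restricted to NS/STOP variants. When
#'   omitted, all columns are counted (the matrix is assumed pre-restricted).
#' @param mode `"site"` or `"allele"`.
#' @return Tibble with `sample_id` and `burden`.
#' @export
per_individual_ns_burden <- function(genotypes, variants = NULL,
                                     mode = c("site", "allele")) {
  assert_genotypes(genotypes)
  mode <- match.arg(mode)
  if (!is.null(variants)) {
    ns_ids <- variants$variant_id[is_ns_class(variants$csq_class)]
    genotypes <- genotypes[, colnames(genotypes) %in% ns_ids, drop = FALSE]
  }
  burden <- if (mode == "site") {
    rowSums(genotypes >= 1L, na.rm = TRUE)
  } else {
    rowSums(genotypes, na.rm = TRUE)
  }
  tibble::tibble(sample_id = rownames(genotypes), burden = as.integer(burden))
}

#' Compare per-individual burden between cases and controls
#'
#' Reports the group means and a two-sided p-value for a location difference
#' in per-individual variant counts, by Wilcoxon rank-sum with mid-rank tie
#' handling (default) or Welch's t-test.
#'
#' @param case_counts,control_counts Numeric count vectors.
#' @param method `"ranksum"` or `"ttest"`.
#' @return One-row tibble with `mean_cases`, `mean_controls`, `p_value`,
#'   `method`, `n_cases`, `n_controls`.
#' @export
compare_burden <- function(case_counts, control_counts,
                           method = c("ranksum", "ttest")) {
  method <- match.arg(method)
  if (!length(case_counts) || !length(control_counts)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  p <- if (method == "ranksum") {
    suppressWarnings(stats::wilcox.test(case_counts, control_counts,
                                        exact = FALSE, correct = TRUE)$p.value)
  } else {
    stats::t.test(case_counts, control_counts)$p.value
  }
  if (is.nan(p)) p <- 1    # degenerate, e.g. all values tied
  tibble::tibble(mean_cases = mean(case_counts),
                 mean_controls = mean(control_counts),
                 p_value = p, method = method,
                 n_cases = length(case_counts),
                 n_controls = length(control_counts))
}
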
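#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kernel burden test result
#'
#' @param x A `skat_fit`.
#' @param ... Unused.
#' @return One-row tibble with `gene`, `q_stat`, `p_value`, `n_variants`.
#' @method tidy skat_fit
#' @export
tidy.skat_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, q_stat = x$q_stat, p_value = x$p_value,
                 n_variants = x$n_variants)
}

#' @rdname tidy.skat_fit
#' @return For `glance`: a one-row tibble adding the sample count, tail
#'   method and number of retained kernel eigenvalues.
#' @method glance skat_fit
#' @export
glance.skat_fit <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, method = x$method,
                 n_eigenvalues = length(x$eigen_spectrum),
                 n_excluded = length(x$excluded))
}

#' Tidy a matched-permutation enrichment result
#'
#' @param x An `enrich_fit`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, null summary, fold
#'   and empirical p.
#' @method tidy enrich_fit
#' @export
tidy.enrich_fit <- function(x, ...) {
  tibble::tibble(set_name = x$set_name, observed_stat = x$observed_stat,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 fold = x$fold, empirical_p = x$empirical_p)
}

#' @rdname tidy.enrich_fit
#' @method glance enrich_fit
#' @export
glance.enrich_fit <- function(x, ...) {
  tibble::tibble(n_permutations = x$n_permutations, matching = x$matching,
                 seed = x$seed)
}
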
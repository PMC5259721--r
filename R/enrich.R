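#' Per-gene association summaries for enrichment testing
#'
#' Summarises a single-variant association table into the per-gene
#' quantities the enrichment tests consume: the number of NS SNVs, the sum
#' of `-log10(p)` over them, the best (minimum) NS SNV p-value and the
#' number of nominally associated NS SNVs.
#'
#' @param variant_results Tibble with `gene`, `csq_class`, `p_value` (one
#'   row per variant; the logistic p-values are the intended input).
#' @param universe Optional character vector of all genes to report
#'   (genes without NS SNVs get count 0 and score 0).
#' @param alpha Nominal significance level for `n_nominal`.
#' @return Tibble with `gene`, `ns_snv_count`, `score`, `best_p`, `n_nominal`.
#' @export
gene_ns_stats <- function(variant_results, universe = NULL, alpha = 0.05) {
  ns <- variant_results[is_ns_class(variant_results$csq_class) &
                          !is.na(variant_results$p_value), , drop = FALSE]
  if (any(ns$p_value <= 0 | ns$p_value > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  agg <- ns |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ns_snv_count = dplyr::n(),
                     score = sum(-log10(.data$p_value)),
                     best_p = min(.data$p_value),
                     n_nominal = sum(.data$p_value < alpha),
                     .groups = "drop")
  universe <- universe %||% unique(variant_results$gene)
  out <- tibble::tibble(gene = universe) |>
    dplyr::left_join(agg, by = "gene") |>
    tidyr::replace_na(list(ns_snv_count = 0L, score = 0, n_nominal = 0L))
  out
}

#' Variant-level gene-set score
#'
#' The observed enrichment statistic `S = sum over NS SNVs in member genes
#' of -log10(p)`. Member genes with no NS SNV contribute 0.
#'
#' @param gene_set Character vector of member gene names.
#' @param variant_results As in [gene_ns_stats()].
#' @return Scalar score.
#' @export
set_score_variant_level <- function(gene_set, variant_results) {
  stats <- gene_ns_stats(variant_results,
                         universe = union(unique(variant_results$gene), gene_set))
  sum(stats$score[stats$gene %in% gene_set])
}

#' Gene-level (kernel-test) gene-set score
#'
#' `S = sum over member genes of -log10(p)` where `p` is the gene's kernel
#' burden p-value. Member genes absent from the results contribute 0
#' (equivalent to p = 1).
#'
#' @param gene_set Character vector of member gene names.
#' @param gene_results Tibble with `gene` and `p_value` (e.g. [skat_scan()]).
#' @return Scalar score.
#' @export
set_score_gene_level <- function(gene_set, gene_results) {
  p <- gene_results$p_value[match(gene_set, gene_results$gene)]
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  sum(-log10(p))
}

# candidate pools for matched resampling: for each member gene, the
# non-member genes eligible to replace it under the matching rule
match_pools <- function(match_values, member_idx, matching = c("exact_count", "log2_bins"),
                        min_candidates = 10L, gene_names = NULL) {
  matching <- match.arg(matching)
  non_members <- setdiff(seq_along(match_values), member_idx)
  lapply(member_idx, function(i) {
    v <- match_values[i]
    pool <- if (matching == "exact_count") {
      exact <- non_members[match_values[non_members] == v]
      if (length(exact) >= min_candidates) exact
      else non_members[match_values[non_members] >= floor(0.8 * v) &
                         match_values[non_members] <= ceiling(1.2 * v)]
    } else {
      bin <- floor(log2(pmax(match_values, 1e-9)) / 0.5)
      same <- non_members[bin[non_members] == bin[i]]
      if (length(same) >= min_candidates) same
      else non_members[abs(bin[non_members] - bin[i]) <= 1]
    }
    if (!length(pool)) {
      nm <- if (is.null(gene_names)) paste0("#", i) else gene_names[i]
      stop("no eligible matched gene for member gene ", nm, call. = FALSE)
    }
    pool
  })
}

# R replicate index sets, each member replaced by a matched non-member,
# without replacement within a replicate (with replacement across them)
matched_null_sets <- function(pools, R) {
  k <- length(pools)
  draws <- matrix(0L, nrow = R, ncol = k)
  for (i in seq_len(k)) {
    draws[, i] <- pools[[i]][sample.int(length(pools[[i]]), R, replace = TRUE)]
  }
  if (k > 1L) {
    bad <- which(apply(draws, 1L, anyDuplicated) > 0L)
    for (r in bad) {
      for (attempt in seq_len(100L)) {
        row <- integer(k)
        ok <- TRUE
        for (i in seq_len(k)) {
          cand <- setdiff(pools[[i]], row[seq_len(i - 1L)])
          if (!length(cand)) { ok <- FALSE; break }
          row[i] <- cand[sample.int(length(cand), 1L)]
        }
        if (ok) { draws[r, ] <- row; break }
        if (attempt == 100L) {
          stop("could not build a duplicate-free matched null set; pools too small",
               call. = FALSE)
        }
      }
    }
  }
  draws
}

#' Matched-permutation gene-set enrichment test
#'
#' Compares an observed gene-set statistic (the sum over member genes of a
#' per-gene score) with its distribution over random gene sets in which each
#' member is replaced by a non-member matched on a covariate -- by default
#' the gene's NS SNV count, so that the null preserves the set's
#' opportunity to accumulate association signal. Exact covariate matches
#' are preferred; when fewer than 10 candidates exist the match widens to a
#' +/-20% bin (counts rounded outward). For length-like covariates
#' (`matching = "log2_bins"`), matching uses log2 bins of width 0.5 with a
#' +/-1-bin widening fallback. Null sets are drawn without replacement
#' within a replicate and with replacement across replicates.
#'
#' The one-sided (enrichment) empirical p-value uses add-one smoothing,
#' `p = (1 + #\{S_null >= S_obs\}) / (R + 1)`, so it is never exactly zero,
#' and the fold change is `S_obs / mean(S_null)`.
#'
#' @param gene_stats Tibble with one row per universe gene: a `gene` column,
#'   the per-gene score in `score_col` and the matching covariate in
#'   `match_col`.
#' @param gene_set Character vector of member genes (must be a strict,
#'   nonempty subset of the universe).
#' @param score_col,match_col Column names in `gene_stats`.
#' @param matching `"exact_count"` or `"log2_bins"`.
#' @param R Number of permutation replicates.
#' @param seed Integer seed (the null stream is reproducible).
#' @param set_name Label carried into the result.
#' @return An object of class `enrich_fit` with fields `set_name`,
#'   `observed_stat`, `null_mean`, `null_sd`, `fold`, `empirical_p`,
#'   `n_permutations`, `matching`, `seed` and the full `null_stats` vector.
#' @export
matched_permutation_test <- function(gene_stats, gene_set,
                                     score_col = "score",
                                     match_col = "ns_snv_count",
                                     matching = c("exact_count", "log2_bins"),
                                     R = 10000L, seed = 1L,
                                     set_name = "gene_set") {
  matching <- match.arg(matching)
  R <- assert_count(R, "R")
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  if (anyDuplicated(gene_stats$gene)) stop("duplicate genes in universe", call. = FALSE)
  member_idx <- match(gene_set, gene_stats$gene)
  if (anyNA(member_idx)) {
    stop("gene set members absent from universe: ",
         paste(gene_set[is.na(member_idx)], collapse = ", "), call. = FALSE)
  }
  if (length(member_idx) >= nrow(gene_stats)) {
    stop("gene set must be a strict subset of the universe", call. = FALSE)
  }
  scores <- gene_stats[[score_col]]
  mvals <- gene_stats[[match_col]]
  observed <- sum(scores[member_idx])

  pools <- match_pools(mvals, member_idx, matching, gene_names = gene_stats$gene)
  null_stats <- withr::with_seed(seed, {
    sets <- matched_null_sets(pools, R)
    rowSums(matrix(scores[sets], nrow = R))
  })
  emp_p <- (1 + sum(null_stats >= observed)) / (R + 1)
  new_enrich_fit(set_name, observed, null_stats, emp_p, R,
                 paste0(match_col, "/", matching), seed)
}

new_enrich_fit <- function(set_name, observed, null_stats, emp_p, R,
                           matching, seed) {
  structure(list(set_name = set_name, observed_stat = observed,
                 null_mean = mean(null_stats), null_sd = stats::sd(null_stats),
                 fold = if (mean(null_stats) > 0) observed / mean(null_stats) else NA_real_,
                 empirical_p = emp_p, n_permutations = R,
                 matching = matching, seed = seed, null_stats = null_stats),
            class = "enrich_fit")
}

#' @export
print.enrich_fit <- function(x, ...) {
  cat(sprintf("<enrich_fit> %s: observed %.4g vs null %.4g +/- %.4g (%.2f-fold), p = %.4g [%d perms, %s]\n",
              x$set_name, x$observed_stat, x$null_mean, x$null_sd,
              x$fold, x$empirical_p, x$n_permutations, x$matching))
  invisible(x)
}

#' Top-N genes by NS SNV association
#'
#' Ranks genes carrying at least one NS SNV either by their best (minimum)
#' NS SNV p-value (default) or by their number of nominally associated NS
#' SNVs, with ties broken by gene name, and returns the top N.
#'
#' @param variant_results As in [gene_ns_stats()].
#' @param n Number of genes to return.
#' @param ranking `"best_p"` or `"n_nominal"`.
#' @param alpha Nominal level used by the `n_nominal` ranking.
#' @return Character vector of gene names in rank order.
#' @export
topn_genes <- function(variant_results, n, ranking = c("best_p", "n_nominal"),
                       alpha = 0.05) {
  ranking <- match.arg(ranking)
  stats <- gene_ns_stats(variant_results, alpha = alpha)
  stats <- stats[stats$ns_snv_count > 0, , drop = FALSE]
  if (n > nrow(stats)) {
    stop(sprintf("N = %d exceeds the %d genes with NS SNVs", n, nrow(stats)),
         call. = FALSE)
  }
  ord <- if (ranking == "best_p") order(stats$best_p, stats$gene)
         else order(-stats$n_nominal, stats$gene)
  stats$gene[ord][seq_len(n)]
}

#' Hypergeometric term enrichment of a gene set
#'
#' For each annotation term, tests whether the top gene set contains more
#' term members than expected from the background: upper-tail
#' hypergeometric p, fold change observed/expected, and Benjamini-Hochberg
#' q-values across the tested terms.
#'
#' @param top_set Character vector of genes (must be within `background`).
#' @param annotation Tibble/data frame with columns `gene` and `term`.
#' @param background Character vector of background genes.
#' @return Tibble with `term`, `n_term`, `n_overlap`, `fold`, `p_value`,
#'   `q_value`, sorted by p.
#' @export
term_enrichment <- function(top_set, annotation, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  top_set <- unique(top_set)
  if (!all(top_set %in% background)) {
    stop("top set must be contained in the background", call. = FALSE)
  }
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  n_bg <- length(background)
  n_top <- length(top_set)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_term = dplyr::n_distinct(.data$gene),
      n_overlap = dplyr::n_distinct(intersect(.data$gene, top_set)),
      .groups = "drop") |>
    dplyr::filter(.data$n_term > 0) |>
    dplyr::mutate(
      expected = n_top * .data$n_term / n_bg,
      fold = .data$n_overlap / .data$expected,
      p_value = stats::phyper(.data$n_overlap - 1, .data$n_term,
                              n_bg - .data$n_term, n_top, lower.tail = FALSE),
      q_value = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$p_value)
  res
}

#' Overlap of top burden genes with GWA intervals, against length-matched null
#'
#' Counts how many of the top kernel-burden genes fall inside any of the
#' supplied intervals and compares that count with random sets in which each
#' top gene is replaced by a gene matched on genomic length (log2 bins),
#' using the matched-permutation machinery.
#'
#' @param top_genes Character vector of gene names (e.g. the top N by
#'   [skat_scan()] p-value).
#' @param intervals Interval tibble with `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [build_intervals()] /
#'   [extend_intervals()].
#' @param gene_models Tibble with `gene`, `chrom`, `start`, `end`.
#' @param R,seed Permutation replicates and seed.
#' @return An `enrich_fit`; `observed_stat` is the overlap count.
#' @export
interval_overlap_test <- function(top_genes, intervals, gene_models,
                                  R = 10000L, seed = 1L) {
  in_iv <- gene_models$gene %in% genes_in_intervals(gene_models, intervals)
  stats <- tibble::tibble(gene = gene_models$gene,
                          score = as.numeric(in_iv),
                          gene_length = gene_models$end - gene_models$start + 1)
  matched_permutation_test(stats, top_genes, score_col = "score",
                           match_col = "gene_length", matching = "log2_bins",
                           R = R, seed = seed, set_name = "interval_overlap")
}
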
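#' Normalize a gene x tissue expression matrix
#'
#' Per gene (row): (1) feature-scale expression across tissues to `[0, 1]`
#' via `(x - min) / (max - min)`, then (2) divide by the Euclidean norm of
#' the scaled vector, so the squared normalized values of every gene sum to
#' one. Genes with constant expression across tissues are excluded (the
#' scaling is undefined) and listed in the `"excluded"` attribute. Note the
#' operation is not idempotent -- re-scaling an already normalized row
#' changes it -- the contract is the unit-norm post-condition.
#'
#' @param expr A data frame/tibble with a `gene` column and one numeric
#'   column per tissue (FPKM-like, non-negative), or a numeric matrix with
#'   gene rownames.
#' @return A tibble of the same shape with normalized values; excluded
#'   gene names in attribute `"excluded"`.
#' @examples
#' normalize_expression(data.frame(gene = "g1", t1 = 0, t2 = 3, t3 = 4))
#' # scaled (0, 0.75, 1) -> normalized (0, 0.6, 0.8)
#' @export
normalize_expression <- function(expr) {
  if (is.matrix(expr)) {
    expr <- tibble::as_tibble(expr, rownames = "gene")
  }
  stopifnot("gene" %in% names(expr))
  vals <- as.matrix(expr[setdiff(names(expr), "gene")])
  if (any(vals < 0, na.rm = TRUE)) stop("expression must be non-negative", call. = FALSE)
  rng <- apply(vals, 1L, range)
  constant <- rng[1, ] == rng[2, ]
  excluded <- expr$gene[constant]
  vals <- vals[!constant, , drop = FALSE]
  scaled <- (vals - rng[1, !constant]) / (rng[2, !constant] - rng[1, !constant])
  norm <- sqrt(rowSums(scaled^2))
  out <- tibble::as_tibble(scaled / norm)
  out <- tibble::add_column(out, gene = expr$gene[!constant], .before = 1)
  attr(out, "excluded") <- excluded
  out
}

#' Tissue enrichment of a gene set against a CDS-length-matched null
#'
#' For every tissue, compares the summed normalized expression of the gene
#' set with random sets in which each member is replaced by a non-member of
#' similar coding length (log2 CDS-length bins of width 0.5, widened by one
#' bin when fewer than 10 candidates match). The same matched null sets are
#' evaluated in every tissue, so per-tissue p-values are comparable.
#' Empirical p-values use add-one smoothing.
#'
#' @param expr_norm Normalized expression tibble from
#'   [normalize_expression()].
#' @param gene_set Character vector of member genes (must be rows of
#'   `expr_norm`).
#' @param gene_models Tibble with `gene` and `cds_len` covering all
#'   expression genes.
#' @param R Number of null replicates.
#' @param seed Integer seed.
#' @return Tibble with one row per tissue: `tissue`, `observed`,
#'   `null_mean`, `null_sd`, `fold`, `empirical_p`, `n_permutations`.
#' @export
tissue_set_test <- function(expr_norm, gene_set, gene_models, R = 1000L,
                            seed = 1L) {
  R <- assert_count(R, "R")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% expr_norm$gene)) {
    stop("gene set members absent from the expression matrix: ",
         paste(setdiff(gene_set, expr_norm$gene), collapse = ", "), call. = FALSE)
  }
  cds <- gene_models$cds_len[match(expr_norm$gene, gene_models$gene)]
  if (anyNA(cds)) {
    stop("cds_len missing for: ",
         paste(utils::head(expr_norm$gene[is.na(cds)], 5), collapse = ", "),
         call. = FALSE)
  }
  member_idx <- match(gene_set, expr_norm$gene)
  tissues <- setdiff(names(expr_norm), "gene")
  vals <- as.matrix(expr_norm[tissues])
  if (length(member_idx) == nrow(expr_norm)) {
    # degenerate: the set is the whole universe, every null set equals it
    return(purrr::map_dfr(tissues, function(tt) {
      obs <- sum(vals[, tt])
      tibble::tibble(tissue = tt, observed = obs, null_mean = obs,
                     null_sd = 0, fold = 1, empirical_p = 1,
                     n_permutations = R)
    }))
  }
  pools <- match_pools(cds, member_idx, matching = "log2_bins",
                       gene_names = expr_norm$gene)
  withr::with_seed(seed, {
    sets <- matched_null_sets(pools, R)
    purrr::map_dfr(tissues, function(tt) {
      x <- vals[, tt]
      obs <- sum(x[member_idx])
      nulls <- rowSums(matrix(x[sets], nrow = R))
      tibble::tibble(tissue = tt, observed = obs,
                     null_mean = mean(nulls), null_sd = stats::sd(nulls),
                     fold = if (mean(nulls) > 0) obs / mean(nulls) else NA_real_,
                     empirical_p = (1 + sum(nulls >= obs)) / (R + 1),
                     n_permutations = R)
    })
  })
}
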
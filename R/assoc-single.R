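#' Fisher's exact allelic test on a 2x2 allele-count table
#'
#' Two-sided exact test on minor/major allele counts in cases versus
#' controls: the p-value sums all tables with fixed margins whose
#' hypergeometric probability does not exceed that of the observed table.
#' The odds ratio is the sample cross-product `ad/bc`; when any cell is zero
#' it is computed with the Haldane correction (0.5 added to every cell) and
#' the result is flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts, rows = groups
#'   (cases, controls), columns = alleles (alt/minor, ref/major).
#' @return One-row tibble with `test`, `odds_ratio`, `beta` (log OR),
#'   `p_value`, `n_used` (total allele count) and `flag` (`"ok"` or
#'   `"haldane"`).
#' @examples
#' fisher_allelic(matrix(c(9, 11, 447, 1757), nrow = 2))
#' @export
fisher_allelic <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2L)) {
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("test undefined: empty margin in the 2x2 table", call. = FALSE)
  }
  p <- stats::fisher.test(table)$p.value
  flag <- "ok"
  t2 <- table
  if (any(table == 0)) {
    t2 <- table + 0.5
    flag <- "haldane"
  }
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble::tibble(test = "fisher", odds_ratio = or, beta = log(or),
                 p_value = min(p, 1), n_used = sum(table), flag = flag)
}

#' Logistic regression association for one variant
#'
#' Maximum-likelihood logistic fit of case status on the per-sample
#' alternate-allele count plus the first `n_covariates` ancestry principal
#' components, with a Wald p-value on the genotype coefficient. Samples with
#' a missing call are excluded from the test (complete-case per site).
#' Monomorphic variants are skipped, and non-convergence or quasi-complete
#' separation yields a flagged result with an undefined p-value rather than
#' a fabricated one.
#'
#' @param genotype Per-sample alternate-allele count (0/1/2/NA), in the row
#'   order of `samples`.
#' @param samples Sample tibble with `status` and, when `n_covariates > 0`,
#'   `PC1...` columns (see [add_ancestry_pcs()]).
#' @param n_covariates Number of leading PCs to adjust for (0-10).
#' @return One-row tibble with `test`, `odds_ratio` (`exp(beta)`), `beta`,
#'   `p_value`, `n_used` and `flag` in `"ok"`, `"monomorphic"`,
#'   `"separation"`, `"no_converge"`.
#' @export
logistic_assoc <- function(genotype, samples, n_covariates = 2L) {
  stopifnot(length(genotype) == nrow(samples))
  n_covariates <- as.integer(n_covariates)
  if (n_covariates < 0L || n_covariates > 10L) {
    stop("`n_covariates` must be between 0 and 10", call. = FALSE)
  }
  y <- as.numeric(case_mask(samples))
  pcs <- pc_matrix(samples, n_covariates)
  ok <- !is.na(genotype) & !is.na(y)
  if (!is.null(pcs)) ok <- ok & stats::complete.cases(pcs)
  g <- genotype[ok]
  if (length(unique(g)) < 2L) {
    return(tibble::tibble(test = "logistic", odds_ratio = NA_real_,
                          beta = NA_real_, p_value = NA_real_,
                          n_used = sum(ok), flag = "monomorphic"))
  }
  x <- cbind(`(Intercept)` = 1, genotype = g,
             if (!is.null(pcs)) pcs[ok, , drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(x, y[ok], family = stats::binomial(),
                   control = stats::glm.control(maxit = 50))
  )
  beta <- fit$coefficients["genotype"]
  mu <- fit$fitted.values
  flag <- "ok"
  if (is.na(beta)) flag <- "no_converge"
  else {
    if (!fit$converged) flag <- "no_converge"
    if (any(mu < 1e-10 | mu > 1 - 1e-10) && abs(beta) > 8) flag <- "separation"
  }
  if (flag != "ok") {
    return(tibble::tibble(test = "logistic", odds_ratio = NA_real_,
                          beta = unname(beta), p_value = NA_real_,
                          n_used = sum(ok), flag = flag))
  }
  w <- mu * (1 - mu)
  xtwx <- crossprod(x * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(xtwx))))[2]
  z <- beta / se
  tibble::tibble(test = "logistic", odds_ratio = unname(exp(beta)),
                 beta = unname(beta),
                 p_value = unname(2 * stats::pnorm(-abs(z))),
                 n_used = sum(ok), flag = "ok")
}

#' Per-variant association scan over a genotype matrix
#'
#' Runs [logistic_assoc()] and/or the allelic [fisher_allelic()] test for
#' every variant column and returns one tidy row per variant (and per test).
#' Fisher allele counts are alternate versus reference alleles among called
#' genotypes in each group.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param samples Sample tibble (row order must match the matrix).
#' @param variants Optional variant tibble to join onto the results.
#' @param test `"logistic"`, `"fisher"` or `"both"`.
#' @param n_covariates PCs for the logistic test.
#' @return Tibble with `variant_id`, test results, and variant annotation.
#' @export
assoc_scan <- function(genotypes, samples, variants = NULL,
                       test = c("logistic", "fisher", "both"),
                       n_covariates = 2L) {
  assert_genotypes(genotypes)
  test <- match.arg(test)
  stopifnot(identical(rownames(genotypes), samples$sample_id))
  is_case <- case_mask(samples)
  res <- list()
  if (test %in% c("logistic", "both")) {
    res$logistic <- purrr::map_dfr(seq_len(ncol(genotypes)), function(j) {
      dplyr::bind_cols(tibble::tibble(variant_id = colnames(genotypes)[j]),
                       logistic_assoc(genotypes[, j], samples, n_covariates))
    })
  }
  if (test %in% c("fisher", "both")) {
    res$fisher <- purrr::map_dfr(seq_len(ncol(genotypes)), function(j) {
      g <- genotypes[, j]
      a_case <- sum(g[is_case], na.rm = TRUE)
      n_case <- 2 * sum(!is.na(g[is_case]))
      a_ctrl <- sum(g[!is_case], na.rm = TRUE)
      n_ctrl <- 2 * sum(!is.na(g[!is_case]))
      tab <- matrix(c(a_case, a_ctrl, n_case - a_case, n_ctrl - a_ctrl), nrow = 2)
      row <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        tibble::tibble(test = "fisher", odds_ratio = NA_real_, beta = NA_real_,
                       p_value = NA_real_, n_used = sum(tab), flag = "empty_margin")
      } else {
        fisher_allelic(tab)
      }
      dplyr::bind_cols(tibble::tibble(variant_id = colnames(genotypes)[j]), row)
    })
  }
  out <- dplyr::bind_rows(res)
  if (!is.null(variants)) {
    out <- dplyr::left_join(out, variants, by = "variant_id")
  }
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 21235)   # 2.4e-6 at two significant figures
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  assert_count(n_tests, "n_tests")
  assert_scalar_prop(alpha, "alpha", 0, 1, lo_open = TRUE)
  alpha / n_tests
}

#' Genomic inflation factor lambda
#'
#' Ratio of the median 1-df chi-square quantile of the observed p-values to
#' the theoretical null median (0.4549364); values near 1 indicate a
#' calibrated test, values above ~1.1 suggest confounding such as
#' population stratification.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`; at least 100.
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L) stop("need at least 100 p-values", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Genomic inflation as a function of the number of ancestry covariates
#'
#' Re-runs the logistic scan with 0..`max_covariates` leading PCs and
#' reports lambda for each choice, mirroring the practice of picking the
#' covariate count that best calibrates the quantile-quantile plot.
#'
#' @inheritParams assoc_scan
#' @param max_covariates Largest number of PCs to try.
#' @param min_maf Restrict the lambda computation to variants at or above
#'   this cohort MAF (discreteness at very rare variants makes their Wald
#'   p-values uninformative about calibration).
#' @return Tibble with `n_covariates` and `lambda`.
#' @export
lambda_by_covariates <- function(genotypes, samples, max_covariates = 10L,
                                 min_maf = 0.05) {
  mafs <- compute_maf(genotypes)
  keep <- !is.na(mafs$maf) & mafs$maf >= min_maf
  g <- genotypes[, keep, drop = FALSE]
  purrr::map_dfr(0:max_covariates, function(k) {
    p <- assoc_scan(g, samples, test = "logistic", n_covariates = k)$p_value
    tibble::tibble(n_covariates = k, lambda = genomic_lambda(p[!is.na(p)]))
  })
}

#' Quantile-quantile and Manhattan plot tables
#'
#' Builds plot-ready tables from an association result: the QQ table pairs
#' sorted observed `-log10(p)` with expected quantiles `-log10(i / (n + 1))`,
#' and the Manhattan table lays variants on a cumulative genome coordinate
#' with an above-threshold flag and gene label.
#'
#' @param results Tibble with `p_value` and, for the Manhattan table,
#'   `chrom` and `pos` (and optionally `gene`).
#' @param threshold Significance threshold used for flagging (e.g.
#'   [bonferroni_threshold()]); `NULL` disables the flag.
#' @return List with tibbles `qq` and `manhattan` (the latter `NULL` when
#'   coordinates are absent).
#' @export
qq_manhattan_tables <- function(results, threshold = NULL) {
  stopifnot(nrow(results) > 0)
  p <- results$p_value
  ok <- !is.na(p)
  n <- sum(ok)
  qq <- tibble::tibble(
    expected = -log10(seq_len(n) / (n + 1)),
    observed = sort(-log10(p[ok]), decreasing = TRUE)
  )
  man <- NULL
  if (all(c("chrom", "pos") %in% names(results))) {
    man <- results[ok, , drop = FALSE]
    offs <- man |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$pos), .groups = "drop") |>
      dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
    man <- man |>
      dplyr::left_join(offs[c("chrom", "offset")], by = "chrom") |>
      dplyr::mutate(coord = .data$pos + .data$offset,
                    neg_log10_p = -log10(.data$p_value),
                    above_threshold = if (is.null(threshold)) FALSE
                                      else .data$p_value < threshold,
                    gene = if ("gene" %in% names(results)) .data$gene else "") |>
      dplyr::select(dplyr::any_of(c("variant_id", "chrom", "pos", "coord",
                                    "neg_log10_p", "above_threshold", "gene")))
  }
  list(qq = qq, manhattan = man)
}
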
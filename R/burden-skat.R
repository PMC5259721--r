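#' Beta-density minor-allele-frequency weights
#'
#' Per-variant weights `w = dbeta(maf, a1, a2)`; the default shape (1, 25)
#' up-weights rarer variants, reducing to `25 * (1 - maf)^24`. Weights are
#' strictly decreasing in MAF for `a1 = 1`.
#'
#' @param mafs Minor allele frequencies in `(0, 0.5]`; a zero MAF is an
#'   error (monomorphic variants must be excluded upstream).
#' @param a1,a2 Beta distribution shape parameters.
#' @return Numeric vector of weights.
#' @examples
#' maf_weights(c(0.5, 0.01))   # ~1.49e-6 and ~19.63
#' @export
maf_weights <- function(mafs, a1 = 1, a2 = 25) {
  if (any(is.na(mafs)) || any(mafs <= 0) || any(mafs > 0.5)) {
    stop("MAFs must lie in (0, 0.5]; exclude monomorphic variants first",
         call. = FALSE)
  }
  stats::dbeta(mafs, a1, a2)
}

# tail probability of Q ~ sum_i lambda_i chi^2_1 by the four-moment
# (non-central chi-square) matching of Liu, Tang & Zhang (2009)
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(1)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    d <- 0
  }
  t_star <- (q - c1) / sqrt(2 * c2)
  x <- t_star * sqrt(2 * (l + 2 * d)) + l + d
  stats::pchisq(x, df = l, ncp = d, lower.tail = FALSE)
}

# Imhof (1961) numerical inversion of the characteristic function
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(liu_pvalue(q, lambda))
  min(max(0.5 + val / pi, 1e-12), 1)
}

skat_mixture_pvalue <- function(q, lambda, method = c("liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda) || q <= 0) return(1)
  p <- switch(method, liu = liu_pvalue(q, lambda), imhof = imhof_pvalue(q, lambda))
  min(max(p, 1e-300), 1)
}

#' Variance-component (kernel) burden test for a gene
#'
#' Score-type test aggregating the variants of a gene against a null
#' logistic model of case status on covariates only. With `r = y - mu` the
#' null residuals, `G` the genotype block and `W = diag(w)` the Beta(a1,a2)
#' MAF weights, the statistic is the weighted linear-kernel quadratic form
#'
#'   `Q = r' G W^2 G' r`
#'
#' whose null distribution is a mixture `sum_i lambda_i chi^2_1`, with
#' eigenvalues taken from the covariate-projected weighted kernel
#' `Z' (V - V X (X'VX)^-1 X'V) Z`, `Z = GW`, `V = diag(mu(1-mu))`. Because
#' the quadratic form is symmetric in risk and protective directions, the
#' test retains power when a gene carries effects of both signs. The tail
#' probability uses four-moment matching by default (`method = "liu"`), with
#' Imhof's exact numerical inversion available as `method = "imhof"`.
#'
#' Monomorphic variants are excluded (listed in the result); missing
#' genotypes are imputed to twice the variant allele frequency. A block with
#' no polymorphic variant yields `Q = 0`, `p = 1`.
#'
#' @param genotypes Samples x variants genotype block for one gene.
#' @param samples Sample tibble with `status` and PC columns as needed.
#' @param n_covariates Number of leading PCs in the null model.
#' @param weights_beta Length-2 Beta shape parameters for the MAF weights.
#' @param method Mixture tail approximation: `"liu"` or `"imhof"`.
#' @param gene Optional gene label carried into the result.
#' @return An object of class `skat_fit`: list with `gene`, `q_stat`,
#'   `p_value`, `n_variants`, `eigen_spectrum`, `excluded`, `method`,
#'   `n_samples`. Use [generics::tidy()] / [generics::glance()] for tibbles.
#' @export
skat_test <- function(genotypes, samples, n_covariates = 2L,
                      weights_beta = c(1, 25), method = c("liu", "imhof"),
                      gene = NA_character_) {
  method <- match.arg(method)
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(genotypes, ncol = 1,
                        dimnames = list(samples$sample_id, "v1"))
  }
  stopifnot(nrow(genotypes) == nrow(samples))
  y <- as.numeric(case_mask(samples))
  pcs <- pc_matrix(samples, n_covariates)
  x <- cbind(`(Intercept)` = rep(1, length(y)), pcs)

  f <- colMeans(genotypes, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  excluded <- colnames(genotypes)[!poly]
  if (!any(poly)) {
    return(new_skat_fit(gene, 0, 1, 0L, numeric(), excluded, method, nrow(samples)))
  }
  g <- genotypes[, poly, drop = FALSE]
  f <- f[poly]
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- 2 * f[j]
  }
  maf <- pmin(f, 1 - f)
  w <- maf_weights(maf, weights_beta[1], weights_beta[2])
  z <- g * rep(w, each = nrow(g))

  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  if (!fit$converged) {
    stop("null model did not converge; gene skipped", call. = FALSE)
  }
  mu <- fit$fitted.values
  r <- y - mu
  v <- mu * (1 - mu)

  q_stat <- sum(crossprod(z, r)^2)

  vz <- z * v
  ztvz <- crossprod(z, vz)
  ztvx <- crossprod(vz, x)                      # Z'VX
  xtvx <- crossprod(x, x * v)
  a <- ztvz - ztvx %*% solve(xtvx, t(ztvx))
  lambda <- eigen((a + t(a)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]

  p <- skat_mixture_pvalue(q_stat, lambda, method)
  new_skat_fit(gene, q_stat, p, ncol(z), lambda, excluded, method, length(y))
}

new_skat_fit <- function(gene, q, p, m, lambda, excluded, method, n) {
  structure(list(gene = gene, q_stat = q, p_value = p, n_variants = m,
                 eigen_spectrum = lambda, excluded = excluded,
                 method = method, n_samples = n),
            class = "skat_fit")
}

#' @export
print.skat_fit <- function(x, ...) {
  cat(sprintf("<skat_fit> gene %s: Q = %.4g, p = %.3g (%d variant(s), %s tail)\n",
              x$gene, x$q_stat, x$p_value, x$n_variants, x$method))
  invisible(x)
}

#' Gene-level kernel burden scan
#'
#' Runs [skat_test()] for every gene, by default over the non-synonymous
#' variants (classes `NS` and `STOP`), optionally restricted to rare
#' variants.
#'
#' @param genotypes Samples x variants genotype matrix.
#' @param samples Sample tibble.
#' @param variants Variant tibble with `variant_id`, `gene`, `csq_class`
#'   (and `is_rare` when `rare_only`).
#' @param ns_only Restrict to non-synonymous (incl. stop) variants.
#' @param rare_only Restrict to variants flagged rare.
#' @inheritParams skat_test
#' @return Tibble with `gene`, `n_variants`, `q_stat`, `p_value`.
#' @export
skat_scan <- function(genotypes, samples, variants, n_covariates = 2L,
                      weights_beta = c(1, 25), method = "liu",
                      ns_only = TRUE, rare_only = FALSE) {
  v <- variants
  if (ns_only) v <- v[is_ns_class(v$csq_class), , drop = FALSE]
  if (rare_only) v <- v[!is.na(v$is_rare) & v$is_rare, , drop = FALSE]
  v <- v[v$variant_id %in% colnames(genotypes), , drop = FALSE]
  purrr::map_dfr(split(v$variant_id, v$gene), function(ids) {
    fit <- tryCatch(
      skat_test(genotypes[, ids, drop = FALSE], samples,
                n_covariates = n_covariates, weights_beta = weights_beta,
                method = method),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(n_variants = length(ids), q_stat = NA_real_,
                            p_value = NA_real_))
    }
    tibble::tibble(n_variants = fit$n_variants, q_stat = fit$q_stat,
                   p_value = fit$p_value)
  }, .id = "gene")
}
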
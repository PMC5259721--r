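test_that("configuration invariants are enforced", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(causal_or = 0.5), "causal_or")
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(recomb_prob = 1.2), "recomb_prob")
  expect_error(sim_config(related_pair_pi_hat = 1.5), "related_pair_pi_hat")
  expect_silent(sim_config(n_cases = 5, n_controls = 5, n_genes = 3))
})

test_that("equal seeds reproduce cohorts byte-identically, different seeds differ", {
  a <- small_cohort(seed = 11)
  b <- small_cohort(seed = 11)
  c <- small_cohort(seed = 12)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$samples, b$samples)
  expect_identical(a$variants, b$variants)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("marginal allele frequencies are exact under Fst = 0", {
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_genes = 10,
                    variants_per_gene = 5, fst = 0, n_haplotypes = 10000,
                    maf_spectrum = list(rare_frac = 0,
                                        rare_range = c(0.001, 0.01),
                                        common_range = c(0.3, 0.3)),
                    seed = 4)
  panel <- simulate_haplotypes(cfg)
  freqs <- colMeans(panel$haplotypes)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_true(all(abs(freqs - 0.3) < 3.5 * se))
  expect_true(all(panel$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(panel$variants$pos) > 0))
})

test_that("recomb_prob = 0 gives perfect LD between equal-frequency variants of a block", {
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_genes = 10,
                    variants_per_gene = 5, recomb_prob = 0,
                    maf_spectrum = list(rare_frac = 0,
                                        rare_range = c(0.001, 0.01),
                                        common_range = c(0.25, 0.25)),
                    n_haplotypes = 2000, seed = 5)
  panel <- simulate_haplotypes(cfg)
  v <- panel$variants
  within <- which(diff(v$block) == 0)
  r2 <- vapply(within[1:10], function(i) haplotype_r2(panel, i, i + 1), numeric(1))
  expect_equal(r2, rep(1, 10))
})

test_that("recomb_prob = 0.5 leaves little adjacent LD under the default spectrum", {
  cfg <- sim_config(n_cases = 5, n_controls = 5, n_genes = 60,
                    variants_per_gene = 10, recomb_prob = 0.5,
                    n_haplotypes = 20000, seed = 6)
  panel <- simulate_haplotypes(cfg)
  v <- panel$variants
  h <- panel$haplotypes
  within <- which(diff(v$block) == 0)
  r2 <- vapply(within, function(i) {
    f <- colMeans(h[, c(i, i + 1)])
    if (any(f %in% c(0, 1))) return(NA_real_)
    haplotype_r2(h, i, i + 1)
  }, numeric(1))
  expect_lt(mean(r2, na.rm = TRUE), 0.05)
})

test_that("null disease model yields a balanced case fraction", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_genes = 10,
                    baseline_logit = 0, causal_or = 1, seed = 7)
  panel <- simulate_haplotypes(cfg)
  # classify the panel's candidate individuals before quota filling:
  # the case quota among the first draws reflects P(case) = 0.5
  co <- simulate_cohort(panel, cfg)
  expect_equal(sum(co$samples$status == "case"), 100)
  expect_equal(sum(co$samples$status == "control"), 100)
})

test_that("null cohorts show no systematic case/control MAF difference", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, n_genes = 40,
                    causal_or = 1, seed = 8, missing_rate = 0)
  co <- simulate_cohort(simulate_haplotypes(cfg), cfg)
  is_case <- co$samples$status == "case"
  fc <- compute_maf(co$genotypes, subset = which(is_case))
  fk <- compute_maf(co$genotypes, subset = which(!is_case))
  f_all <- compute_maf(co$genotypes)$alt_freq
  # binomial sampling bound on the difference of two group frequencies
  se <- sqrt(f_all * (1 - f_all) * (1 / (2 * 300) + 1 / (2 * 300)))
  ok <- !is.na(fc$alt_freq) & se > 0
  frac_within <- mean(abs(fc$alt_freq - fk$alt_freq)[ok] <= 4 * se[ok])
  expect_gte(frac_within, 0.95)
})

test_that("a planted causal gene elevates case MAF at its variants", {
  pre <- sim_config(n_cases = 10, n_controls = 10, n_genes = 12,
                    variants_per_gene = 12, seed = 9,
                    maf_spectrum = list(rare_frac = 1,
                                        rare_range = c(0.01, 0.01),
                                        common_range = c(0.1, 0.2)))
  panel <- simulate_haplotypes(pre)
  sizes <- table(panel$variants$gene)
  target <- names(which.max(sizes))
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_genes = 12,
                    variants_per_gene = 12, seed = 9,
                    maf_spectrum = list(rare_frac = 1,
                                        rare_range = c(0.01, 0.01),
                                        common_range = c(0.1, 0.2)),
                    causal_gene_set = target, causal_or = 3,
                    missing_rate = 0)
  co <- simulate_cohort(simulate_haplotypes(cfg), cfg)
  is_case <- co$samples$status == "case"
  fc <- compute_maf(co$genotypes, subset = which(is_case))$alt_freq
  fk <- compute_maf(co$genotypes, subset = which(!is_case))$alt_freq
  idx <- which(co$variants$is_causal & (fc + fk) > 0)
  up <- sum(fc[idx] > fk[idx])
  p_sign <- stats::binom.test(up, length(idx), 0.5, alternative = "greater")$p.value
  expect_lt(p_sign, 0.01)
})

test_that("unreachable case quotas fail with a bounded-retry diagnostic", {
  cfg <- sim_config(n_cases = 500, n_controls = 5, n_genes = 5,
                    baseline_logit = -12, n_haplotypes = 40, seed = 10)
  panel <- simulate_haplotypes(cfg)
  expect_error(simulate_cohort(panel, cfg, max_batches = 2L),
               "could not reach requested cohort size")
})

test_that("inject_related_pair hits its target relatedness", {
  g <- hwe_genotypes(50, runif(20000, 0.1, 0.5), seed = 30)
  dup <- inject_related_pair(g, 1, seed = 1)
  expect_identical(dup$genotypes[dup$new_id, ], dup$genotypes[dup$template_id, ])
  expect_gte(ibd_estimate(dup$genotypes, c(dup$template_id, dup$new_id)), 0.95)
  indep <- inject_related_pair(g, 0, seed = 2)
  expect_lte(ibd_estimate(indep$genotypes, c(indep$template_id, indep$new_id)), 0.05)
  half <- inject_related_pair(g, 0.5, seed = 3)
  est <- ibd_estimate(half$genotypes, c(half$template_id, half$new_id))
  expect_lt(abs(est - 0.5), 0.05)
  expect_error(inject_related_pair(g, 1.2), "target_pi_hat")
})

test_that("write_cohort emits a well-formed VCF that round-trips", {
  co <- small_cohort(seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co$genotypes, co$samples, co$variants,
                        file.path(dir, "toy"))
  lines <- readLines(paths["vcf"])
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, ncol(co$genotypes))
  header_cols <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1]]
  expect_length(header_cols, 9 + nrow(co$genotypes))

  rt <- read_cohort(paths["vcf"], paths["pheno"])
  expect_identical(unname(rt$genotypes[co$samples$sample_id, ]),
                   unname(co$genotypes))
  expect_identical(rt$variants$gene, co$variants$gene)
  expect_identical(rt$variants$csq_class, co$variants$csq_class)
  # missing encoded ./. comes back as NA, never as 0
  miss <- which(is.na(co$genotypes), arr.ind = TRUE)
  expect_gt(nrow(miss), 0)
  expect_true(all(is.na(rt$genotypes[co$samples$sample_id, ][miss])))
})

test_that("a tiny 3 x 2 cohort writes exactly two data rows and three samples", {
  g <- matrix(c(0L, 1L, 2L, NA, 0L, 1L), nrow = 3,
              dimnames = list(c("sA", "sB", "sC"), c("v1", "v2")))
  smp <- tibble::tibble(sample_id = c("sA", "sB", "sC"),
                        status = c("case", "control", "case"), subpop = 1L)
  vt <- tibble::tibble(variant_id = c("v1", "v2"), chrom = "1",
                       pos = c(100L, 200L), ref = c("A", "C"),
                       alt = c("G", "T"), gene = "g1",
                       csq_class = c("NS", "SYN"))
  dir <- withr::local_tempdir()
  paths <- write_cohort(g, smp, vt, file.path(dir, "mini"))
  body <- grep("^#", readLines(paths["vcf"]), value = TRUE, invert = TRUE)
  expect_length(body, 2)
  expect_length(strsplit(body[1], "\t")[[1]], 12)   # 9 fixed + 3 samples
  rt <- read_cohort(paths["vcf"], paths["pheno"])
  expect_identical(rt$genotypes[c("sA", "sB", "sC"), "v2"],
                   c(sA = NA_integer_, sB = 0L, sC = 1L))
})
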
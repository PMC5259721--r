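make_vcf <- function(dir, gt_rows, alt = c("G", "T")) {
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="c">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sX", "sY"), collapse = "\t"),
    vapply(seq_along(gt_rows), function(i) {
      paste(c("1", 100 * i, paste0("v", i), "A", alt[i], ".", "PASS",
              "GENE=g1;CSQ_CLASS=NS", "GT", gt_rows[[i]]), collapse = "\t")
    }, character(1))), vcf)
  vcf
}

make_pheno <- function(dir, ids = c("sX", "sY"), status = c(2L, 1L)) {
  p <- file.path(dir, "t.pheno.tsv")
  utils::write.table(data.frame(sample_id = ids, status = status), p,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("read_cohort decodes genotypes, missing and annotations", {
  dir <- withr::local_tempdir()
  vcf <- make_vcf(dir, list(c("0/1", "1/1"), c("./.", "0/0")))
  ph <- make_pheno(dir)
  co <- read_cohort(vcf, ph)
  expect_identical(co$genotypes[, "v1"], c(sX = 1L, sY = 2L))
  expect_identical(co$genotypes[, "v2"], c(sX = NA_integer_, sY = 0L))
  expect_identical(co$samples$status, c("case", "control"))
  expect_identical(co$variants$csq_class, c("NS", "NS"))
})

test_that("read_cohort rejects sample mismatches naming the offender", {
  dir <- withr::local_tempdir()
  vcf <- make_vcf(dir, list(c("0/0", "0/1")))
  ph <- make_pheno(dir, ids = c("sX", "sZ"))
  expect_error(read_cohort(vcf, ph), "sY")
  expect_error(read_cohort(vcf, ph), "sZ")
})

test_that("read_cohort rejects multi-allelic records and malformed GT", {
  dir <- withr::local_tempdir()
  vcf <- make_vcf(dir, list(c("0/1", "0/0")), alt = "G,T")
  ph <- make_pheno(dir)
  expect_error(read_cohort(vcf, ph), "multi-allelic")
  vcf2 <- make_vcf(dir, list(c("0/3", "0/0")))
  expect_error(read_cohort(vcf2, ph), "malformed GT")
})

test_that("call-rate filter applies the >= contract at the 99% boundary", {
  g <- hwe_genotypes(100, rep(0.3, 3), seed = 2)
  g[1:2, 1] <- NA   # 98% called -> removed
  g[1, 2] <- NA     # 99% called -> retained
  out <- filter_call_rate(g, 0.99)
  expect_identical(colnames(out), c("v00002", "v00003"))
  expect_identical(attr(out, "removed"), "v00001")
  # idempotent (same variants retained on re-application)
  again <- filter_call_rate(out, 0.99)
  expect_identical(colnames(again), colnames(out))
  expect_identical(attr(again, "removed"), character(0))
  expect_equal(again, out, ignore_attr = TRUE)
  # min_rate = 0 retains even a fully missing variant (rate >= 0)
  g[, 3] <- NA
  expect_identical(colnames(filter_call_rate(g, 0)), colnames(g))
})

test_that("MAF arithmetic reproduces carrier-count reconstructions", {
  # 12 heterozygous carriers among 884 diploid controls
  g <- matrix(c(rep(1L, 12), rep(0L, 872)), ncol = 1,
              dimnames = list(sprintf("c%03d", 1:884), "rs_a"))
  expect_equal(round(compute_maf(g)$maf, 8), 0.00678733)
  # 14 heterozygous among 536 cases
  g <- matrix(c(rep(1L, 14), rep(0L, 522)), ncol = 1,
              dimnames = list(sprintf("c%03d", 1:536), "rs_b"))
  expect_equal(round(compute_maf(g)$maf, 5), 0.01306)
  # 3 heterozygous among 260 controls
  g <- matrix(c(rep(1L, 3), rep(0L, 257)), ncol = 1,
              dimnames = list(sprintf("c%03d", 1:260), "rs_c"))
  expect_equal(round(compute_maf(g)$maf, 6), 0.005769)
})

test_that("MAF folds to <= 0.5, flags all-missing, and is relabel-invariant", {
  g <- cbind(v1 = c(2L, 2L, 2L, 1L), v2 = c(0L, 0L, 0L, 0L),
             v3 = c(NA, NA, NA, NA), v4 = c(0L, 1L, 2L, 1L))
  rownames(g) <- paste0("s", 1:4)
  m <- compute_maf(g)
  expect_true(all(m$maf[!is.na(m$maf)] <= 0.5))
  expect_equal(m$maf[m$variant_id == "v1"], 1 - 7 / 8)  # folded
  expect_equal(m$maf[m$variant_id == "v2"], 0)          # monomorphic
  expect_true(is.na(m$maf[m$variant_id == "v3"]))       # undefined, not 0
  # allele relabelling (alt count g -> 2 - g) leaves the folded MAF unchanged
  g2 <- g; g2[, "v4"] <- 2L - g2[, "v4"]
  expect_equal(compute_maf(g2)$maf[4], m$maf[4])
})

test_that("rare flag uses a strict < threshold on control MAF", {
  v <- tibble::tibble(variant_id = paste0("v", 1:4),
                      maf_controls = c(0.0099, 0.01, 0.005769, NA))
  out <- flag_rare(v)
  expect_identical(out$is_rare, c(TRUE, FALSE, TRUE, NA))
  expect_identical(flag_rare(out)$is_rare, out$is_rare)  # idempotent
})

test_that("IBD estimation needs its informative-variant floor", {
  g <- hwe_genotypes(10, rep(0.3, 100), seed = 3)
  expect_error(ibd_estimate(g, c("s0001", "s0002")), "informative variants")
  expect_error(prune_related(g, sample_table(rep(0, 10))), "informative")
})

test_that("relatedness pruning removes exactly one member per planted pair", {
  g <- hwe_genotypes(30, runif(3000, 0.1, 0.5), seed = 4)
  dup <- inject_related_pair(g, 1, seed = 5, template = "s0010")
  smp <- sample_table(rep(0, 31), ids = rownames(dup$genotypes))
  pruned <- prune_related(dup$genotypes, smp)
  expect_length(pruned$removed, 1)
  expect_true(pruned$removed %in% c("s0010", "s0010_rel"))
  # re-scan: no remaining pair above threshold
  expect_length(prune_related(pruned$genotypes, pruned$samples)$removed, 0)
  # no pair above threshold -> identity
  ident <- prune_related(g, sample_table(rep(0, 30)))
  expect_identical(ident$genotypes, g)
  expect_length(ident$removed, 0)
})

test_that("a pair exactly at the threshold is retained (strict >)", {
  g <- hwe_genotypes(20, runif(2500, 0.2, 0.5), seed = 6)
  half <- inject_related_pair(g, 0.5, seed = 7)
  est <- ibd_estimate(half$genotypes, c(half$template_id, half$new_id))
  smp <- sample_table(rep(0, 21), ids = rownames(half$genotypes))
  at <- prune_related(half$genotypes, smp, threshold = as.numeric(est))
  expect_length(at$removed, 0)
  below <- prune_related(half$genotypes, smp, threshold = as.numeric(est) - 1e-6)
  expect_length(below$removed, 1)
})

test_that("ancestry PCs separate divergent subpopulations", {
  withr::with_seed(8, {
    p_anc <- runif(5000, 0.05, 0.5)
    f <- 0.05
    p1 <- rbeta(5000, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    p2 <- rbeta(5000, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    g <- rbind(vapply(p1, function(p) rbinom(100, 2L, p), integer(100)),
               vapply(p2, function(p) rbinom(100, 2L, p), integer(100)))
    dimnames(g) <- list(sprintf("s%04d", 1:200), sprintf("v%05d", 1:5000))
  })
  pcs <- pca_ancestry(g, 2)
  label <- rep(c(0, 1), each = 100)
  expect_gt(abs(cor(pcs$PC1, label)), 0.9)
  # orthonormal components, up to sign
  cp <- crossprod(as.matrix(pcs[c("PC1", "PC2")]))
  expect_lt(max(abs(cp - diag(2))), 1e-8)
})

test_that("a homogeneous population shows no dominant component", {
  g <- hwe_genotypes(200, runif(5000, 0.05, 0.5), seed = 9)
  pcs <- pca_ancestry(g, 2)
  ve <- attr(pcs, "var_explained")
  expect_lt(ve[1], 2.5 / 200)   # near the 1/n baseline, no cluster axis
  withr::with_seed(10, {
    fake <- sample(rep(c(0, 1), each = 100))
  })
  expect_lt(abs(cor(pcs$PC1, fake)), 0.3)
})

test_that("degenerate genotype matrices are rejected by the PCA", {
  g <- matrix(1L, 10, 5, dimnames = list(paste0("s", 1:10), paste0("v", 1:5)))
  expect_error(pca_ancestry(g), "polymorphic|degenerate")
  g2 <- hwe_genotypes(3, rep(0.4, 10), seed = 11)
  expect_error(pca_ancestry(g2, 3), "n_components")
})
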
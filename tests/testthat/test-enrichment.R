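fake_variant_results <- function(genes, csq, p) {
  tibble::tibble(gene = genes, csq_class = csq, p_value = p)
}

test_that("variant-level set scores sum -log10 p over member NS SNVs", {
  vr <- fake_variant_results(c("a", "a", "b", "c"),
                             c("NS", "NS", "SYN", "NS"),
                             c(0.1, 0.01, 1e-6, 1))
  expect_equal(set_score_variant_level("a", vr), 3)        # 1 + 2
  expect_equal(set_score_variant_level(c("a", "c"), vr), 3)  # p = 1 adds 0
  expect_equal(set_score_variant_level("b", vr), 0)        # only a SYN variant
  expect_equal(set_score_variant_level("zz", vr), 0)       # no NS SNVs at all
})

test_that("gene-level set scores mirror the kernel-test p-values", {
  gr <- tibble::tibble(gene = c("a", "b", "c"), p_value = c(0.5, 0.05, 1))
  expect_equal(set_score_gene_level(c("a", "b"), gr),
               -log10(0.5) - log10(0.05), tolerance = 1e-10)
  expect_equal(round(set_score_gene_level(c("a", "b"), gr), 4), 1.6021)
  expect_equal(set_score_gene_level("a", gr), -log10(0.5))
  expect_equal(set_score_gene_level("absent", gr), 0)
})

make_gene_stats <- function(n = 300, seed = 1) {
  withr::with_seed(seed, {
    counts <- pmax(1L, rpois(n, 4))
    tibble::tibble(gene = sprintf("G%03d", seq_len(n)),
                   ns_snv_count = counts,
                   score = vapply(counts,
                                  function(k) sum(-log10(runif(k))), numeric(1)))
  })
}

test_that("matched permutation test validates its contract", {
  gs <- make_gene_stats()
  expect_error(matched_permutation_test(gs, gs$gene), "strict subset")
  expect_error(matched_permutation_test(gs, character()), "empty")
  expect_error(matched_permutation_test(gs, "NOPE"), "absent")
})

test_that("matched permutation results are reproducible and smoothed", {
  gs <- make_gene_stats(seed = 2)
  set <- gs$gene[1:6]
  f1 <- matched_permutation_test(gs, set, R = 500, seed = 42)
  f2 <- matched_permutation_test(gs, set, R = 500, seed = 42)
  expect_identical(f1$null_stats, f2$null_stats)
  expect_identical(f1$empirical_p, f2$empirical_p)
  f3 <- matched_permutation_test(gs, set, R = 500, seed = 43)
  expect_false(identical(f1$null_stats, f3$null_stats))
  expect_gte(f1$empirical_p, 1 / 501)
  # null sets respect within-replicate uniqueness and exclude members
  expect_true(all(tidy(f1)$observed_stat == f1$observed_stat))
})

test_that("null replacement sets preserve the matching covariate", {
  gs <- make_gene_stats(seed = 3)
  set <- gs$gene[c(1, 5, 9)]
  pools <- exocohort:::match_pools(gs$ns_snv_count, match(set, gs$gene),
                                   "exact_count", gene_names = gs$gene)
  for (i in seq_along(set)) {
    target <- gs$ns_snv_count[match(set[i], gs$gene)]
    vals <- gs$ns_snv_count[pools[[i]]]
    if (length(vals) >= 10) {
      expect_true(all(vals == target) ||
                    all(vals >= floor(0.8 * target) & vals <= ceiling(1.2 * target)))
    }
    expect_false(any(gs$gene[pools[[i]]] %in% set))
  }
})

test_that("decreasing a member SNV p never weakens observed enrichment", {
  gs <- make_gene_stats(seed = 4)
  set <- gs$gene[1:5]
  base <- matched_permutation_test(gs, set, R = 400, seed = 9)
  gs2 <- gs
  gs2$score[1] <- gs2$score[1] + 2   # one member SNV p dropped 100-fold
  better <- matched_permutation_test(gs2, set, R = 400, seed = 9)
  expect_gt(better$observed_stat, base$observed_stat)
  expect_lte(better$empirical_p, base$empirical_p)
})

test_that("an enriched set with 10x smaller SNV p-values is detected", {
  withr::with_seed(5, {
    counts <- pmax(1L, rpois(400, 4))
    gene <- sprintf("G%03d", 1:400)
    set <- sample(gene, 10)
    score <- vapply(seq_along(gene), function(i) {
      u <- runif(counts[i])
      if (gene[i] %in% set) u <- u / 10
      sum(-log10(u))
    }, numeric(1))
  })
  gs <- tibble::tibble(gene = gene, ns_snv_count = counts, score = score)
  fit <- matched_permutation_test(gs, set, R = 10000, seed = 6)
  expect_lte(fit$empirical_p, 0.01)
  expect_gt(fit$fold, 1)
})

test_that("top-N gene ranking follows best NS SNV p with lexicographic ties", {
  vr <- fake_variant_results(c("a", "b", "c", "c"),
                             c("NS", "NS", "NS", "NS"),
                             c(0.2, 0.01, 0.05, 0.9))
  expect_identical(topn_genes(vr, 2), c("b", "c"))
  expect_identical(topn_genes(vr, 3), c("b", "c", "a"))
  tie <- fake_variant_results(c("zz", "aa"), c("NS", "NS"), c(0.05, 0.05))
  expect_identical(topn_genes(tie, 1), "aa")
  expect_error(topn_genes(vr, 10), "exceeds")
  # alternative ranking: count of nominal SNVs
  expect_identical(topn_genes(vr, 1, ranking = "n_nominal"), "b")
})

test_that("term enrichment reproduces the hypergeometric upper tail", {
  bg <- sprintf("G%04d", 1:1000)
  term_genes <- bg[1:100]
  top <- c(bg[1:9], bg[200:240])     # 50 genes, 9 in the term
  ann <- tibble::tibble(gene = term_genes, term = "T1")
  res <- term_enrichment(top, ann, bg)
  expect_equal(res$fold, 9 / 5)
  p_oracle <- sum(stats::dhyper(9:50, 100, 900, 50))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  # term covering the whole background: fold 1, p 1
  res_all <- term_enrichment(top, tibble::tibble(gene = bg, term = "ALL"), bg)
  expect_equal(res_all$fold[res_all$term == "ALL"], 1)
  expect_equal(res_all$p_value[res_all$term == "ALL"], 1)

  # no overlap: fold 0, p = P(X >= 0) = 1
  res0 <- term_enrichment(bg[500:520],
                          tibble::tibble(gene = bg[1:50], term = "T2"), bg)
  expect_equal(res0$fold, 0)
  expect_equal(res0$p_value, 1)
  expect_error(term_enrichment(top, ann, character()), "background")
})

test_that("BH q-values are monotone with the p-values across terms", {
  withr::with_seed(7, {
    bg <- sprintf("G%04d", 1:500)
    ann <- tibble::tibble(gene = sample(bg, 600, replace = TRUE),
                          term = sample(paste0("T", 1:12), 600, replace = TRUE))
    top <- sample(bg, 40)
  })
  res <- term_enrichment(top, ann, bg)
  expect_identical(res$q_value, stats::p.adjust(res$p_value, "BH"))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})

test_that("interval overlap test handles saturated and empty intervals", {
  gm <- tibble::tibble(gene = sprintf("g%02d", 1:60), chrom = "1",
                       start = seq(1e5, by = 5e4, length.out = 60),
                       end = seq(1e5, by = 5e4, length.out = 60) + 2e4)
  top <- gm$gene[1:8]
  whole <- tibble::tibble(chrom = "1", start = 1, end = 1e9)
  fit <- interval_overlap_test(top, whole, gm, R = 200, seed = 1)
  expect_equal(fit$observed_stat, 8)
  expect_equal(fit$empirical_p, 1)
  none <- tibble::tibble(chrom = "2", start = 1, end = 1e9)
  fit0 <- interval_overlap_test(top, none, gm, R = 200, seed = 1)
  expect_equal(fit0$observed_stat, 0)
  expect_equal(fit0$empirical_p, 1)
})

test_that("genes planted in intervals with strong burden signal are detected", {
  withr::with_seed(8, {
    gm <- tibble::tibble(gene = sprintf("g%03d", 1:200), chrom = "1",
                         start = seq(1e5, by = 1e5, length.out = 200),
                         end = seq(1e5, by = 1e5, length.out = 200) +
                           round(runif(200, 1e4, 5e4)))
    iv <- tibble::tibble(chrom = "1", start = gm$start[1:20] - 10,
                         end = gm$end[1:20] + 10)
    top <- gm$gene[1:15]     # top burden genes all in intervals
  })
  fit <- interval_overlap_test(top, iv, gm, R = 2000, seed = 9)
  expect_equal(fit$observed_stat, 15)
  expect_lte(fit$empirical_p, 0.05)
})
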
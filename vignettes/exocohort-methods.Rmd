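---
title: "Models and methods behind exocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exocohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`exocohort` analyses case/control exome cohorts for rare-variant association
and implements a synthetic-cohort generator with known ground truth so that
every analysis stage — QC, single-variant tests, gene-level kernel burden
tests, matched-permutation enrichment, LD-interval construction and tissue
enrichment — can be exercised and calibrated without access-restricted human
data. This vignette explains the models, the tunable parameters, the
numerical choices, and what the package's tests do and do not demonstrate.

## The synthetic cohort model

### Site frequency spectrum and population structure

Each variant receives an ancestral minor-allele frequency drawn from a
two-band spectrum: by default 80% of variants fall in (0.0005, 0.01) and 20%
in (0.01, 0.3), log-uniform within each band. This mirrors the rare-heavy
composition of exome callsets, where roughly 40% of sites sit below 1%
control MAF. Subpopulation frequencies diverge from the ancestral value
under the Balding–Nichols model: for divergence $F \in [0, 1)$,
$p_s \sim \mathrm{Beta}\!\big(p\,(1-F)/F,\ (1-p)(1-F)/F\big)$, which has mean
$p$ and variance $F\,p(1-p)$. With $F = 0$ the ancestral frequency is used
exactly. Two subpopulations of equal size are simulated by default with
$F = 0$ (i.e. a homogeneous cohort unless divergence is requested).

### Linkage disequilibrium

Haplotypes are generated per LD block (`ld_block_len` consecutive variants,
20 by default; blocks are mutually independent). Within a block each
haplotype carries a latent standard-normal ancestry score following a
stationary AR(1) process with autocorrelation $\phi = 1 -$ `recomb_prob`;
the allele at variant $v$ is the indicator $\Phi(z_v) < p_v$. This latent
construction has three properties that a literal allele-copying chain cannot
combine:

* marginal frequencies are exact at every `recomb_prob`, so the frequency
  spectrum is never distorted by the LD machinery;
* at `recomb_prob = 0` the latent score is constant across a block, so
  equal-frequency variants are perfectly correlated ($r^2 = 1$): block
  boundaries are exact ground truth for interval-construction tests;
* dependence decays through the Gaussian copula, so for rare variants even
  moderate $\phi$ yields small haplotype $r^2$ — at `recomb_prob = 0.5` the
  mean adjacent-variant $r^2$ under the default spectrum is below 0.05,
  i.e. blocks do not leak spurious LD into association tests.

An allele-copying process (copy the previous allele with probability
$1-c$, redraw otherwise) was considered and rejected: conditional on no
switch it makes adjacent variants comonotone, so adjacent rare variants of
similar frequency would retain $r^2 \approx (1-c)^2$ — strong residual LD
even at $c = 0.5$ — and the marginal frequencies drift within blocks.

### Disease model and sampling

Disease status is additive on the log-odds scale, with no dominance:
$\mathrm{logit}\,P(\text{case}) = \beta_0(s) + \log(\mathrm{OR})\sum_{v \in
\text{causal}} g_v$, where $g_v$ is the alternate-allele count and the
intercept $\beta_0$ may differ by subpopulation (that is how stratification
confounding is provoked on purpose). Individuals are formed by pairing
haplotypes within a subpopulation, their status is drawn, and sampling
continues until the requested numbers of cases and controls are reached;
when the panel is exhausted, fresh haplotypes are drawn on the same variant
structure (each individual always receives unused haplotypes, so cohort
members are unrelated by construction). An unreachable quota — e.g. a very
negative intercept with many cases requested — aborts after a bounded
number of extra batches with a diagnostic.

Genes are contiguous runs of variants whose lengths are log-uniform with
mean `variants_per_gene`; this makes the NS-SNV-count and length matching
of the enrichment null distributions genuinely non-trivial. Variants are
labelled non-synonymous with probability 0.225 (the NS fraction of a typical
exome callset), and 1.5% of those are stop gain/loss. Genotypes are set
missing completely at random at rate 0.002 so call-rate QC has work to do.
Cryptic relatedness is planted by appending a sample that copies a template
genotype with probability $\hat\pi$ and redraws from Hardy–Weinberg
otherwise; copying a full genotype corresponds to IBD state 2 at that site,
so the expected method-of-moments relatedness equals the copying rate.

## Quality control

* **Call rate.** Variants called in at least 99% of samples are retained
  (`filter_call_rate`, `>=` comparison).
* **MAF.** Minor-allele counts over called alleles, folded to $\le 0.5$;
  an all-missing variant yields `NA`, never 0. Rarity is a strict
  `maf_controls < 0.01`.
* **Relatedness.** $\hat\pi = P(\text{IBD}=1)/2 + P(\text{IBD}=2)$ by the
  classical method of moments on identity-by-state counts with cohort
  allele frequencies. The estimator needs common variants: below 200
  informative markers (MAF $\ge$ 0.05, called in both samples) the
  functions refuse to estimate or prune, because the sampling noise of
  $\hat\pi$ at that depth spills past any reasonable threshold. Pairs above
  $\hat\pi > 0.1875$ (strict) lose one member — the lower call rate, ties
  broken toward keeping the lexicographically smaller id — resolved from
  the strongest pair down. Known limitation: with pooled frequencies under
  strong stratification, within-subpopulation pairs are biased upward;
  the pipeline therefore prunes before any stratification-sensitive step
  but documents that heavily structured cohorts deserve within-cluster
  frequencies.
* **Ancestry PCs.** Variants are centred and scaled by
  $\sqrt{2p(1-p)}$, missing calls imputed to the variant mean, and the top
  eigenvectors of the sample covariance returned as unit-norm coordinates.
  Eigenvector signs are arbitrary; tests treat sign flips as equivalent.

## Association tests

**Fisher allelic test.** Exact two-sided p on the 2×2 table of
alternate/reference allele counts in cases versus controls, summing all
tables with fixed margins whose hypergeometric probability does not exceed
the observed one (this is `stats::fisher.test`'s two-sided rule; the test
suite verifies it against an independent exhaustive enumeration to 1e-12
over every table with total count up to 20 and hundreds of random larger
tables). The reported odds ratio is the sample cross-product $ad/bc$, with
the Haldane 0.5 correction and an explicit flag when a cell is zero.

**Logistic regression.** Maximum-likelihood fit of status on genotype plus
the first `n_covariates` PCs (default 2, configurable 0–10 with a
convenience that reports the inflation factor per choice), Wald p on the
genotype coefficient. Monomorphic variants are skipped with a reason;
non-convergence and quasi-complete separation return flagged rows with an
undefined p rather than a fabricated value. Samples missing the call are
excluded from that variant only.

**Multiplicity and diagnostics.** The Bonferroni threshold is
$\alpha/m$; with $\alpha = 0.05$ over 21,235 non-synonymous variants this
is $2.4 \times 10^{-6}$ at two significant figures. The genomic inflation
factor $\lambda$ is the median observed 1-df chi-square over its null
median 0.4549. QQ tables use the $i/(n+1)$ expected quantiles; the
Manhattan table lays variants on a cumulative genome coordinate with an
above-threshold flag.

## Gene-level kernel burden test

For a gene with genotype block $G$ (samples × variants), weights
$w_v = \mathrm{dbeta}(\mathrm{MAF}_v; 1, 25)$ up-weight rarer variants
(at MAF 0.5 the weight is $25 \cdot 0.5^{24} \approx 1.5\times 10^{-6}$;
at 0.01 it is $25 \cdot 0.99^{24} \approx 19.64$). With null fitted
probabilities $\hat\mu$ from a covariates-only logistic model,
$V = \mathrm{diag}(\hat\mu(1-\hat\mu))$, $Z = GW$ and residuals
$r = y - \hat\mu$, the statistic is the variance-component score form

$$Q = r^\top Z Z^\top r,$$

distributed under the null as $\sum_i \lambda_i \chi^2_1$ with $\lambda_i$
the eigenvalues of $Z^\top \big(V - VX(X^\top VX)^{-1}X^\top V\big) Z$.
Because $Q$ is quadratic, risk and protective effects in the same gene both
increase it. The mixture tail uses the four-moment non-central chi-square
matching of Liu, Tang and Zhang by default, with Imhof's numerical
characteristic-function inversion (`stats::integrate`) as the exact option;
the two agree to well under 2% in the regimes the tests probe, and both
agree within a factor of two with a 200,000-draw phenotype-permutation p on
a 60-sample, 3-variant gene. With one variant and no covariates the test
reduces analytically to the marginal score test, which the suite asserts to
three significant figures. Monomorphic variants are excluded (and listed);
missing genotypes are imputed to twice the allele frequency; an all-zero
block is reported as $Q = 0$, $p = 1$.

The per-individual NS burden counts sites with at least one alternate
allele by default; an allele-count convention is exposed as an option
because published per-individual totals rarely state which was used. The
case/control comparison reports both group means and a rank-sum p (t-test
optional).

## Matched-permutation enrichment

The observed statistic of a gene set is the sum over member genes of a
per-gene score: the sum of $-\log_{10} p$ over the gene's NS SNVs
(variant-level) or $-\log_{10}$ of the gene's kernel-test p (gene-level);
genes without NS SNVs contribute 0. The null preserves the set's signal
opportunity: each member is replaced by a non-member matched on a
covariate, by default the NS SNV count. Matching is exact when at least 10
candidates exist, otherwise widened to ±20% (counts rounded outward); for
length-like covariates (genomic length for interval overlap, CDS length
for tissue enrichment) matching uses log2 bins of width 0.5 with a ±1-bin
fallback, because lengths are continuous and heavy-tailed. A gene with no
candidate even after widening raises an error naming it — a deliberate
contract, since silently matching badly would bias the null. Null sets are
drawn without replacement within a replicate, with replacement across
replicates, and the one-sided empirical p uses add-one smoothing
$(1 + \#\{S_{null} \ge S_{obs}\})/(R + 1)$, so p is never exactly zero and
a saturated null reports exactly 1. The fold change is defined as
$S_{obs}/\overline{S_{null}}$ (the reference statistic leaves "fold"
undefined; this is the package's definition, recorded here). The default
replicate count is 10,000.

Top-N gene sets rank genes by their best (minimum) NS SNV p-value, ties
broken by gene name; ranking by the count of nominally associated SNVs is
provided as an alternative, since "genes with most associated SNVs" admits
both readings. Term enrichment of a top-N set is a standard hypergeometric
upper tail per term with Benjamini–Hochberg q-values across terms; the
fold is observed over expected overlap.

## GWA intervals

Haplotype $r^2$ comes from direct phased-haplotype counts. An interval
around a lead SNP spans the most distant panel SNPs with $r^2 >$ 0.5
(strict) to the lead within a ±1 Mb search window (the window is a package
choice, configurable), plus a 250 kb flank on each side, clipped at
position 1; a lead with no linked SNP falls back to lead ± flank. For
overlap analyses intervals are extended by a further 500 kb per side —
the two flank values serve different analyses and are bound to their
respective operations. Overlapping intervals are not merged, because
membership is "overlaps any interval"; gene membership is any 1-bp overlap
of the gene body under 1-based inclusive coordinates, and BED export
converts to 0-based half-open. A European-panel-only variant of the LD
computation is available as a haplotype-subset filter rather than a second
algorithm.

## Tissue enrichment

Expression profiles are normalized per gene across tissues: min–max
feature scaling to [0, 1] followed by division by the Euclidean norm, so
each gene's squared values sum to one. The scaling direction (across
tissues within a gene, not across genes within a tissue) follows from the
unit-norm condition being stated per gene's expression levels; the
alternative reading is noted as unresolved in the interface documentation.
The operation is deliberately not idempotent — re-scaling a normalized row
changes it — the asserted contract is the unit-norm post-condition.
Constant-expression genes are excluded with a reason. The per-tissue test
compares the set's summed normalized expression with CDS-length-matched
random sets; the same null sets are evaluated in every tissue so that
per-tissue p-values are comparable, and the planted-signal test asserts the
smallest p lands in the spiked tissue.

## Pipeline

`run_pipeline()` chains simulate → write/read round trip → QC →
single-variant → burden → optional enrichment/interval/tissue stages,
writes each stage's table as TSV plus a JSON summary, and records an md5
digest per table; equal seeds yield identical digests end to end. All
randomness descends from one integer seed through deterministically derived
per-operation sub-seeds. Stage parameters (call-rate 0.99, rare MAF 0.01,
IBD 0.1875, 2 PCs, Beta(1, 25) weights, $r^2 > 0.5$, flanks 250/500 kb,
$\alpha = 0.05$) are collected in a single defaults list and logged.

## Calibration experiments and their design

The packaged acceptance checks run two kinds of evidence:

* **Self-contained arithmetic** — the Bonferroni threshold at 21,235 tests,
  carrier-count MAF reconstructions (12 heterozygotes among 884 diploid
  controls → 0.00678733, 14/536 → 0.01306, 3/260 → 0.005769), and exact
  agreement of the Fisher test with enumeration.
* **Synthetic-cohort calibration** at 2,000 samples and ~5,000 variants in
  500 genes. The calibration cohorts use an explicit common-variant
  spectrum (MAF 0.05–0.5, log-uniform, weak LD): the inflation factor is a
  median-based diagnostic whose sampling standard deviation at only a few
  hundred usable markers is ~0.1 — far wider than the ±0.05 band being
  checked — and Wald p-values at minor-allele counts of a handful are
  conservative by discreteness. Calibration is therefore measured where
  the asymptotics it checks actually apply; this is an evaluation-design
  choice, not a change to the generator's rare-heavy defaults. Under these
  conditions the null rejection rate sits within three binomial standard
  errors of 5% for both the logistic and the kernel test, λ lies in
  [0.95, 1.05] with two PCs, and a stratified cohort (Fst 0.05, subpopulation
  baseline logits ±0.2, i.e. case fractions ≈ 55%/45%) inflates λ to ≈ 3.8
  without covariates and returns to ≈ 1.00 with two PCs.
* **Power and recovery** — a planted per-allele OR of 2 at MAF 0.2 is
  recovered with mean $\exp(\hat\beta) \approx 2.0$ over 100 replicates; a
  gene set with 10× smaller SNV p-values reaches empirical p ≤ 1e-4 at
  R = 10,000; planted causal genes rank at the top of the burden scan;
  perfect-LD blocks are recovered exactly by the interval builder in every
  replicate seed.

What passing these does **not** show about real data: the generator has no
sequencing or genotype-calling error model (missingness is MCAR, not
coverage-driven), no indels or multi-allelic sites, a single chromosome
with uniform marker spacing, block-structured rather than coalescent LD,
and exactly additive effects. Calibration on these cohorts demonstrates the
statistics are implemented correctly, not that a 228-case exome study is
well powered — the package's own burden tests make the opposite point at
that scale.

## Numerical choices and degenerate inputs

* Kernel eigenvalues below $10^{-10}$ of the largest are discarded; the
  projected kernel is symmetrized before `eigen(symmetric = TRUE)`.
* Mixture tail probabilities are clipped to $[10^{-300}, 1]$; Imhof
  integration falls back to moment matching if `integrate` fails.
* Empirical p-values are never 0 by construction; Fisher p is capped at 1.
* Multi-allelic VCF records are rejected at load with the offending ids —
  splitting them would require inventing per-allele MAFs and consequence
  classes.
* `min_rate = 0` retains a fully missing variant (the `>=` contract);
  an all-missing variant's MAF is `NA`, and rare flags propagate `NA`.
* Problem sizes in the test suite (cohorts of 40–2,000 samples, permutation
  depths of 400–200,000) were chosen so the full suite and the acceptance
  script each complete in a few minutes on a single core.
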
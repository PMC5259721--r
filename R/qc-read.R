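#' Read a cohort from a VCF and a phenotype table
#'
#' Loads genotypes as alternate-allele counts from a multi-sample VCF
#' (biallelic SNVs only; multi-allelic records are rejected with an error,
#' since splitting them would require inventing per-allele frequencies and
#' consequence classes), together with per-variant `GENE` and `CSQ_CLASS`
#' INFO annotations and a tab-separated phenotype file with columns
#' `sample_id`, `status` (1 = control, 2 = case) and optional numeric
#' covariates. The VCF and phenotype sample sets must coincide; offenders on
#' either side are named in the error.
#'
#' @param vcf_path Path to a VCF 4.x file with GT genotypes.
#' @param pheno_path Path to the tab-separated phenotype file.
#' @return A list with `genotypes` (samples x variants integer matrix in
#'   phenotype-file sample order), `samples` (tibble with `sample_id`,
#'   `status` as `"case"`/`"control"` and any further phenotype columns) and
#'   `variants` (tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `csq_class`).
#' @export
read_cohort <- function(vcf_path, pheno_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  if (!file.exists(pheno_path)) stop("phenotype file not found: ", pheno_path, call. = FALSE)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic records are not supported; offending variants: ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "), call. = FALSE)
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")  # variants x samples
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = 1,
                     dimnames = list(unname(fix[, "ID"]), names(gt_raw)))
  }
  decode <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("|", "/", x, fixed = TRUE)
    known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
    bad <- !is.na(x) & !x %in% names(known)
    if (any(bad)) {
      stop("malformed GT field(s), first at variant ",
           rownames(gt_raw)[(which(bad)[1] - 1L) %% nrow(gt_raw) + 1L], call. = FALSE)
    }
    ok <- !is.na(x) & x != "./."
    out[ok] <- known[x[ok]]
    out
  }
  calls <- matrix(decode(as.vector(gt_raw)), nrow = nrow(gt_raw),
                  dimnames = dimnames(gt_raw))
  calls <- t(calls)                                   # samples x variants

  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(pheno))) {
    stop("phenotype file must have columns sample_id and status", call. = FALSE)
  }
  vcf_samples <- rownames(calls)
  only_vcf <- setdiff(vcf_samples, pheno$sample_id)
  only_pheno <- setdiff(pheno$sample_id, vcf_samples)
  if (length(only_vcf) || length(only_pheno)) {
    stop("sample sets differ between VCF and phenotype file; ",
         if (length(only_vcf)) paste0("missing from phenotype: ",
                                      paste(only_vcf, collapse = ", "), "; ") else "",
         if (length(only_pheno)) paste0("missing from VCF: ",
                                        paste(only_pheno, collapse = ", ")) else "",
         call. = FALSE)
  }
  calls <- calls[pheno$sample_id, , drop = FALSE]

  samples <- tibble::as_tibble(pheno)
  samples$status <- ifelse(samples$status == 2, "case", "control")

  variants <- tibble::tibble(
    variant_id = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    gene = vcfR::extract.info(vcf, "GENE"),
    csq_class = vcfR::extract.info(vcf, "CSQ_CLASS")
  )
  colnames(calls) <- variants$variant_id
  list(genotypes = calls, samples = samples, variants = variants)
}
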
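# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed so that every operation draws from its own stream
# while all randomness still flows from one user-supplied seed
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

with_sub_seed <- function(seed, tag, code) {
  withr::with_seed(sub_seed(seed, tag), code)
}

assert_scalar_prop <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%s, %s%s",
                 name, if (lo_open) "(" else "[", format(lo),
                 format(hi), if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
  if (!ok) stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# genotype matrices are integer matrices (samples x variants) over {0,1,2,NA}
assert_genotypes <- function(g, name = "genotypes") {
  if (!is.matrix(g)) stop(sprintf("`%s` must be a samples x variants matrix", name), call. = FALSE)
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stop(sprintf("`%s` must contain only 0, 1, 2 or NA", name), call. = FALSE)
  }
  if (is.null(rownames(g)) || is.null(colnames(g))) {
    stop(sprintf("`%s` must carry sample rownames and variant colnames", name), call. = FALSE)
  }
  invisible(g)
}

is_ns_class <- function(csq_class) csq_class %in% c("NS", "STOP")

case_mask <- function(samples) {
  st <- samples$status
  if (is.numeric(st)) return(st == 2)
  st %in% c("case", "2")
}

pc_matrix <- function(samples, n_covariates) {
  if (n_covariates == 0L) return(NULL)
  cols <- paste0("PC", seq_len(n_covariates))
  missing <- setdiff(cols, names(samples))
  if (length(missing)) {
    stop("sample table lacks principal-component columns: ",
         paste(missing, collapse = ", "),
         " (run pca_ancestry() first)", call. = FALSE)
  }
  as.matrix(samples[cols])
}
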
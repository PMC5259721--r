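#' Haplotype r-squared between two variants
#'
#' The classical LD measure from direct phased-haplotype counts:
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' Symmetric in its arguments and invariant to allele relabelling at either
#' site. Monomorphic variants have undefined LD and raise an error.
#'
#' @param panel A `hap_panel`, or a plain 0/1 haplotype matrix.
#' @param a,b Variant column indices or `variant_id`s.
#' @return Scalar r-squared in `[0, 1]`.
#' @examples
#' h <- cbind(a = c(1, 1, 1, 0, 0, 0, 0, 1), b = c(1, 1, 1, 1, 0, 0, 0, 0))
#' haplotype_r2(h, "a", "b")   # 0.25
#' @export
haplotype_r2 <- function(panel, a, b) {
  h <- if (inherits(panel, "hap_panel")) panel$haplotypes else panel
  xa <- h[, a]
  xb <- h[, b]
  pa <- mean(xa); pb <- mean(xb)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("r-squared undefined for a monomorphic variant", call. = FALSE)
  }
  pab <- mean(xa * xb)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Build a GWA interval around a lead SNP by LD expansion
#'
#' Among panel variants on the lead's chromosome within `window` of its
#' position, finds those with `r2 > r2_threshold` (strict) to the lead and
#' takes the span from the most distant qualifying SNPs, then adds `flank`
#' base pairs on either side (clipped at position 1). When no other SNP
#' qualifies, the interval is the lead position plus/minus the flank.
#'
#' @param lead A one-row tibble/list with `id`, `chrom`, `pos`.
#' @param panel A `hap_panel` (the lead must be present, matched by `id` or
#'   by chromosome and position).
#' @param r2_threshold Strict lower bound on LD with the lead.
#' @param flank Flank added to each side, in bp.
#' @param window Search half-width around the lead, in bp.
#' @return One-row tibble: `chrom`, `start`, `end` (1-based inclusive),
#'   `lead_id`, `n_linked_snps` (qualifying SNPs other than the lead).
#' @export
build_interval <- function(lead, panel, r2_threshold = 0.5,
                           flank = 250000, window = 1000000) {
  stopifnot(inherits(panel, "hap_panel"))
  v <- panel$variants
  li <- which(v$variant_id == lead$id)
  if (!length(li)) li <- which(v$chrom == lead$chrom & v$pos == lead$pos)
  if (!length(li)) stop("lead SNP absent from panel: ", lead$id, call. = FALSE)
  li <- li[1]
  lead_pos <- v$pos[li]
  h <- panel$haplotypes
  cand <- which(v$chrom == v$chrom[li] & abs(v$pos - lead_pos) <= window)
  cand <- setdiff(cand, li)
  freqs <- colMeans(h[, cand, drop = FALSE])
  cand <- cand[freqs > 0 & freqs < 1]
  if (mean(h[, li]) %in% c(0, 1)) {
    stop("lead SNP is monomorphic in the panel", call. = FALSE)
  }
  linked <- cand[vapply(cand, function(j) haplotype_r2(h, li, j), numeric(1)) >
                   r2_threshold]
  span <- range(c(lead_pos, v$pos[linked]))
  tibble::tibble(chrom = v$chrom[li],
                 start = max(1, span[1] - flank),
                 end = span[2] + flank,
                 lead_id = lead$id %||% v$variant_id[li],
                 n_linked_snps = length(linked))
}

#' @rdname build_interval
#' @param leads Tibble of lead SNPs (`id`, `chrom`, `pos`), one interval per
#'   row.
#' @export
build_intervals <- function(leads, panel, r2_threshold = 0.5,
                            flank = 250000, window = 1000000) {
  purrr::map_dfr(seq_len(nrow(leads)), function(i) {
    build_interval(leads[i, ], panel, r2_threshold, flank, window)
  })
}

#' Extend intervals by a fixed pad
#'
#' Grows each interval by `pad` bp on both ends, clipping starts at 1.
#' Overlapping intervals are deliberately not merged: downstream membership
#' is "overlaps any interval".
#'
#' @param intervals Interval tibble with `start`, `end`.
#' @param pad Pad in bp.
#' @return The padded interval tibble.
#' @export
extend_intervals <- function(intervals, pad = 500000) {
  dplyr::mutate(intervals, start = pmax(1, .data$start - pad),
                end = .data$end + pad)
}

#' Genes overlapping any interval
#'
#' A gene is a member iff its `[start, end]` body overlaps any interval by
#' at least 1 bp, under the shared 1-based inclusive convention (a gene
#' starting exactly at an interval end is a member).
#'
#' @param gene_models Tibble with `gene`, `chrom`, `start`, `end`.
#' @param intervals Interval tibble with `chrom`, `start`, `end`.
#' @return Character vector of member gene names, in gene-model order.
#' @export
genes_in_intervals <- function(gene_models, intervals) {
  hit <- vapply(seq_len(nrow(gene_models)), function(i) {
    any(intervals$chrom == gene_models$chrom[i] &
          intervals$start <= gene_models$end[i] &
          intervals$end >= gene_models$start[i])
  }, logical(1))
  gene_models$gene[hit]
}

#' Export intervals as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention and writes a tab-separated file.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `lead_id` used as the BED name column).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
intervals_to_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = if ("lead_id" %in% names(intervals)) intervals$lead_id else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
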
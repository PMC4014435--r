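## Genomic block partition for the weighted block jackknife, and
## BED-interval masking of panels.

#' Partition SNPs into contiguous genomic blocks
#'
#' Blocks are fixed, non-overlapping windows of `window` bp laid along each
#' chromosome: block k on a chromosome covers 1-based positions
#' `[k*window + 1, (k+1)*window]`.  SNPs on different chromosomes never
#' share a block.  Used as the resampling unit of the weighted block
#' jackknife (default window 5 Mb, large relative to linkage
#' disequilibrium).
#'
#' @param snps a [snp_table()] (or data.frame with `chrom`, `pos`), sorted
#'   by chromosome then position.
#' @param window block width in bp (default 5e6).
#' @return object of class `block_partition`: list with `window`,
#'   `block_of` (integer block index per SNP, 1-based, in order of first
#'   appearance) and `block_key` (chromosome/window labels per block).
#' @export
assign_blocks <- function(snps, window = 5e6) {
  stopifnot(window >= 1)
  chrom <- as.character(snps$chrom)
  pos <- as.numeric(snps$pos)
  # sortedness within the first-appearance chromosome order
  ord <- order(match(chrom, unique(chrom)), pos)
  if (!identical(ord, seq_along(ord))) {
    stop("SNPs must be sorted by (chromosome, position)", call. = FALSE)
  }
  key <- paste0(chrom, ":", floor((pos - 1) / window))
  ids <- unique(key)
  structure(list(window = window,
                 block_of = match(key, ids),
                 block_key = ids),
            class = "block_partition")
}

#' Number of blocks in a partition
#' @param blocks a `block_partition`.
#' @return integer block count.
#' @export
n_blocks <- function(blocks) length(blocks$block_key)

#' Evenly sized surrogate block partition
#'
#' For inputs without genomic coordinates (e.g. the trio topology
#' simulator, where sites are exchangeable) a partition into `n` equal
#' contiguous chunks stands in for genomic blocks.
#'
#' @param n_sites number of sites.
#' @param n number of blocks.
#' @return a `block_partition`.
#' @export
uniform_blocks <- function(n_sites, n = 100) {
  n <- min(n, n_sites)
  structure(list(window = NA_real_,
                 block_of = as.integer(ceiling(seq_len(n_sites) * n / n_sites)),
                 block_key = as.character(seq_len(n))),
            class = "block_partition")
}

#' Restrict a panel to (or exclude) BED intervals
#'
#' Intervals follow the BED convention: 0-based, half-open `[start, end)`.
#' A SNP at 1-based position p is covered iff `start < p <= end`.
#'
#' @param panel a `genotype_panel` or `frequency_panel`.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (e.g. from [read_bed()]).
#' @param mode `"keep"` retains covered SNPs, `"drop"` removes them.
#' @return the masked panel, with genotype/count columns subset
#'   consistently.
#' @export
apply_region_mask <- function(panel, intervals, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  if (any(intervals$start >= intervals$end)) {
    stop("malformed interval: start >= end", call. = FALSE)
  }
  covered <- positions_in_intervals(panel$snps$chrom, panel$snps$pos,
                                    intervals)
  keep <- if (mode == "keep") covered else !covered
  subset_any_panel(panel, keep)
}

positions_in_intervals <- function(chrom, pos, intervals) {
  covered <- logical(length(pos))
  for (cc in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    sel <- which(chrom == cc)
    if (!length(sel)) next
    for (j in seq_len(nrow(iv))) {
      covered[sel] <- covered[sel] |
        (pos[sel] > iv$start[j] & pos[sel] <= iv$end[j])
    }
  }
  covered
}

subset_any_panel <- function(panel, keep) {
  if (inherits(panel, "genotype_panel")) {
    subset_panel(panel, snp = keep)
  } else if (inherits(panel, "frequency_panel")) {
    snps <- panel$snps[keep, , drop = FALSE]
    rownames(snps) <- NULL
    class(snps) <- c("snp_table", "data.frame")
    structure(list(snps = snps, populations = panel$populations,
                   derived = panel$derived[, keep, drop = FALSE],
                   total = panel$total[, keep, drop = FALSE]),
              class = "frequency_panel")
  } else {
    stop("unsupported panel type", call. = FALSE)
  }
}
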
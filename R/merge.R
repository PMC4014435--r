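## Merging ancient call sets into modern panels: panel-site restriction,
## allele-mismatch handling, damage/transition exclusion, haploidization,
## ancestry-tract masking, missingness/ascertainment filters, and
## polarization to derived-allele orientation.

#' Merge an ancient call set into a modern panel
#'
#' Only SNPs present in the modern panel are retained; the ancient
#' sample's genotype becomes the alt-allele count of its observed
#' allele(s).  Observed alleles outside the panel's ref/alt pair are set
#' missing and counted as mismatches; call sites absent from the panel
#' are dropped and counted.  The ancient sample is appended as a new
#' individual (class `"ancient"`, population label = sample id).
#'
#' @param panel a [genotype_panel()] of modern individuals.
#' @param calls an [ancient_calls()] object.
#' @return list with elements `panel` (the merged [genotype_panel()]) and
#'   `report` (a `merge_report`: counts by drop reason plus the usable
#'   SNP count; the accounting identity
#'   `not_in_panel + allele_mismatch = called input sites - usable`
#'   holds exactly).
#' @export
merge_ancient <- function(panel, calls) {
  key_panel <- paste(panel$snps$chrom, panel$snps$pos)
  key_calls <- paste(calls$sites$chrom, calls$sites$pos)
  if (anyDuplicated(key_calls)) {
    stop("duplicate positions in ancient call set", call. = FALSE)
  }
  idx <- match(key_panel, key_calls)          # call row per panel SNP
  called <- !is.na(calls$sites$allele1)
  n_input_called <- sum(called)
  not_in_panel <- sum(called & !(key_calls %in% key_panel))

  a1 <- calls$sites$allele1[idx]
  a2 <- calls$sites$allele2[idx]
  ref <- panel$snps$ref; alt <- panel$snps$alt
  ok1 <- a1 == ref | a1 == alt
  g_anc <- rep(NA_integer_, n_snp(panel))
  mismatch <- 0L
  if (calls$ploidy == 1L) {
    hit <- !is.na(a1)
    mis <- hit & !ok1
    mismatch <- sum(mis)
    use <- hit & ok1
    g_anc[use] <- as.integer(a1[use] == alt[use])
  } else {
    hit <- !is.na(a1) & !is.na(a2)
    ok2 <- a2 == ref | a2 == alt
    mis <- hit & !(ok1 & ok2)
    mismatch <- sum(mis)
    use <- hit & ok1 & ok2
    g_anc[use] <- as.integer(a1[use] == alt[use]) +
      as.integer(a2[use] == alt[use])
  }
  inds <- rbind(panel$individuals,
                data.frame(id = calls$sample_id, pop = calls$sample_id,
                           class = "ancient", ploidy = calls$ploidy))
  merged <- genotype_panel(panel$snps, inds,
                           rbind(panel$genotypes, g_anc))
  usable <- sum(!is.na(g_anc))
  report <- structure(list(sample_id = calls$sample_id,
                           n_input_called = n_input_called,
                           not_in_panel = not_in_panel,
                           allele_mismatch = mismatch,
                           usable = usable),
                      class = "merge_report")
  list(panel = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("<merge_report> %s: %d called sites; %d not in panel, ",
                     "%d allele mismatches; %d usable SNPs\n"),
              x$sample_id, x$n_input_called, x$not_in_panel,
              x$allele_mismatch, x$usable))
  invisible(x)
}

#' Exclude deamination-damage or transition sites
#'
#' With `mode = "single"` (one ancient sample in the analysis) only the
#' sites where that sample shows the damage allele -- T at a C/T pair or
#' A at a G/A pair -- are dropped.  With `mode = "multi"` (several
#' ancient samples, where correlated damage cannot be attributed) every
#' transition site is dropped.
#'
#' @param panel a merged [genotype_panel()].
#' @param ancient_ids id(s) of the ancient individual(s).
#' @param mode `"single"` or `"multi"`.
#' @return the filtered panel; `attr(, "n_dropped")` counts removed SNPs.
#' @export
exclude_damage <- function(panel, ancient_ids, mode = c("single", "multi")) {
  mode <- match.arg(mode)
  if (mode == "single" && length(ancient_ids) != 1L) {
    stop("mode 'single' requires exactly one ancient id", call. = FALSE)
  }
  if (mode == "multi") {
    drop <- panel$snps$transition
  } else {
    i <- ind_index(panel, ancient_ids)
    drop <- shows_allele(panel, i, damage_allele(panel$snps)) &
      panel$snps$transition
  }
  out <- subset_panel(panel, snp = !drop)
  attr(out, "n_dropped") <- sum(drop)
  out
}

# the allele that deamination damage produces at each transition site
# (NA at transversions)
damage_allele <- function(snps) {
  ifelse((snps$ref == "C" & snps$alt == "T") |
         (snps$ref == "T" & snps$alt == "C"), "T",
  ifelse((snps$ref == "G" & snps$alt == "A") |
         (snps$ref == "A" & snps$alt == "G"), "A", NA))
}

# does individual i carry >= 1 copy of `base` (per site)?  FALSE at
# missing genotypes and where base is NA.
shows_allele <- function(panel, i, base) {
  g <- panel$genotypes[i, ]
  ploidy <- panel$individuals$ploidy[i]
  out <- (panel$snps$alt == base & !is.na(g) & g > 0L) |
         (panel$snps$ref == base & !is.na(g) & g < ploidy)
  out & !is.na(base)
}

#' Haploidize diploid individuals
#'
#' Randomly samples one allele at every heterozygous genotype (0 -> 0,
#' 2 -> 1, 1 -> 0 or 1 with probability 1/2) and sets the individuals'
#' ploidy to 1, so whole-genome diploids can enter analyses on the same
#' footing as pseudo-haploid ancient samples.
#'
#' @param panel a [genotype_panel()].
#' @param ids individuals to haploidize (must be diploid).
#' @param seed RNG seed.
#' @return the modified panel.
#' @export
haploidize <- function(panel, ids, seed) {
  idx <- ind_index(panel, ids)
  if (any(panel$individuals$ploidy[idx] != 2L)) {
    stop("target individual is already haploid", call. = FALSE)
  }
  set.seed(derive_seed(seed, "haploidize"))
  g <- panel$genotypes
  for (i in idx) {
    row <- g[i, ]
    het <- !is.na(row) & row == 1L
    row[!is.na(row) & row == 2L] <- 1L
    row[het] <- rbinom(sum(het), 1L, 0.5)
    g[i, ] <- row
  }
  panel$genotypes <- g
  panel$individuals$ploidy[idx] <- 1L
  validate_panel(panel)
  panel
}

#' Mask an individual to one local-ancestry component
#'
#' Appends a "virtual individual" `<id>.<ancestry>` whose genotypes are
#' kept only inside tracts homozygous for the target ancestry and missing
#' everywhere else, the device used to extract single-source genomes from
#' recently admixed individuals.
#'
#' @param panel a [genotype_panel()].
#' @param id individual to mask.
#' @param tracts data.frame with columns `chrom`, `start`, `end` (BED
#'   convention: 0-based half-open) and `ancestry`.
#' @param target ancestry label to keep.
#' @return panel with the virtual individual appended.
#' @export
apply_ancestry_mask <- function(panel, id, tracts, target) {
  if (any(tracts$start >= tracts$end)) {
    stop("malformed interval: start >= end", call. = FALSE)
  }
  check_tract_overlap(tracts)
  i <- ind_index(panel, id)
  keep <- positions_in_intervals(panel$snps$chrom, panel$snps$pos,
                                 tracts[tracts$ancestry == target, ,
                                        drop = FALSE])
  g_new <- panel$genotypes[i, ]
  g_new[!keep] <- NA_integer_
  inds <- rbind(panel$individuals,
                data.frame(id = paste0(id, ".", target),
                           pop = paste0(panel$individuals$pop[i], ".",
                                        target),
                           class = panel$individuals$class[i],
                           ploidy = panel$individuals$ploidy[i]))
  genotype_panel(panel$snps, inds, rbind(panel$genotypes, g_new))
}

check_tract_overlap <- function(tracts) {
  for (cc in unique(tracts$chrom)) {
    tr <- tracts[tracts$chrom == cc, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (nrow(tr) < 2) next
    ov <- tr$start[-1] < tr$end[-nrow(tr)] &
      tr$ancestry[-1] != tr$ancestry[-nrow(tr)]
    if (any(ov)) {
      stop("overlapping tracts with contradictory ancestry on ", cc,
           call. = FALSE)
    }
  }
  invisible(tracts)
}

#' Filter SNPs on missingness and ascertainment tags
#'
#' Drops SNPs whose missing fraction among *modern* individuals is
#' strictly greater than `max_missing` (so exactly 10% missing survives
#' the default), and optionally keeps only SNPs whose ascertainment tags
#' intersect `required_tags` (e.g. to restrict to non-European discovery
#' panels).
#'
#' @param panel a [genotype_panel()].
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @param required_tags character vector of tags, or `NULL` to skip tag
#'   filtering.  An empty vector is an error (ambiguous intent).
#' @return the filtered panel.
#' @export
filter_sites <- function(panel, max_missing = 0.10, required_tags = NULL) {
  modern <- panel$individuals$class == "modern"
  keep <- rep(TRUE, n_snp(panel))
  if (any(modern)) {
    miss <- colMeans(is.na(panel$genotypes[modern, , drop = FALSE]))
    keep <- miss <= max_missing
  }
  if (!is.null(required_tags)) {
    if (!length(required_tags)) {
      stop("required_tags must be NULL or non-empty", call. = FALSE)
    }
    tag_list <- strsplit(panel$snps$tags, ",", fixed = TRUE)
    keep <- keep & vapply(tag_list, function(tg) {
      any(tg %in% required_tags)
    }, logical(1))
  }
  subset_panel(panel, snp = keep)
}

#' Polarize a panel to derived-allele orientation
#'
#' Re-orients every SNP so that the alternative allele is the derived
#' allele: where the ancestral allele equals the current alt, ref/alt are
#' swapped and genotypes (or counts) complemented; sites with unknown
#' ancestral allele, or an ancestral allele outside the ref/alt pair, are
#' dropped and counted.  Idempotent: after polarization `anc == ref`
#' everywhere.
#'
#' @param panel a [genotype_panel()] or [frequency_panel()].
#' @return the polarized panel; `attr(, "n_dropped")` counts removed SNPs.
#' @export
polarize <- function(panel) {
  s <- panel$snps
  keep <- !is.na(s$anc) & (s$anc == s$ref | s$anc == s$alt)
  flip <- keep & s$anc == s$alt
  out <- subset_any_panel(panel, keep)
  fl <- flip[keep]
  s2 <- out$snps
  tmp <- s2$ref[fl]; s2$ref[fl] <- s2$alt[fl]; s2$alt[fl] <- tmp
  out$snps <- s2
  if (inherits(out, "genotype_panel")) {
    g <- out$genotypes
    ploidy <- out$individuals$ploidy
    g[, fl] <- ploidy - g[, fl, drop = FALSE]
    out$genotypes <- g
  } else {
    out$derived[, fl] <- out$total[, fl, drop = FALSE] -
      out$derived[, fl, drop = FALSE]
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-population derived-allele frequencies from a genotype panel
#'
#' Treats each population's non-missing chromosomes as the denominator.
#' Single individuals can be passed as one-member populations (a diploid
#' contributes within-individual frequencies 0/0.5/1, a haploid 0/1).
#'
#' @param panel a polarized [genotype_panel()].
#' @param pops population labels (default: all).
#' @return a [frequency_panel()] of derived and total chromosome counts.
#' @export
population_frequencies <- function(panel, pops = NULL) {
  if (is.null(pops)) pops <- unique(panel$individuals$pop)
  m <- n_snp(panel)
  der <- matrix(0L, length(pops), m)
  tot <- matrix(0L, length(pops), m)
  for (k in seq_along(pops)) {
    rows <- which(panel$individuals$pop == pops[k])
    g <- panel$genotypes[rows, , drop = FALSE]
    ploidy <- panel$individuals$ploidy[rows]
    obs <- !is.na(g)
    der[k, ] <- colSums(g * obs, na.rm = TRUE)
    tot[k, ] <- colSums(obs * ploidy)
  }
  frequency_panel(panel$snps, pops, der, tot)
}
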
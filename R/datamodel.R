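## Core domain containers: SNP tables, genotype panels, frequency panels,
## ancient call sets, block partitions.  Plain data.frame/matrix-backed S3.

BASES <- c("A", "C", "G", "T")
TRANSITION_PAIRS <- list(c("C", "T"), c("G", "A"))

#' Build a validated SNP table
#'
#' A SNP table is a `data.frame` with one row per bi-allelic autosomal SNP
#' and columns `id`, `chrom`, `pos` (1-based), `ref`, `alt`, `anc`
#' (ancestral allele, `NA` when unknown), `tags` (comma-separated
#' ascertainment-panel labels, `""` when none) and the derived column
#' `transition` (`TRUE` iff the allele pair is C/T or G/A, the pairs that
#' post-mortem cytosine deamination can mimic).
#'
#' @param id character SNP identifiers (unique).
#' @param chrom character chromosome labels.
#' @param pos integer 1-based physical positions.
#' @param ref,alt single-base reference/alternative alleles.
#' @param anc ancestral allele (single base) or `NA` when unknown.
#' @param tags comma-separated ascertainment tags, `""` for none.
#' @return data.frame of class `snp_table`.
#' @export
snp_table <- function(id, chrom, pos, ref, alt, anc = NA_character_,
                      tags = "") {
  n <- length(id)
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    anc = rep_len(as.character(anc), n), tags = rep_len(as.character(tags), n),
    stringsAsFactors = FALSE
  )
  df$transition <- is_transition_pair(df$ref, df$alt)
  validate_snp_table(df)
  class(df) <- c("snp_table", "data.frame")
  df
}

is_transition_pair <- function(ref, alt) {
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C") |
    (ref == "G" & alt == "A") | (ref == "A" & alt == "G")
}

validate_snp_table <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate SNP id: ", df$id[duplicated(df$id)][1], call. = FALSE)
  }
  if (any(df$pos < 1L)) stop("SNP positions must be >= 1", call. = FALSE)
  bad <- !(df$ref %in% BASES) | !(df$alt %in% BASES)
  if (any(bad)) {
    stop("unparseable allele at SNP ", df$id[bad][1], call. = FALSE)
  }
  if (any(df$ref == df$alt)) {
    stop("ref and alt allele identical at SNP ",
         df$id[df$ref == df$alt][1], call. = FALSE)
  }
  known <- !is.na(df$anc)
  if (any(known & !(df$anc %in% BASES))) {
    stop("ancestral allele must be A/C/G/T or NA", call. = FALSE)
  }
  invisible(df)
}

#' Construct a genotype panel
#'
#' The central container: an individuals-by-SNP matrix of alternative-allele
#' counts together with SNP metadata and per-individual population label,
#' class (`modern`, `ancient` or `archaic`) and ploidy (1 or 2).  Missing
#' genotypes are `NA`.  Haploid individuals may only carry 0/1/NA, diploid
#' 0/1/2/NA.
#'
#' @param snps a [snp_table()].
#' @param individuals data.frame with columns `id`, `pop`, `class`, `ploidy`.
#' @param genotypes integer matrix, `nrow(individuals)` x `nrow(snps)`.
#' @return object of class `genotype_panel` with elements `snps`,
#'   `individuals`, `genotypes`.
#' @export
genotype_panel <- function(snps, individuals, genotypes) {
  if (!inherits(snps, "snp_table")) {
    snps <- snp_table(snps$id, snps$chrom, snps$pos, snps$ref, snps$alt,
                      if (is.null(snps$anc)) NA_character_ else snps$anc,
                      if (is.null(snps$tags)) "" else snps$tags)
  }
  individuals <- data.frame(
    id = as.character(individuals$id), pop = as.character(individuals$pop),
    class = as.character(individuals$class),
    ploidy = as.integer(individuals$ploidy), stringsAsFactors = FALSE
  )
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  obj <- structure(list(snps = snps, individuals = individuals,
                        genotypes = genotypes), class = "genotype_panel")
  validate_panel(obj)
  obj
}

validate_panel <- function(panel) {
  g <- panel$genotypes
  if (nrow(g) != nrow(panel$individuals) || ncol(g) != nrow(panel$snps)) {
    stop("genotype matrix is ", nrow(g), " x ", ncol(g),
         " but panel has ", nrow(panel$individuals), " individuals and ",
         nrow(panel$snps), " SNPs", call. = FALSE)
  }
  if (anyDuplicated(panel$individuals$id)) {
    stop("duplicate individual id", call. = FALSE)
  }
  if (!all(panel$individuals$class %in% c("modern", "ancient", "archaic"))) {
    stop("individual class must be modern/ancient/archaic", call. = FALSE)
  }
  if (!all(panel$individuals$ploidy %in% c(1L, 2L))) {
    stop("ploidy must be 1 or 2", call. = FALSE)
  }
  lim <- panel$individuals$ploidy
  bad <- g < 0L | g > lim  # recycles lim down columns
  if (any(bad, na.rm = TRUE)) {
    stop("genotype outside 0..ploidy for at least one individual",
         call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs\n",
              nrow(x$individuals), nrow(x$snps)))
  tab <- table(x$individuals$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel a `genotype_panel` (or, for `n_snp`, any object with a
#'   `snps` table).
#' @return integer count of individuals / SNPs.
#' @export
n_ind <- function(panel) nrow(panel$individuals)

#' @rdname n_ind
#' @export
n_snp <- function(panel) nrow(panel$snps)

ind_index <- function(panel, id) {
  i <- match(id, panel$individuals$id)
  if (anyNA(i)) stop("unknown individual id: ",
                     paste(id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Subset a genotype panel by SNPs and/or individuals
#'
#' @param panel a `genotype_panel`.
#' @param snp index vector (integer/logical) over SNPs, or NULL.
#' @param ind index vector over individuals, or NULL.
#' @return the subsetted `genotype_panel`.
#' @export
subset_panel <- function(panel, snp = NULL, ind = NULL) {
  if (is.null(snp)) snp <- seq_len(n_snp(panel))
  if (is.null(ind)) ind <- seq_len(n_ind(panel))
  snps <- panel$snps[snp, , drop = FALSE]
  rownames(snps) <- NULL
  class(snps) <- c("snp_table", "data.frame")
  inds <- panel$individuals[ind, , drop = FALSE]
  rownames(inds) <- NULL
  structure(list(snps = snps, individuals = inds,
                 genotypes = panel$genotypes[ind, snp, drop = FALSE]),
            class = "genotype_panel")
}

#' Construct a population allele-frequency panel
#'
#' Per-population derived (or alternative) allele counts and total observed
#' chromosome counts per SNP, the representation used for low-coverage
#' population panels where individual genotypes are unavailable.
#'
#' @param snps a [snp_table()].
#' @param populations character population labels.
#' @param derived integer matrix populations x SNPs of derived-allele counts.
#' @param total integer matrix of observed chromosome counts.
#' @return object of class `frequency_panel`.
#' @export
frequency_panel <- function(snps, populations, derived, total) {
  derived <- as.matrix(derived); total <- as.matrix(total)
  storage.mode(derived) <- "integer"; storage.mode(total) <- "integer"
  rownames(derived) <- rownames(total) <- populations
  obj <- structure(list(snps = snps, populations = as.character(populations),
                        derived = derived, total = total),
                   class = "frequency_panel")
  validate_freq_panel(obj)
  obj
}

validate_freq_panel <- function(fp) {
  if (nrow(fp$derived) != length(fp$populations) ||
      ncol(fp$derived) != nrow(fp$snps) ||
      !identical(dim(fp$derived), dim(fp$total))) {
    stop("frequency panel dimension mismatch", call. = FALSE)
  }
  if (any(fp$total < 0L, na.rm = TRUE)) {
    stop("negative chromosome count", call. = FALSE)
  }
  bad <- which(fp$derived > fp$total | fp$derived < 0L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("derived count exceeds total at population '%s', SNP '%s'",
                 fp$populations[bad[1, 1]], fp$snps$id[bad[1, 2]]),
         call. = FALSE)
  }
  invisible(fp)
}

#' Derived-allele frequencies of a frequency panel
#'
#' @param fp a `frequency_panel`.
#' @return numeric matrix populations x SNPs; `NA` where no chromosomes
#'   were observed.
#' @export
panel_frequencies <- function(fp) {
  f <- fp$derived / fp$total
  f[fp$total == 0L] <- NA_real_
  f
}

#' @export
print.frequency_panel <- function(x, ...) {
  cat(sprintf("<frequency_panel> %d populations x %d SNPs\n",
              length(x$populations), nrow(x$snps)))
  invisible(x)
}

#' Construct an ancient call set
#'
#' Holds the observed allele(s) of one ancient sample at a set of sites,
#' prior to merging with a modern panel.  Pseudo-haploid samples carry one
#' observed allele per site (`allele1`, `allele2 = NA`), diploid samples
#' two.  `NA` in `allele1` marks a missing site.
#'
#' @param sample_id sample identifier.
#' @param sites data.frame with columns `chrom`, `pos`, `allele1`,
#'   `allele2` (optional; all-NA for haploid samples).
#' @param ploidy 1 (pseudo-haploid) or 2.
#' @param provenance named list of thresholds/seed recorded for audit.
#' @return object of class `ancient_calls`.
#' @export
ancient_calls <- function(sample_id, sites, ploidy = 1L,
                          provenance = list()) {
  if (is.null(sites$allele2)) sites$allele2 <- NA_character_
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      allele1 = as.character(sites$allele1),
                      allele2 = as.character(sites$allele2),
                      stringsAsFactors = FALSE)
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) {
    stop("duplicate positions in ancient call set", call. = FALSE)
  }
  obs <- c(sites$allele1, sites$allele2)
  if (!all(obs %in% BASES | is.na(obs))) {
    stop("observed alleles must be A/C/G/T or NA", call. = FALSE)
  }
  if (ploidy == 1L && !all(is.na(sites$allele2))) {
    stop("haploid call set carries second alleles", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id), sites = sites,
                 ploidy = as.integer(ploidy), provenance = provenance),
            class = "ancient_calls")
}

#' @export
print.ancient_calls <- function(x, ...) {
  cat(sprintf("<ancient_calls> sample %s (ploidy %d): %d sites, %d called\n",
              x$sample_id, x$ploidy, nrow(x$sites),
              sum(!is.na(x$sites$allele1))))
  invisible(x)
}
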
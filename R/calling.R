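## Read filtering, pseudo-haploid calling and hard diploid-variant filters
## for ancient samples.

#' Filter pileup reads on base and mapping quality
#'
#' Removes reads with base quality < `min_bq` or mapping quality
#' < `min_mq` (strictly below: a read exactly at the threshold is kept),
#' and always drops N bases.
#'
#' @param bases character vector of read bases at one site.
#' @param bq,mq integer Phred base/mapping qualities, same length.
#' @param min_bq,min_mq thresholds (defaults 30/30).
#' @return the retained base vector.
#' @export
filter_reads <- function(bases, bq, mq, min_bq = 30, min_mq = 30) {
  keep <- bq >= min_bq & mq >= min_mq & bases %in% BASES
  bases[keep]
}

#' Pseudo-haploid call at one site
#'
#' Draws one read uniformly among the retained reads (over reads, not
#' distinct alleles, so allele sampling is proportional to read-base
#' composition) and reports its base; missing when no read survives.
#'
#' @param bases retained read bases (after [filter_reads()]).
#' @return single base, or `NA_character_` when no reads remain.
#' @export
call_pseudohaploid <- function(bases) {
  if (!length(bases)) return(NA_character_)
  bases[sample.int(length(bases), 1L)]
}

#' Pseudo-haploid calling over a whole pileup
#'
#' Applies [filter_reads()] then [call_pseudohaploid()] at every site.
#'
#' @param pu a `pileup` data.frame ([read_pileup()], [simulate_pileup()]).
#' @param sample_id label for the resulting call set.
#' @param min_bq,min_mq quality thresholds passed to [filter_reads()].
#' @param seed RNG seed for the read draws.
#' @return an [ancient_calls()] object (ploidy 1).
#' @export
call_pileup <- function(pu, sample_id, min_bq = 30, min_mq = 30, seed = 1) {
  set.seed(derive_seed(seed, paste0("call:", sample_id)))
  allele <- vapply(seq_len(nrow(pu)), function(i) {
    kept <- filter_reads(pu$bases[[i]], pu$bq[[i]], pu$mq[[i]],
                         min_bq, min_mq)
    call_pseudohaploid(kept)
  }, character(1))
  ancient_calls(sample_id,
                data.frame(chrom = pu$chrom, pos = pu$pos, allele1 = allele),
                ploidy = 1L,
                provenance = list(min_bq = min_bq, min_mq = min_mq,
                                  seed = seed))
}

#' Hard-filter configuration for diploid variant calls
#'
#' Defaults encode the stringent post-call filters used for a
#' higher-coverage ancient genome: Phred-scaled variant quality
#' strictly > 40, read depth within `[6, 30]`, distance from the nearest
#' alignment gap >= 5 bp, and exclusion of annotated repeat regions.
#'
#' @param min_qual exclusive lower bound on variant QUAL.
#' @param depth_range inclusive `[lo, hi]` depth interval.
#' @param min_gap_dist minimum distance from gaps, bp.
#' @param exclude_repeats drop records flagged as in-repeat.
#' @return list of class `diploid_filter_config`.
#' @export
diploid_filter_config <- function(min_qual = 40, depth_range = c(6, 30),
                                  min_gap_dist = 5, exclude_repeats = TRUE) {
  if (depth_range[1] > depth_range[2] || any(depth_range <= 0)) {
    stop("depth_range must be positive with lo <= hi", call. = FALSE)
  }
  structure(list(min_qual = min_qual, depth_range = depth_range,
                 min_gap_dist = min_gap_dist,
                 exclude_repeats = exclude_repeats),
            class = "diploid_filter_config")
}

#' Apply hard filters to diploid variant records
#'
#' A record passes iff QUAL > `min_qual` (strict), depth inside
#' `depth_range`, gap distance >= `min_gap_dist`, and (when
#' `exclude_repeats`) not inside a repeat.  Records with any missing
#' annotation fail with reason `missing_annotation`.
#'
#' @param records data.frame with columns `qual`, `depth`, `gap_dist`,
#'   `in_repeat` (plus any carry-through columns such as `genotype`).
#' @param cfg a [diploid_filter_config()].
#' @return data.frame with logical `pass` and character `reason`
#'   (comma-separated failure codes, `""` when passing), one row per
#'   input record, in input order.
#' @export
filter_diploid_variants <- function(records, cfg = diploid_filter_config()) {
  n <- nrow(records)
  reasons <- character(n)
  add <- function(reasons, bad, code) {
    ifelse(bad, ifelse(reasons == "", code, paste(reasons, code, sep = ",")),
           reasons)
  }
  miss <- is.na(records$qual) | is.na(records$depth) |
    is.na(records$gap_dist) | is.na(records$in_repeat)
  reasons <- add(reasons, miss, "missing_annotation")
  ok <- !miss
  reasons <- add(reasons, ok & records$qual <= cfg$min_qual, "low_qual")
  reasons <- add(reasons, ok & (records$depth < cfg$depth_range[1] |
                                records$depth > cfg$depth_range[2]), "depth")
  reasons <- add(reasons, ok & records$gap_dist < cfg$min_gap_dist,
                 "near_gap")
  if (cfg$exclude_repeats) {
    reasons <- add(reasons, ok & records$in_repeat, "repeat")
  }
  data.frame(pass = reasons == "", reason = reasons,
             stringsAsFactors = FALSE)
}

#' Is an observed allele the deamination-damage allele?
#'
#' `TRUE` iff the site's allele pair is C/T and the observed allele is T,
#' or the pair is G/A and the observed allele is A -- the patterns that
#' post-mortem cytosine deamination produces.  Transversion sites are
#' never damage-flagged.
#'
#' @param snps one or more rows of a [snp_table()].
#' @param allele observed allele(s), recycled against `snps`.
#' @return logical vector.
#' @export
flag_damage <- function(snps, allele) {
  allele <- rep_len(as.character(allele), nrow(snps))
  in_pair <- allele == snps$ref | allele == snps$alt | is.na(allele)
  if (any(!in_pair)) {
    stop("observed allele not in the site's allele pair at SNP ",
         snps$id[!in_pair][1], call. = FALSE)
  }
  ct <- (snps$ref == "C" & snps$alt == "T") |
        (snps$ref == "T" & snps$alt == "C")
  ga <- (snps$ref == "G" & snps$alt == "A") |
        (snps$ref == "A" & snps$alt == "G")
  out <- (ct & allele == "T") | (ga & allele == "A")
  out & !is.na(allele)
}
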
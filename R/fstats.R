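## D-statistics, f3-statistics, derived-allele sharing, and the weighted
## block jackknife (Busing-style, weights = per-block informative-site
## counts).

#' Weighted block jackknife standard error
#'
#' Leave-one-block-out estimates are combined with the weighted delete-m
#' jackknife of Busing et al.: with g blocks of weight m_j (total n),
#' h_j = n / m_j, pseudovalues
#' `tau_j = h_j * theta - (h_j - 1) * theta_{-j}` and jackknife mean
#' `theta_J = g * theta - sum_j (1 - m_j / n) theta_{-j}`, the variance is
#' `(1/g) * sum_j (tau_j - theta_J)^2 / (h_j - 1)`.  With equal weights
#' this reduces to the ordinary delete-one jackknife.
#'
#' Ratio statistics are supported natively: pass per-block sums of the
#' numerator and denominator, so the leave-one-out estimate is
#' `(N - num_j) / (D - den_j)`.  For a plain mean, pass the block sums as
#' `num` and the block site counts as `den`.
#'
#' @param num per-block numerator sums.
#' @param den per-block denominator sums (same length).
#' @param weights per-block informative-site counts (defaults to `den`
#'   when `den` counts sites, otherwise pass explicitly).
#' @return list with `estimate`, `se`, `n_blocks`, and the per-block
#'   leave-one-out estimates `loo` for audit.
#' @export
weighted_block_jackknife <- function(num, den, weights = NULL) {
  keep <- !(num == 0 & den == 0)
  if (!is.null(weights)) keep <- keep & weights > 0
  num <- num[keep]; den <- den[keep]
  weights <- if (is.null(weights)) rep(1, length(num)) else weights[keep]
  g <- length(num)
  if (g < 2) stop("need >= 2 non-empty blocks for a jackknife SE",
                  call. = FALSE)
  theta <- sum(num) / sum(den)
  loo <- (sum(num) - num) / (sum(den) - den)
  n <- sum(weights)
  h <- n / weights
  theta_j <- g * theta - sum((1 - weights / n) * loo)
  tau <- h * theta - (h - 1) * loo
  v <- sum((tau - theta_j)^2 / (h - 1)) / g
  list(estimate = theta, se = sqrt(v), n_blocks = g, loo = loo)
}

stat_result <- function(stat, estimate, se, n_blocks, n_sites,
                        blocks = NULL, meta = list()) {
  z <- if (se > 0) estimate / se else NA_real_
  structure(list(stat = stat, estimate = estimate, se = se, z = z,
                 n_blocks = n_blocks, n_sites = n_sites, blocks = blocks,
                 meta = meta),
            class = "pp_stat")
}

#' @export
print.pp_stat <- function(x, ...) {
  cat(sprintf("%s = %.6g  SE = %.4g  Z = %.3f  (%d sites, %d blocks)\n",
              x$stat, x$estimate, x$se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' Four-population D-statistic on derived-allele frequencies
#'
#' For the configuration D(O, X; P1, P2) with derived-allele frequency
#' vectors o, x, p1, p2 over a shared SNP list,
#' `D = sum (o - x)(p1 - p2) / sum (o + x - 2 o x)(p1 + p2 - 2 p1 p2)`.
#' D < 0 indicates excess derived-allele matching of X with P1 (gene flow
#' or shared drift between X and P1 relative to P2); D is exactly
#' antisymmetric under swapping P1 and P2.  Sites with any missing
#' frequency, or a zero denominator contribution, are uninformative.
#' The SE is a weighted 5 Mb block jackknife over `blocks`.
#'
#' @param o,x,p1,p2 derived-allele frequency vectors (NA = missing).
#' @param blocks a [assign_blocks()] partition over the same SNP list.
#' @return a `pp_stat` with estimate, jackknife SE and Z.
#' @export
d_statistic <- function(o, x, p1, p2, blocks) {
  stopifnot(length(o) == length(x), length(o) == length(p1),
            length(o) == length(p2), length(o) == length(blocks$block_of))
  num <- (o - x) * (p1 - p2)
  den <- (o + x - 2 * o * x) * (p1 + p2 - 2 * p1 * p2)
  use <- !is.na(num) & !is.na(den) & den != 0
  if (!any(use)) stop("no informative sites", call. = FALSE)
  b <- blocks$block_of[use]
  bn <- rowsum_by(num[use], b)
  bd <- rowsum_by(den[use], b)
  bw <- rowsum_by(rep(1, sum(use)), b)
  jk <- weighted_block_jackknife(bn, bd, bw)
  stat_result("D", jk$estimate, jk$se, jk$n_blocks, sum(use),
              blocks = data.frame(block = names(bn), num = bn, den = bd,
                                  n = bw, row.names = NULL))
}

rowsum_by <- function(x, g) {
  out <- rowsum(x, g)
  setNames(out[, 1], rownames(out))
}

#' Three-population (f3) admixture test
#'
#' Per-site term `(c - a)(c - b)` for target C and sources A, B, averaged
#' over informative sites; significantly negative values (conventionally
#' Z <= -3) indicate that C is admixed between A- and B-related
#' populations.  When `corrected = TRUE` the finite-sample
#' heterozygosity term `c(1-c) / (n - 1)` (n = observed chromosomes in C)
#' is subtracted per site, removing the upward bias caused by sampling
#' noise in the target's frequency estimate; it requires n >= 2 at every
#' used site and is undefined for single-chromosome targets.
#'
#' @param c_freq,a,b derived-allele frequency vectors (target, sources).
#' @param blocks a block partition over the same SNP list.
#' @param c_counts observed chromosome counts in the target per site
#'   (required when `corrected`).
#' @param corrected subtract the finite-sample term (default TRUE when
#'   `c_counts` supplied).
#' @return a `pp_stat`.
#' @export
f3_statistic <- function(c_freq, a, b, blocks, c_counts = NULL,
                         corrected = !is.null(c_counts)) {
  stopifnot(length(c_freq) == length(a), length(c_freq) == length(b),
            length(c_freq) == length(blocks$block_of))
  term <- (c_freq - a) * (c_freq - b)
  use <- !is.na(term)
  if (corrected) {
    if (is.null(c_counts)) {
      stop("corrected f3 needs target chromosome counts", call. = FALSE)
    }
    if (any(c_counts[use & !is.na(c_counts)] < 2) ||
        anyNA(c_counts[use])) {
      stop("corrected f3 requires >= 2 observed chromosomes in the target",
           call. = FALSE)
    }
    term <- term - c_freq * (1 - c_freq) / (c_counts - 1)
  }
  use <- !is.na(term)
  if (!any(use)) stop("no informative sites", call. = FALSE)
  b_id <- blocks$block_of[use]
  bn <- rowsum_by(term[use], b_id)
  bw <- rowsum_by(rep(1, sum(use)), b_id)
  jk <- weighted_block_jackknife(bn, bw, bw)
  stat_result("f3", jk$estimate, jk$se, jk$n_blocks, sum(use),
              meta = list(corrected = corrected))
}

#' Derived-allele sharing between an ancient sample and modern individuals
#'
#' Over the set of sites where the ancient sample carries the derived
#' allele, the raw rate for each modern individual is the fraction of its
#' non-missing sites in that set at which it carries at least one derived
#' allele (per-individual denominators by default; set
#' `shared_denominator = TRUE` to divide every individual by the full
#' derived-site count instead).  Rates are normalized by the
#' lowest-sharing individual, which gets exactly 1.
#'
#' @param ancient_derived per-site derived-allele dosage of the ancient
#'   sample (0/1 for pseudo-haploid, 0/1/2 for diploid; NA = missing).
#' @param panel a polarized [genotype_panel()]; all modern individuals
#'   are scored.
#' @param shared_denominator use one common denominator (the ancient
#'   derived-site count) for all individuals.
#' @return data.frame with columns `id`, `pop`, `n_sites`, `raw`,
#'   `normalized`, sorted in panel order.
#' @export
derived_allele_sharing <- function(ancient_derived, panel,
                                   shared_denominator = FALSE) {
  stopifnot(length(ancient_derived) == n_snp(panel))
  set <- !is.na(ancient_derived) & ancient_derived >= 1L
  if (!any(set)) stop("ancient sample carries no derived alleles",
                      call. = FALSE)
  modern <- which(panel$individuals$class == "modern")
  g <- panel$genotypes[modern, set, drop = FALSE]
  carries <- !is.na(g) & g >= 1L
  nonmiss <- rowSums(!is.na(g))
  denom <- if (shared_denominator) rep(sum(set), length(modern)) else nonmiss
  raw <- rowSums(carries) / denom
  data.frame(id = panel$individuals$id[modern],
             pop = panel$individuals$pop[modern],
             n_sites = nonmiss, raw = raw,
             normalized = raw / min(raw),
             stringsAsFactors = FALSE)
}
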
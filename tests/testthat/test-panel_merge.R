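# Merging ancient calls into panels, damage/transition exclusion,
# haploidization, ancestry masking, site filters, polarization.

# panel with known ref/alt structure for merge tests
merge_panel <- function() {
  s <- snp_table(paste0("m", 1:5), "1", c(100L, 200L, 300L, 400L, 500L),
                 ref = c("C", "C", "A", "G", "T"),
                 alt = c("T", "T", "C", "A", "A"),
                 anc = c("C", "T", "A", "G", "T"))
  ind <- data.frame(id = c("x", "y"), pop = "POP", class = "modern",
                    ploidy = 2L)
  genotype_panel(s, ind, matrix(c(0L, 1L, 2L, 1L, 0L,
                                  2L, 0L, 1L, 2L, 1L), 2, 5, byrow = TRUE))
}

test_that("merge keeps panel sites, maps alleles, counts reasons", {
  p <- merge_panel()
  calls <- ancient_calls("anc", data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 999L),
    allele1 = c("T", "G", "G", "C")), ploidy = 1L)
  res <- merge_ancient(p, calls)
  g <- res$panel$genotypes[3, ]
  expect_identical(unname(g), c(1L, NA_integer_, NA_integer_, NA_integer_,
                                NA_integer_))
  expect_equal(res$report$not_in_panel, 1L)       # pos 999
  expect_equal(res$report$allele_mismatch, 2L)    # G at C/T, G at A/C
  expect_equal(res$report$usable, 1L)
  # accounting identity
  expect_equal(res$report$not_in_panel + res$report$allele_mismatch,
               res$report$n_input_called - res$report$usable)
  expect_equal(res$panel$individuals$class[3], "ancient")
  expect_error(merge_ancient(p, ancient_calls("a2", data.frame(
    chrom = "1", pos = c(100L, 100L), allele1 = c("C", "T")))),
    "duplicate")
})

test_that("merge accounting identity holds on random call sets", {
  p <- merge_panel()
  set.seed(5)
  for (rep in 1:5) {
    pos <- sample(c(p$snps$pos, 600L, 700L), 5)
    calls <- ancient_calls("a", data.frame(
      chrom = "1", pos = pos,
      allele1 = ifelse(runif(5) < 0.2, NA,
                       sample(c("A", "C", "G", "T"), 5, TRUE))))
    res <- merge_ancient(p, calls)
    expect_equal(res$report$not_in_panel + res$report$allele_mismatch,
                 res$report$n_input_called - res$report$usable)
  }
})

test_that("diploid calls merge with both alleles checked", {
  p <- merge_panel()
  calls <- ancient_calls("dip", data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    allele1 = c("C", "C", "A"), allele2 = c("T", "G", "A")), ploidy = 2L)
  res <- merge_ancient(p, calls)
  g <- res$panel$genotypes[3, ]
  expect_identical(unname(g)[1:3], c(1L, NA_integer_, 0L))
  expect_equal(res$report$allele_mismatch, 1L)
})

test_that("damage exclusion: single vs multi mode", {
  p <- merge_panel()
  # ancient shows: T at m1 (C/T damage), C at m2 (C/T non-damage),
  # A at m4 (G/A damage), A at m5 (T/A transversion)
  calls <- ancient_calls("anc", data.frame(
    chrom = "1", pos = c(100L, 200L, 400L, 500L),
    allele1 = c("T", "C", "A", "A")), ploidy = 1L)
  merged <- merge_ancient(p, calls)$panel
  single <- exclude_damage(merged, "anc", "single")
  expect_setequal(single$snps$id, c("m2", "m3", "m5"))
  multi <- exclude_damage(merged, "anc", "multi")
  expect_setequal(multi$snps$id, c("m3", "m5"))
  expect_false(any(multi$snps$transition))   # assertable invariant
  expect_error(exclude_damage(merged, c("anc", "x"), "single"),
               "exactly one")
})

test_that("haploidization is deterministic at homozygotes, fair at hets", {
  s <- snp_table(paste0("h", 1:3), "1", 1:3, rep("C", 3), rep("A", 3))
  ind <- data.frame(id = "d", pop = "P", class = "modern", ploidy = 2L)
  p <- genotype_panel(s, ind, matrix(c(0L, 2L, NA), 1, 3))
  h <- haploidize(p, "d", seed = 1)
  expect_identical(unname(h$genotypes[1, ]), c(0L, 1L, NA_integer_))
  expect_equal(h$individuals$ploidy, 1L)
  expect_true(all(h$genotypes %in% c(0L, 1L, NA_integer_)))
  expect_error(haploidize(h, "d", seed = 1), "already haploid")
  # heterozygote resolves 0/1 with probability 1/2
  m <- 10000
  s2 <- snp_table(sprintf("g%05d", 1:m), "1", 1:m, rep("C", m),
                  rep("A", m))
  p2 <- genotype_panel(s2, ind, matrix(1L, 1, m))
  h2 <- haploidize(p2, "d", seed = 3)
  expect_true(all(h2$genotypes %in% c(0L, 1L)))
  expect_lt(abs(mean(h2$genotypes) - 0.5), 3 * sqrt(0.25 / m))
})

test_that("ancestry masks create virtual individuals with BED semantics", {
  p <- merge_panel()   # positions 100..500
  tr_all <- data.frame(chrom = "1", start = 0, end = 1000,
                       ancestry = "EUR")
  v <- apply_ancestry_mask(p, "x", tr_all, "EUR")
  expect_equal(v$individuals$id[3], "x.EUR")
  expect_identical(unname(v$genotypes[3, ]), unname(p$genotypes[1, ]))
  # no target tracts: all missing
  v0 <- apply_ancestry_mask(p, "x", tr_all, "AFR")
  expect_true(all(is.na(v0$genotypes[3, ])))
  # boundary: tract (99, 100] covers position 100 only (end-exclusive in
  # 0-based terms; position 101 would need end >= 101)
  tr_b <- data.frame(chrom = "1", start = 99, end = 100, ancestry = "EUR")
  vb <- apply_ancestry_mask(p, "x", tr_b, "EUR")
  expect_identical(is.na(vb$genotypes[3, ]),
                   p$snps$pos != 100L)
  expect_error(apply_ancestry_mask(p, "x", data.frame(
    chrom = "1", start = c(0, 150), end = c(200, 300),
    ancestry = c("EUR", "AFR")), "EUR"), "contradictory")
})

test_that("site filter applies strict missingness and tag rules", {
  m <- 10
  s <- snp_table(sprintf("f%02d", 1:3), "1", 1:3, rep("C", 3),
                 rep("A", 3), tags = c("eur", "afr", "afr,eas"))
  ind <- data.frame(id = sprintf("i%02d", 1:m), pop = "P",
                    class = "modern", ploidy = 2L)
  g <- matrix(0L, m, 3)
  g[1, 1] <- NA       # 10% missing: kept (strict >)
  g[1:2, 2] <- NA     # 20%: dropped
  p <- genotype_panel(s, ind, g)
  kept <- filter_sites(p, max_missing = 0.10)
  expect_setequal(kept$snps$id, c("f01", "f03"))
  # ascertainment tags
  tagged <- filter_sites(p, max_missing = 1, required_tags = c("eas"))
  expect_equal(tagged$snps$id, "f03")
  expect_error(filter_sites(p, required_tags = character(0)), "non-empty")
  # ancient individuals do not count toward modern missingness
  ind2 <- ind; ind2$class[1] <- "ancient"
  p2 <- genotype_panel(s, ind2, g)
  expect_equal(n_snp(filter_sites(p2, max_missing = 0.10)), 2L)
})

test_that("polarization flips to derived orientation and is idempotent", {
  p <- merge_panel()  # anc: C,T,A,G,T  vs ref C,C,A,G,T alt T,T,C,A,A
  pol <- polarize(p)
  # m2 has anc == alt: flipped; m5 anc T, pair T/A: anc==ref, kept as is
  expect_setequal(pol$snps$id, c("m1", "m2", "m3", "m4", "m5"))
  expect_identical(pol$snps$anc, pol$snps$ref)
  i2 <- which(pol$snps$id == "m2")
  expect_equal(pol$snps$ref[i2], "T")
  expect_identical(unname(pol$genotypes[, i2]),
                   2L - unname(p$genotypes[, which(p$snps$id == "m2")]))
  # unknown / out-of-pair ancestral alleles are dropped and counted
  p$snps$anc[1] <- "G"
  p$snps$anc[3] <- NA
  pol2 <- polarize(p)
  expect_setequal(pol2$snps$id, c("m2", "m4", "m5"))
  expect_equal(attr(pol2, "n_dropped"), 2L)
  # idempotence
  pol3 <- polarize(pol2)
  expect_identical(pol3$genotypes, pol2$genotypes)
  expect_identical(pol3$snps, pol2$snps)
})

test_that("frequency-panel polarization is an involution on flipped sites", {
  s <- snp_table(c("q1", "q2"), "1", 1:2, c("C", "G"), c("T", "A"),
                 anc = c("T", "G"))
  fp <- frequency_panel(s, c("P1", "P2"),
                        derived = matrix(c(3L, 5L, 1L, 7L), 2, 2),
                        total = matrix(10L, 2, 2))
  pol <- polarize(fp)
  expect_equal(pol$derived[, 1], c(P1 = 7L, P2 = 5L))   # q1 flipped
  expect_equal(pol$derived[, 2], c(P1 = 1L, P2 = 7L))   # q2 untouched
  f0 <- panel_frequencies(fp)[, 1]
  expect_equal(unname(panel_frequencies(pol)[, 1]), unname(1 - f0))
})

test_that("population frequencies treat individuals as small populations", {
  p <- polarize(merge_panel())
  fp <- population_frequencies(p, "POP")
  expect_equal(unname(fp$total[1, 1]), 4L)                 # 2 diploids
  m2 <- which(fp$snps$id == "m2")
  # derived counts complement at the flipped site
  expect_equal(unname(fp$derived[1, m2]), 4L - sum(merge_panel()$genotypes[, 2]))
})
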
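# Domain types, EIGENSTRAT/VCF/TSV/BED readers and writers, block
# assignment, region masking.

random_panel <- function(n_ind, n_snp, seed) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n_snp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  s <- snp_table(sprintf("s%04d", seq_len(n_snp)),
                 chrom = sort(sample(1:2, n_snp, replace = TRUE)),
                 pos = seq_len(n_snp) * 1000L, ref = ref, alt = alt,
                 anc = ifelse(runif(n_snp) < 0.8, ref, NA))
  ploidy <- sample(1:2, n_ind, replace = TRUE)
  ind <- data.frame(id = sprintf("i%02d", seq_len(n_ind)),
                    pop = sample(c("P1", "P2"), n_ind, replace = TRUE),
                    class = "modern", ploidy = ploidy)
  g <- matrix(NA_integer_, n_ind, n_snp)
  for (i in seq_len(n_ind)) {
    g[i, ] <- ifelse(runif(n_snp) < 0.1, NA_integer_,
                     rbinom(n_snp, ploidy[i], 0.4))
  }
  genotype_panel(s, ind, g)
}

test_that("snp_table enforces its invariants", {
  expect_error(snp_table(c("a", "a"), "1", c(1, 2), "C", "T"), "duplicate")
  expect_error(snp_table("a", "1", 1, "C", "C"), "identical")
  expect_error(snp_table("a", "1", 0, "C", "T"), ">= 1")
  expect_error(snp_table("a", "1", 1, "C", "X"), "allele")
  s <- snp_table(letters[1:4], "1", 1:4, c("C", "G", "A", "A"),
                 c("T", "A", "G", "C"))
  expect_equal(s$transition, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("EIGENSTRAT roundtrip is the identity, including dialect extras", {
  p <- tiny_panel()
  prefix <- tempfile()
  write_genotypes(p, prefix, "eigenstrat")
  p2 <- read_genotypes(prefix, "eigenstrat")
  expect_identical(p2$genotypes, p$genotypes)
  expect_identical(p2$snps$anc, p$snps$anc)
  expect_identical(p2$snps$tags, p$snps$tags)
  expect_identical(p2$individuals, p$individuals)
  # haploid rows only ever contain 0/1/9 in the .geno text
  geno <- readLines(paste0(prefix, ".geno"))
  hap_col <- substr(geno, 3, 3)   # individual "c" is haploid
  expect_true(all(hap_col %in% c("0", "1", "9")))
})

test_that("roundtrip identity holds for random panels in both formats", {
  for (seed in 1:3) {
    p <- random_panel(5, 40, seed)
    prefix <- tempfile()
    write_genotypes(p, prefix, "eigenstrat")
    expect_identical(read_genotypes(prefix, "eigenstrat")$genotypes,
                     p$genotypes)
    vcf <- paste0(tempfile(), ".vcf")
    write_genotypes(p, vcf, "vcf")
    p2 <- suppressWarnings(read_genotypes(vcf, "vcf"))
    expect_identical(unname(p2$genotypes), unname(p$genotypes))
    expect_identical(p2$individuals$ploidy, p$individuals$ploidy)
  }
})

test_that("0-SNP panel roundtrips", {
  p <- subset_panel(tiny_panel(), snp = integer(0))
  prefix <- tempfile()
  write_genotypes(p, prefix, "eigenstrat")
  p2 <- read_genotypes(prefix, "eigenstrat")
  expect_equal(nrow(p2$snps), 0L)
  expect_equal(dim(p2$genotypes), c(3L, 0L))
})

test_that("malformed EIGENSTRAT input raises distinct errors", {
  p <- tiny_panel()
  prefix <- tempfile()
  write_genotypes(p, prefix, "eigenstrat")
  # .geno with more columns than .ind rows
  ind <- readLines(paste0(prefix, ".ind"))
  writeLines(ind[1:2], paste0(prefix, ".ind"))
  expect_error(read_genotypes(prefix, "eigenstrat"), "columns")
  writeLines(ind, paste0(prefix, ".ind"))
  geno <- readLines(paste0(prefix, ".geno"))
  writeLines(geno[-1], paste0(prefix, ".geno"))
  expect_error(read_genotypes(prefix, "eigenstrat"), "rows")
  writeLines(c(sub("0", "7", geno[1]), geno[-1]), paste0(prefix, ".geno"))
  expect_error(read_genotypes(prefix, "eigenstrat"), "unparseable")
  expect_error(read_genotypes(tempfile(), "eigenstrat"), "missing")
})

test_that("VCF reader maps ./. to missing and skips non-biallelic rows", {
  path <- paste0(tempfile(), ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.",
    "1\t200\tv2\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/0",   # multi-allelic: skip
    "1\t300\tv3\tG\tGA\t.\tPASS\t.\tGT\t0/1\t0/0",    # indel: skip
    "1\t400\tv4\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0"
  ), path)
  p <- suppressWarnings(read_genotypes(path, "vcf"))
  expect_equal(nrow(p$snps), 2L)
  expect_equal(attr(p, "skipped"), 2L)
  expect_identical(unname(p$genotypes[, 1]), c(1L, NA_integer_))
  expect_identical(unname(p$genotypes[, 2]), c(2L, 0L))
})

test_that("frequency tables roundtrip and validate", {
  path <- tempfile()
  writeLines(c("snp\tchrom\tpos\tref\talt\tanc\tYRI_der\tYRI_tot",
               "s1\t1\t100\tC\tT\tC\t5\t10"), path)
  fp <- read_frequency_table(path)
  expect_equal(unname(panel_frequencies(fp)[1, 1]), 0.5)
  # roundtrip
  out <- tempfile()
  write_frequency_table(fp, out)
  fp2 <- read_frequency_table(out)
  expect_identical(fp2$derived, fp$derived)
  expect_identical(fp2$total, fp$total)
  expect_identical(fp2$snps$anc, fp$snps$anc)
  # invariant violation names the cell
  writeLines(c("snp\tchrom\tpos\tref\talt\tanc\tYRI_der\tYRI_tot",
               "s1\t1\t100\tC\tT\tC\t11\t10"), path)
  expect_error(read_frequency_table(path), "YRI.*s1")
})

test_that("block assignment follows the 5 Mb window convention", {
  s <- snp_table(paste0("r", 1:4), c("1", "1", "1", "2"),
                 c(1L, 4999999L, 5000001L, 5000001L),
                 rep("C", 4), rep("T", 4))
  b <- assign_blocks(s)
  expect_equal(b$block_of[1], b$block_of[2])      # same 5 Mb window
  expect_true(b$block_of[3] != b$block_of[2])     # next window
  expect_true(b$block_of[4] != b$block_of[3])     # other chromosome
  expect_error(assign_blocks(s[c(2, 1, 3, 4), ]), "sorted")
})

test_that("block count matches independent window enumeration", {
  set.seed(42)
  for (rep in 1:3) {
    chrom <- sort(sample(1:3, 200, replace = TRUE))
    pos <- unlist(lapply(table(chrom), function(n) {
      sort(sample.int(3e7, n))
    }))
    s <- snp_table(sprintf("x%03d", 1:200), chrom, pos,
                   rep("A", 200), rep("G", 200))
    b <- assign_blocks(s, 5e6)
    # oracle: count distinct (chrom, floor((pos-1)/W)) pairs
    oracle <- nrow(unique(data.frame(chrom, floor((pos - 1) / 5e6))))
    expect_equal(n_blocks(b), oracle)
    expect_equal(length(unique(b$block_of)), oracle)
  }
})

test_that("region masks use BED half-open coordinates", {
  p <- tiny_panel()   # positions 100, 200, 5000001, 6000000 on chr 1
  bed <- data.frame(chrom = "1", start = 0, end = 7e6)
  expect_equal(n_snp(apply_region_mask(p, bed, "keep")), 4L)
  expect_equal(n_snp(apply_region_mask(p, bed, "drop")), 0L)
  # off-by-one: interval (99, 100] covers position 100 only
  bed1 <- data.frame(chrom = "1", start = 99, end = 100)
  kept <- apply_region_mask(p, bed1, "keep")
  expect_equal(kept$snps$pos, 100L)
  # start == pos does not cover (0-based start is exclusive in 1-based)
  bed2 <- data.frame(chrom = "1", start = 100, end = 101)
  expect_equal(n_snp(apply_region_mask(p, bed2, "keep")), 0L)
  expect_error(apply_region_mask(p, data.frame(chrom = "1", start = 5,
                                               end = 5), "keep"),
               "malformed")
})

test_that("keep and drop masks partition the SNP set", {
  p <- random_panel(3, 50, 7)
  bed <- data.frame(chrom = c("1", "2"), start = c(0, 10000),
                    end = c(20000, 30000))
  kept <- apply_region_mask(p, bed, "keep")
  dropped <- apply_region_mask(p, bed, "drop")
  expect_equal(n_snp(kept) + n_snp(dropped), n_snp(p))
  expect_length(intersect(kept$snps$id, dropped$snps$id), 0)
  # masking with the complement leaves nothing
  expect_equal(n_snp(apply_region_mask(kept, bed, "drop")), 0L)
})

test_that("pileup reader parses the samtools text dialect", {
  path <- tempfile()
  writeLines(c(
    "1\t100\tC\t4\t..Tt\tIIII\tIIII",
    "1\t200\tG\t3\t^I.aN\tABC\t]]]",      # read start marker + N base
    "1\t300\tA\t2\t.+2AG,\tII\t]]",       # insertion segment skipped
    "1\t400\tT\t0\t*\t*\t*"
  ), path)
  pu <- read_pileup(path)
  expect_equal(pu$bases[[1]], c("C", "C", "T", "T"))
  expect_equal(pu$bq[[1]], rep(40L, 4))
  expect_equal(pu$bases[[2]], c("G", "A", "N"))
  expect_equal(pu$bq[[2]], c(32L, 33L, 34L))
  expect_equal(pu$mq[[2]], rep(60L, 3))
  expect_equal(pu$bases[[3]], c("A", "A"))  # ref-match + insertion + comma
  expect_length(pu$bases[[4]], 0)
})
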
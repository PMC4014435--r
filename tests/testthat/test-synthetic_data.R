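# Drift simulator, panel sampling, ancient-sample degradation, pileup
# simulation and the trio topology oracle.

test_that("demography graph validates structure", {
  expect_error(demography_graph(data.frame(child = "A", parent = "root",
                                           f = 1)), "\\[0, 1\\)")
  expect_error(demography_graph(
    data.frame(child = c("A", "B"), parent = c("B", "A"), f = 0.1)),
    "cycle|parent")
  expect_error(demography_graph(
    data.frame(child = "A", parent = "root", f = 0.1),
    admixture = data.frame(child = "C", parent1 = "A", parent2 = "root",
                           alpha = 1.5)), "alpha")
})

test_that("zero drift copies and alpha = 1 follows parent 1", {
  g <- demography_graph(
    data.frame(child = c("A", "B"), parent = "root", f = 0),
    admixture = data.frame(child = "C", parent1 = "A", parent2 = "B",
                           alpha = 1))
  sim <- simulate_frequencies(g, 500, seed = 2)
  expect_identical(sim$freq["A", ], sim$freq["root", ])
  expect_identical(sim$freq["B", ], sim$freq["root", ])
  expect_identical(sim$freq["C", ], sim$freq["A", ])
})

test_that("drift matches Balding-Nichols moments", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0.1),
                        root_freq = c(0.3, 0.3))   # degenerate root: p fixed
  sim <- simulate_frequencies(g, 10000, seed = 3)
  x <- sim$freq["A", ]
  expect_true(all(x >= 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.3), 0.005)             # ~3.5 MC SE
  expect_lt(abs(var(x) - 0.1 * 0.3 * 0.7), 0.0015)
})

test_that("simulation is deterministic in (graph, seed) and seed-sensitive", {
  w <- null_world()
  s1 <- simulate_frequencies(w, 200, seed = 11)
  s2 <- simulate_frequencies(w, 200, seed = 11)
  s3 <- simulate_frequencies(w, 200, seed = 12)
  expect_identical(s1$freq, s2$freq)
  expect_identical(s1$snps, s2$snps)
  expect_false(identical(s1$freq, s3$freq))
  expect_true(all(s1$freq >= 0 & s1$freq <= 1))
  expect_identical(unname(s1$freq["O", ]), rep(0, 200))  # outgroup fixed
})

test_that("snp map respects the transition:transversion ratio", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0.1))
  sim <- simulate_frequencies(g, 20000, seed = 5)
  ts_frac <- mean(sim$snps$transition)
  expect_lt(abs(ts_frac - 2 / 3), 0.012)           # ~3.5 MC SE
  expect_identical(sim$snps$anc, sim$snps$ref)     # root orientation
})

test_that("panel sampling follows the binomial law", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0),
                        root_freq = c(0.5, 0.5))
  sim <- simulate_frequencies(g, 100, seed = 7)
  sim$freq["A", 1:2] <- c(0, 1)
  panel <- sample_panel(sim, data.frame(pop = "A", n = 2000, ploidy = 2,
                                        class = "modern"), seed = 8)
  expect_true(all(panel$genotypes[, 1] == 0L))
  expect_true(all(panel$genotypes[, 2] == 2L))
  expect_lt(abs(mean(panel$genotypes[, 3]) - 1.0), 0.07)  # 3 MC SE
  hap <- sample_panel(sim, data.frame(pop = "A", n = 10, ploidy = 1,
                                      class = "ancient"), seed = 8)
  expect_true(all(hap$genotypes %in% c(0L, 1L)))
  expect_true(all(hap$genotypes[, 2] == 1L))
})

test_that("degradation damages only C>T/G>A and respects rates", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0.2))
  sim <- simulate_frequencies(g, 2000, seed = 9)
  panel <- sample_panel(sim, data.frame(pop = "A", n = 1, ploidy = 1,
                                        class = "ancient"), seed = 9)
  id <- panel$individuals$id[1]
  # no damage, no missingness: calls equal true alleles
  calls0 <- degrade_ancient(panel, id, delta = 0, missing_rate = 0, seed = 1)
  tru <- ifelse(panel$genotypes[1, ] >= 1L, sim$snps$alt, sim$snps$ref)
  expect_identical(calls0$sites$allele1, tru)
  # delta = 1: every observed C at a C/T site becomes T
  calls1 <- degrade_ancient(panel, id, delta = 1, missing_rate = 0, seed = 1)
  ct <- (sim$snps$ref == "C" & sim$snps$alt == "T") |
        (sim$snps$ref == "T" & sim$snps$alt == "C")
  expect_false(any(calls1$sites$allele1[ct] == "C"))
  ga <- (sim$snps$ref == "G" & sim$snps$alt == "A") |
        (sim$snps$ref == "A" & sim$snps$alt == "G")
  expect_false(any(calls1$sites$allele1[ga] == "G"))
  # alleles never leave the site pair
  ok <- calls1$sites$allele1 == sim$snps$ref |
        calls1$sites$allele1 == sim$snps$alt
  expect_true(all(ok[!is.na(calls1$sites$allele1)]))
  expect_error(degrade_ancient(panel, id, delta = 2, missing_rate = 0,
                               seed = 1), "\\[0, 1\\]")
})

test_that("heavy missingness emulates a ~1k-usable-SNP sample", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0.1))
  sim <- simulate_frequencies(g, 100000, seed = 10)
  panel <- sample_panel(sim, data.frame(pop = "A", n = 1, ploidy = 1,
                                        class = "ancient"), seed = 10)
  calls <- degrade_ancient(panel, panel$individuals$id[1], delta = 0.05,
                           missing_rate = 0.99, seed = 2)
  n_called <- sum(!is.na(calls$sites$allele1))
  expect_lt(abs(n_called - 1000), 3 * sqrt(100000 * 0.99 * 0.01) + 1)
})

test_that("pileup simulation: depth, error rate, quality law", {
  g <- demography_graph(data.frame(child = "A", parent = "root", f = 0.1))
  sim <- simulate_frequencies(g, 3000, seed = 4)
  panel <- sample_panel(sim, data.frame(pop = "A", n = 1, ploidy = 1,
                                        class = "ancient"), seed = 4)
  id <- panel$individuals$id[1]
  pu0 <- simulate_pileup(panel, id, lambda = 0, seed = 1)
  expect_true(all(lengths(pu0$bases) == 0))
  # epsilon = 0: every read copies the true allele
  pu <- simulate_pileup(panel, id, lambda = 5, epsilon = 0, seed = 1)
  tru <- ifelse(panel$genotypes[1, ] >= 1L, sim$snps$alt, sim$snps$ref)
  match_all <- vapply(seq_len(nrow(pu)), function(i) {
    all(pu$bases[[i]] == tru[i])
  }, logical(1))
  expect_true(all(match_all))
  expect_true(all(unlist(pu$bq) == 37L) && all(unlist(pu$mq) == 60L))
  # epsilon = 0.01: mismatch fraction ~1%  (>= 100k reads at lambda 40)
  pu2 <- simulate_pileup(panel, id, lambda = 40, epsilon = 0.01, seed = 2)
  mism <- sum(vapply(seq_len(nrow(pu2)), function(i) {
    sum(pu2$bases[[i]] != tru[i])
  }, numeric(1)))
  ntot <- sum(lengths(pu2$bases))
  expect_gt(ntot, 1e5)
  expect_lt(abs(mism / ntot - 0.01), 3 * sqrt(0.01 * 0.99 / ntot))
})

test_that("trio oracle hits the panmixia and deep-divergence limits", {
  ct0 <- simulate_trio_counts(0, 50000, seed = 21)
  r0 <- ct0$n_disc / (ct0$n_conc + ct0$n_disc)
  expect_lt(abs(r0 - 2 / 3), 3 * sqrt(2 / 9 / 50000))
  ct20 <- simulate_trio_counts(20, 20000, seed = 22)
  expect_lt(ct20$n_disc / (ct20$n_conc + ct20$n_disc), 1e-4)
  expect_error(simulate_trio_counts(-1, 100, seed = 1), ">= 0")
})

test_that("trio counts are reproducible and age-invariant", {
  a <- simulate_trio_counts(0.5, 20000, seed = 33)
  b <- simulate_trio_counts(0.5, 20000, seed = 33)
  expect_identical(a$blocks, b$blocks)
  # the ancient sampling age only shortens the ancient external branch,
  # which carries singletons; informative counts cannot change
  c_ <- simulate_trio_counts(0.5, 20000, seed = 33, age = 0.4)
  expect_identical(a$blocks, c_$blocks)
})
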
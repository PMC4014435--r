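# Shared fixture builders.  All data is generated in code; the drift and
# sample-size choices are fixed design points of the simulated world (see
# the methods vignette) and are not tuned per test.

# Small hand-built panel: 3 individuals (2 diploid, 1 haploid), 4 SNPs
# covering transition/transversion and known/unknown ancestral alleles.
tiny_panel <- function() {
  s <- snp_table(paste0("rs", 1:4), "1", c(100L, 200L, 5000001L, 6000000L),
                 ref = c("C", "G", "A", "T"), alt = c("T", "A", "C", "G"),
                 anc = c("C", "A", NA, "T"),
                 tags = c("eur", "", "afr,eas", ""))
  ind <- data.frame(id = c("a", "b", "c"), pop = c("P1", "P1", "P2"),
                    class = "modern", ploidy = c(2L, 2L, 1L))
  g <- matrix(c(0L, 1L, 2L, NA,
                2L, 0L, 1L, 1L,
                0L, 1L, NA, 1L), 3, 4, byrow = TRUE)
  genotype_panel(s, ind, g)
}

# Symmetric four-population world for D-statistic null calibration:
# X and the clade (P1, P2) split at the root; no gene flow.  Outgroup is
# the ancestral state (frequency 0).
null_world <- function() {
  demography_graph(
    edges = data.frame(child = c("ancX", "X", "anc12", "P1", "P2"),
                       parent = c("root", "ancX", "root", "anc12", "anc12"),
                       f = c(0.05, 0.05, 0.05, 0.05, 0.05)),
    outgroup = "O"
  )
}

# Same world with alpha = 0.1 gene flow into X from P1b, a lineage
# sharing continental-scale drift (F = 0.2) with P1.
admixed_world <- function(alpha = 0.1) {
  demography_graph(
    edges = data.frame(
      child  = c("ancX", "Xbase", "anc12", "anc1", "P1", "P1b", "P2"),
      parent = c("root", "ancX", "root", "anc12", "anc1", "anc1", "anc12"),
      f      = c(0.05, 0.05, 0.05, 0.2, 0.02, 0.02, 0.02)),
    admixture = data.frame(child = "X", parent1 = "P1b", parent2 = "Xbase",
                           alpha = alpha),
    outgroup = "O"
  )
}

# Admixture target world for f3: C = alpha A + (1 - alpha) B with source
# drift F = 0.1 on each branch.
f3_world <- function(alpha = 0.5) {
  demography_graph(
    edges = data.frame(child = c("A", "B"), parent = "root", f = 0.1),
    admixture = data.frame(child = "C", parent1 = "A", parent2 = "B",
                           alpha = alpha)
  )
}

# Two well-separated source populations for admixture-model tests
# (continental-scale differentiation, F = 0.15 per branch).
admix_sources_world <- function(n = 30, m = 5000) {
  demography_graph(
    edges = data.frame(child = c("A", "B"), parent = "root", f = 0.15),
    samples = data.frame(pop = c("A", "B"), n = n, ploidy = 2,
                         class = "modern")
  )
}

# genome map giving exactly `n` 5 Mb blocks on one pseudo-chromosome set
block_genome <- function(n_blocks = 100, window = 5e6) {
  data.frame(chrom = as.character(seq_len(ceiling(n_blocks / 25))),
             length = pmin(25, n_blocks - (seq_len(ceiling(n_blocks / 25))
                                           - 1) * 25) * window)
}

# frequencies for the four D populations at m sites; returns list of
# vectors plus a block partition
d_world_freqs <- function(world, m, seed, n_blocks = 100) {
  sim <- simulate_frequencies(world, m, seed,
                              genome = block_genome(n_blocks))
  blocks <- assign_blocks(sim$snps)
  list(o = sim$freq["O", ], x = sim$freq["X", ], p1 = sim$freq["P1", ],
       p2 = sim$freq["P2", ], blocks = blocks, sim = sim)
}
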
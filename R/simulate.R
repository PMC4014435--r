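## Synthetic data with known truth: Balding-Nichols allele-frequency drift
## on a population tree with admixture edges, genotype sampling, ancient
## sample degradation (deamination damage + missingness), read pileups,
## and an explicit three-lineage coalescent simulator used as the
## independent oracle for the divergence-time estimator.

#' Declare a population demography graph
#'
#' Drift edges connect a child population to its single parent with a
#' drift parameter `f` in `[0, 1)` (Balding-Nichols); admixture nodes have
#' two parents and a mixing proportion `alpha` (weight of `parent1`).
#' Ancestral/derived orientation is fixed by construction: the root draw
#' is the derived-allele frequency, so the simulated ancestral allele is
#' known exactly, and a designated outgroup can be represented as a
#' population carrying frequency 0 everywhere (see `outgroup`).
#'
#' @param edges data.frame with columns `child`, `parent`, `f`.
#' @param admixture optional data.frame with columns `child`, `parent1`,
#'   `parent2`, `alpha`.
#' @param root root node label (default `"root"`).
#' @param root_freq length-2 numeric, the Uniform(lo, hi) law of the root
#'   derived-allele frequency.  The default (0.05, 0.95) guarantees
#'   polymorphism, mimicking SNP-panel ascertainment.
#' @param samples optional data.frame with columns `pop`, `n`, `ploidy`,
#'   `class` describing individuals to draw per leaf.
#' @param outgroup optional label: an extra population fixed for the
#'   ancestral allele (frequency 0) at every site.
#' @return object of class `demography_graph`.
#' @export
demography_graph <- function(edges, admixture = NULL, root = "root",
                             root_freq = c(0.05, 0.95), samples = NULL,
                             outgroup = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      f = as.numeric(edges$f), stringsAsFactors = FALSE)
  if (any(edges$f < 0 | edges$f >= 1)) {
    stop("drift f must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(admixture)) {
    admixture <- data.frame(child = as.character(admixture$child),
                            parent1 = as.character(admixture$parent1),
                            parent2 = as.character(admixture$parent2),
                            alpha = as.numeric(admixture$alpha),
                            stringsAsFactors = FALSE)
    if (any(admixture$alpha < 0 | admixture$alpha > 1)) {
      stop("admixture alpha must be in [0, 1]", call. = FALSE)
    }
  }
  children <- c(edges$child, if (!is.null(admixture)) admixture$child)
  if (anyDuplicated(children)) {
    stop("node with more than one incoming edge set", call. = FALSE)
  }
  if (root %in% children) stop("root cannot have a parent", call. = FALSE)
  g <- structure(list(edges = edges, admixture = admixture, root = root,
                      root_freq = as.numeric(root_freq), samples = samples,
                      outgroup = outgroup),
                 class = "demography_graph")
  topo_order(g)  # errors on cycles / unknown parents
  g
}

topo_order <- function(graph) {
  nodes <- unique(c(graph$root, graph$edges$child, graph$edges$parent,
                    graph$admixture$child, graph$admixture$parent1,
                    graph$admixture$parent2))
  parents_of <- function(nd) {
    i <- which(graph$edges$child == nd)
    if (length(i)) return(graph$edges$parent[i])
    j <- which(graph$admixture$child == nd)
    if (length(j)) return(c(graph$admixture$parent1[j],
                            graph$admixture$parent2[j]))
    character(0)
  }
  ordered <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nd) {
      all(parents_of(nd) %in% ordered)
    }, logical(1))]
    if (!length(ready)) stop("demography graph has a cycle", call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' Read a demography graph from a JSON config file
#'
#' Schema (all keys top-level): `edges` (array of `{child, parent, f}`),
#' `admixture` (optional array of `{child, parent1, parent2, alpha}`),
#' `root`, `root_freq` (length-2), `samples` (array of
#' `{pop, n, ploidy, class}`), `outgroup`, `genome` (optional
#' `{chromosomes, length}`), `m` (site count), `seed`.
#'
#' @param path JSON file.
#' @return list with elements `graph` (a [demography_graph()]), `m`,
#'   `seed`, `genome`.
#' @export
read_demography <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("edges", "admixture", "root", "root_freq", "samples",
             "outgroup", "genome", "m", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown demography config key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  graph <- demography_graph(
    cfg$edges,
    admixture = cfg$admixture,
    root = if (is.null(cfg$root)) "root" else cfg$root,
    root_freq = if (is.null(cfg$root_freq)) c(0.05, 0.95) else cfg$root_freq,
    samples = cfg$samples,
    outgroup = cfg$outgroup
  )
  genome <- if (is.null(cfg$genome)) default_genome_map() else
    data.frame(chrom = as.character(cfg$genome$chromosomes),
               length = as.numeric(cfg$genome$length))
  list(graph = graph, m = if (is.null(cfg$m)) 10000L else as.integer(cfg$m),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       genome = genome)
}

#' Default genome map for simulated SNPs
#'
#' 22 autosomes of 125 Mb each; positions are drawn uniformly over this
#' map, so 5 Mb jackknife blocks are well populated at panel-scale site
#' counts.
#'
#' @return data.frame with columns `chrom`, `length`.
#' @export
default_genome_map <- function() {
  data.frame(chrom = as.character(1:22), length = 125e6)
}

#' Simulate derived-allele frequencies down a demography graph
#'
#' Root frequencies are Uniform(lo, hi) draws; along each drift edge the
#' child frequency given parent frequency p is Balding-Nichols,
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (mean p, variance `F p (1-p)`; exact
#' copy when F = 0); an admixture node gets the deterministic mixture
#' `alpha p1 + (1 - alpha) p2`.  Each site is also assigned a genomic
#' position (uniform over `genome`, then sorted) and an allele pair with
#' the given transition:transversion ratio; the ancestral allele is the
#' reference allele by construction, so the alternative allele is always
#' the derived one.
#'
#' @param graph a [demography_graph()].
#' @param m number of sites (>= 1).
#' @param seed RNG seed.
#' @param genome genome map data.frame (`chrom`, `length`).
#' @param ts_tv transition:transversion ratio for allele-pair assignment
#'   (default 2, the genome-wide human value).
#' @return object of class `sim_freqs`: list with `snps` (a
#'   [snp_table()]), `freq` (node x site matrix of derived-allele
#'   frequencies, including the outgroup row at 0 if declared), `graph`,
#'   `seed`.
#' @export
simulate_frequencies <- function(graph, m, seed,
                                 genome = default_genome_map(), ts_tv = 2) {
  stopifnot(m >= 1)
  set.seed(derive_seed(seed, "frequencies"))
  nodes <- topo_order(graph)
  freq <- matrix(NA_real_, length(nodes), m, dimnames = list(nodes, NULL))
  freq[graph$root, ] <- runif(m, graph$root_freq[1], graph$root_freq[2])
  for (nd in nodes) {
    if (nd == graph$root) next
    i <- which(graph$edges$child == nd)
    if (length(i)) {
      p <- freq[graph$edges$parent[i], ]
      f <- graph$edges$f[i]
      freq[nd, ] <- if (f == 0) p else bn_drift(p, f)
    } else {
      j <- which(graph$admixture$child == nd)
      a <- graph$admixture$alpha[j]
      freq[nd, ] <- a * freq[graph$admixture$parent1[j], ] +
        (1 - a) * freq[graph$admixture$parent2[j], ]
    }
  }
  if (!is.null(graph$outgroup)) {
    og <- matrix(0, 1, m, dimnames = list(graph$outgroup, NULL))
    freq <- rbind(freq, og)
  }
  snps <- random_snp_map(m, genome, ts_tv)
  structure(list(snps = snps, freq = freq, graph = graph, seed = seed),
            class = "sim_freqs")
}

bn_drift <- function(p, f) {
  k <- (1 - f) / f
  q <- rbeta(length(p), p * k, (1 - p) * k)
  # rbeta returns NaN only for zero shapes (p exactly 0 or 1): fixed sites
  # stay fixed under drift
  fix <- p == 0 | p == 1
  q[fix] <- p[fix]
  q
}

random_snp_map <- function(m, genome, ts_tv) {
  chrom <- sample(genome$chrom, m, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  pos <- floor(runif(m, 1, genome$length[match(chrom, genome$chrom)] + 1))
  # positions must be unique within a chromosome (sites are SNPs)
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- floor(runif(sum(dup), 1,
                            genome$length[match(chrom[dup],
                                                genome$chrom)] + 1))
  }
  ord <- order(match(chrom, genome$chrom), pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  is_ts <- runif(m) < ts_tv / (ts_tv + 1)
  ts_pairs <- rbind(c("C", "T"), c("G", "A"))
  tv_pairs <- rbind(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))
  pick_ts <- ts_pairs[sample.int(2, m, replace = TRUE), , drop = FALSE]
  pick_tv <- tv_pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  flip <- runif(m) < 0.5   # which member of the pair is ancestral
  pair <- pick_tv
  pair[is_ts, ] <- pick_ts[is_ts, ]
  anc <- ifelse(flip, pair[, 1], pair[, 2])
  der <- ifelse(flip, pair[, 2], pair[, 1])
  snp_table(sprintf("snp%06d", seq_len(m)), chrom, pos,
            ref = anc, alt = der, anc = anc)
}

#' Draw a genotype panel from simulated frequencies
#'
#' Diploid genotypes are Binomial(2, p), haploid Bernoulli(p), independent
#' across sites and individuals.
#'
#' @param sim a `sim_freqs` object from [simulate_frequencies()].
#' @param samples data.frame with columns `pop`, `n`, `ploidy`, `class`;
#'   defaults to the graph's sample spec.  The outgroup population (all
#'   frequencies 0) may be sampled like any other.
#' @param seed RNG seed.
#' @return a [genotype_panel()]; `attr(panel, "truth")` records the
#'   frequency matrix and seed used.
#' @export
sample_panel <- function(sim, samples = NULL, seed = sim$seed) {
  if (is.null(samples)) samples <- sim$graph$samples
  if (is.null(samples)) stop("no sample spec given", call. = FALSE)
  samples$n <- as.integer(samples$n)
  samples$ploidy <- as.integer(samples$ploidy)
  if (is.null(samples$class)) samples$class <- "modern"
  set.seed(derive_seed(seed, "panel"))
  m <- ncol(sim$freq)
  rows <- list(); ids <- character(0); g <- list()
  for (s in seq_len(nrow(samples))) {
    pop <- samples$pop[s]
    if (!pop %in% rownames(sim$freq)) {
      stop("sample spec names unknown population: ", pop, call. = FALSE)
    }
    p <- sim$freq[pop, ]
    for (k in seq_len(samples$n[s])) {
      ids <- c(ids, sprintf("%s_%d", pop, k))
      rows[[length(rows) + 1L]] <-
        data.frame(pop = pop, class = samples$class[s],
                   ploidy = samples$ploidy[s])
      g[[length(g) + 1L]] <- rbinom(m, samples$ploidy[s], p)
    }
  }
  inds <- do.call(rbind, rows)
  inds <- data.frame(id = ids, inds, stringsAsFactors = FALSE)
  panel <- genotype_panel(sim$snps, inds, do.call(rbind, g))
  attr(panel, "truth") <- list(freq = sim$freq, seed = seed)
  panel
}

#' Degrade one sample into an ancient call set
#'
#' Emulates post-mortem cytosine deamination and low coverage: at C/T
#' sites each observed C flips to T with probability `delta`
#' (complementarily G to A at G/A sites), and each site is independently
#' set missing with probability `missing_rate`.  Only transition-pair
#' sites can be damaged; degraded call sets never contain alleles outside
#' the site's allele pair.
#'
#' @param panel a [genotype_panel()] containing the target sample.
#' @param sample_id which individual to degrade.
#' @param delta per-allele damage probability in `[0, 1]`.
#' @param missing_rate per-site missingness probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param as_id sample id recorded on the call set (default `sample_id`);
#'   useful when the degraded copy is merged back into a panel that
#'   still contains the pristine source individual.
#' @return an [ancient_calls()] object; `attr(, "truth")` keeps the
#'   undamaged alleles.
#' @export
degrade_ancient <- function(panel, sample_id, delta, missing_rate, seed,
                            as_id = sample_id) {
  if (delta < 0 || delta > 1 || missing_rate < 0 || missing_rate > 1) {
    stop("delta and missing_rate must be in [0, 1]", call. = FALSE)
  }
  i <- ind_index(panel, sample_id)
  ploidy <- panel$individuals$ploidy[i]
  g <- panel$genotypes[i, ]
  s <- panel$snps
  set.seed(derive_seed(seed, paste0("degrade:", sample_id)))
  # allele identities per copy
  a1 <- ifelse(g >= 1L, s$alt, s$ref)
  a2 <- if (ploidy == 2L) ifelse(g >= 2L, s$alt, s$ref) else
    rep(NA_character_, length(g))
  truth <- list(allele1 = a1, allele2 = a2)
  a1 <- damage_flip(a1, s, delta)
  if (ploidy == 2L) a2 <- damage_flip(a2, s, delta)
  drop <- runif(length(g)) < missing_rate | is.na(g)
  a1[drop] <- NA_character_
  if (ploidy == 2L) a2[drop] <- NA_character_
  calls <- ancient_calls(
    as_id,
    data.frame(chrom = s$chrom, pos = s$pos, allele1 = a1, allele2 = a2),
    ploidy = ploidy,
    provenance = list(delta = delta, missing_rate = missing_rate,
                      seed = seed)
  )
  attr(calls, "truth") <- truth
  calls
}

damage_flip <- function(allele, snps, delta) {
  if (delta == 0) return(allele)
  pair_ct <- (snps$ref == "C" & snps$alt == "T") |
             (snps$ref == "T" & snps$alt == "C")
  pair_ga <- (snps$ref == "G" & snps$alt == "A") |
             (snps$ref == "A" & snps$alt == "G")
  hit <- runif(length(allele)) < delta
  allele[pair_ct & allele == "C" & hit] <- "T"
  allele[pair_ga & allele == "G" & hit] <- "A"
  allele
}

#' Simulate a read pileup over true alleles
#'
#' Per-site read depth is Poisson(`lambda`); each read copies one of the
#' individual's true alleles uniformly and is mutated to a uniformly
#' chosen other base with probability `epsilon`.  Base/mapping qualities
#' follow a two-point law: high (BQ 37 / MQ 60) with probability
#' `1 - low_frac`, low (BQ 20 / MQ 20) otherwise, emulating the reads the
#' MQ/BQ < 30 filters are meant to remove.
#'
#' @param panel a [genotype_panel()].
#' @param sample_id individual whose true alleles seed the reads.
#' @param lambda mean depth (>= 0).
#' @param epsilon per-base error probability in `[0, 1)`.
#' @param low_frac fraction of low-quality reads (default 0).
#' @param seed RNG seed.
#' @return a `pileup` data.frame (see [read_pileup()]).
#' @export
simulate_pileup <- function(panel, sample_id, lambda, epsilon = 0,
                            low_frac = 0, seed = 1) {
  stopifnot(lambda >= 0, epsilon >= 0, epsilon < 1)
  i <- ind_index(panel, sample_id)
  ploidy <- panel$individuals$ploidy[i]
  g <- panel$genotypes[i, ]
  s <- panel$snps
  set.seed(derive_seed(seed, paste0("pileup:", sample_id)))
  depth <- rpois(nrow(s), lambda)
  depth[is.na(g)] <- 0L
  bases <- vector("list", nrow(s))
  bq <- vector("list", nrow(s)); mq <- vector("list", nrow(s))
  for (j in seq_len(nrow(s))) {
    d <- depth[j]
    if (d == 0L) {
      bases[[j]] <- character(0); bq[[j]] <- integer(0); mq[[j]] <- integer(0)
      next
    }
    alleles <- if (ploidy == 2L) {
      c(if (g[j] >= 1L) s$alt[j] else s$ref[j],
        if (g[j] >= 2L) s$alt[j] else s$ref[j])
    } else {
      if (g[j] >= 1L) s$alt[j] else s$ref[j]
    }
    b <- sample(alleles, d, replace = TRUE)
    err <- runif(d) < epsilon
    if (any(err)) {
      b[err] <- vapply(b[err], function(x) sample(setdiff(BASES, x), 1), "")
    }
    low <- runif(d) < low_frac
    bases[[j]] <- b
    bq[[j]] <- ifelse(low, 20L, 37L)
    mq[[j]] <- ifelse(low, 20L, 60L)
  }
  out <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref,
                    stringsAsFactors = FALSE)
  out$bases <- bases; out$bq <- bq; out$mq <- mq
  class(out) <- c("pileup", "data.frame")
  out
}

#' Monte Carlo three-lineage topology simulator
#'
#' Independent oracle for the divergence-time estimator: simulates, site
#' by site, the genealogy of two gene copies from a modern population and
#' one ancient lineage that diverged `tau` coalescent units (of 2N
#' generations) ago.  Before `tau` the two modern copies coalesce at rate
#' 1; all lineages surviving to `tau` enter the ancestral population,
#' where each pair coalesces at rate 1.  Mutations fall on the
#' genealogy's branches as a Poisson process (infinite sites, one
#' mutation per site); sites whose mutation lies on the internal branch
#' (two derived copies) are informative and classed concordant (both
#' modern copies derived) or discordant (the ancient and one modern copy
#' derived).  Modern and ancestral population sizes are equal; the
#' ancient sample's age `age` shortens only the ancient external branch,
#' which carries singleton mutations exclusively, and so provably cannot
#' change the two-derived-allele classes -- the test suite asserts this
#' invariance.
#'
#' @param tau divergence in coalescent units (>= 0).
#' @param n_sites number of informative sites to accumulate.
#' @param seed RNG seed.
#' @param n_blocks number of surrogate jackknife blocks (sites are
#'   exchangeable; blocks exist for jackknife mechanics).
#' @param age ancient sampling age in coalescent units (< `tau`).
#' @return a [divergence_counts()] object.
#' @export
simulate_trio_counts <- function(tau, n_sites, seed, n_blocks = 100,
                                 age = 0) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (age < 0 || age > tau) stop("age must be in [0, tau]", call. = FALSE)
  set.seed(derive_seed(seed, "trio"))
  # Mutations fall on the genealogy as a Poisson process, so informative
  # mutations arise at rate mu * (internal branch length) per genealogy
  # and the expected class counts are proportional to the expected
  # internal branch lengths -- the quantity the closed form integrates.
  # External-branch mutations yield singletons, which the classifier
  # ignores; they (and the ancient sampling age, which only shortens the
  # ancient external branch) are therefore never realized here.
  mu <- 0.1   # small: at most one informative mutation per genealogy a.s.
  conc <- logical(0)
  while (length(conc) < n_sites) {
    batch <- max(50000L, ceiling((n_sites - length(conc)) / mu * 1.3))
    t1 <- rexp(batch)                      # M1-M2 coalescence attempt
    pre <- t1 < tau
    e2 <- rexp(batch)                      # 2-lineage ancestral coalescence
    # pre-tau coalescence: internal branch spans (t1, tau + e2], clade MM;
    # otherwise three lineages reach the ancestral population, the first
    # pair is uniform among the three, internal branch length e2
    first_pair <- sample.int(3, batch, replace = TRUE)  # 1 = {M1,M2}
    l_int <- ifelse(pre, (tau - t1) + e2, e2)
    clade_mm <- ifelse(pre, TRUE, first_pair == 1L)
    n_mut <- rpois(batch, mu * l_int)
    conc <- c(conc, rep(clade_mm, n_mut))
  }
  conc <- conc[seq_len(n_sites)]
  blocks <- uniform_blocks(n_sites, n_blocks)
  count_topologies(ancient = as.integer(!conc),
                   modern = ifelse(conc, 2L, 1L), blocks = blocks)
}

# stable per-stage seed derivation so adding one stage never perturbs
# another stage's draws; keeps everything below 2^31
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
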
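---
title: "palaeopop: models, estimators and the simulated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{palaeopop: models, estimators and the simulated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A low-coverage ancient genome cannot be genotyped like a modern sample:
most sites are covered by zero or one read, post-mortem cytosine
deamination creates spurious C→T (and complementary G→A) substitutions,
and sequencing artefacts differ between samples.  `palaeopop` implements
the standard analysis chain for relating such genomes to modern
reference panels — pseudo-haploid calling, careful merging, allele-sharing
statistics with honest standard errors, admixture-model projection, PCA
projection, and coalescent divergence dating — together with a simulator
that generates data with known truth so that every estimator can be
validated end to end.

# Calling and filtering

Reads with mapping quality or base quality below 30 are removed
(*strictly* below: a read at the threshold survives), as are N bases.
At each remaining site a **pseudo-haploid call** draws one read uniformly
at random — over reads, not distinct alleles, so the sampled allele
follows the read-base composition.  Higher-coverage genomes that admit
diploid calling are filtered with hard thresholds instead: Phred variant
quality strictly greater than 40, depth inside [6, 30], at least 5 bp
from the nearest alignment gap, and outside annotated repeats.  The
depth rule is stated in its source as "≥6 or ≤30", a literal disjunction
that admits everything; it is read here as the interval, and both bounds
are configurable (`diploid_filter_config()`) so either reading can be
forced.

Damage handling follows two regimes.  With a single ancient sample in an
analysis, only transition sites where that sample *shows the damage
allele* (T at a C/T site, A at a G/A site) are removed — the sample's
other transition calls are informative and kept.  With multiple ancient
samples, damage patterns can correlate between samples and bias
allele-sharing tests, so *all* transition sites are dropped.

# Merging and orientation

Ancient call sets are merged onto the modern panel's site list: calls at
sites absent from the panel are discarded (counted), and observed
alleles outside the panel's ref/alt pair are set missing (counted as
mismatches).  The merge report's accounting identity — reasons sum
exactly to input minus usable — is asserted in the tests.  Sites with
more than 10% missing data among modern individuals (strictly more) are
dropped.  Whole-genome diploids can be haploidized by sampling one
allele at each heterozygote, and recently admixed individuals can be
masked to one local-ancestry component, producing "virtual individuals"
carrying only tracts homozygous for the target ancestry.

All downstream statistics work in **derived-allele orientation**:
`polarize()` re-orients each site so the alternative allele is the one
not matching the ancestral allele, dropping (and counting) sites whose
ancestral state is unknown or off-pair.  In simulation the ancestral
allele is known by construction, so polarization is exact; with real
data its accuracy is bounded by the outgroup inference, which this
package consumes, not produces.

# Allele-sharing statistics

For derived-allele frequency vectors $o, x, p_1, p_2$ over $M$ sites,

$$D = \frac{\sum_i (o_i - x_i)(p_{1i} - p_{2i})}
           {\sum_i (o_i + x_i - 2 o_i x_i)(p_{1i} + p_{2i} - 2 p_{1i} p_{2i})},$$

with the sign convention that $D < 0$ means excess derived-allele
matching between $X$ and $P_1$.  $D$ is exactly antisymmetric in
$(P_1, P_2)$.  The three-population statistic is the mean of
$(c_i - a_i)(c_i - b_i)$; when the target frequency comes from $n_i$
sampled chromosomes the estimator subtracts
$\hat c_i(1-\hat c_i)/(n_i - 1)$, whose expectation equals the sampling
variance $c_i(1-c_i)/n_i$, making the corrected $f_3$ unbiased under
drift (verified against simulation truth in the tests).  The correction
defaults on for population targets and is undefined (off) for
single-chromosome targets.

Standard errors use the **weighted block jackknife** over 5 Mb genomic
windows: leave-one-block-out estimates combined with Busing-style
weights proportional to each block's informative-site count.  With equal
weights the formula reduces to the ordinary delete-one jackknife, which
the tests exploit as an independent oracle.  Blocks much wider than
linkage disequilibrium make the site-level dependence irrelevant to the
SE; the simulator draws sites independently, so for simulated data the
blocks only exercise the mechanics.

Derived-allele sharing reports, per modern individual, the fraction of
the ancient sample's derived sites at which the individual carries at
least one derived allele.  The denominator is per-individual (its
non-missing subset); a shared-denominator variant is available.  Rates
are normalized by the lowest-sharing individual, which is exactly 1.

# Admixture model and projection

The admixture model gives individual $i$ (with $c_i \in \{1,2\}$ gene
copies) derived dosage $g_{im} \sim \mathrm{Bin}(c_i, \sum_k q_{ik} p_{km})$.
`fit_admixture()` maximizes the binomial log-likelihood by plain FRAPPE
EM, with $Q$ rows on the simplex and $P$ clamped to
$[10^{-9}, 1-10^{-9}]$; each of the (default ten) replicates starts from
Dirichlet(1) rows and Uniform(0.05, 0.95) frequencies, and the
best-likelihood replicate wins.  The EM trace is non-decreasing by
construction and a decrease beyond $10^{-8}$ relative slack is a hard
error, asserted on every run.

Ancient samples are **projected**: EM over $q$ only, with $P$ fixed and
the likelihood restricted to the sample's non-missing SNPs, so the
projected genome never influences the clustering solution.  Projection
initializes at the uniform simplex point and is therefore deterministic.

Two numerical choices deviate from the obvious defaults and deserve a
note.  First, the convergence tolerance is $10^{-7}$ relative change in
log-likelihood (not $10^{-6}$): without quasi-Newton acceleration EM
approaches the simplex boundary slowly, and at $10^{-6}$ the fitted
memberships of two well-separated populations are still visibly short of
their one-hot limits; $10^{-7}$ resolves them at modest extra cost.
Second, the EM inner loop is compiled (RcppArmadillo): the update is a
dense $N \times M \times K$ sweep for hundreds to thousands of
iterations, which is impractical in interpreted code at panel scale.

Cluster labels are arbitrary; comparisons across runs first align
columns by greedy maximum-correlation matching (exhaustive matching over
all $K!$ permutations is available and exact for the small $K$ this
model targets).  The accuracy evaluation (`rmse_subset_eval()`)
re-projects every modern individual on each ancient sample's SNP subset
and reports, per population, the root-mean-square difference over
(individual, cluster) pairs against the full-SNP projection.  Because
the baseline is a projection under the same fixed $P$, the full-subset
RMSE is exactly zero, and accuracy degrades monotonically (in median) as
subsets shrink.  The source phrase "root mean standard error" is read as
root-mean-square error, which the same source's results section and
figure captions use.

# PCA projection

The component space is built from the fit panel only: SNP-wise
centering (optional $1/\sqrt{p(1-p)}$ scaling), mean imputation of the
fit panel's missing entries, SVD.  A projected sample is placed by least
squares of its centered genotypes against the SNP loadings restricted to
its non-missing sites — no imputation of the projected sample, so
missingness widens its uncertainty without pulling it toward the mean.
A fit-panel member with complete data projects exactly onto its own
score coordinates, and a three-genome fit panel (the archaic-space
variant) has at most two nontrivial components; both facts are asserted
in the tests.  Scaling defaults to centering only, with unit-variance
scaling as an option, since the source does not state a scaling.

# Divergence time from topology counts

For one ancient lineage and the two gene copies of a modern genome,
polarized sites with two derived copies are informative:
(modern = 2, ancient = 0) is *concordant* — the modern copies form the
derived clade — and (modern = 1, ancient = 1) is *discordant*.  With
divergence $\tau$ (in units of $2N$ generations), equal modern and
ancestral population sizes, and infinite-sites mutation, the expected
internal-branch lengths give

$$R(\tau) = \frac{\tfrac{2}{3} e^{-\tau}}{\tau + e^{-\tau}},$$

the expected discordant fraction: $R(0) = 2/3$ (all three topologies
exchangeable under panmixia), strictly decreasing to 0.  `estimate_tau()`
inverts $R$ at the observed fraction by bisection on $[0, 20]$ to
$10^{-8}$; a ratio at or above $2/3$ returns $\tau = 0$ with a boundary
flag, and a ratio below $R(20)$ returns the ceiling with a censoring
flag — never a silent truncation.  The confidence interval jackknifes
the ratio over blocks and maps both ends through $R^{-1}$ (the interval
flips because $R$ decreases).  Because the closed form is a derivation,
not a quotation, the package carries an independent Monte Carlo oracle
(`simulate_trio_counts()`) that simulates the three-lineage genealogy
explicitly and drops mutations as a Poisson process on branches; the
tests require agreement within three Monte Carlo standard errors across
a $\tau$ grid.  One subtlety fixed during development: placing a single
mutation uniformly per genealogy weights genealogies by the inverse of
their total length and does *not* converge to $R(\tau)$; Poisson
mutation (count proportional to branch length) is both the correct
infinite-sites model and the one the closed form integrates.

The ancient sample's age enters neither the estimator nor the oracle's
informative classes: age shortens only the ancient external branch,
which carries singleton mutations, and singletons are ignored by the
classifier.  Population-level panels without individual genotypes use
two **virtual haploid genomes** — independent Bernoulli($p_i$) draws from
the population's derived-allele frequencies — interpreted as the
divergence of an average individual under within-population panmixia.

Years are $T = \tau \cdot 2 N_e \cdot g$ with generation time $g = 25$
years and continental $N_e$ values (Africa 29,300 (23,900–35,200),
Europe 5,800 (900–11,500), Asia 3,000 (300–6,600)); intervals combine
$\tau$ and $N_e$ uncertainty by the extreme-product rule, one defensible
reading of "combining the uncertainty" of both components.  Panel
ascertainment (only panel-polymorphic sites analyzed) biases the
observed ratio; the simulator can reproduce matched ascertainment, and
no analytic correction is attempted.

# The simulated world

`simulate_frequencies()` drifts a root derived-allele frequency down a
population tree: along an edge with drift $F$, the child frequency given
parent $p$ is Balding–Nichols, $\mathrm{Beta}(p\tfrac{1-F}{F},
(1-p)\tfrac{1-F}{F})$ — mean $p$, variance $F p(1-p)$ — which keeps
frequencies in $[0,1]$ without the clipping artefacts of Gaussian drift;
admixture nodes mix parental frequencies deterministically as
$\alpha p_1 + (1-\alpha) p_2$.  Defaults and their reasons:

* **Root law Uniform(0.05, 0.95)** guarantees polymorphism, mimicking
  SNP-array ascertainment;
* **ts:tv ratio 2:1**, the genome-wide human value, so damage-relevant
  transition sites occur at a realistic rate;
* **genome map**: 22 autosomes of 125 Mb, positions uniform, so 5 Mb
  jackknife blocks are well populated at panel-scale site counts;
* **outgroup** represented as a frequency-0 population (the ancestral
  state), matching exact polarization by construction;
* **drift scales** in the test worlds: 0.05 per branch for
  within-continent structure, 0.15–0.2 for continental-scale
  differentiation, chosen once from typical human $F_{ST}$ ranges;
* **ancient degradation**: per-allele damage probability $\delta$
  applied to C at C/T sites (G at G/A), i.e. only where damage is
  confusable with a real polymorphism, and per-site missingness up to
  0.99, spanning the ~160k-to-~1k usable-SNP range of real
  single-sample merges;
* **pileups**: Poisson depth, uniform base error, two-point quality law
  (BQ 37/MQ 60 vs BQ 20/MQ 20) so the quality filters have something to
  remove.

What the simulator does **not** emulate: linkage disequilibrium (sites
are exchangeable; jackknife blocks exercise mechanics, not dependence),
reference bias, contamination, real ascertainment schemes, and
sequencing-platform batch effects.  A green test therefore establishes
correctness of the estimators under their own model assumptions, not
robustness to those artefacts.

Determinism: every operation takes an explicit seed and derives a
labeled substream from it, so adding a pipeline stage never perturbs
another stage's draws, and seeded CLI runs are byte-identical.

# Known limitations

* The admixture fit offers no cross-validation for choosing $K$; $K$ is
  an input.
* The divergence closed form assumes equal modern and ancestral
  population sizes; violations bias $\tau$ through the discordance
  plateau.
* EIGENSTRAT support is the dense-text dialect with two documented
  extension columns; packed binary formats are out of scope.
* Multi-allelic VCF records are skipped (with a count), not decomposed.
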
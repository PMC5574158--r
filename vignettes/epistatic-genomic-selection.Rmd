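---
title: "Simulating genomic selection under complementary epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection under complementary epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(episel)
```

`episel` runs in-silico divergent genomic-selection experiments on a
Drosophila-like genome and asks how functional epistasis shapes the
response to sequence-based selection.  This vignette explains the
models the package implements, the choices behind its defaults, and
what its synthetic data can and cannot stand in for.

## The simulated system

The genome consists of three chromosomes (X, 2, 3) mirroring the
*D. melanogaster* karyotype used in population-genetic work; the tiny,
non-recombining, mostly heterochromatic chromosome 4 is ignored.
Physical lengths default to 22, 48 and 52 Mb, female genetic lengths to
70, 107 and 110 cM, and the male map is zero everywhere because male
Drosophila do not recombine.  Meiosis is gene dropping with a Poisson
crossover count per chromosome (mean = female map length in Morgans)
and crossover positions uniform on the centimorgan scale, so
recombination fractions follow Haldane's map function; crossover
interference is not modelled, which matches how standard breeding-scheme
simulators treat the map and only requires map lengths as input.

X-chromosome transmission is enforced by sex: daughters receive the
sire's X intact plus a recombined maternal X; sons receive only a
recombined maternal X.  Internally a male's single X haplotype is
stored duplicated, so the dosage coding counts a male X allele as two
copies.  This "doubled" coding flows unchanged into every genomic
relationship matrix.  One consequence is that a male is structurally
"homozygous" at X sites, so the excess-homozygosity inbreeding
coefficient reported per generation is computed on autosomes only.

## Founder haplotypes: what the generator emulates

Real studies of this design start from a panel of ~205 fully inbred,
fully sequenced lines.  The generator substitutes that panel with:

* per-site frequencies drawn i.i.d. from a symmetric
  Beta(`sfs_shape`, `sfs_shape`) with `sfs_shape = 0.2`, giving the
  U-shaped site frequency spectrum characteristic of sequence variants
  (draws that could not segregate in a finite panel are redrawn, and
  columns monomorphic in the sampled panel are resampled so every
  retained site is polymorphic);
* 205 fully homozygous lines, each line's allele at each site a single
  Bernoulli draw copied to both haplotypes;
* sites mutually independent given their frequencies, so long-range LD
  in the panel is near zero in expectation (`E[r^2] ~ 1/n_lines`), as
  in the real panel after ten generations of random mating.

What this emulation deliberately does **not** reproduce: real
haplotype block structure and short-range LD of a natural population,
a realistic recombination landscape along the chromosome (the map is
linear in bp unless a breakpoint table is supplied), and mutation.
Results that hinge on fine-scale LD between markers and causal sites
are therefore optimistic at short distances and should be read as
qualitative.

A real panel can be used instead: `load_haplotypes_vcf()` ingests
phased, biallelic SNPs from a VCF (indels and multi-allelic records are
skipped, unphased genotypes rejected) and joins them to a genetic map
supplied as a site table or 4-column TSV.

## Trait architectures

Four hundred causal sites (QTN) are grouped into 200 disjoint pairs.
Absolute effects come from a two-component mixture: 297 draws from
Exponential(rate 5) — many undetected small effects — plus 103
lognormal draws emulating effects estimated by an association study,
which are the largest ones because significance filters select them.
The lognormal median defaults to ten times the exponential median
(`sdlog = 0.5`).  That single ratio was calibrated once against a
printed summary of the architecture this design reproduces — about 28%
of loci accounting for 90% of the summed `2 p q alpha^2` contributions
in the base population — and is deliberately larger than a naive
"bimodal histogram" reading would suggest; with a smaller ratio the
concentration statistic, the up/down response asymmetry, and the
epistasis-versus-additive ordering of upward responses all degrade
together.

The pair value *z* is the arithmetic mean of the two locus effects.
Under the **complementary** architecture the two-locus genotypic value
is *z* when the genotype carries at least one dominant allele at *both*
loci and 0 otherwise — complete dominance at each locus, the classical
9:7 epistasis table — and an individual's genotypic value is the sum
over the 200 pairs.  Under the **additive** architecture each locus
contributes *a*, 0 or −*a* for the dominant homozygote, heterozygote
and recessive homozygote, with *a* equal to the *z* of its pair, so the
two architectures are matched locus by locus.

Orientation is where several open choices had to be settled:

* The dominant allele at every locus is the **major** allele; the minor
  allele is recessive.  This mirrors panels in which the alternative
  (usually rare) allele was assigned the recessive role.
* A locus's trait-increasing allele is then determined by the sign of
  its effect: negative sign means the recessive (minor) allele
  increases the trait — the typical case, which is what makes the
  selection responses asymmetric.
* Pairs are formed at random **within** sign classes.  Fully random
  pairing with signed averaging would let a pair's net sign flip the
  effective trait-increasing allele of its weaker member after the
  per-locus calibration had already fixed it, and could nearly cancel
  the pair value; same-sign pairing keeps the arithmetic-mean rule, the
  per-locus orientation and the calibration mutually consistent.

`assign_qtn_sites()` calibrates the set so that the mean frequency of
trait-increasing alleles is 0.17 and the Pearson correlation between
absolute effect and increasing-allele frequency is −0.42 (both
targets configurable).  The mean is hit by flipping a computed number
of loci to major-allele-increasing; the correlation by Gaussian-copula
rank matching of absolute effects to increasing-allele frequencies,
with the copula parameter found by deterministic bisection.  Achieved
values are stored as attributes; tolerances are ±0.02 and ±0.05,
widened as `1/sqrt(n)` and `2/sqrt(n)` for small QTN sets where the
sampling noise of a mean or correlation exceeds those windows.

Environmental variance is calibrated on the realized base population:
`sigma_e2 = Var(g) (1 − H2) / H2` with `H2 = 0.5`, so phenotypes are
`y = g + e`, `e ~ N(0, sigma_e2)`.

### A note on realized additive shares

Under linkage equilibrium the calibrated complementary architecture
puts close to half of its genetic variance in the additive component
(narrow-sense heritability ≈ 0.25 at `H2 = 0.5`).  The realized base
population, however, descends from ~205 homozygous founder haplotypes
through ten generations of mating on three chromosomes with no male
recombination.  That leaves substantial within-chromosome identity
disequilibrium: individuals vary in how much of a chromosome is
identical by descent, homozygosity is therefore positively correlated
along chromosomes, and because most pair values share the same sign the
pairwise covariances add up rather than cancel.  The result is a
realized genetic variance well above — and a realized additive share
well below — the linkage-equilibrium expectation.  The effect is
founder-count-driven (it persists when burn-in population size is
increased) and is a genuine property of this design, worth keeping in
mind when comparing progeny-test heritabilities against
linkage-equilibrium theory.

## Base population and selection scheme

`build_base_population()` runs `max(burn_generations, 1)` rounds of
random mating at size `N`, starting from the founder lines themselves,
so the first round *is* the line crosses and `burn_generations = 0`
yields direct line crosses.  The default is 10 rounds at `N = 500`.
Each replicate of an experiment re-derives a fresh base population from
the same panel and the same QTN effects.

Selection then proceeds for 7 discrete generations: all `N = 500`
candidates are phenotyped and genotyped; breeding values are predicted
from all phenotypes and genotypes accumulated so far (the current
generation included); the top 25 males and 25 females (10% per sex) by
posterior-mean additive value are selected (bottom for downward
selection; ties broken by id); sires and dams are paired one-to-one by
a random permutation, and every pair produces 20 offspring with an
exactly equal sex ratio.  Monogamous pairing is a design choice — it
reproduces the scheme's family arithmetic (25 × 20 = 500) exactly —
where a looser "random mating among the selected" reading would also
have been defensible.

## Evaluation models

Four GBLUP variants are available: additive with all sites (A-SEQ) or
causal sites only (A-QTN), and "full" models (E-SEQ, E-QTN) adding a
dominance random effect and an additive-by-additive epistatic effect
with the Hadamard kernel `G * G`.  Kernels use the classical codings:
`G = MM'/Σ2pq` with centered dosages, and `D = M_d M_d'/Σ4p²q²` with
dominance codes `−2q², 2pq, −2p²` for dosages 2, 1, 0 — the
orientation that is orthogonal to the additive codes under
Hardy-Weinberg proportions (the package's orthogonality test pins this
down, since printed versions of these codes are ambiguous about which
allele the dosage counts).  Frequencies are recomputed from all
individuals entering the kernel at each evaluation cycle (a flag allows
freezing them); sites monomorphic in that reference are excluded with a
message.  Additive-by-dominance and dominance-by-dominance kernels are
intentionally not built.

Fitting is Bayesian: each kernel-structured effect is reparameterised
through the eigendecomposition of its kernel, giving diagonal full
conditionals; variance components get scaled-inverse-chi-square priors
with df = 5 and scales set by the standard R²-matching rule
(`S = Var(y) · R2_share · (df + 2) / mean(diag K)`, prior R² = 0.5
split equally among the genetic terms); the intercept has a flat prior.
Defaults are 10,000 iterations with 2,000 burn-in and posterior means
without thinning.  For additive-only models the eigenfactor is obtained
directly from the thin SVD of the centered dosage matrix, which avoids
ever forming the n × n kernel and makes one Gibbs update O(m); for the
full models the three kernels are eigendecomposed (symmetrised, 1e−8
ridge, eigenvalues below 1e−10 of the maximum truncated).

The selection criterion under E variants is the additive posterior mean
only: parents are chosen on predicted breeding values, and the
dominance and epistatic posterior means are predictions of
non-transmissible deviations.  The sampler was validated against the
closed-form multi-kernel BLUP solution at fixed variance components.

Two caveats discovered while validating the sampler are worth
recording.  First, with *unrelated* genotypes (independent sites, no
pedigree) `D` and `G∘G` are nearly diagonal and therefore confounded
with the residual — estimates of their variances are then essentially
prior-driven.  On family-structured data the kernels are identified,
and on purely additive data the non-additive variances shrink well
below their prior modes, but with default priors their posterior means
do not reach zero at a few thousand records.  Second, the
small-eigenvalue directions of a kernel mix slowly; the package logs
effective sample sizes per variance component rather than enforcing a
floor.

## Metrics

* **Breeding values** are estimated by progeny test: an individual is
  mated to `n_offspring = 1000` randomly chosen opposite-sex
  individuals of its generation (one offspring each, genotypes dropped
  at causal sites only), and its breeding value is twice the deviation
  of the offspring phenotypic mean from the population mean.  The
  population mean is taken over a fresh phenotype realisation of the
  generation so that the focal individual's own environmental deviate
  does not enter the reference.  **Additive variance** is the variance
  of these breeding values; because each one costs 1000 simulated
  offspring, per-generation tracking uses a configurable subsample.
* **Response** is the phenotypic mean per generation expressed in
  phenotypic SD units of the base population, per replicate, then
  summarised across replicates by mean, median and quartiles.  The
  "mode across replicates" summary sometimes seen in figures is not
  reproduced: a mode of a handful of continuous values is ill-defined.
* **Accuracy** is the Pearson correlation between predicted and
  progeny-test breeding values of the candidates, under every
  architecture (under additivity the genotypic-deviation correlation is
  available as a cheap check).
* **LD decay** uses genotype-based r² between causal pairs within a
  chromosome and fits the Hill–Weir sampling expectation of r² by
  nonlinear least squares with `C = c_scale × distance`, assuming
  recombination proportional to physical distance within a chromosome;
  the sample size in the expectation is the number of individuals.  A
  fit whose scale implies the data sit at the sampling asymptote is
  flagged rather than trusted.
* **Inbreeding** is excess homozygosity,
  `F_h = (O − E)/(k − E)` with `E = Σ(1 − 2pq)` at base-population
  frequencies, computed on autosomes (see above).
* **Substitution effects** under epistasis are obtained by exact
  enumeration: the expected pair value for each genotype at a locus is
  averaged over the partner's Hardy-Weinberg genotype probabilities at
  current frequencies, and alpha is the frequency-weighted regression
  slope on dosage (equal to `z q_B (1 − q_C²)` in closed form).
  Contribution spectra `2pq alpha²` are recomputed at whichever
  generation's frequencies are requested, since the reference
  generation for alpha is itself frequency-dependent.

## Problem sizes and numerical choices

The full published design (millions of sites, 10 replicates, 16
experimental cells) is far beyond a single-machine test suite.  The
package's test and acceptance configurations use 1,500 sites (400 of
them causal), N = 500, 7 generations, 3 runs per cell and
2,000-iteration chains with 500 burn-in; the founder generator keeps
205 lines.  Response to selection is driven by the causal sites and by
the phenotypes available on candidates, so the site count mainly thins
the non-causal marker background of A-SEQ.  E-SEQ evaluation is
supported but roughly an order of magnitude more expensive per
replicate (three dense kernels and their eigendecompositions per
generation), so the scaled experiment cells are evaluated with A-SEQ.

Seeds: every stochastic entry point takes a `seed` argument;
`run_experiment()` expands its root seed into named child seeds per
replicate so module-level reruns are stable.  Reported determinism is
bit-exact: rerunning a configuration reproduces haplotypes, chains and
metrics identically.

## Known limitations

* Synthetic founders have no real haplotype structure; short-range
  LD-dependent quantities are qualitative.
* The identity-disequilibrium inflation of non-additive variance
  described above makes realized narrow-sense heritabilities lower than
  linkage-equilibrium calculations suggest.
* Downward selection retains more movable variance than a real,
  selection-shaped site frequency spectrum would allow, because the
  symmetric Beta spectrum keeps more small-effect loci at intermediate
  frequencies; downward responses are correspondingly on the high side.
* Crossover interference, mutation, sex-specific effect sizes,
  higher-order epistasis and overlapping generations are out of scope.
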
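---
title: "Inferring post-marital residence from IBD segments and uniparental markers"
author: "matrikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring post-marital residence from IBD segments and uniparental markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrikin)
```

## The problem

Post-marital residence rules leave a genomic footprint in cemetery
populations. Under matrilocality, women remain in their natal community while
men marry in: the community's mitochondrial gene pool collapses onto one or a
few maternal lineages (a *dominant matriline*), Y-chromosome diversity stays
high, the buried men are disproportionately unrelated in-migrants, and
female-female pairs carry more autosomal and X-linked kinship than male-male
pairs. Patrilocality mirrors the pattern; bilocal ("mixed") residence blurs
it. `matrikin` implements the statistics and simulators needed to read that
footprint out of two inputs that ancient-DNA pipelines routinely produce: a
refinedIBD-style table of identity-by-descent (IBD) segments and a
per-individual metadata table (site, sex, mtDNA and Y haplotype labels).

Because real ancient genomes cannot be redistributed, the package carries a
first-class synthetic-data module: pedigree communities simulated under a
chosen residence rule, gene-dropped genomes, and IBD tables with the
statistical structure the analyses assume. All downstream code is exercised
against these synthetic panels.

## Kinship from IBD segments

`mergeAndClassify()` reduces a segment table to one row per pair. Segments are
merged within each haplotype-pair channel, bridging gaps up to `gapCm`
(default 1 cM; detection pipelines fragment long segments, and the merge
threshold is deliberately configurable because published pipelines vary it by
application). The union of channels on each of the first sample's haplotypes
gives the IBD1/IBD2 decomposition: IBD2 is the overlap of the two
per-haplotype unions, IBD1 the remainder. With genome fractions $f_1$ and
$f_2$ over a 3,545 cM autosomal map, the kinship coefficient is

$$\varphi = \tfrac{1}{4} f_1 + \tfrac{1}{2} f_2 ,$$

and relationship degrees use power-of-two bins: degree $d$ covers
$\varphi \in (2^{-(d+3/2)},\, 2^{-(d+1/2)}]$, with "unrelated" below the
degree-7 lower edge ($2^{-8.5} \approx 0.0028$). Parent-offspring and full
siblings share degree 1 and are separated by the IBD2 fraction
($f_2 < 0.02$ and $f_1 > 0.9 \Rightarrow$ parent-offspring). Kinship above
the degree-1 upper edge — duplicates or identical twins — is reported as
degree 0 ("identical"), a deliberate extension of the 1–7 scale.
X-chromosome segments are accepted in the input but excluded from autosomal
kinship; their summed length is reported separately because X sharing is
auxiliary evidence (it separates, e.g., maternal from paternal relatives).

Interval arithmetic runs in physical coordinates and converts merged lengths
back to cM through the genome model's bp-per-cM scale. For tables the package
itself emits this is exact (the synthetic map is uniform at 1 cM/Mb); for
external tables with a non-uniform map the conversion is an approximation,
and a custom `GenomeModel` should supply the appropriate scale.

Per-individual *weighted relatedness* is the sum over relatives of degree
seven or closer of $1/d$ — a scalar that is high for members of an extended
kin group and zero for unconnected in-migrants. Sex differences in this score
are tested with a two-sided Welch t-test, and the sex composition of the
dominant matriline with a two-sided Fisher exact test; both delegate to the
standard R implementations and are validated in the test suite against
closed-form and enumeration oracles.

## Uniparental diversity and the screen

Haplotype diversity is the probability that two haplotypes sampled *without
replacement* differ:

$$h = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

identically the fraction of discordant unordered pairs (the biased,
with-replacement variant is available by flag). Sites are first pruned of
first-degree pairs — greedily removing the individual with the most remaining
first-degree links, ties broken by ascending id, which retains all children
of a parent-children star — so that sibships do not masquerade as low
diversity. The normalized relative-pair count `r_norm` (relatives of degree
≤ 7 among retained pairs, scaled to [0, 1]) is computed on the same pruned
set so the two statistics share a denominator. The screen correlates `h`
against `r_norm` across sites (two-sided Pearson), per period-by-region
group; groups with fewer than three sites or degenerate variance are reported
as skipped rather than raised. A per-site summary CSV (site, period, region,
h, n, r_norm) can be supplied directly, which is the route for published
per-site tables.

## The minimum-births estimator

A dominant matriline observed with $k$ de novo mutations among its members
implies a minimum number of female births. With mutation rate $\mu$ per site
per generation and molecule length $L$ (defaults: whole mtDNA, $L = 16{,}569$
and $\mu = 4.72\times10^{-7}$), the count of de novo mutations over $N$
births is modelled as $X \sim \mathrm{Poisson}(N \mu L)$ and the estimator
returns the smallest $N$ with $P(X \ge k) \ge c$. The default confidence is
$c = 0.5$ (a median-consistent bound): the published quantity is a stated
lower bound whose exact conditioning is not reproducible from the main text,
and the median keeps the estimate assumption-light while preserving the
monotonicity properties (non-decreasing in $k$ and $c$, non-increasing in
$\mu$ and $L$) that the tests verify. At the defaults, $k = 4$ gives
$N = 470$. A Monte-Carlo backend re-estimates the Poisson tail by simulation
as a cross-check.

## The two simulators

**Deme migration.** An island model with 10 demes of 25 females and 25 males
(defaults), non-overlapping generations, sex-specific migration probabilities
$m_f, m_m$ applied before pairing (marriage-time dispersal), random
monogamous within-deme pairing, and offspring replacing parents at fixed deme
sizes. Founders carry all-distinct haplotypes and no mutation is applied, so
within-deme diversity decays by drift and is replenished only by migration —
the regime of interest, since the question is which *combination* of male and
female rates reproduces observed mtDNA and Y diversity. Defaults (50
generations, 100 replicates) were chosen for stable envelopes at desk-scale
runtime; all are configurable. A replicate in which a deme loses one sex is
flagged and resampled. Rejection inference accepts a grid cell when the
observed $(h_{mt}, h_Y)$ pair falls inside the cell's central simulated
envelopes (default 95% coverage, default grid step 0.05); the marginal
accepted intervals summarise the region, an empty region is reported rather
than raised, and an additive `tolerance` can widen the envelopes (infinite
tolerance accepts everything).

**Pedigree residence regimes.** Seven-generation communities (a founding
couple plus six descendant generations) built by `generatePedigree()`:
Poisson(2.5) offspring per monogamous couple, in-marrying spouses unrelated
with fresh haplotypes, daughters (under matrilocality) staying and founding
resident families while sons disperse — remaining in the burial community
with probability `stayProb = 0.5` but founding no local family — and the sex
roles swapped under patrilocality; under mixed residence each child stays
with probability 0.5. These parameter choices emulate an outbreeding
community and produce no consanguineous unions, so offspring ROH is absent
by construction. Because a branching community can grow far beyond what an
excavation recovers, the multi-site fixture generator down-samples each
site's burials to `maxSiteSample = 40` individuals (seeded), the scale of
the larger excavated Iron Age cemetery samples; statistics on fixture panels
therefore have the sample sizes of real per-site panels rather than of the
full latent community. Lineage extinction before the requested depth is signalled as
a retriable condition, never returned as silent empty output.

For each replicate community the package computes expected kinship for all
resident pairs by recursive path counting — with the X-specific rules that
males are hemizygous, transmit their single X intact to daughters and no X to
sons (mother-son X kinship 1/2, father-son 0) — and realized kinship by
gene-dropping founder genomes down the pedigree (Poisson crossovers at 1 per
100 cM, uniform positions, no interference; interference is irrelevant at the
segment-count resolution used here). The regime classifier summarises a pair
table into six features (mean kinship in FF/MM/FM pairs, fraction of
unrelated pairs involving each sex, X-to-autosome kinship ratio) and scores
each regime by a Gaussian log-likelihood of the observed feature vector
under that regime's simulated feature distribution. The per-regime
covariance is shrunk halfway towards its diagonal (with a 5%-of-pooled-sd
variance floor) so that small reference ensembles stay well-conditioned;
scores are the normalized likelihoods and sum to one.

## Consensus clustering of the site graph

The inter-site graph weights each pair of sites by the average pairwise IBD
in cM between their individuals (total cross-pair IBD divided by the number
of cross pairs; pairs below 12 cM, configurable, are excluded from the
numerator as likely background sharing). Community detection delegates to
igraph's Leiden implementation, run `nRuns = 100` times with distinct seeds;
the bespoke stages are the consensus machinery: a co-assignment matrix
(fraction of runs placing two sites together), a consensus partition from the
components of the co-assignment graph thresholded at 0.5 (threshold 1.0
recovers the strict agreement partition), and a maximum clade-credibility
tree over the per-run hierarchical partitions. Each run's partition is
refined one level (clusters of four or more sites re-clustered on their
induced subgraph) and viewed as a two-level tree; clades are scored by their
log-frequency across runs, the best-scoring run tree is selected with
deterministic lexicographic tie-breaking, and its clades are annotated with
supports. When no resolution is given, a stability scan picks the midpoint of
the longest plateau of the community-count-versus-resolution curve.

## Numerical and design notes

- **Determinism.** Every stochastic entry point takes a seed and uses R's
  RNG (including the C++ gene-drop and deme simulators), so a single integer
  reproduces any run bit-identically. Retries after lineage extinction
  increment the seed deterministically.
- **Coordinates.** IBD records are half-open; emitted bp coordinates are
  synthetic (1 cM/Mb). The LOD column of emitted tables is a monotone
  stand-in (the segment's cM length) since simulated segments have no
  genotype likelihoods.
- **Degenerate inputs.** Diversity of fewer than two haplotypes, empty
  observed pair tables, references missing a regime, and non-positive
  segment lengths are classed errors; empty acceptance regions and skipped
  test strata are reported results, not errors.
- **Problem sizes.** The shipped tests and the acceptance script run the
  simulators at the scale used throughout this vignette: an 11-point-per-axis
  migration grid at 100 replicates per cell, 30-40 reference replicates per
  residence regime, 10,000-replicate gene-drop checks for canonical
  relationships, and 20 planted-partition graphs. These sizes give
  Monte-Carlo errors comfortably inside the assertion tolerances on a single
  CPU.

## What the synthetic data do and do not show

The generator reproduces the features the analyses rely on: dominant
matrilines with de novo subclades, sex-asymmetric migrant influx, realistic
IBD sharing down to distant relatives, ROH from consanguineous unions when
such unions are constructed explicitly, and uniparental labels consistent
with the pedigree. It does not emulate overlapping generations, population
growth, genotyping error, imputation artefacts, phase switch errors, or
haplogroup nomenclature — so green tests demonstrate correctness of the
statistics and inference machinery under the stated models, not robustness
to every artefact of empirical ancient-DNA data. The IBD *detection* step
itself (phasing + refinedIBD) is out of scope: the package consumes and
emits that format but never calls variants or segments.

## Session info

```{r}
sessionInfo()
```
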
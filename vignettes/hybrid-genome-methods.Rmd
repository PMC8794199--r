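---
title: "Models and methods for local-ancestry dynamics in hybrid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for local-ancestry dynamics in hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

# The scientific problem

When two species hybridize, the resulting populations carry mosaics of
ancestry from both parents. Over the following generations selection prunes
this mosaic: ancestry from the *minor* parent (the species that contributed
less) is preferentially lost near incompatible loci and in regions of low
recombination where deleterious alleles stay linked to their neighbours.
`hybridscan` provides the computational machinery to study this process:

* a forward-in-time Wright–Fisher simulator of ancestry tracts under
  configurable selection models,
* post-processing of HMM-style local ancestry calls,
* windowed summaries and (partial) rank correlations of ancestry against
  genomic architecture,
* detection of minor-parent ancestry *deserts* and *islands*, their
  cross-population sharing, and permutation nulls for the amount of sharing,
* rejection ABC for the demographic history of a hybrid population, and
* scans of F2 intercross panels for segregation distortion and two-locus
  (Dobzhansky–Muller) incompatibilities.

The defaults throughout describe a pair of recently formed fish hybrid
zones: admixture ~120 generations ago, founding minor-parent fraction
~0.15 in one population type and ~0.5 in the other, roughly one
ancestry-informative marker (AIM) per 395 bp, and an F2 mapping panel of
943 individuals with 50/50 expected ancestry.

# The simulator

## Model

Each haplotype is a run-length-encoded sequence of ancestry tracts in
genetic-map (cM) coordinates. Founders are pure minor-parent individuals
with probability `m0`, otherwise pure major. Each generation:

1. **Migration.** A `Binomial(N, mig)` subset of individuals is replaced by
   pure parentals (each side separately), before fitness evaluation.
2. **Selection.** Each individual's fitness is evaluated at the configured
   loci (below); parents of the next generation are sampled with
   probability proportional to fitness. This soft, fecundity-style
   implementation keeps N constant while matching the "probability of
   survival" interpretation of the selection coefficients.
3. **Recombination.** Each gamete receives `Poisson(L/100)` crossovers per
   chromosome, placed uniformly in cM — a map-based model with no
   interference, the standard choice for forward simulation of admixture.

Tract storage in cM makes crossover placement uniform and keeps each
meiosis O(number of tracts). The engine is written in C++ (Rcpp) because
the ABC module consumes tens of thousands of forward simulations.

## Selection modes

* `dmi_pairs` — epistatic incompatibilities. For a pair (L1, L2) with
  selection coefficient *s* and dominance *h*, fitness is multiplied by
  `1 − s·f(a)·f(b)`, where *a* is the minor-parent dosage at L1, *b* the
  major-parent dosage at L2, and `f(0)=0, f(1)=h, f(2)=1`. The published
  description of this model does not print its fitness matrix; this
  interpolation was chosen because it reduces to the `1−s` / `1−hs`
  viability form at a single locus and treats the two loci symmetrically.
* `hybridization_load` and `single_parent` — per-site selection against the
  dosage of one parent, `1 − s·f(d)` per site, multiplicative across sites.
  Dominance defaults to `h = 0.5` (additive), another unprinted choice.

## F2 panels

An F2 individual is the sum of two independent F1 gametes (the F1 is
heterozygous everywhere). Viability selection applies survival `1−s` to a
disfavored homozygote and `1−hs` to heterozygotes at configured distorter
loci, and `1−s` to configured two-locus genotype combinations; rejected
individuals are redrawn. A configuration in which no genotype survives is
reported as an error rather than looping forever.

## HMM-like posteriors

`emit_posteriors()` emulates the output of a local-ancestry HMM: the true
state receives posterior mass `U(0.9, 1)` with probability `1 − error`, and
with probability `error` a wrong state receives the top mass, confidently
(`U(0.9,1)`) half the time and ambiguously (`U(0.5,0.9)`) otherwise. This
reproduces the downstream-relevant statistics of real HMM output — the
fraction of wrong hard calls and the existence of sub-threshold sites —
without modelling read data. What it does *not* emulate: spatial
autocorrelation of errors, coverage-driven missingness, or reference bias.
A green test on these posteriors therefore validates the *filters*, not any
claim about a particular HMM's accuracy.

# Ancestry-call processing

Hard calls require posterior ≥ 0.9 (inclusive); sites called in fewer than
25% of individuals are masked (a site at exactly 25% is retained). Markers
failing an exact Hardy–Weinberg test at a Bonferroni-corrected family level
of 0.1 are removed before transition scanning, since genotyping error
manifests as heterozygote excess/deficit. The HWE test enumerates all
heterozygote counts compatible with the observed allele counts (the exact
conditional test); exactness matters for the extreme-tail markers this
filter targets.

Ancestry transitions are emitted per individual as the interval between the
last confident site of one state and the first confident site of the next;
unconfident sites are skipped, never treated as boundaries.

Tract masking operates on maximal runs of constant diploid dosage; run
boundaries are placed midway between the flanking confident sites, so runs
partition each chromosome. Runs of dosage 1 or 2 count as minor-parent
tracts (threshold 0.004 cM), runs of dosage 0 as major-parent tracts
(0.035 cM). Whether the original analysis masked haploid-resolved or
diploid runs is not stated; the diploid-run convention is isolated in
`dosage_runs()`.

# Windowed statistics

Windows tile each chromosome from position 0, in bp or in cM; cM windows
are materialized as bp intervals by exact inverse interpolation of the
piecewise-linear map. All coordinates are 0-based half-open, BED-native; a
marker exactly on a boundary belongs to the right-hand window.

`spearman()` uses average ranks and the large-sample t approximation (an
exact permutation p is available for small n). `spearman_partial()` ranks
all variables, projects the x- and y-ranks off the covariate ranks by least
squares, and correlates the residuals — the convention of the `ppcor`
package, equivalent to the recursive partial-correlation formula for one
covariate. Degenerate projections (a covariate identical to y) return `NA`
with a warning rather than a spurious 0; collinear covariates are an error.

# Deserts and islands

Detection follows a two-step outlier scan on per-site mean minor ancestry:

1. focal sites in the lower 2.5% genome-wide tail (for deserts; the upper
   tail for islands, implemented by reflecting ancestry, which makes the
   two detections exact mirror images);
2. expansion 5' and 3' through consecutive sites still beyond the 5%
   threshold. The region boundary is the outermost such site — the first
   site *exceeding* the edge threshold is excluded. The published wording
   is ambiguous on this point; the convention is isolated in
   `find_outlier_regions()` and covered by oracle tests.
3. verification that the 0.05 cM window containing the region midpoint
   falls in the 10% window-ancestry tail, holds ≥ 10 AIMs, and that the
   region is > 10 kb; merging of regions closer than 50 kb; dropping of
   short merged regions; and, for islands, removal of regions whose
   midpoint-window ancestry differs by more than 0.10 (absolute) between
   thinned and unthinned marker sets.

Ties: sites equal to the genome-wide maximum are never "in the lower
tail", so constant landscapes produce no regions; below the maximum the
thresholds are inclusive, which matters in drifted populations where many
sites sit at exactly 0.

**Sharing.** A region is shared with another population iff that
population's 0.05 cM window containing the region midpoint falls beyond its
own 10% tail (strict inequality, so a constant landscape shares nothing).

**Permutation nulls.** The test statistic is the number of windows in the
other population's 10% tail overlapping any focal region. Two nulls are
provided:

* *value shuffle* (`permutation_null_shuffle`): permute window ancestries
  uniformly; 1000 replicates. This destroys the strong autocorrelation of
  window ancestry (tracts span many 0.05 cM windows), so observed counts
  are overdispersed relative to this null and its p-values are **not**
  calibrated — the same artifact that motivates the second scheme.
* *block rotation* (`permutation_null_blocks`): circularly rotate the
  window-ancestry vector by ~130 offsets tiling the genome. Rotations
  preserve autocorrelation exactly and are exchangeable with the observed
  configuration under the null of unrelated populations, so this p-value
  is calibrated for any statistic. It is the package's primary permutation
  p; because it is discrete (~130 offsets), exact-uniformity checks use
  the U-smoothed (randomized) version computed from the returned null
  distribution.

A per-region matched-window null (`matched_window_null`) additionally
conditions on region length (in windows) and coding-bp content.

# ABC demography

Summary statistics: median minor-parent tract length (cM), mean hybrid
index, and the mean across chromosomes of the coefficient of variation of
chromosome-wide ancestry across individuals (alternative: CV of ancestry
in 250 kb windows along the genome). Tract length carries most of the
information about admixture time; the CV reflects drift and therefore
population size.

Rejection sampling draws parameters from uniform/log-uniform priors,
simulates, and accepts the top *k* = 500 draws (or an epsilon ball) by
Euclidean distance on MAD-standardized statistics; the MAD is used because
the statistics live on very different scales and the simulated spread is
heavy-tailed. MAP estimates are KDE modes (Silverman bandwidth, 512-point
grid, log scale for log-uniform parameters); intervals are 2.5–97.5%
quantiles of the accepted draws.

Inside `run_rejection` the statistics of simulated populations are computed
from the true tracts (engine-side, for speed); `compute_summary_stats()`
computes the same statistics from a dosage matrix. Pseudo-observed
validation uses engine statistics on both sides, so observed and simulated
statistics are always computed identically within a run. Coverage studies
evaluate many pseudo-observed datasets against a shared simulated reference
table, the standard ABC cross-validation design.

# F2 scans

The segregation-distortion scan thins markers to one per 50 kb and applies
a two-sided exact binomial test of the minor-allele count against 0.5
(alleles = 2 × non-missing individuals); markers below p = 5×10⁻⁴ are
flagged and contiguous runs reported. The rejection simulation for the
implied selection strength draws s, h ~ U(0,1), renormalizes
(0.25(1−s), 0.5(1−hs), 0.25), samples 943 individuals, and accepts
replicates whose mean ancestry is itself called distorted at the same
binomial threshold — a proxy for "the 5% tail of the real data", which is
not reproducible without the original panel. Accepted dominance
coefficients mirror their prior; accepted selection coefficients show that
detectable distorters require s ≳ 0.25.

The two-locus scan tests every marker's 3×3 genotype table against the
independence expectation built from the pair's observed marginals
(complete cases per pair), χ² with 4 df; cells with zero expectation are
excluded. Markers within 5 cM of the focal marker (configurable; `Inf`
excludes the whole focal chromosome) are reported but excluded from
genome-wide minimum-p bookkeeping, because linkage to a distorted focal
locus inflates the statistic without epistasis — under strong selection
even markers tens of cM away are affected, so power analyses here exclude
the focal chromosome. The genome-wide threshold simulates the focal
genotype per individual as `Binomial(2, hybrid index)` — preserving
genome-wide ancestry structure while breaking two-locus associations —
and takes the 5% quantile of minimum p over 500 replicate scans.

# What the synthetic world does and does not establish

The generator reproduces the statistical structure the analyses consume:
admixture proportions (~0.15 and ~0.5), ~120 generations of recombination,
heterogeneous recombination maps, AIM densities down to 1/395 bp,
HMM-like posterior noise, and 943-individual F2 panels. It does not
reproduce: sequence-level processes (AIM discovery, reference bias),
crossover interference, sex chromosomes or mitochondria, spatially
correlated HMM errors, or assortative mating. Desk-scale genomes (2–12
chromosomes of 20–30 cM) are used in tests, chosen so that per-window
marker counts and the ratio of selected loci to genome length remain
comparable to the real system; chromosome count is roughly half the real
karyotype to fit compute budgets. Green tests establish that the
implementations are correct and calibrated in this world — not that any
particular empirical coefficient from real data will be reproduced.

# Numerical and design choices worth knowing

* All randomness flows through R's RNG (including inside the C++ engine),
  so `set.seed()`/`seed =` arguments make every pipeline reproducible.
* Empirical quantiles are type 7 (linear interpolation) everywhere.
* Exact binomial two-sided p sums outcome probabilities ≤ the observed
  outcome's probability, with the same relative slack as `binom.test`.
* Interval arithmetic (merging, window overlap) is implemented directly on
  0-based half-open coordinates and tested against per-basepair brute
  force; BED files are read natively without coordinate conversion.
* Zero-recombination plateaus in maps are allowed; inverse interpolation
  returns the leftmost bp of a plateau.
* In YAML configurations, bare `N:` and `T:` are YAML-1.1 booleans; the
  loader maps the parsed `TRUE`/`FALSE` keys back to `T`/`N`, and quoting
  (`"N":`) also works.
* `time since admixture` is visible to the simulator's observables mainly
  through tract lengths and the *local*-ancestry variance; the variance of
  individual hybrid indices *decreases* with time (founders are pure;
  recombination mixes), and the genome-wide admixture fraction drifts only
  at rate ≈ individual variance / N per generation. Property tests assert
  the growing local-ancestry variance.

# Known limitations

* The value-shuffle permutation p is reported but intentionally
  uncalibrated under spatial autocorrelation; use the block-rotation p for
  inference.
* The DMI fitness interpolation and the load/single-parent dominance are
  parameter-compatible with, but not guaranteed identical to, the original
  study's unpublished fitness matrices.
* ABC posteriors here are validated for coverage on synthetic truths; no
  claim is made about matching the original study's real-data posteriors.
* The F2 two-locus scan has low power below s ≈ 0.25, as in the original
  analysis; reported interactions at moderate s should be treated as
  hypotheses.
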
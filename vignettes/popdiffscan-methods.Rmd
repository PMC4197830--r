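---
title: "Population differentiation scans and sweep classification: methods"
author: "popdiffscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population differentiation scans and sweep classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Geographically localized positive selection drives the frequency of a
beneficial allele up in one population while leaving it unchanged elsewhere,
producing variants with exceptionally *high* population differentiation.
Conversely, balancing selection could in principle hold allele frequencies
unusually *uniform* across populations. `popdiffscan` implements an outlier
framework around these two signatures for phased, ancestral-polarized
population sequencing panels (three continental groups, with populations
nested inside them), together with the simulation machinery needed to
calibrate it and to ask whether candidate sites look like *hard* (classic,
single-origin) or *soft* (standing-variation) sweeps.

# Statistics

**DAF and delta-DAF.** With alleles polarized to the inferred ancestral
state, the derived allele frequency (DAF) of group $g$ at a site is the
fraction of observed haplotypes carrying the derived allele (missing
genotypes shrink the denominator). The differentiation statistic is the
pairwise difference $\Delta\mathrm{DAF} = \mathrm{DAF}_A - \mathrm{DAF}_B$;
its magnitude is ranked genome-wide and the empirical rank P-value is
$P_i = \mathrm{rank}_i/N$. The sign is kept as a *direction*: the group with
the higher DAF is the one in which the derived allele would have been
selected. Ranking by magnitude with a retained direction makes the two
orientations of a pair equivalent; ties are broken by genomic position so
that results are reproducible.

**cvDAF.** For low differentiation, the coefficient of variation of the
population DAFs, $\mathrm{sd}/\mathrm{mean}$ with the sample ($n-1$)
standard deviation. Rare alleles are trivially undifferentiated and alleles
at frequency 0.5 in every population are enriched for miscalled paralogs, so
the LowD scan is restricted to pooled DAF in $[0.40, 0.60]$ *excluding* the
open interval $(0.45, 0.55)$ — boundary semantics preserved exactly.

**Weir–Cockerham $F_\mathrm{ST}$.** The per-site two-population
variance-components estimator $\hat\theta = a/(a+b+c)$, with observed
heterozygosity taken from the diploid genotypes (a counts-only variant with
Hardy–Weinberg heterozygosity backs the count-table interface). Slightly
negative estimates are retained; sites monomorphic in both groups are
undefined.

**EHH, iHS, XP-EHH.** Extended haplotype homozygosity at distance $x$ from a
focal site is the probability that two random core-allele carriers are
identical over all intervening sites,
$\mathrm{EHH}(x) = \sum_h \binom{n_h}{2} / \binom{n}{2}$. iHH integrates the
curve over genetic distance (trapezoids, truncated after the first point
below 0.05, summed over both sides; integrals that hit the window edge while
still above the cutoff are flagged as truncated rather than dropped, with a
strict mode available in the consuming code by filtering the flag). Raw
$\mathrm{iHS} = \ln(\mathrm{iHH}_\mathrm{ancestral}/\mathrm{iHH}_\mathrm{derived})$,
raw $\mathrm{XP\text{-}EHH} = \ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$ with
all-haplotype EHH per population. Scores are standardized within
derived-allele-frequency classes of width 0.05, with classes below 20 scores
merged into their nearest neighbour — the conventions of the statistics'
original descriptions, since the source analysis defers to "standard
procedures". Haplotype statistics are conventionally computed on 30
individuals per group (`subsample_individuals()`), mirroring the design that
makes group sizes comparable.

# The scans

The HighD scan works in four steps: (i) mark the top 1% of sites by
$|\Delta\mathrm{DAF}|$ rank; (ii) partition *all* scanned sites, per
chromosome and in genomic order, into consecutive non-overlapping blocks of
5,000 variants (the last block may be short and is scanned like any other);
(iii) take each block's maximum-magnitude marked site; (iv) retain it if it
strictly exceeds 0.7 (between continents) or 0.25 (within). Windowing over
all variants rather than only the marked ones keeps blocks genomically
local, which is the point of peak-picking: clusters of differentiated sites
usually reflect a single driver plus hitchhikers. An exomic-INDEL style
`mode = "threshold"` applies the threshold without windowing, for variant
sets too small to window. The LowD scan filters on the pooled-DAF band, then
keeps each 100-variant window's minimum-cvDAF site when it is below 0.01.
Imputation quality filters sites at $\mathrm{impq} > 0.8$ (strict
inequality); sites without a quality annotation are kept and counted, or
dropped in strict mode.

Matched controls are sampled without replacement from a site universe,
matched on DAF in the target's assigned population (±0.02, relaxed stepwise
to ±0.05 before a target is declared unmatched) and on distance to the
nearest gene start binned as 0, (0,1kb], (1,10kb], (10,100kb], >100kb. The
tolerances and bins are package defaults, exposed in the interface.

# Hard versus soft sweeps

For a candidate site, the haplotypes of the derived-allele carriers over a
2-kb window are written as strings with one symbol per site *polymorphic
among the carriers themselves* — a site at which all carriers agree carries
no information about their mutual divergence, and this convention makes the
degenerate single-haplotype case exactly $D = 0$. The homogeneity statistic
is the frequency-weighted mean Levenshtein distance from the major
haplotype,
$$D = \sum_h f_h \, \mathrm{Lev}(\mathrm{major}, h) / S,$$
with $S$ the major haplotype's length, weights over *all* carriers (the
major contributes 0), and major-haplotype ties broken lexicographically.
This reading of "weighted by the relative frequency of the alternative
haplotype" makes $D$ the expected per-site divergence of a random carrier
from the modal haplotype; the renormalized-over-alternatives reading is
implemented behind `weighting = "alternatives"`. True edit distance is used
(not the substitution-only distance), so strings with shifted patterns can
be closer than their mismatch count; the one practical consequence is that
$D$ is invariant to a global allele-symbol swap but not always to a
single-column swap.

A site is *hard-like* when $D \le 0.026$ — the mean in a reference set of
accepted classic sweeps — **and** the local recombination rate (map average
over the window) lies inside the range observed at those reference sites,
0 to 0.025 cM/Mb, both bounds inclusive; a missing rate makes the site
unclassifiable. The conditioning range is a property of the reference set
*given its recombination map*: on simulated data with a uniform map the
corresponding range must be derived from that map (the bundled demo config
uses the generator's uniform rate as its upper bound), otherwise nothing can
ever satisfy a real-map-derived range. The chance-corrected excess is the
hard-like fraction among targets minus that among matched controls, with a
Fisher exact test on the 2×2 counts.

# The generator

`simulate_neutral()`/`simulate_sweep()` run a forward-time Wright–Fisher
simulation of a three-population out-of-Africa demography: an ancestral
population (burn-in of 8 rescaled-ancestral-size generations, enough for
$\ge 98\%$ of equilibrium diversity), African growth, an out-of-Africa
bottleneck population, a European/East-Asian split with exponential growth,
and symmetric pairwise migration. The shipped defaults
(`inst/extdata/ooa_model.yaml`) follow the published three-population
calibration of low-coverage phase-I sequence data (Gravel et al. 2011,
PNAS 108:11983) with mutation rate 2.36×10⁻⁸ and recombination rate
1.25×10⁻⁸ per bp per generation; they approximate, not replicate, any
particular external model file. Under these defaults simulated common-site
mean $F_\mathrm{ST}$ is ≈0.13 (AFR–EUR) and ≈0.10 (EUR–ASN), matching the
panel the model was fit to.

Rescaling by $\lambda$ (default 10) divides sizes and times and multiplies
per-generation rates, preserving $\theta = 4N\mu$, $\rho = 4Nr$ and times in
units of $2N$; a property test checks that the focal-site
$\Delta\mathrm{DAF}$ distribution is invariant across $\lambda$. Mutation is
infinite-sites on the integer bp grid with collisions redrawn;
recombination is uniform; per-generation crossover and mutation totals are
drawn once as Poisson counts and scattered uniformly over gametes, which is
distributionally identical to per-gamete draws. Polarization is exact by
construction. Default problem sizes are desk scale: 100-kb regions (the
reference analysis used 600 kb) and 50 sampled diploids per continental
group standing in for the 911-genome panel; each continental sample is
labelled with three exchangeable sub-population codes so population-level
interfaces can be exercised, which means the generator does not emulate
within-continent structure — within-continent comparisons are null by
construction.

**Sweeps.** A new variant is introduced at the region centre on one random
haplotype, `duration` ∈ [200, 1200] generations before the sweep end, which
is always 401 generations before sampling; additive selection (fitnesses
$1, 1+s, 1+2s$) acts until the end time, then the allele drifts. $s$ is
initialized from the deterministic logistic path with an
establishment-inflated starting frequency and retuned multiplicatively on
the logit path between attempts; attempts restart from a checkpoint taken at
sweep start (so rejections replay only the sweep phase) until the realized
final frequency in the selected population is within ±0.05 of the target
(target 1.0 accepts ≥0.95). If the sweep begins before the selected
population exists, selection acts in its ancestor until the split — the
sibling population then inherits standing frequency, a realistic and
intended consequence. The focal bp is nudged to the nearest unoccupied
position if a standing mutation already occupies it.

# Power benchmark and calibration

Thresholds come only from neutral replicates: the 95th percentile
(linearly interpolated empirical quantile) of the neutral score
distribution defines a 5% false discovery rate, and sensitivity is the
fraction of sweep replicates whose *selected variant* exceeds it, per
final-frequency class and overall, with exact binomial intervals. Two
calibrations are available and the choice matters greatly:

* `threshold_mode = "per_site"` (default) pools the per-site scores of all
  neutral replicates — the analogue of a genome-wide empirical outlier
  threshold. Under the default demography this threshold is ≈0.39 for the
  max-over-pairs $|\Delta\mathrm{DAF}|$, which partial sweeps to final
  frequency 0.2 can never exceed: their detectability is structurally zero
  at 5% FDR, and overall sensitivity across the five classes consequently
  tops out near 75–80% rather than the high-90s sometimes quoted for this
  family of statistics. This is a property of any neutral model faithful to
  observed continental differentiation, not of the implementation.
* `"replicate_max"` uses each neutral replicate's maximum score — a
  per-region family-wise calibration, far more conservative (threshold
  ≈0.88), appropriate when a whole region is declared significant on its
  peak score.

The calibration identity — neutral detection at the 95th-percentile
threshold is 5% up to binomial error — is asserted on held-out neutral
replicates. The benchmark evaluates $\Delta\mathrm{DAF}$ and $F_\mathrm{ST}$
at every site, and the expensive haplotype statistics at a per-replicate
subsample of common sites (neutral) or the focal site (sweeps), on 30
individuals per group; powers are compared on raw (unstandardized) scores,
whose per-statistic empirical thresholds make standardization immaterial up
to frequency composition.

# Neutral expectation of HighD counts

`expected_neutral_highd()` runs the between-continent HighD scan on neutral
replicates and scales the retained count to the accessible genome
(2,526,390,487 bp), with a bootstrap CI over replicates;
`migration_sensitivity()` re-evaluates it over a grid of migration-rate
multipliers at matched seeds. Expected counts fall as migration rises
(migration homogenizes frequencies) and the dependence is steep — one
reason neutral expectations of extreme-tail counts are a fragile way to
estimate the selected fraction.

# Numerical and engineering choices

* Coordinates are 1-based inclusive everywhere; BED input is converted on
  read. Sites sort by (chrom, pos, alt).
* Missing genotypes reduce frequency denominators; groups with no observed
  alleles at a site yield missing DAF and are skipped (and counted) by
  consumers.
* Multiallelic records: skipped by default, split per alternate allele on
  request. Symbolic SVs with no ancestral annotation are assumed derived
  relative to an ancestral reference allele, logged as an assumption.
* The simulator stores haplotypes as 16-bit mutation ids sorted by position
  through an id→position registry; ids are recycled on loss or fixation and
  an adaptive purge keeps the pool from exhausting on long regions. A
  saturation of the infinite-sites grid or of the id pool raises an error
  naming the remedy.
* Empirical quantiles use R's default linear interpolation (type 7).
  Rank ties break by genomic order. Major-haplotype ties break
  lexicographically.
* Replicate seeds derive deterministically from a base seed
  (`replicate_seed`), all below 2³¹; the C++ core uses a seeded xoshiro256++
  generator, so replicates are bit-reproducible across runs and platforms.

# What passing tests do and do not show

The generator produces SNPs only (indel and SV handling is exercised through
hand fixtures), uniform recombination (no hotspots), no within-continent
structure, no archaic admixture and no background selection. Simulation
scale is 100 kb/λ=10/50 diploids per group by default, with the test suite
using 500 neutral and 550 sweep replicates. Quantities that depend on the
real callset, real annotation density, or hotspot-scale recombination —
headline HighD counts, the empirical hard-sweep excess percentages,
concordance medians — are *not* reproduced by the synthetic harness; the
suite instead checks the machinery (oracle agreement, boundary semantics,
calibration identities) and the distributional signatures the method relies
on (sweep detectability, homogeneity ordering of complete versus partial
sweeps, delta-DAF–F_ST concordance). Two figure-level magnitudes from the
source analysis (≈0.065/0.126 mean weighted Levenshtein for complete/partial
sweep classes) are not reached at the focal site under this generator: the
carriers of a *new* variant all coalesce within the allele's age, bounding
their mutual divergence well below those values, and diagnostic runs show
such magnitudes arise only when haplotypes are taken at the scan-retained
(often hitchhiking) site of much longer regions. The class *ordering* and
approximate ratio (partial ≈ 2× complete) are robustly reproduced and are
what the classification relies on.
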
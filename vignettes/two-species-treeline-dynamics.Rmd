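---
title: "Two-species larch stand dynamics, climate splicing and sedaDNA haplotypes: methods"
author: "larch2s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-species larch stand dynamics, climate splicing and sedaDNA haplotypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(larch2s)
```

## What the package models

At the northern treeline of central Siberia, two larch species meet: *Larix
sibirica*, which grows fast, disperses far and demands warmth, and *Larix
gmelinii*, which grows slowly but tolerates cold and crowding. Their boundary
is not a simple climate isoline; the working hypothesis encoded here is that
**competitive exclusion mediated by stand density** governs which species
occupies a site. Dense stands exclude the crowding-sensitive *L. sibirica*;
only when cooling climate thins stands below roughly a hundred trees per
hectare can it re-establish alongside *L. gmelinii*.

`larch2s` provides three connected toolsets:

1. an individual-based, spatially explicit, two-species stand simulator in
   yearly time steps, with a stabilisation (spin-up) phase and a forced
   simulation phase;
2. a climate-forcing builder that splices windows of recent monthly weather
   onto a millennial paleoclimate series, and per-site variants of it;
3. a sedimentary-DNA toolkit: classification of 61-nt mitochondrial *nad4*
   amplicon reads into the two species' diagnostic variants, per-sample
   dominance calls, and the vegetation-table ordination (genus aggregation,
   abundance filter, square-root transform, PCA, PC1 comparison of DNA
   against pollen).

Synthetic-data generators produce every input with known ground truth, so the
full pipeline runs and is tested without any external download.

## The stand simulator

The plot is a rectangle (default 1 ha, 100 m × 100 m) with open boundaries:
seeds dispersing beyond the edge are lost. Each tree carries species,
position, height and age; each seed-bank item carries species, position and
age. Within a year the sub-models run in fixed order — seed introduction
(when the phase introduces species), growth, seed production, seed dispersal,
establishment, mortality/ageing — and the year counter advances.

Weather enters through three indices derived from the monthly forcing:
growing degree days above a 5 °C base (monthly-mean exceedance × days in
month, non-leap convention), June–August mean temperature (reported in the
output series), and the annual precipitation sum.

Every rate that depends on warmth is scaled by the saturating degree-day
response

$$T(g) = \frac{\max(0,\, g - g_{\min})}{\max(0,\, g - g_{\min}) + g_{1/2}},$$

zero at or below the species threshold $g_{\min}$ and approaching one for
warm summers; $g_{1/2}$ is the half-saturation constant.

Crowding acts through a neighbourhood competition index at a point,

$$\mathrm{NCI}(x, y) = \sum_{j:\, d_j \le R,\ d_j > 0} \frac{h_j}{\max(d_j, 0.5\,\mathrm{m})},$$

the height-over-distance sum of all trees within radius $R$ (default 10 m),
with a 0.5-m distance floor to avoid singularities and exclusion of trees at
exactly the query point (so a tree does not compete with itself). The kernel
is the package's single C++ routine; everything else is vectorised R.

The sub-models, one parameter per mechanism:

* **Growth**: height increment $= h_{\max}' \cdot T(g) \cdot
  e^{-c_g \cdot \mathrm{NCI}}$, capped at the species maximum height.
* **Seed production**: each tree taller than its maturity height drops
  $\mathrm{Poisson}(f \cdot (h - h_{mat}) \cdot T(g))$ seeds at its own
  coordinates.
* **Dispersal**: each age-0 seed moves once, by an exponential distance
  (species mean $\mu_d$) in a uniform direction; later seed-bank years do not
  move again.
* **Establishment**: each seed becomes a 0.05-m recruit with probability
  $p_e \cdot T(g) \cdot e^{-c_e \cdot \mathrm{NCI}} \cdot w$, where
  $w = \mathrm{clamp}(P_{yr}/P_{ref},\, 0.5,\, 1)$ couples recruitment to
  annual precipitation ($P_{ref}$ = 250 mm; disableable via
  `use_precip = FALSE`).
* **Mortality/ageing**: each tree dies with probability
  $\min(1,\, m_0 + c_m \cdot \mathrm{NCI})$; trees at the species' maximum
  age die; seeds die at the seed-bank rate and leave the bank after their
  residence limit.

All randomness flows through R's RNG; a scenario derives one sub-seed per
replicate from its root seed, so identical `ScenarioSpec`s reproduce
byte-identical series.

### Species asymmetry and calibration

The species differ only through their parameter files
(`inst/extdata/species_params.yaml`, versioned). The asymmetry follows the
ecology sketched above: *L. sibirica* has the higher growth rate, dispersal
distance and degree-day demand, and is far more sensitive to crowding in
establishment, growth and mortality; *L. gmelinii* is slower but hardier.

The exact numbers are **calibrated, not literature-transcribed**: they were
tuned once so that, under the default synthetic forcing, (i) mean stand
density increases with temperature, (ii) warm stands equilibrate above 300
trees/ha and exclude *L. sibirica* while cold sparse stands below 100
trees/ha admit both species, and (iii) in cold-site temporal runs the median
total density in the year of the first successful *L. sibirica*
establishment sits near 100 trees/ha. Two calibration lessons are worth
recording. First, suppression of *L. sibirica* in dense stands is limited by
canopy *gaps*, not by the mean competition level: with short dispersal the
*L. gmelinii* stand is clumped and leaves empty patches in which recruits
escape competition entirely, so the shipped *L. gmelinii* dispersal mean
(18 m) is deliberately long enough to spread regeneration, and the
*L. sibirica* establishment sensitivity ($c_e = 8$ per NCI unit) makes
recruitment strongly gap-limited. Second, the degree-day thresholds
($g_{\min}$ = 250/260 °C·day) place the *L. gmelinii* viability collapse
between the −2 °C and −1 °C offsets of the default climate, which is what
makes stand density — not raw temperature — the variable that opens the door
for *L. sibirica*.

### Phases, scenarios and the emergence summary

A scenario runs `stab_years` (default 1000) stabilisation steps in which
whole weather years are resampled uniformly with replacement from the first
30 forcing years, then one step per forcing year. Seed rain (default 100
seeds ha⁻¹ yr⁻¹ per introduced species) can differ between phases, which
yields the 3 × 3 introduction matrix (sibirica / gmelinii / both, in each
phase) of `runSpatialMatrix()`. Stand density counts trees at or above a
height cutoff (default 1.3 m, breast height; the figure-mapping alternative
of 5 m is a parameter).

The temporal experiment (`runTemporalExperiment()`) introduces both species
throughout, so die-out events can be followed by re-introduction. Its
**emergence summary** operationalises "first successful *L. sibirica*
establishment after initial *L. gmelinii* dominance" as: the first
*L. sibirica* recruit that survives at least 10 years (detected when a tree
reaches age 10; birth year = confirmation year − 10), born after the first
simulation year in which *L. gmelinii* holds at least 90% of stand density
with at least 10 trees/ha total. The summary reports the total stand density
in that recruit's birth year, per replicate, and the cross-replicate median
is the experiment's headline number.

Replicates whose live-tree count exceeds a cap (default 10⁶) are flagged
`aborted` and stop stepping — runaway populations at warm sites are recorded,
not fatal.

## Climate forcing

`assembleMasterForcing()` implements the splice: the pre-overlap span
(default −3982..1933) is covered by 19-year blocks drawn uniformly with
replacement (seeded) from the recent series' admissible start years
(1934..1995 by default), and the overlap (1934–2013) is appended verbatim.
Each block is adjusted to the corresponding window of the simulated paleo
series using the **pooled all-month window mean** ("total mean"): an additive
offset for temperature and, by default, a single multiplicative factor for
precipitation (preserving non-negativity; an additive mode exists, floored
at `prec_floor`). The pre-overlap span (5916 years) is not divisible by 19,
so the final block is truncated to the remaining 7 years and adjusted against
the same truncated span — the simplest scheme that preserves the 5996-year
total. The chosen window start-years and the recipe are stored in the output
metadata and in the JSON sidecar of `writeClimateTable(..., sidecar = TRUE)`
for exact replay.

Site variants (`siteAdjustSeries()`) shift temperature additively by the
site-minus-master overlap-mean difference and scale precipitation by the
overlap-mean ratio, mirroring the splice adjustment. The three default sites
span the ecotone: a warm southern taiga site (+1.5 °C), a northern ecotone
site (−1.3 °C) and a cold tundra site north of the treeline (−1.6 to
−1.8 °C; shipped value −1.8), with precipitation factors 1.10/0.95/0.90.
These offsets are part of the calibrated study conditions.

## Synthetic generators

* **Recent climate**: monthly climatological normals of a continental
  subarctic station (July mean +13 °C, ~281 mm yr⁻¹) plus a yearly AR(1)
  temperature anomaly (SD 0.6 °C, autocorrelation 0.3), monthly white noise,
  and unit-mean lognormal precipitation noise.
* **Paleo series**: the same machinery plus a smooth cosine trend — an
  anomaly of +2 °C at the series start declining to zero at a minimum 200
  years before the end, then recovering by +0.5 °C (recent warming). With
  noise off, the first-year-minus-minimum summer difference equals the
  amplitude exactly and the coolest year sits exactly at the minimum; with
  noise on, the trend is locally flat near its minimum, so the literal
  coolest single year of a draw wanders — the anchors are properties of the
  trend, and the tests assert them in the noise-free limit.
* **Amplicon reads**: each read copies one of the two 61-nt variant
  sequences (sibirica fraction = `mixture`) and receives i.i.d. per-base
  substitution errors; truth labels are returned alongside. The shipped
  two-record reference FASTA is a synthetic stand-in with the documented
  structure (61 nt, single diagnostic site, here placed mid-amplicon at
  site 31), not a deposited survey sequence.
* **Coupled taxa tables**: per-sample taxon probabilities are a softmax of
  linear responses to one shared latent vegetation-turnover gradient; DNA
  and pollen draw multinomial counts at their own depths (defaults 5000
  reads, 300 grains — the conventional minimum terrestrial pollen sum) after
  independent per-proxy response jitter. This is the simplest structure
  under which comparing PC1 across proxies is meaningful.

What the generators deliberately do **not** emulate: PCR amplification bias,
chimeras and DNA damage; pollen-production and transport biases; real ESM
output or spatial climate fields; age-depth uncertainty. Green tests
therefore demonstrate correctness of the algorithms and internal consistency
of the pipeline, not fidelity to any particular deposited dataset.

## sedaDNA classification and ordination

Reads are dereplicated (identical sequences merged, counts summed), filtered
to the exact amplicon length (61 nt) and a minimum multiplicity (default 2)
— explicit, configurable stand-ins for an upstream metabarcoding cleanup.
A read is assigned to a variant if its Hamming distance to the reference
outside the diagnostic site is at most 3 and its diagnostic base maps to an
allele; `N` at the diagnostic site is never assigned. Dominance per sample:
"none" below 10 assigned reads, a variant at ≥ 90% of assigned reads,
otherwise "mixed". The 0.9/10 defaults are declared package choices
reproducing a three-way dominant/dominant/mixed coding on synthetic
mixtures.

Ordination follows the standard paleo-data recipe: counts summed to genus,
per-sample percentages, retention of genera reaching ≥ 0.5% in ≥ 2 samples,
square-root transform, PCA on the column-centred (not scaled) matrix via
`stats::prcomp` (scaling is exposed as an option; unscaled is the default
because the square-rooted percentages already share one scale). The PC1 sign
is oriented so the *Larix* loading is non-negative — "more larch" points the
same way in every dataset — falling back to the largest-magnitude loading
when *Larix* is absent. `compareProxies()` then reports Pearson and Spearman
correlations of matched PC1 series.

## Numerical choices and degenerate inputs

* Distance floor 0.5 m in the NCI; trees at exactly the query point excluded.
* Precipitation floored at `prec_floor` (≥ 0) after every adjustment; a zero
  master/real precipitation mean with a nonzero target is an error
  (undefined ratio) rather than a silent fallback.
* Climate CSVs are written with 17 significant digits so values survive the
  text round-trip bit-exactly.
* Dereplication output is sorted by count (descending) then sequence, making
  it independent of input order.
* Zero-total samples, non-contiguous years, missing months and sub-0.5
  dominance thresholds raise informative errors.
* All generators and simulations are seed-deterministic; sub-seeds are drawn
  below 2³¹.

## Problem sizes

The shipped desk scale, used by the tests and the acceptance script, is:
0.25-ha plots (50 m × 50 m) with 3 replicates and the forcing truncated to
its final 2000 years for the temporal experiment; 0.16-ha plots, 5
replicates and 300-year constant-climate runs for the ensemble properties;
10⁴ draws for every distributional oracle. The full 5996-year, 1-ha mode is
available behind the `--full` CLI flag and the corresponding function
arguments.

## Known limitations

* Sub-model functional forms are minimal one-parameter mechanisms chosen for
  testability; the parameter values are calibrated to the emergent patterns
  described above, not measured.
* No permafrost, fire, insect, topography or hybridisation processes.
* The emergence definition depends on the dominance-onset rule (90% / 10
  trees/ha); very sparse sites where *L. gmelinii* never reaches 10 trees/ha
  report no emergence.
* Classification assumes primer-trimmed, orientation-normalised reads.
* With three replicates the emergence median is a coarse statistic; its
  spread across seeds is of order ±20 trees/ha at the default scale.
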
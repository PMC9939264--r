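---
title: "Inferring social units across timescales: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social units across timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialunits)
```

## The inference problem

`socialunits` targets societies in which stable social units — sets of
individuals that keep close spatial proximity and concentrate their social
interactions over days to months — are embedded in fission–fusion
dynamics: units temporarily shed subunits and periodically merge into
supergroups. The observable data are (a) a twice-daily field census of
aggregations, in which observers record the identities of marked
individuals, a count of unmarked ones, and whether the aggregation behaved
as one cohesive set (`single`) or as several distinct sets encountered
together (`multiple`); and (b) GPS tracks from a tagged subset of
individuals. Because any individual may go unseen for days or weeks, the
social units recovered from such data depend on the aggregation window and
on how sampling noise is handled. The package implements one pipeline with
those choices exposed as an explicit configuration
(`approach_config()`), so that their consequences can be compared on equal
terms.

## Pipeline and assumptions

**Filtering.** Only `single`, complete records enter the analysis:
`multiple` records do not identify a cohesive set, and incomplete records
add identification noise. Individuals observed two or fewer times in a
focal period are removed (`min_obs = 3`), since assignments from one or
two sightings are unreliable. We apply the sighting filter over the
window's *sampling* interval — the data that actually build that window's
network — rather than the narrower focal interval; the alternative was
genuinely open, and this choice keeps the filter aligned with the
information content of each network.

**Windows.** Calendar months define windows, with half-open
`[start, end)` intervals throughout; a record on a boundary date belongs
to the later window. Sliding 1-month (and non-overlapping 2-month) focal
blocks sample one extra month of context on each side; the static basis
pools the whole study. Only interior months serve as focal months, so
every sliding window has a full month of context on both sides.

**Association.** The simple ratio index divides a dyad's co-observations
by the records containing at least one member of the dyad. The sampling
unit of the denominator is the single census record; dyads never observed
have index 0 rather than missing. Edges below 0.5 are zeroed before
community detection. Because 0.5 sits exactly on a ratio boundary
(a dyad together in exactly half its sightings), `simple_ratio_index()`
carries its integer numerators and denominators along, and
`threshold_network()` decides the boundary on the exact ratio
(`num >= threshold * den`), so floating-point rounding can never flip a
boundary dyad.

**Community detection.** Walktrap (random-walk distance agglomeration
with a maximum-modularity cut) is run via igraph, the implementation in
standard use in this field; the walk length keeps the algorithm's
conventional default of 4 steps. Individuals without a single
above-threshold edge become singleton communities; singletons are
retained and visible in the size distribution rather than silently
dropped. The test suite cross-checks the igraph implementation against an
independent re-implementation of the algorithm (exact recomputation of
the walk distances and Ward-style merge costs) on planted-structure
graphs; on such graphs, where community structure is well defined, the
two implementations agree exactly. On structureless random graphs many
merge costs tie to within floating-point noise and the greedy merge order
becomes implementation-defined — a known limitation of any walktrap
comparison, and the reason our cross-validation uses planted structure.

**Bootstrap meta-network.** To quantify assignment uncertainty at sparse
timescales, the observed records are resampled with replacement 100
times; each replicate rebuilds the network (SRI, 0.5 threshold) and
re-runs walktrap. The meta-network weight of a pair is the fraction of
replicates — among those in which both individuals appeared — where the
pair shared a community; pairs never jointly present score 0. The
denominator choice matters because an individual can vanish from a
resample. The meta-network goes to walktrap *un-thresholded* as a
weighted graph: the 0.5 rule applies to SRI networks, and co-membership
probabilities are already a consensus signal.

**Oversize splitting.** In sparse data, community detection tends to
return whole connected components, which can lump units that were
observed together (e.g. in a supergroup) into one community. Each
detected community is compared against `M`, the largest number of
*identified* individuals in any single cohesive aggregation of the
window. A community larger than `M` was never observed as one aggregation,
so the bootstrap procedure is re-run on the census restricted to its
members, recursively, until nothing exceeds `M`, a re-run fails to split
(fixed point), or a depth limit of 10 is hit (the partition is then
accepted with a warning). Re-runs draw fresh seeds derived from the
window and community label, so the whole path replays identically from
one seed. The restriction works because the modularity cut is then local:
in the global network, splitting the lumped pair may cost more modularity
than it gains, while on the pair's own records the bootstrap happily
separates them. The check applies to the meta-network path only, where
the component-inclusion tendency is strongest.

**Carryover linking.** Communities in consecutive windows are linked by a
mutual-majority rule: a community continues a predecessor's global
identity when their overlap exceeds half of *both* communities' members.
This is strict — an even split of a unit into two halves continues
neither, and both halves get fresh identities with a recorded `split` —
and it makes matches provably one-to-one. Overlap ties break toward the
larger source community, then the lexicographically smaller label. The
published analyses this mirrors used an external dynamic-community
library whose parameters are not documented; the rule here is therefore
fixed and documented in its place, and comparisons on real data should
expect small discrepancies from this step.

**Interpolation.** An individual absent from one window but assigned to
the same global unit in the windows on either side is re-added to that
unit, flagged `interpolated`. Only single-window gaps are filled; longer
absences are treated as genuine (dispersal, mortality, extended absence
from the study area). Interpolation runs before stability scoring, and
interpolated members count as present in the Jaccard sets.

**Stability and cohesion.** Jaccard similarity compares a global unit's
member sets in consecutive windows. Cohesion uses GPS fixes subsampled to
one per 5-minute bin (first fix per bin, timestamps snapped to the bin
start so fixes pair exactly); for each unit and day, distances are
computed for every tracked dyad at every shared bin and averaged into one
daily value, and the window summary is the mean and maximum of the daily
values. The nesting order (dyad-bin values → daily mean → window
mean/max) is fixed and documented because the verbal definition of "mean
daily pairwise distance" does not pin it down. Fixes are paired only
within the same bin — no interpolation between fixes — and coordinates
are consumed as projected planar metres; sex filtering (the tracked males)
is the caller's responsibility via `gps_ids`.

## The synthetic society generator

`simulate_society()` generates the ground truth the pipeline is validated
against. Its defaults describe the study conditions the package is
designed for:

| parameter | default | meaning |
|---|---|---|
| `n_units`, `unit_size_mean` | 8, 20 | population of ~160 in units of ~15–30 |
| `study_start`, `study_end` | 2020-09-01 → 2021-05-01 | an 8-month study |
| `fission_rate` | 0.02 /unit/day | a unit fissions every ~7 weeks |
| `fission_duration_mean` | 7 days | splits last hours–weeks (geometric) |
| `supergroup_windows` | none | supplied explicitly for dry-season scenarios |
| `supergroup_join_prob` | 0.5 | per-unit, per-window participation |
| `marked_fraction` | 0.90 | share of individually identifiable birds |
| `census_detect_prob` | 0.5 | per-cluster, per-session detection |
| `individual_miss_prob` | 0.2 | marked member overlooked in one record |
| `n_gps_males_per_unit` | 3 | tagged philopatric males |
| `gps_interval` | 300 s | one fix per 5 minutes, 06:00–18:00 |
| `within_unit_spread` | 50 m | scatter around the cluster centroid |
| `home_range_scale` | 1000 m | side of the reflected-random-walk square |

Fission moves a uniform 20–50% of a unit's members into a temporary
cluster — subunit membership is deliberately non-repeatable across
events, matching field descriptions of such splits. Supergroup
participation is redrawn per unit per window, and latent unit identity is
never destroyed: supergroups disband back into their original units. No
published rates exist for fission or supergroup formation, so these
defaults were chosen once for realism and testability and are not
calibrated to any field estimate. Two observation-process parameters
(`multiple_encounter_prob`, `incomplete_prob`, both 0.05) exist so that
the generator exercises the filtering rules with `multiple` and
incomplete records at plausible field rates.

Movement is deliberately simple: unit centroids follow reflected random
walks inside square home ranges on a widely spaced grid
(`unit_spacing = 5000` m), fission subunits take a persistent offset from
their parent's path, and members scatter isotropically around the
centroid. This suffices for dyadic-distance statistics. The generator
does *not* emulate demography (births, deaths, dispersal), sex-specific
movement, habitat preference, duty-cycled tags, or positional error —
so passing tests demonstrate correct inference under the stated
observation model, not robustness to every pathology of real field data.

With all observation probabilities at their deterministic extremes the
census is an exact function of the truth, which the tests exploit for
byte-level regression; event counts match their generating distributions'
moments; and all randomness flows from a single seed through derived
per-stage streams, so every run replays exactly.

## Numerical and degenerate-input choices

* SRI thresholding decides the 0.5 boundary on exact integer ratios (see
  above); weights at exactly the threshold are kept, matching the strict
  "less than" replacement rule.
* Zero-denominator dyads and empty resamples score 0, never `NA`.
* Windows too short for a basis, empty retained-individual sets,
  communities with fewer than two tracked members, and dyads with no
  shared time bins each have a defined outcome (error, warned empty
  partition, omitted row, warned omission respectively) rather than an
  implicit one.
* Community labels are canonicalised (`C01`, `C02`, … by first member) so
  that identical inputs yield byte-identical partitions.
* The linker requires at least two windows; the 8-month basis therefore
  reports per-window communities only, and carryover configurations on it
  are rejected at construction.

## Problem sizes used in validation

The test suite and the acceptance script run on synthetic societies of 8
units × ~20 individuals over 6–8 months (≈1,500–2,100 usable census
records, ≈0.8 M GPS fixes), with 100 bootstrap replicates per window —
the scale the package documents as its reference conditions. Smaller
fixtures (2–3 units, days–weeks) back the exact-arithmetic and
property-based checks. At these sizes the full validation completes in a
few minutes on one CPU; the pipeline itself is vectorised (matrix
cross-products for SRI, data.table joins for GPS pairing) and scales
comfortably to populations several times larger.

## Known limitations

* The dynamic-linking rule approximates, but does not reproduce, the
  external library used in the motivating analyses; global unit counts on
  real data can differ slightly at that step.
* Walktrap merge order on graphs without community structure is
  implementation-defined at floating-point ties.
* Interpolation fills only single-window gaps by design; units that skip
  detection for two consecutive windows fragment into separate global
  identities.
* The simulator's observation model is missing-at-random; correlated
  detection failures (weather, observer routes) are not represented.
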
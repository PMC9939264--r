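# socialunits

Multi-timescale inference of social units from field census and GPS data.

## The problem

In fission–fusion, multi-level animal societies — the motivating system is
a wild population of vulturine guineafowl (*Acryllium vulturinum*) — stable
social units persist for months or years, but they temporarily split into
subunits (hours to weeks) and merge into supergroups (days to months).
Field data are sparse: a twice-daily census detects only some aggregations,
only ~90% of individuals carry identifying colour bands, and any one bird
may go unobserved for days or weeks. Under these conditions the "social
unit" an analysis recovers depends strongly on the time window over which
observations are aggregated and on the methodological choices made to
combat sparse sampling. `socialunits` implements the full inference
pipeline and makes those choices explicit, comparable and testable.

## The method

1. **Filtering.** Only complete census records of cohesive (`single`)
   aggregations are used; individuals seen two or fewer times in a focal
   period are dropped.
2. **Association networks.** For each focal window (sliding 1-month or
   2-month windows sampling one extra month on each side, or one static
   window over the whole study), a group-by-individual matrix is built and
   dyadic association is scored with the simple ratio index

   SRI(i,j) = x / (x + y_i + y_j),

   the number of aggregations with both individuals over the number with
   at least one. Edges below 0.5 are set to zero, because community
   detection is far more sensitive to edge presence than to edge weight.
3. **Unit detection.** The walktrap community algorithm (random-walk
   agglomeration, maximum-modularity cut) is run either directly on the
   thresholded network, or on a bootstrapped *meta-network* whose edge
   weights are the probability, across 100 resamplings of the observed
   aggregations, that two individuals land in the same community. Detected
   communities larger than the largest aggregation of identified
   individuals actually observed in that window are recursively re-split
   on their own records.
4. **Carryover membership.** Per-window communities are linked across
   windows by mutual-majority overlap into persistent global unit
   identities; individuals missing from a single window are interpolated
   back into their unit.
5. **Unit properties.** Membership stability is the Jaccard similarity of
   a unit's member sets in consecutive windows; spatial cohesion is the
   mean and maximum daily dyadic GPS distance among tracked (male) members
   of the same unit, after subsampling fixes to a common 5-minute grid.

A ground-truthed synthetic-society generator (`simulate_society()`)
produces census and GPS data with known unit membership, fission events
and supergroup windows, so every stage can be validated end to end.

## Worked example

```r
library(socialunits)

params <- society_params(n_units = 4, unit_size_mean = 12,
                         study_start = "2020-09-01", study_end = "2021-01-01",
                         census_detect_prob = 0.6, individual_miss_prob = 0.15,
                         fission_rate = 0.03, seed = 42)
sim <- simulate_society(params)
males <- sim$truth$individuals$individual[sim$truth$individuals$gps_male]

cfg <- approach_config("1-month", bootstrap = TRUE, carryover = TRUE,
                       n_boot = 100, seed = 42)
res <- run_approach(filter_census(sim$census), cfg,
                    gps = sim$gps, gps_ids = males)
res
#> <approach_result> 1-month+boot+carry: 4 unit(s), 45 individuals, 2 window(s)
#>   unit sizes: 8 / 11 / 15 (min/median/max)

res$stability
#>   global_unit window_t window_t1 jaccard
#> 1        G001  2020-10   2020-11       1
#> 2        G002  2020-10   2020-11       1
#> 3        G003  2020-10   2020-11       1
#> 4        G004  2020-10   2020-11       1

head(res$cohesion, 4)
#>   unit window_id mean_daily_distance max_daily_distance n_dyads n_days
#> 1 G001   2020-10            89.05766           94.52177       3     31
#> 2 G002   2020-10           103.58002          265.29605       3     31
#> 3 G003   2020-10           154.41099          524.65359       3     31
#> 4 G004   2020-10           305.01749          600.81714       3     31
```

The four true units are recovered as four global identities with perfect
month-to-month stability (Jaccard 1). Mean daily dyadic distances near
89 m reflect the configured 50 m within-unit scatter (two such members sit
`sqrt(pi) * 50 ≈ 89` m apart on average); units whose months include
fission events show larger maxima. Dropping `carryover` counts each
window's communities separately:

```r
cmp <- compare_approaches(list(res,
        run_approach(filter_census(sim$census), approach_config("1-month", seed = 42))))
cmp$summary[, c("approach", "unit_count", "individuals_included", "size_median", "mean_jaccard")]
#>             approach unit_count individuals_included size_median mean_jaccard
#> 1 1-month+boot+carry          4                   45          11            1
#> 2            1-month          8                   45          11           NA
```

`approach_grid()` enumerates all ten basis × bootstrap × carryover
combinations for a systematic comparison.

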
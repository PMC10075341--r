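# bearmarks

Analysis of brown bear (*Ursus arctos*) marking behavior at rubbing trees
from camera-trap event logs, for behavioral ecologists working with
ethogram-coded footage.

Bears communicate at focal trees through chemical marking (dorsal and facial
rubbing, pedal marking), olfactory investigation, and *visual marking* —
debarking the trunk with claws and teeth. `bearmarks` implements the
complete analysis chain around a five-category ethogram:

* **Events**: native and aggregated-export CSV dialects, clustering of
  camera triggers into independent visit events (30-min window per site),
  behavior/class tabulations, duration summaries, mark-height splits.
* **Sequences**: behavioral sequences bracketed by virtual `START`/`END`
  states, first-order Markov transition matrices
  (p̂(i→j) = n(i→j) / Σ_k n(i→k)), display pruning of edges with p < 0.1,
  entry/exit distributions, Graphviz DOT export.
* **Solar time**: NOAA sunrise/sunset (official zenith 90.833°), the four
  diel periods (sunrise/day/sunset/night built from ±1 h around the solar
  events), a strictly monotone sun-relative time on [−1, +1] anchored at
  solar midnight/sunrise/noon/sunset, day-of-year, camera-trap-day effort,
  and the monthly relative independent capture index
  RIC = 1000 · captures / camera-trap days.
* **Inference**: exposure-corrected χ² goodness of fit
  (E_i = N · w_i / Σw with exposure weights w), exact binomial post hocs
  (tail-doubling, Bonferroni), binomial GLMs of debarking probability on
  sun-time × day-of-year with Wald CIs and AICc model comparison, and
  one-way ANOVA + Tukey HSD on behavior durations.
* **Synthetic data**: a generator that injects known monthly, diel, class,
  sequence and debarking structure, so every pipeline claim is testable
  against ground truth without footage.

## Worked example

```r
library(bearmarks)

fx <- make_fixture_results_1()          # fixed 285-event log
tb <- tabulate_behavior_frequencies(fx)
tb$percent <- round_half_up(tb$percent, 1)
tb
#> # A tibble: 5 × 3
#>   behavior      n_events percent
#>   <chr>            <int>   <dbl>
#> 1 dorsal             222    77.9
#> 2 investigation      204    71.6
#> 3 pedal               67    23.5
#> 4 facial              62    21.8
#> 5 clawing             25     8.8
```

Each row is the share of the 285 visit events in which the behavior occurred
(behaviors co-occur, so columns don't sum to 100): dorsal rubbing dominates,
visual marking (here coded as clawing) is rarest.

A full simulated-year run:

```r
res <- run_pipeline(run_config(output_dir = "bundle", seed = 1))
res$gof_month
#> Exposure-corrected chi-square GOF: chi2 = 64.649, df = 11, P = 1.254e-09
#> Binomial post hocs (Bonferroni-adjusted):
#> # A tibble: 12 × 7
#>    bin   observed expected     p0 direction     p_raw    p_adj
#>  1 Jan          1     11.8 0.0849 below     0.000122  0.00146
#>  ...
#>  5 May         29     11.8 0.0849 above     0.0000104 0.000124
#>  ...
```

Monthly marking activity departs strongly from the exposure-implied
expectation (χ² on 11 df), with the hibernation months significantly below
and May — the mating-season peak — significantly above it. The `bundle`
directory holds the frequency/class/duration tables, transition matrices and
DOT diagrams, RIC series, actogram table, GOF JSONs, GLM and AICc tables,
`results.json` and the stage log.

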
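---
title: "Analysing brown bear marking behavior at rubbing trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing brown bear marking behavior at rubbing trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearmarks)
```

## The problem

Brown bears (*Ursus arctos*) communicate at focal "rubbing trees" through a
small, well-defined behavioral repertoire: chemical marking (dorsal and
facial rubbing, pedal marking), olfactory investigation, and visual marking —
debarking the trunk with claws or teeth, which leaves a conspicuous,
long-lasting mark. Camera traps at rubbing trees yield short trigger videos
that are coded against this ethogram. `bearmarks` implements the full
analysis chain for such data: event-log ingestion and independence
filtering, sex/age-by-behavior tabulation, first-order Markov analysis of
behavioral sequences, solar-anchored temporal analysis, and the inferential
layer (exposure-corrected goodness-of-fit tests, binomial GLMs of debarking
probability, duration ANOVA), plus a synthetic visit generator so that every
stage is testable without footage.

## Event model and independence filtering

A *detection* is one camera trigger: a site, a UTC timestamp, a sex/age
class, and an ordered list of behavior bouts (code, start offset, duration).
Detections at one site are clustered into *independent visit events*: a
detection within the independence window of the previous retained detection
extends the open event (bout offsets shifted by the detection delay), a
larger gap opens a new event. The window defaults to 30 minutes, the common
camera-trap convention; no published criterion exists for these data, so the
window is an explicit parameter. A gap of exactly the window starts a new
event, which makes the operation idempotent.

Sex/age labels are stored at the fine level (nine labels, including
`female_with_cubs` and the `unknown_*` fallbacks) and mapped to five coarse
reporting rows (`adult_male`, `adult_female`, `subadult`, `cub`, `unknown`);
`female_with_cubs` reports as `adult_female`.

Behavior-duration summaries zero-fill: an event in which a behavior never
occurs contributes 0 s to that behavior's distribution, so minima of zero
flag non-performance rather than missing data. Printed percentages use
half-up rounding to one decimal (`round_half_up()`), not banker's rounding.

## Behavioral sequences as a first-order Markov chain

Each event's bouts, ordered in time, form a behavioral sequence bracketed by
virtual `START` and `END` states. Two merge views are built in:
dorsal/facial couple into `rubbing` (the chemical information is presumed
identical) and the three visual actions (clawing, biting, removal of
experimental bark strips) couple into `debarking`. Investigation can be
dropped before analysis — it occurs at essentially every transition and
carries similar probabilities to and from every state, so it dominates
diagrams without adding structure. Consecutive identical states collapse to
one: a continued behavior is not a self-transition.

Transition counts pool adjacent state pairs over sequences (never across
events); maximum-likelihood probabilities are row-normalized counts.
Pruning removes edges with estimated probability strictly below a threshold
(default 0.1) *from the diagram only* — probabilities are not renormalized,
because pruning is a display decision focusing attention on predominant
transitions, not a model change. Diagrams export as Graphviz DOT with
lexicographic node/edge order, so identical models give byte-identical
files.

## Solar-anchored time

Because day length at 43°N varies by about six hours over the year, clock
time is a poor axis for diel analysis. Two sun-anchored representations are
used, both computed from NOAA's low-precision solar equations at the
official zenith of 90.833° (accurate to ±2 min at mid-latitudes; latitudes
within the polar circles are rejected):

* **Four diel periods** — sunrise (±1 h around official sunrise), day,
  sunset (±1 h around official sunset), night — tiling the 24-h clock day
  with half-open intervals. Evening night is attributed to the calendar date
  of its evening portion.
* **Sun-relative time** on `[-1, +1]`: a five-anchor piecewise-linear map
  (solar midnight −1, sunrise −0.5, solar noon 0, sunset +0.5, next solar
  midnight +1). The construction is not uniquely determined by its verbal
  description ("a continuous number considering both sunrise and sunset");
  this five-anchor form was chosen because it is continuous, strictly
  monotone, season-invariant at the anchors, and invertible — the inverse
  (`clock_from_sun_time()`) is what lets the synthetic generator inject diel
  structure on the sun-time scale and map it back to clock time on any date.

Survey effort is counted in camera-trap days (any calendar day intersecting
a deployment counts in full; only the annual total is published, so the
day-resolution convention is ours), and monthly activity is summarized by
the relative independent capture index, RIC = 1000 × captures / camera-trap
days. "Julian date" is the ecological day-of-year (1–365 in 2021), not the
astronomical Julian day.

## Inference

**Exposure-corrected goodness of fit.** Observed event counts per month (or
per diel period) are tested against expectations proportional to exposure —
camera-trap days per month, or the summed per-day durations of each diel
period over all deployed days — with the classical χ² statistic on
`bins − 1` degrees of freedom. Post hoc, each bin gets an exact binomial
test of its count among all events at the exposure-implied proportion.
Two-sidedness is obtained by doubling the smaller tail (capped at 1); this
differs from the minimum-likelihood two-siding of `binom.test()` and was
chosen for monotonicity and transparency. Bonferroni correction uses m =
number of bins (12 months; 4 periods).

**Debarking GLM.** A binomial GLM of debark (yes/no) on sun-relative time,
day-of-year and their interaction, fitted by IRLS (tolerance 1e-8, max 50
iterations), covariates in raw units (the day-of-year coefficient is
per-day). Wald 95% intervals are estimate ± 1.96 SE; model comparison uses
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with models within ΔAICc < 2 flagged as
competing. Complete separation is detected (boundary warnings or runaway
Wald SEs) and reported as an error naming the offending term, rather than
returning meaningless estimates. Tree identity is not modeled as a random
effect: with 13 sites and few debarking events the variance component is
not estimable, matching the published analysis choice.

**Durations.** One-way ANOVA across behaviors on per-event total seconds,
followed by Tukey HSD (studentized-range) pairwise comparisons; the
per-pair t is the mean difference over its pooled SE.

## The synthetic generator

`generate_events()` draws a full study year with the structure the analyses
assume, so pipeline-level claims can be tested against known ground truth:

* 13 sites near 43°N, deployed all year (4,745 camera-trap days);
* monthly visit counts Poisson with expectations
  (4, 4, 16, 40, 56, 42, 28, 22, 18, 14, 12, 4) — ≈260 visits peaking in
  May, near-zero in the hibernation months;
* clock times drawn on the sun-time scale from a mixture: a major Gaussian
  bump at sunset (+0.5, sd 0.12, weight 0.45), a weaker one just after
  sunrise (−0.45, sd 0.10, weight 0.25), and a uniform floor (0.30), mapped
  back through the inverse sun-time transform of the visit's site and date —
  so the injected diel pattern is season-invariant by construction;
* sex/age classes from a fixed mix dominated by adult males (0.45), with
  per-class repertoires that make subadults mostly investigate and adult
  males mark most;
* marking sequences of adult males drawn from a ground-truth chain shaped
  like observed sequences (rubbing the dominant entry and exit state,
  debarking reached only from rubbing and almost always followed by it);
* debarking allowed only for adult males between April 1 and June 30, with
  probability from a logistic model (intercept 1.75, −0.02 per day, +1.0
  per unit sun-time). The intercept is calibrated so the window-averaged
  logistic rate equals the chain's probability of a debark-containing path
  (0.312): the two layers then agree on the marginal debark rate and pooled
  eligible-event sequences are distributed as chain draws, which is what
  makes whole-pipeline chain recovery a well-posed test;
* lognormal bout durations (dorsal longest, ≈20 s median), capped at the
  60-s video length, and seasonal mark heights (mostly above the shoulder
  line in April–May).

Visits are independent events by definition, so the generator re-draws any
time landing within 35 min of an existing visit at the same site; the
30-min filter then passes the stream through unchanged.

What the generator does **not** emulate: visits with no recorded behavior at
all (every generated visit has at least one bout, because the one-row-per-
bout CSV dialect cannot carry empty visits — the hand-built results fixture
covers that case), revisit dynamics of identified individuals, opportunistic
multi-year collections, spatial structure between trees, and camera failure.
Passing pipeline tests therefore demonstrate correctness of the *analysis*
under the assumed data-generating structure, not robustness to the many ways
field data depart from it.

## Numerical and design notes

* Problem sizes in the test suite are chosen for precision at desk scale:
  2,000 multinomial replicates for the χ² size check, 2,000 simulated
  sequences (≈7,000 transitions) for chain recovery, 40 × 5,000
  observations for GLM bias, 200 × 500 for CI coverage, and 20 simulated
  years for seed-averaged pattern checks.
* Sequence-recovery convergence is monitored with RMSE over transient rows;
  the max-abs error of the sparsest row is dominated by its own sampling
  noise and is reported but not used as the convergence criterion.
* Transition ties and ordering: states are ordered `START`, lexicographic
  middle states, `END` everywhere, making counts, probabilities, CSV and
  DOT output deterministic.
* Degenerate inputs: events with no bouts yield `[START, END]` sequences
  with a warning; chains that cannot reach `END` are rejected by the
  sequence sampler and flagged by the entry/exit summary; months with
  captures but zero camera-trap days raise a data-consistency error.
* The GLM layer reports the computed p-value for every term, including
  interaction terms, from the Wald z statistic.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(run_config(output_dir = "bundle", seed = 1))
res$frequencies
res$gof_month
res$glms$interaction
```

The bundle directory then contains the frequency and class tables, duration
summary, transition matrices and DOT diagrams under both sequence views, the
RIC series and actogram table, both goodness-of-fit JSON results, the GLM
and AICc tables, a consolidated `results.json`, and the stage log.
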
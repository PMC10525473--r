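---
title: "Generating fully synthetic patient cohorts from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating fully synthetic patient cohorts from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prediction models for incident disease need patient-level training data that
rarely exists in open form. What *is* published, in large epidemiological
surveys, are summary statistics: how many people of each age group were
followed, how many developed the disease within the follow-up window, the
sex composition, and — from Cox models — hazard ratios linking binary risk
factors to incidence. `synthcohort` turns exactly that kind of table into a
fully synthetic patient-level cohort, with no access to any real record, and
then *manufactures* class separability in the joint distribution while
provably never changing a single marginal count.

The packaged configuration describes a 5-year type 2 diabetes incidence
survey: four age groups (40 to <55, 55 to <65, 65 to <75, 75+ years), 87,601
participants who stayed healthy and 6,163 who developed diabetes, and six
binary risk factors (unhealthy diet, physical inactivity, current alcohol
consumption, poor sleep, general/central obesity, hypertension) alongside
age and sex. Every record is a row of nine numbers: normalized age, seven
0/1 features, and a 0/1 outcome label.

## Stage 1: the primary database

Generation works one (age group × outcome) *subgroup* at a time, so class
labels can never mix, and every stochastic column is built by **exact-count
construction**: a column of length $n$ with prevalence $p$ receives exactly
$\mathrm{round}(np)$ ones at random positions. This is deliberate — it makes
"the generated table reproduces the configured statistics" an *equality*
that the conservation audit can test, rather than an expectation.

* **Age** is drawn from a normal distribution with the group's published
  mean and SD, truncated to the group's bounds by inverse-CDF sampling, then
  divided by 100 so it is commensurate with the binary features. The last
  group's open bound ("75+") is closed at 100, the stated upper limit of the
  surveyed ages.
* **Sex** is published per age group but not per outcome subgroup, so the
  group's male fraction is carried into both subgroups; the (smaller)
  diabetic arm is rounded first and the healthy arm takes the remainder, so
  the group's sex totals are conserved exactly. On the packaged counts this
  yields diabetic-arm male counts of 673, 852, 484 and 87 across the four
  groups.
* **Binary risk factors** are published as a hazard ratio plus an overall
  exposure prevalence $q$ per age group. Treating the hazard ratio over the
  fixed follow-up window as a risk ratio, Bayes inversion gives the
  exposure prevalence among future diabetics,
  $p_d = \mathrm{hr}\,q \,/\, (1 - q + \mathrm{hr}\,q)$, and the healthy
  arm's prevalence is whatever conserves the total exposed mass
  $q(n_d + n_h)$. This inversion is exact: recomputing the risk ratio from
  the generated 2×2 counts returns the configured value (the test suite
  checks recovery within 5% at 10,000 records per arm). When a requested
  ratio is unattainable at the given arm sizes — the attainable risk ratio
  at disease probability $d$ is capped by
  $\mathrm{odds}(\min(1, q/d))/\mathrm{odds}(q)$ — the split clips to
  $[0,1]$ and warns rather than silently distorting $q$.
* **Class balancing** duplicates the minority (diabetic) subgroups whole
  $\lfloor k \rfloor$ times and apportions the remaining rows across
  subgroups by largest remainder (taking the first rows of each), so the
  minority total hits the configured target (84,692 at full scale)
  exactly and deterministically.

The survey publishes its counts directly, but *not* the per-factor hazard
ratios, prevalences, or age moments; the packaged fixture therefore carries
documented synthetic placeholders for those (hazard ratios 1.5–3.0, mildly
age-graded; prevalences 0.2–0.5, e.g. hypertension rising with age), each
flagged `user_supplied: false`. Conclusions about the real survey require
replacing them; every packaged test that touches them is a property or
tolerance check, never a claim about the source survey.

## Stage 2: the shuffle–train loop

A primary database built this way has *independent* columns within each
subgroup — the classes differ only in their marginal prevalences, and a
classifier plateaus not far above chance. The loop reshapes the
within-class joint structure without touching any marginal:

1. **One-time randomization.** Each feature column of each subgroup is
   permuted by a Fisher–Yates pass and then a deterministic mirror swap
   (with `sl = floor(n/2)`, element `i` swaps with `sl - i` for
   `i = 0..floor(sl/2)`). The mirror breaks up the long constant runs a
   mostly-binary column keeps under random permutation; both steps are
   multiset-preserving and run once, before the loop.
2. **Windowed main shuffle.** Each cycle selects a window — start
   `round(B*n)`, length `max(1, round(P*n))`, half-open, clipped to the
   table — shared by all subgroups as *fractions* of their rows. Inside it,
   the age column is Fisher–Yates-permuted, and every binary column is
   bit-flipped (`x -> 1 - x`) and then *compensated*: the flip's net change
   in ones is undone by converting entries of the opposite value in the
   stretch after the window, so the column total is exactly restored.
3. **Train and steer.** The subgroups are recombined, split 8:2 (a tenth of
   the training split is held out for validation curves), and a small
   feed-forward classifier — hidden layers 16/64/32, ReLU, sigmoid output —
   is trained for five epochs. Its test accuracy feeds an Adam-like
   controller that updates the window fraction `P`; the start `B` advances
   by 0.12, wrapping past 1 and resetting to 0 whenever the window it
   implies would overrun the table. A snapshot and a cycle record are kept;
   after up to 100 cycles the snapshot with the highest test accuracy is
   the product.

### Why contiguous compensation matters

The compensation step converts the *first* convertible entries after the
window — a contiguous run — rather than randomly scattered ones. This is
the single most consequential design choice in the package. Contiguous
compensation means every cycle both complements a block and consolidates
the displaced ones into runs; over cycles the columns develop long,
persistent, class-specific run structure that a classifier can separate
almost completely. With scattered compensation (available as
`placement = "random"` on `rebalance_column()`, `shuffle_cycle()` and
`run_generation_loop()`) the compensation continually re-randomizes the
outside region and the joint structure saturates early, well short of the
contiguous variant. Both variants conserve every count exactly.

### Controller conventions and degenerate windows

The controller is
$v' = \beta_1 v + (1-\beta_1)g$, $s' = \beta_2 s + (1-\beta_2)g^2$,
$\Delta P = \eta\, v'/(\sqrt{s'}+\epsilon)\cdot g$, with
$\eta = 1$, $\beta_1 = 0.95$, $\beta_2 = 0.99$, $\epsilon = 10^{-4}$, and
gradient $g = 1 - \text{test accuracy}$: shuffling pressure decays as
separability is achieved, and a perfect classifier is a fixed point. Three
details were genuinely open and are resolved as follows:

* **Sign convention.** With minus signs in both accumulators the second
  moment $s$ goes negative and the square root is undefined; the default
  therefore accumulates with plus signs ("standard"), and the minus-sign
  variant is available (`convention = "as_printed"`, $s$ floored at zero)
  for fidelity experiments. It drives `P` to its floor and performs
  markedly worse.
* **The trailing $g$ factor** in the step is retained by default
  (`keep_trailing_g = FALSE` drops it). Without it the first step is
  $\eta(1-\beta_1)g / (\sqrt{(1-\beta_2)}\,g + \epsilon) \approx \eta/2$
  whatever the accuracy, saturating `P` within a couple of cycles; the
  trailing factor is what scales the step by the error.
* **Clipping.** `P` is clipped to $[0.01, 1]$ so the window is never empty
  nor larger than the table; `B` lives in $[0, 1)$. The overrun test in the
  `B` advance uses the effective window length `max(1, round(P*n))`, so
  `B = 1` (reachable as 0.88 + 0.12, which does not trip the "exceeds 1"
  wrap) always resets — without this, tiny tables with `round(P*n) = 0`
  would leave `B` at an illegal 1.
* **Saturation.** If a flipped window cannot be compensated after it, the
  remainder spills before it, and as a last resort part of the window
  itself is un-flipped, with a classed warning. Conservation is therefore
  unconditional — even for a full-table window — at the price of a partial
  shuffle in degenerate geometry; `shuffle_cycle()` tallies affected
  columns in an attribute instead of escalating per column.

### Training internals

The classifiers are trained by mini-batch Adam (rate $10^{-3}$, batch 256,
bias-corrected moments) on binary cross-entropy; hidden activations are
ReLU, the output a sigmoid, initialization is He-scaled. Nothing about the
training procedure is exotic, and all of it is exposed (`lr`,
`batch_size`, `epochs_per_cycle`). The loop classifier is re-initialized
each cycle from a cycle-derived seed, which keeps cycle accuracies
comparable and snapshots independent; a continuously trained variant
(`reinit_network = FALSE`, which forces a fixed split so held-out rows stay
held out) was evaluated and bought no material gain. Whether the 8:2 split
should be redrawn per cycle is unstated in the method's description; the
default redraws with a cycle-derived seed, and `fixed_split = TRUE` is
available. Every stochastic step — generation, shuffling, splitting,
initialization, batch order, dropout — derives from four named seeds in the
configuration (or one override), so runs are exactly reproducible.

## Stage 3: evaluation

* **Independent retraining** (`evaluate_best()`): a deeper network — hidden
  layers 16/64/32/16 with dropout 0.2 after the first three (the layer
  table places dropout before the ReLU; with ReLU and inverted dropout the
  two orders are mathematically identical), sigmoid output — is trained
  from scratch on an 8:2 split with random state 46 and scored on the
  held-out rows. This asks the question the dataset's consumers care
  about: can a model that never saw the loop learn the classes?
* **Score histograms** (`class_score_histograms()`): each row is reduced to
  the sum of its feature columns and the two classes are binned on 100
  shared equal-width bins spanning the pooled score range (the binning
  range was an open convention; pooled-range equal-width is ours). The
  summed bin-wise minimum of the two normalized histograms — the overlap
  coefficient — turns "the classes look separated" into a scalar: 1 for
  identical distributions, 0 for disjoint ones. By default all eight
  feature columns are summed; `score_columns` reproduces narrower
  conventions (e.g. the seven columns excluding age).
* **Conservation audit** (`audit_statistics()`): per subgroup and binary
  column, the observed ones-count is compared with the count recorded when
  the table was generated and balanced. The audit passes only on exact
  equality everywhere, and a single corrupted bit fails exactly one row of
  the report. Age is permuted but never altered, so its multiset is
  checked in the test suite by exact sorted comparison.

## Problem sizes and what the tests show

The packaged experiments run at desk scale: the survey configuration scaled
proportionally (within-group proportions and the balancing ratio preserved)
to about 20,000 balanced records, 100 cycles, 5 epochs per cycle — sizes
chosen so the full pipeline, including its acceptance script, runs in
minutes on one CPU. The property suite (marginal conservation, involutions,
hazard-ratio round-trips, controller contracts) is scale-free. The
full-scale run — 172,290 records — is the same code path and is not
exercised by the packaged tests; the scaled run plus the conservation audit
on its snapshots stands in for it. Nothing in the pipeline depends on
absolute size: windows, balancing and splits are all defined as fractions.

What passing tests do and do not show: the generator reproduces *configured
marginals* exactly and the loop *manufactures* separability — they say
nothing about resemblance to real patients. Correlations between risk
factors at generation time are deliberately absent (the loop, not the
generator, shapes joint structure); the run structure the loop builds is an
artifact of the method, not epidemiology; and with placeholder hazard
ratios the cohort is a structural stand-in, not a claim about the source
survey.

## Known limitations

* Hazard ratios are treated as risk ratios over a single fixed window; the
  time-to-event structure of true Cox hazards is ignored.
* Requested (hazard ratio, prevalence) pairs outside the attainable region
  for the configured arm sizes are clipped with a warning; the audit will
  still pass (counts are conserved as built) but the realized ratio is the
  capped one.
* Minority balancing by verbatim duplication means test-set diabetic rows
  usually have train-set duplicates; loop-cycle accuracy therefore
  overstates generalization, which is why the independent retraining
  evaluation exists.
* The overlap coefficient depends on the binning convention; compare
  datasets only under identical edges.
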
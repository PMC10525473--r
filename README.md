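# synthcohort

Fully synthetic patient-level cohorts from published summary statistics —
no real records required.

Large incidence surveys publish, per age group, the number of people
followed, how many developed the disease within the window, the sex
composition, and Cox hazard ratios (HR) with exposure prevalences for
binary risk factors. `synthcohort` turns such a table into a patient-level
dataset and then runs a **shuffle–train feedback loop** that reshapes the
within-class joint structure — while *exactly* preserving every marginal
count — until a neural classifier can separate the outcome classes. The
packaged configuration describes a 5-year type 2 diabetes incidence survey
(four age groups, 87,601 healthy / 6,163 incident-diabetes participants,
six binary risk factors plus age and sex).

## The method in brief

**Generation** works per (age group × outcome) subgroup, by exact-count
construction — a column of length $n$ at prevalence $p$ gets exactly
$\mathrm{round}(np)$ ones:

* ages ~ truncated normal on the group's bounds, divided by 100;
* sex keeps the age group's male fraction in both outcome arms
  (diabetic arm rounded first, totals conserved exactly);
* each binary factor's overall prevalence $q$ is split between arms by
  inverting the hazard ratio as a risk ratio:
  $p_d = \mathrm{hr}\,q/(1-q+\mathrm{hr}\,q)$, with $p_h$ chosen so the
  exposed mass $q(n_d+n_h)$ is conserved — recomputing the ratio from the
  generated 2×2 counts returns $\mathrm{hr}$;
* the minority class is balanced by whole-copy duplication plus
  largest-remainder apportionment to the configured target (84,692 at
  full scale).

**The loop**, per cycle: select a window (start fraction $B$, length
fraction $P$); inside it Fisher–Yates-permute age and bit-flip every
binary column, compensating each flip in the run after the window so
column totals are unchanged; recombine, split 8:2, train an
8–16–64–32–1 ReLU/sigmoid classifier for 5 epochs; feed its test accuracy
into an Adam-like controller ($\eta=1$, $\beta_1=0.95$, $\beta_2=0.99$,
$\epsilon=10^{-4}$, gradient $g = 1-\mathrm{accuracy}$) that updates $P$,
and advance $B$ by 0.12. The snapshot with the best test accuracy across
up to 100 cycles is the product. A deeper dropout network (16/64/32/16,
dropout 0.2) retrained from scratch with random state 46 judges the result,
alongside 100-bin per-class score histograms (with an overlap coefficient)
and an exact marginal-conservation audit.

## Worked example

```r
library(synthcohort)

cfg <- diabetes_survey_config()      # packaged survey summary statistics
cfg
#> <survey_config> schema 1
#> 4 age groups, 6 risk factors
#> healthy: 87601  diabetic: 6163  balance target: 84692

# desk scale: same structure, ~20,000 balanced records
small <- scale_config(cfg, 20000)
loop  <- run_generation_loop(small, cycles = 100, seed = 1)
glance(loop)
#> # A tibble: 1 × 4
#>   cycles best_cycle best_test_accuracy n_records
#>    <int>      <int>              <dbl>     <int>
#> 1    100         85              0.980     20000

# judge the selected snapshot with a network that never saw the loop
ev <- evaluate_best(loop$best_dataset, epochs = 10, seed = 46)
ev$test_accuracy
#> [1] 0.978

class_score_histograms(loop$best_dataset)
#> <score_histograms> 100 bins; 10169 healthy / 9831 diabetic rows
#> overlap coefficient: 0.1189

audit_passed(audit_statistics(loop$best_dataset))
#> [1] TRUE
```

Read: the loop raised the 5-epoch classifier's held-out accuracy to 98% at
its best cycle; an independently trained evaluation network confirms the
separability (97.8% at epoch 10); the per-class score distributions overlap
in only ~12% of their mass; and every subgroup's per-column ones-count still
equals the generated database's — the shuffling changed *which rows* carry
the exposures, never *how many*.

`tidy(loop)` gives the per-cycle records, `autoplot(loop)` the accuracy
trace and `autoplot(loop, "params")` the $P$/$B$ trajectories. The packaged
fixture's hazard ratios, prevalences and age moments are documented
synthetic placeholders (the survey publishes only the counts); replace them
with published values before drawing substantive conclusions.

A thin command-line front end ships in `inst/cli/`:

```sh
Rscript inst/cli/synthcohort loop -c config.yaml --cycles 100 --out-dir runs/
Rscript inst/cli/synthcohort evaluate --dataset runs/best.csv --epochs 100 --report report.json
```

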
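# evospec

Evolutionary specification of multilevel categorical predictors for clinical
risk models.

## The problem

Emergency-department chief complaints are recorded at two levels of
specificity: a specific complaint ("abdominal cramping") nested inside a
complaint category ("abdominal pain"). Models that predict a critical-care
outcome at triage (in-hospital death, direct ICU admission, or emergent
surgery/catheterization) must decide, complaint by complaint, which level to
use — and the right answer is an empirical property of the data, not
something a hypothesis can settle in advance. evospec is for biostatisticians
and clinical-informatics researchers who want to learn that specification
from data.

## The method

A candidate specification is a binary mask `b` of length `n` (one bit per
specific complaint): `b_i = 1` selects complaint `i` as its own predictor.
Conditional on the mask, the design is built in one of two ways:

* **flattened** — a single mutually exclusive level: patients with a selected
  complaint carry that complaint's indicator and are removed from their
  parent category; everyone else carries the category indicator;
* **hierarchical** — the category indicator is retained for all patients and
  a selected complaint adds a supplementary indicator.

Both designs also include age band, gender, arrival mode and five
discretized vital signs (each with a dedicated missing category). The
fitness of a mask is the 5-fold cross-validated AUC of a logistic regression
on that design, with outcome-stratified folds fixed across all candidates. A
genetic algorithm (population 40, tournament selection with k = 3, uniform
crossover at rate 0.6 with mixing ratio 0.2, per-offspring bit-flip mutation
at rate 0.2 with flip rate 0.05, elitist top-N retention) searches the mask
space; two single-level baselines (`complaints_only`, `categories_only`)
bracket it. Selected models are compared with paired DeLong tests and
evaluated within bullseye subgroups — *inner* patients (own complaint
selected), *middle* (category altered by a sibling selection) and *outer*
(untouched). Because no public triage cohort exists, the package ships a
synthetic ED cohort generator with planted ground truth (category effects,
signed specific effects on a known informative set, calibrated ~3% outcome
prevalence, power-law complaint frequencies).

## Worked example

```r
library(evospec)

sim <- generate_cohort(synthetic_config(n_patients = 20000, seed = 7))
print(sim$cohort)
#> ED cohort: 20000 visits, 40 unique complaints (40 in hierarchy), 5 categories
#>   critical-outcome prevalence: 3.13%

res <- run_experiment(cohort = sim$cohort, truth = sim$truth,
                      modes = c("flattened", "hierarchical"),
                      config = ga_config(generations = 12, rng_seed = 7,
                                         fold_seed = 42))
print(res)
#> specification-optimization experiment
#>   baseline AUC: complaints_only 0.6557, categories_only 0.6279
#>   flattened GA: best CV-AUC 0.6679 (18/40 complaints selected)
#>   hierarchical GA: best CV-AUC 0.6689 (18/40 complaints selected)
#>   mode agreement: 80.0%

print(res$runs$flattened$bullseye)
#> bullseye evaluation (GA vs baselines)
#>   region     n events auc_ga auc_complaints_only auc_categories_only
#>    inner 12531    421 0.6853              0.6856              0.6315
#>   middle  7469    205 0.6238              0.5856              0.6093
#>    outer     0      0     NA                  NA                  NA
#>  overall 20000    626 0.6679              0.6557              0.6279
#>  stars_vs_complaints stars_vs_categories
#>                                      ***
#>                   **
#>
#>                   **                 ***
```

Reading the output: both GA specifications beat both single-level baselines
overall (stars are DeLong p-values: `*` < 0.05, `**` < 0.01, `***` < 0.001).
The subgroup rows show where the gains come from — inner patients gain over
the categories-only baseline because their specific complaint now carries its
own coefficient; middle patients gain over the complaints-only baseline
because their category indicator becomes informative once risk-shifting
siblings are removed or separated. The two encodings agree on 80% of the
complaints here (jointly selected + jointly excluded). This is a short demo
run; recovery experiments in the test suite use 50,000 visits and 30
generations.

A thin command-line front end over the same pipeline ships in
`inst/scripts/evospec.R`:

```sh
Rscript inst/scripts/evospec.R --simulate --mode both --generations 30 \
    --seed 7 --out results/
```

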
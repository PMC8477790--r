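# tmepre

Two-component tumor-microenvironment scoring for predicting anti-PD1
response in colorectal cancer, from bulk gene-expression data.

Checkpoint blockade mostly helps microsatellite-instable (MSI) colorectal
tumors, yet many MSI patients do not respond and some microsatellite-stable
(MSS) patients would. Response needs two things bulk expression can read
out: CD8+ T cells must have infiltrated the tumor, and those cells must not
yet be terminally exhausted. `tmepre` derives and applies a pair of
nearest-centroid gene signatures capturing exactly that:

* **TME1.TcellInfiltration** — trained on MSI tumors with CD8A strictly
  above its 40th percentile (within MSI) versus MSS tumors strictly below
  it. The score measures how permissive the microenvironment is to CD8+
  T-cell infiltration; CD8A itself is excluded from the signature.
* **TME2.TcellResponse** — trained, within the high-infiltration MSI
  tumors, on samples with both PD1 (PDCD1) and TIM3 (HAVCR2) below their
  medians (T cells can still respond) versus samples with both above
  (terminally exhausted). Higher scores mean an anti-PD1-responsive
  microenvironment.

Signatures are picked by stability selection — 200 rounds of 10-fold
cross-validation, a Welch t-test per gene on each round's retained 90%,
keeping genes ranked in the top 60 in at least 80% of rounds — then fitted
as standardized nearest-centroid scorers

    score(x) = ( ||z - c_neg|| - ||z - c_pos|| ) / m,   z = (x - mu) / sigma

over the m signature genes, with the cutoff set to the minimum
positive-class training score (training sensitivity 1). A predicted
responder must clear both cutoffs; nonresponders carry a mechanism label
(insufficient infiltration vs terminal exhaustion). For validation cohorts
from other platforms a rank-based quartile rule replaces the fitted
cutoffs, and the package includes the survival machinery used to judge the
predictions (log-rank, Cox hazard ratios, Stouffer Z-transform combination
of cohort p-values), a CD8-restricted read-out of TME2 for purified T-cell
profiles, and a synthetic-cohort simulator with planted ground truth so
the entire derivation is testable without external data.

## Worked example

```r
library(tmepre)

sim <- simulate_cohort(sim_config(seed = 42))      # 131 MSI + 284 MSS, 1000 genes
fit <- build_tmepre(sim$expr, sim$annotations)     # full two-component derivation
fit$model
#> <tmepre_model>
#>   TME1 infiltration: 47 genes, cutoff -0.1313 (marker CD8A, percentile 0.40)
#>   TME2 response:     35 genes, cutoff 0.112 (markers PDCD1, HAVCR2)
#>   validation rule quantiles: 0.25 / 0.75; CD8-restricted subset: 9 genes

scores   <- score_samples(fit$model, sim$expr)
training <- classify_training_cohort(fit$model, scores, sim$annotations)
training$summary[, c("msi_status", "n", "n_responder", "pct_responder")]
#>   msi_status     n n_responder pct_responder
#> 1 MSI          131          67          51.1
#> 2 MSS          284         194          68.3
```

The MSI responder fraction (51.1%) tracks the simulator's planted truth:
60% of MSI tumors infiltrated, half of those exhausted. (The MSS fraction
is high here only because the synthetic MSS background is identical to the
MSI background apart from infiltration frequency; see the methods vignette
for what the simulator does and does not emulate.)

Validation-style prediction and survival read-out on a fresh cohort:

```r
valid <- simulate_cohort(sim_config(n_msi = 66, n_mss = 134, seed = 43))
pred  <- classify_validation_cohort(fit$model, score_samples(fit$model, valid$expr))
surv  <- simulate_survival(valid$annotations, pred, hr_true = 3, seed = 44)
survival_readout(pred, surv)
#> <tmepre_survival> n = 200 (140 events); HR = 6.44; log-rank p = 4.808e-19
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted model,
selection reports and survival read-outs. A command-line interface wraps
the same functions:

```sh
Rscript inst/scripts/tmepre simulate --out-dir sim --seed 9
Rscript inst/scripts/tmepre derive --matrix sim/matrix.tsv \
    --annotations sim/annotations.tsv --seed 10 --out model.json
Rscript inst/scripts/tmepre score --model model.json --matrix sim/matrix.tsv --out scores.tsv
```

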
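# dsskit

Quantitative drug sensitivity scoring for high-throughput dose–response
screens of cancer cell lines and primary patient cells tested *ex vivo*.
It is aimed at analysts of drug sensitivity and resistance testing (DSRT)
data who need a single, comparable response metric per sample–drug pair —
and, when healthy-donor controls are available, a cancer-*selective* one —
rather than an IC50 that ignores most of the curve.

## The method

Each curve (percent growth inhibition vs. dose, normalized against per-plate
DMSO and benzethonium-chloride controls) is fitted with a four-parameter
logistic in log10 concentration *x*:

    R(x) = R_min + (R_max − R_min) / (1 + 10^{s (m − x)})

with asymptotes `R_min ≤ R_max` (percent inhibition), log10 IC50 `m`, and
slope `s > 0`. The drug sensitivity score integrates the fitted curve above
a minimum activity level `A_min` (default 10%) in closed form,

    I = ∫ (R(x) − A_min) dx   over the part of the tested window where R > A_min,

and normalizes it to 0–100:

* **DSS1** `= 100·I / ((100 − A_min)(x_hi − x_lo))` — area relative to the
  maximum attainable;
* **DSS2** `= DSS1 · log10(max(R_max, 1))/2` — penalizes low top asymptotes;
* **DSS3** `= DSS2 · (x2 − x1)/(x_hi − x_lo)` — additionally penalizes
  narrow active dose windows.

Around the score sit the rest of the workflow: the discrete Activity Area
and relative IC50 comparators, differential scoring against control samples
(dDSS), responder sub-group detection via the one-sided D'Agostino skewness
test with iterative peeling, AUROC/DeLong evaluation of competing metrics,
Ward/Spearman clustering of drug response profiles with
Rand/adjusted-Rand/Jaccard/Fowlkes–Mallows evaluation against
mechanism-of-action classes and a permutation test for index differences,
and kinase-addiction (KISS) scoring against drug–kinase target matrices
with SIF/GraphML network export. A seeded synthetic-cohort generator with
known ground truth makes the whole pipeline testable offline. The methods
vignette (`vignettes/drug-sensitivity-scoring.Rmd`) documents the model,
the defaults and every numerically consequential choice.

## Worked example

```r
library(dsskit)

sim <- simulate_cohort(n_patients = 12, n_controls = 4, n_drugs = 4,
                       planted_subgroups = list(list(
                         drug = "drug_02",
                         responders = c("patient_01", "patient_02", "patient_03"),
                         effect = 25)),
                       noise_sd = 5, seed = 42)

fits  <- fit_curves(sim$data)                                  # 4PL per curve
scores <- score_curves(fits, metric = "DSS2")                  # samples x drugs
ddss  <- differential_scores(scores, paste0("control_0", 1:4)) # vs control mean
detect_responder_subgroups(ddss)
#> # A tibble: 4 × 9  (gamma, p, FDR, responders, rank-sum confirmation)
#>   drug_id  gamma p.value   fdr n_responders ranksum_p
#> 1 drug_01 -1.53   0.997  0.997            0  NA
#> 2 drug_02  0.945  0.0327 0.131            3   0.00357
#> 3 drug_03  0.580  0.120  0.240            0  NA
#> 4 drug_04 -0.151  0.623  0.831            0  NA
```

The planted drug (`drug_02`) is the only one whose dDSS distribution shows
significant positive skewness (γ = 0.95, one-sided p = 0.033); peeling its
right tail recovers exactly the three planted responder samples
(`patient_01`, `patient_03`, `patient_02`), and the Wilcoxon rank-sum test
confirms their separation from the remaining samples (p = 0.0036). `fits`
carries the per-curve parameters (`r_min`, `r_max`, `ic50_nM`, `slope`,
`rss`, `converged`); `scores` and `ddss` are samples × drugs matrices that
round-trip through `write_score_matrix()` / `read_score_matrix()` with
their metric and settings. `autoplot()` on a fit shows the fitted curve
over the points; on a score matrix it draws the heatmap, and
`plot_waterfall()` the per-sample differential profile.

A thin command-line interface over the same functions ships in
`inst/cli/dsskit.R`:

```sh
Rscript inst/cli/dsskit.R simulate --out-dir demo --seed 11
Rscript inst/cli/dsskit.R score --input demo/dose_response.csv \
    --metric DSS2 --controls control_01,control_02 --out-dir demo
Rscript inst/cli/dsskit.R subgroups --scores demo/ddss.csv --out-dir demo
```

and `run_pipeline()` executes the full normalize → fit → score →
differential → subgroups → cluster → KISS chain from a YAML config,
writing every intermediate CSV plus a manifest with the config hash and
seeds, byte-identically on re-run.

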
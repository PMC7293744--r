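# rwsr: risk-weighted sparse regression for prognostic gene signatures

`rwsr` discovers sparse prognostic gene signatures from gene-expression
and right-censored overall-survival data across **two independent
cohorts**, and builds the downstream prognosis layer around them. It is
aimed at biostatisticians and computational biologists working on
expression-based survival signatures (e.g. tumor cohorts profiled on
different platforms) who need the whole path — screening, robust sparse
selection, cross-cohort validation, risk stratification — reproducible
and testable end to end.

## The method

Three modelling steps, run per cohort and intersected across cohorts:

1. **Univariate Cox screen.** Each gene is fit in the Cox
   proportional-hazards model
   `h(t|x_g) = h0(t) exp(beta_g x_g)` by Newton-Raphson on the Breslow
   partial likelihood. Genes with `HR = exp(beta) < 1` and `p < 0.01`
   are *protective*, `HR > 1` and `p < 0.01` *risky*. Candidates are
   intersected across cohorts by direction (`com_prot`, `com_risk`); a
   gene whose direction flips between cohorts is discarded.
2. **Risk weighting.** Per patient, the risk score
   `rs_i = sum_g x_ig beta_g` and the risk-probability vector
   `rp_ig = x_ig beta_g / rs_i` (each row sums to 1 — the fractional
   contribution of each gene to the patient's risk).
3. **Robust sparse regression (WLAD-SCAD).** With design
   `z_ig = rp_ig * x_ig` and response `rs`, minimize

   ```
   sum_i w_i |rs_i - z_i' gamma|  +  n sum_j p_lambda(|gamma_j|)
   ```

   a weighted least-absolute-deviation loss with the SCAD penalty
   (`a = 3.7`), solved by local linear approximation. The weights
   `w_i = min_j h_j / h_i` come from leverages against a trimmed clean
   subset (the `floor(0.6 n)` patients closest to the feature-wise
   median after min-max normalization), which protects the fit from
   outlying patients. `lambda` is chosen by BIC over a 30-point grid.

The final signature is the **intersection of the two cohorts' sparse
supports**. It is then evaluated per cohort: multivariate-Cox risk
score `sum_g x_ig gamma_g`, median high/low split, Kaplan-Meier +
log-rank, IPCW time-dependent ROC/AUC, clinical stratification, and the
eight stage-by-risk groups (stage 0-III crossed with high/low risk).

A synthetic-cohort generator with planted protective/risky genes,
exponential survival and uniform right-censoring makes every stage
testable without external data; simulated cohorts carry their ground
truth alongside (`geneTruth()`).

## Worked example

```r
library(rwsr)

# two cohorts, 300 patients x 500 genes, sharing 5 planted protective
# (log-HR -1) and 5 risky (+1) genes
pair <- simulatePairedCohorts(simulationConfig(seed = 1))
pair$A
#> SurvivalCohort: 500 genes x 300 samples (126 events, 42.0%)
#>   planted truth: 5 protective, 5 risky, 490 null

res <- deriveSignature(pair$A, pair$B)
res
#> SignatureResult: 10-gene signature (5 protective, 5 risky)
#>   genes: g0129, g0167, g0187, g0270, g0299, g0307, g0324, g0418, g0466, g0471
#>   R-squared: 0.937 / 0.939

logrankTest(survTime(pair$A), survEvent(pair$A),
            groupLabels(res@groups$A))
#> Log-rank test: chi2 = 207.1078 on 1 df, p = 5.873e-47

timeDependentAuc(res@riskScores$A, survTime(pair$A), survEvent(pair$A),
                 horizon = median(survTime(pair$A)))
#> TimeROC at horizon 1.788: AUC = 0.9798 (301 curve points)
```

The derived signature here is exactly the 10 planted genes
(`geneTruth(pair$A)` confirms), the per-cohort R-squared of the step-3
fit is ~0.94, the median split separates survival with log-rank
chi2 = 207, and the risk score discriminates death by median follow-up
with AUC 0.98.

A thin command-line wrapper (`inst/scripts/rwsr`) exposes `simulate`,
`screen`, `fit`, `run` and `evaluate` subcommands over the same
functions; `runPipeline()` / `runFromManifest()` write deterministic
TSV/JSON outputs that reproduce byte-identically from the saved
manifest.

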
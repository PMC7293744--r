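---
title: "Risk-weighted sparse regression for prognostic gene signatures"
author: "rwsr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-weighted sparse regression for prognostic gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given genome-wide expression profiles and right-censored overall-survival
data for two independent patient cohorts, we want a small, robust set of
genes whose expression predicts prognosis in *both* cohorts, together
with a per-patient risk score that stratifies patients into clinically
meaningful risk groups. Single-cohort feature selection on thousands of
genes is fragile: univariate screens admit false positives, penalized
fits are sensitive to outlying patients, and a signature tuned to one
platform rarely transfers to another. The workflow implemented here
addresses all three concerns: a per-cohort screen with a cross-cohort
candidate intersection, a robust (L1-loss, leverage-weighted) sparse
regression, and a final intersection of the two cohorts' sparse
supports.

## The three-step model

**Step 1 — univariate Cox screen.** For each gene $g$ the Cox
proportional-hazards model
$h(t \mid x_g) = h_0(t)\, e^{\beta_g x_g}$
is fit by maximizing the Breslow partial likelihood
$$\ell(\beta) = \sum_{i:\,\delta_i = 1}\Big(\eta_i -
\log \!\!\sum_{j \in R(t_i)} \!\! e^{\eta_j}\Big), \qquad
R(t) = \{j : t_j \ge t\},$$
with Newton-Raphson and step-halving (convergence at max
$|\text{score}| < 10^{-8}$ within 50 iterations; monotone likelihoods
are reported unconverged with the coefficient capped). Genes with
hazard ratio $\mathrm{HR} = e^{\hat\beta} < 1$ and Wald $p < \alpha$
are *protective*; $\mathrm{HR} > 1$ and $p < \alpha$ are *risky*; the
rest are nonassociated. The default $\alpha = 0.01$ is the conventional
screen cutoff for this design. Candidates are then intersected across
cohorts by direction: `com_prot` (protective in both) and `com_risk`
(risky in both); a gene with inconsistent direction is discarded.

**Step 2 — risk scores and risk probabilities.** Over a set of screened
genes, patient $i$ gets the risk score $rs_i = \sum_g x_{ig}\hat\beta_g$
and the risk-probability vector
$rp_{ig} = x_{ig}\hat\beta_g / rs_i$, the fractional contribution of
each gene to the patient's score. Rows of $rp$ sum to 1 by
construction; components may be negative or exceed 1 under mixed-sign
contributions. When $|rs_i|$ falls below $10^{-8}$ the ratio is
undefined; such patients are flagged degenerate and excluded from the
step-3 design rather than imputed.

**Step 3 — robust sparse regression (WLAD-SCAD).** With design
$z_{ig} = rp_{ig} x_{ig}$ and response $rs_i$, the coefficients
minimize
$$Q(\gamma) = \sum_i \omega_i\,\bigl|rs_i - z_i^\top\gamma\bigr|
  + n \sum_j p_\lambda(|\gamma_j|),$$
where $p_\lambda$ is the SCAD penalty (shape $a = 3.7$, the Fan–Li
convention) and the observation weights $\omega$ downweight
high-leverage patients: features are min-max normalized to $[0,1]$,
each patient's Euclidean distance from the feature-wise median is
computed, the $\lfloor 0.6\,n \rfloor$ least-distant patients form a
clean subset $X_S$, and
$\omega_i = \min_j h_j / h_i$ with
$h_i = x_i (X_S^\top X_S)^{-1} x_i^\top$
(Moore–Penrose pseudo-inverse when the subset Gram matrix is
singular). The L1 loss plus the leverage weights make the fit resistant
to both response outliers and design outliers. The support of
$\hat\gamma$ — coefficients with $|\gamma_j| \ge 10^{-4}$ — is the
cohort's candidate signature; the final signature is the intersection
of the two cohorts' supports.

The signature is then assessed per cohort: a multivariate Cox fit on
exactly the signature genes gives the prognostic risk score
$\sum_g x_{ig}\hat\gamma_g$, the median split defines high/low risk
groups (ties at the median go to low risk — an arbitrary but
deterministic convention), and Kaplan-Meier/log-rank, time-dependent
ROC, stratified comparisons and the stage-by-risk eight-group
assignment quantify its prognostic value.

## Design choices that were genuinely open

**Per-direction step-3 fits.** The step-3 regression is run separately
on the common protective candidates and the common risky candidates,
per cohort, and the cohort's support is the union. Two reasons. First,
within a single-direction gene set all contributions $x_{ig}\beta_g$
share a sign, so on a positive expression scale the risk score is
bounded away from zero and the risk probabilities are well behaved;
over a mixed union the score crosses zero for many patients, the ratio
$x\beta/rs$ explodes, and the regression degenerates (we observed
goodness-of-fit values hundreds of units below zero and near-total loss
of the planted signal when fitting the union). Second, the
direction-resolved gene accounting that motivates this workflow tracks
protective and risky survivors separately through step 3, which is only
possible if the fits are direction-resolved.

**Goodness of fit.** The reported $R^2$ per cohort compares the step-3
fitted values against the actual risk scores, pooling residual and
total sums of squares over the two direction fits with each direction
centered on its own mean. Pooling raw values instead would inflate
$R^2$ toward 1 purely because protective and risky scores sit on
opposite sides of zero. Under the default simulation conditions the
value is about 0.93-0.94, and it is a property of the fitted regression
(for non-least-squares fits it can in principle be negative).

**AUC horizon.** The time-dependent ROC (cumulative cases, dynamic
controls, IPCW weights from the Kaplan-Meier estimate of the censoring
distribution) requires an evaluation horizon. No defensible default
exists — the choice is clinical — so the horizon is a required
argument; the acceptance script uses the median follow-up time.

**Log-rank and tie handling.** Kaplan-Meier and the log-rank statistic
are computed through the `survival` package (`survfit`, `survdiff`);
ties are handled in the Breslow convention throughout, matching the Cox
engine.

## The synthetic-cohort generator

The generator emulates the structure of a two-cohort expression/survival
study: $p$ genes $\times$ $n$ patients, a shared sparse set of planted
protective and risky genes, exponential survival with hazard
$h_0 \exp(\sum_g \beta_g x_g)$ driven only by the planted genes, and
independent Uniform$(0, H)$ right-censoring. Paired cohorts share the
planted truth but draw independent noise. Defaults — $n = 300$,
$p = 500$, five protective genes at $\beta = -1$ and five risky at
$\beta = +1$, baseline hazard $0.1$ per time unit, censoring horizon
$10$, expression $\mathcal{N}(6, 1)$ — are the study conditions the
package is validated under, chosen once: the expression model mimics a
positive log2-microarray-like scale (location does not affect the Cox
screen, which is shift-invariant, but positivity matters for the
step-2/3 risk-probability construction), and the hazard/censoring pair
yields roughly 60-70% observed events.

What the generator does *not* emulate: probe/batch effects, library-size
normalization, platform differences between cohorts, correlated gene
modules, or covariate-outcome confounding (age, sex, stage, grade and
invasiveness are generated independent of survival). Passing tests
therefore demonstrate the statistical machinery under a clean sparse
proportional-hazards truth, not robustness to real-data artifacts.

## Numerical choices

* **Inner solver.** Each LLA (local linear approximation) outer
  iteration replaces the SCAD penalty by the ridge-form tangent
  $n\,p'_\lambda(|\gamma_j^{(k)}|)/(2|\gamma_j^{(k)}|)\,\gamma_j^2$ and
  solves the weighted-LAD subproblem by IRLS on the smoothed absolute
  value $\sqrt{r^2 + \varepsilon^2}$, $\varepsilon = 10^{-6}$ (at most
  200 inner iterations, tolerance $10^{-8}$).
* **Exact LAD finish.** For the unpenalized problem ($\lambda = 0$) the
  IRLS solution is refined by simplex-style vertex descent — a
  weighted-LAD optimum interpolates $p$ observations, so the solver
  walks from vertex to vertex along improving edges until none remains.
  This closes the $O(n\varepsilon)$ smoothing gap and is verified in
  the tests against an independent all-subsets vertex enumeration.
* **Monotonicity guard.** The exact SCAD objective is evaluated after
  every outer iteration; a step that would increase it is rejected and
  the previous iterate kept, so the recorded objective trace is
  non-increasing by construction (LLA is a
  majorization-minimization scheme, so rejections are rare).
* **Support threshold.** IRLS never produces exact zeros; coefficients
  with $|\gamma_j| < 10^{-4}$ are hard-set to zero and frozen.
  Coefficients at zero have an unbounded ridge weight and stay frozen.
* **Penalty grid.** 30 log-spaced points over
  $[0.01\,\lambda_{\max}, \lambda_{\max}]$ with
  $\lambda_{\max} = \max_j |z_j^\top y| / n$; $\lambda$ is selected by
  $\mathrm{BIC}(\lambda) = n \log(\overline{\omega|r|}) + \log(n)\,
  |\mathrm{support}|$, ties broken toward the sparser (larger)
  $\lambda$. The selection is invariant to grid ordering.
* **Tie rules.** Clean-subset selection breaks distance ties by
  original row index; the median split sends ties at the cutoff to the
  low-risk group; screens order output by gene id. Together with the
  absence of any RNG downstream of the generator, the whole pipeline is
  deterministic: rerunning from a saved manifest reproduces outputs
  byte-identically.
* **Degenerate inputs.** Zero-variance genes classify as nonassociated;
  constant design features abort min-max normalization with the feature
  named; zero-leverage rows get weight 1 with a warning; fewer than 10
  usable patients abort the step-3 fit; an empty candidate intersection
  or an empty support intersection raises an error naming the stage.

## Validation problem sizes

The test-suite checks run at deliberately modest sizes: grid-search Cox
oracles at $n \le 8$ with a $10^{-4}$-step grid; the LAD LP oracle on
50 instances up to $n = 40$, $p \le 5$; the null screen at 5,000 genes
and $n = 200$; effect recovery over 200 replicates at $n = 300$; and
signature recovery over 20 paired replicates at the default study
conditions. The acceptance script (`scripts/acceptance.R`) recomputes
the same quantities at 10 paired replicates and writes them as JSON.

## Example

```{r example}
library(rwsr)
pair <- simulatePairedCohorts(simulationConfig(seed = 1))
res <- deriveSignature(pair$A, pair$B)
res
supportGenes(res)
res@rSquared

co <- pair$A
lr <- logrankTest(survTime(co), survEvent(co),
                  groupLabels(res@groups$A))
roc <- timeDependentAuc(res@riskScores$A, survTime(co), survEvent(co),
                        horizon = median(survTime(co)))
```

## Known limitations

* Breslow tie handling only (no Efron correction); no time-varying
  covariates, stratified baselines or frailty terms in the Cox engine.
* The step-3 regression models the risk score, not the survival outcome
  directly; its selection behavior inherits whatever biases the
  univariate screen introduces into $\hat\beta$.
* $\lambda$ selection is BIC over a fixed grid; cross-validation is out
  of scope.
* Cross-cohort normalization is the user's responsibility: the two
  cohorts are screened independently, and only directions and supports
  — never coefficients — are compared across them.
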
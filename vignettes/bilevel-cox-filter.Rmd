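---
title: "Bi-level Cox-filter selection: model, procedures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-level Cox-filter selection: model, procedures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-small cell lung cancer has two major histological subtypes,
adenocarcinoma (AC) and squamous cell carcinoma (SCC), which are
increasingly treated as distinct diseases. A gene may carry prognostic
information in one subtype and not the other, and genes act in concert
within pathways. `bilevelcox` selects prognostic features at two levels
— gene sets and the genes within them — separately for each subtype,
from three inputs: a genes-by-samples log2 expression matrix, a clinical
table (follow-up time, death indicator, subtype), and a GMT gene-set
collection.

## The per-gene Cox-filter model

For each gene the package fits a Cox proportional hazards model with
three covariates: the subtype indicator, the gene's expression, and
their interaction,

$$\lambda_i(t) = \lambda_0(t)\,\exp\{\beta_1 I(j_i = \mathrm{SCC}) +
\beta_2 X_{i} + \beta_3 X_{i} I(j_i = \mathrm{SCC})\}.$$

The subtype-specific effects are $\beta_{AC} = \beta_2$ (change in log
hazard rate per expression unit among AC patients) and
$\beta_{SCC} = \beta_2 + \beta_3$. A gene with $\beta_{AC} \neq 0$,
$\beta_{SCC} = 0$ is AC-specific, and vice versa. Both effects are
tested with two-sided Wald tests; the SCC variance is
$\mathrm{var}(\hat\beta_2) + \mathrm{var}(\hat\beta_3) +
2\,\mathrm{cov}(\hat\beta_2, \hat\beta_3)$, read off the inverse
information matrix. Wald rather than likelihood-ratio tests are used
because $\beta_{SCC}$ is a linear combination whose variance the fit
already provides.

Numerical choices:

* maximum partial likelihood with the Efron approximation for tied
  event times (the default of mainstream survival software; the
  estimation itself is delegated to the `survival` package's fitter);
* Newton–Raphson convergence at relative log-partial-likelihood change
  $< 10^{-9}$ or 50 iterations;
* a gene whose fit is degenerate (constant expression, separation or
  monotone likelihood, non-finite information) is flagged
  `converged = FALSE` and assigned $p_{AC} = p_{SCC} = 1$, so a
  genome-wide scan always completes and such genes are never selected;
* a cohort with no observed death is an error — the partial likelihood
  is undefined.

P-values are adjusted per subtype with Benjamini–Hochberg step-up FDR
control (Bonferroni available behind a flag). BH was adopted because
the selection cutoffs are FDR-scale quantities throughout.

## The sign-average risk profile

Within each gene set and subtype, genes are split by the sign of their
estimated subtype effect into a *hazardous* group $H$ (higher
expression, higher hazard, $\hat\beta > 0$) and a *preventive* group
$P$ ($\hat\beta \le 0$; an exact zero — a measure-zero event — goes to
$P$ by convention). The per-patient, per-set risk summary is the sign
average

$$Z_{ik} = \frac{\sum_{l \in H} X_{il} - \sum_{l \in P} X_{il}}
{|\text{considered}|},$$

where *considered* is the set's genes that are present in the data and
have a converged fit (the denominator counts only those). Each patient
is summarised with the grouping of their *own* subtype, since a gene
can be hazardous in one subtype and preventive in the other. A set
with no considered gene is dropped from the profile, never
zero-filled.

When a selection is applied to held-out or test samples, both the
groupings and any downstream coefficients are frozen from the training
data; re-estimating them on the scored samples would leak outcome
information.

## Forward and backward bi-level selection

Both procedures apply the same three-covariate Cox model twice — once
with genes, once with gene sets (the sign average $Z$ standing in for
expression) — and differ only in the order.

**Forward** (sets first): compute $Z$ over *all* genes of every set;
fit the set-level model; BH-adjust across sets per subtype and keep
sets with $q \le \alpha_{set}$; then, among the genes belonging to the
kept sets, re-adjust the gene-level p-values *within that restricted
family* and keep genes with $q \le \alpha_{gene}$. The restricted
family is used because the second test family is explicitly
conditional on the first step; a flag switches to genome-wide
q-values.

**Backward** (genes first): candidate genes are those with genome-wide
$q \le \alpha_{gene}$; $Z$ is recomputed over candidates only (sets
without candidates drop out); set-level fits and BH keep sets with
$q \le \alpha_{set}$; the final genes are the candidates contained in
the kept sets.

In backward mode the candidate filter of the subtype being selected is
applied to all patients when building $Z$ (one profile per subtype
run), while each patient keeps the hazard grouping of their own
subtype. The source methods leave this unspecified; one filter per run
keeps the set-level model a single, well-defined fit over the whole
cohort.

With every gene in its own singleton set and equal cutoffs, the two
directions provably coincide with plain genome-wide per-gene
thresholding — a degenerate configuration the test suite asserts.

### Tuning the cutoffs

Both cutoffs live on the grid {0.01, 0.05, 0.1, 0.15, 0.2} and are
tuned jointly over the 25 pairs by stratified 10-fold
cross-validation (folds stratified on subtype × event so deaths are
spread evenly). The objective had to be chosen here: for each fold and
pair, the full procedure runs on the training folds, each held-out
patient is scored with

$$\hat g(X_i) = \sum_{k \in \text{selected sets}}
\hat\beta_{j(i),k} \, Z_{ik},$$

with slopes and groupings frozen from training, and the
censoring-adjusted concordance is computed per subtype on the
validation fold ($\tau$ fixed at the 90th percentile of the training
follow-up). The chosen pair maximises the mean held-out C per subtype;
ties within $10^{-12}$ go to the smallest $(\alpha_{set},
\alpha_{gene})$ lexicographically (parsimony). A fold with an empty
selection contributes C = 0.5: an empty signature is exactly a random
guess. A flag ties the two cutoffs equal (5-point grid).

## Evaluation metrics

**Censoring-adjusted concordance.** Over the window $(0, \tau)$, pairs
$(i, j)$ with an observed death $T_i < \min(T_j, \tau)$ count as
concordant when the earlier death has the higher risk score (tied
scores ½), each pair weighted by $1/\hat G(T_i^-)^2$ with $\hat G$ the
Kaplan–Meier estimator of the censoring distribution — the inverse
probability of censoring weighting that removes the estimand's
dependence on the censoring pattern. Defaults chosen here: $\tau$ at
the 90th percentile of follow-up (configurable; the estimator degrades
where $\hat G$ is tiny), and $\hat G$ floored at 0.05 to bound the
weights in small samples. Standard errors by nonparametric bootstrap
over samples (200 resamples, seeded).

**Stability (Rand) index.** With $k \ge 2$ repeated runs (e.g. CV
folds) producing feature lists $gs_1, \dots, gs_k$, stability is the
mean pairwise Jaccard overlap $|gs_i \cap gs_j| / |gs_i \cup gs_j|$,
at the gene level and, with lists of set names, at the pathway level.
Conventions for degenerate pairs: two empty lists agree perfectly (1);
empty versus non-empty is 0.

## The simulation framework

The generator emulates the statistical structure the selection methods
are sensitive to, not any particular platform:

* genes partitioned into `n_sets` blocks (default 100 sets of 10);
  within a block each gene is $\sqrt\rho F_k + \sqrt{1-\rho}\,
  \varepsilon$ with a shared standard normal factor per sample, giving
  mean 0, unit variance and within-set correlation $\rho$ (default
  0.5) — within-set correlation is the key feature, since it is what
  separates bi-level from per-gene selection;
* four planted prognostic genes named after the markers used in the
  motivating study — `COPA`, `ECE2`, `SMAD4` sharing one set, `ARRB1`
  in another;
* two scenarios: *exclusive* (AC and SCC have disjoint prognostic
  genes: `ARRB1`, `ECE2` for AC; `COPA`, `SMAD4` for SCC) and *shared*
  (all four act identically in both subtypes);
* effect magnitude $|\beta| = 1.5$ by default (strong; 0.5 for
  moderate). Signs are aligned for genes acting in the same subtype
  within the same set: with block correlation, opposing signs inside a
  set cancel through the shared factor and would erase the marginal
  effect the scenario means to plant;
* survival by inverse transform from an exponential baseline
  ($\lambda_0 = 0.1$): $T_i = -\log U_i / (\lambda_0 e^{\eta_i})$ with
  $\eta_i$ the subtype-specific linear predictor over the causal
  genes; censoring times exponential with the rate root-found so the
  expected censored fraction equals the target (default 30%);
* cohort sizes default to 70 AC + 55 SCC, the sizes of a typical
  early-stage two-subtype RNA-seq cohort.

The replicate harness draws fresh training and independent test
cohorts per replicate, applies each selection method, and aggregates
selection sizes, per-causal-gene selection frequencies, mean test-set
concordance with its standard error across replicates, and the
stability index across the replicate selections. The *null* harness is
identical except every causal effect is zero, so survival is
independent of expression and any selection is a false positive; a
permutation-style null (shuffling survival against expression) is the
natural alternative but breaks the marginal survival distribution, so
the at-source null was preferred.

What the generator does **not** emulate: RNA-seq count noise (the
methods consume continuous log-scale values), overlapping gene sets
(blocks partition the genome), platform effects, and real
gene–gene correlation beyond the single-factor block structure.
Passing tests therefore demonstrate correctness of the procedures and
their qualitative behavior under block correlation — not performance
on any specific real cohort.

## Problem sizes used in the shipped checks

The package's automated checks run the oracle comparisons on cohorts
of 14–30 samples (where brute-force partial-likelihood maximisation is
exact and fast), the calibration and random-guess benchmarks on 50–100
replicates of 200–300-sample cohorts, and the recovery contrast on 50
replicates of a 300-sample cohort with the default 100-set genome.
These sizes were chosen to make every check a routine desk-scale run
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* Only two subtypes are supported; the interaction parameterisation is
  specific to a binary subtype indicator.
* No additional clinical covariates inside the screening model
  (confounder adjustment is a downstream analysis on the risk score).
* The set-level model inherits the sign-average's equal-weight
  assumption — a set whose genes act with heterogeneous magnitudes is
  summarised crudely.
* Cross-validated concordance on small validation folds is noisy; the
  tuning objective averages over folds but remains a high-variance
  criterion, which is inherent to the design, not the implementation.
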
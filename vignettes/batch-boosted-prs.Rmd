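---
title: "Batch-screened boosting for polygenic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-screened boosting for polygenic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsboost)
```

## The model

A polygenic risk score (PRS) is a weighted sum of allele dosages. For $n$
individuals and $p$ genetic variants with dosage matrix
$\mathbf{X} = (x_{ij}) \in [0,2]^{n \times p}$ (the count of the designated
effect allele), the package fits the linear model

$$\mathrm{E}[y_i \mid \mathbf{X}] = \beta_0 + \sum_{j=1}^p \beta_j x_{ij},$$

seeking a *sparse* $\hat\beta$ that minimizes the mean squared error of
prediction (MSEP) on held-out samples. For binary traits the same linear
predictor enters a logistic model,
$\mathrm{logit}\,P(y_i = 1 \mid \mathbf{X}) = \beta_0 + \sum_j \beta_j x_{ij}$,
and the fitting criterion becomes the mean log loss
$-\tfrac1n\sum_i [y_i \ln \hat p_i + (1-y_i)\ln(1-\hat p_i)]$.

In genome-scale data both $n$ and $p$ are large and $p \gg n$ is common, so
neither ordinary least squares nor naive penalized fits on the full matrix
are practical. The package's approach is *component-wise gradient boosting*
made tractable by *correlation-driven batch screening*.

## The algorithm

Starting from prediction $\hat y^{(0)} \equiv 0$, classical component-wise
boosting repeats: compute the negative gradient $u^{(m)}$ of the loss at the
current prediction (for squared error, simply the residuals); fit a simple
linear base-learner $h_j(X_j) = \beta_0 + \beta_j X_j$ of $u^{(m)}$ on every
variant; select the best-fitting one — equivalently, the variant with the
largest absolute Pearson correlation to $u^{(m)}$ — and move the
coefficients a fraction $\nu$ (the learning rate) toward that fit. Early
stopping of the iteration count provides implicit regularization and
variable selection.

Scanning all $p$ variants every iteration is the bottleneck. `prs_boost()`
therefore interposes an outer *batch-building* loop:

1. **Screen.** Compute the correlation of every variant with the current
   negative gradient and collect the `p_batch` variants with the largest
   absolute correlation into a batch. Record the largest absolute
   correlation among the *excluded* variants as the batch's threshold
   `c_stop` (sentinel $-\infty$ if the batch holds all variants).
2. **Boost.** Run component-wise boosting within the batch. After each
   step, stop the inner loop if `c_stop` exceeds the best current in-batch
   correlation (some outside variant may now fit better), or after
   `m_batch` steps.
3. **Monitor.** After each batch, evaluate the loss on an independent
   validation set. Stop when it has not improved for `b_stop` consecutive
   batches (or at `b_max` batches / `m_max` total iterations), and return
   the coefficient snapshot from the best-validation batch.

Only the active batch's dosage columns are needed for the inner loop, so
memory scales with $n \cdot p_\text{batch}$ rather than $n \cdot p$.

### The inner stopping comparison

One numerical subtlety deserves a design note. The threshold `c_stop` is
computed once, when the batch is created, and the in-batch correlations it
is compared against are computed later, against a residual whose scale has
shrunk as the inner loop fits. A Pearson correlation divides by the current
residual standard deviation, so comparing a *frozen* threshold with *later*
correlations would systematically inflate the in-batch side and delay the
switch to a new batch. `prsboost` therefore performs the comparison with the
residual standard deviation frozen at batch creation on both sides —
equivalently, on the covariance scale $|\mathrm{cov}(x_j, u)| / \mathrm{sd}(x_j)$.
With this convention a clean theoretical property holds exactly: if the
variant columns are mutually orthogonal, the batched algorithm selects the
same variant as full-data boosting at every single iteration, for any batch
size (the test suite verifies this to machine precision over 200
iterations). Variant *selection* within a step is unaffected by the
convention, since the residual scale is common to all candidates there.

Absolute values are used on both sides of the comparison: selection is by
absolute correlation, so sign-free comparison is the only coherent reading.

### Mandatory covariates

Covariates such as age, sex, or genotype principal components can be
supplied to `prs_boost()`. They are included in *every* base-learner design
and their coefficients move at every step with the same learning rate; they
never compete with the variants for selection and are never screened into
batches. Fitting them inside the boosting loop (rather than regressing them
out afterwards) lets the variant search operate on phenotype variation not
already explained by the covariates. Screening correlations are computed
against the raw negative gradient without pre-residualizing on covariates;
each base-learner's own covariate terms absorb confounding step by step.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `nu` | 0.1 | learning rate; the usual boosting default, small enough to avoid overfitting single base-learners |
| `p_batch` | 1000 | batch size; medium batches balance per-step correlation cost against re-screening frequency |
| `m_batch` | `p_batch` | inner iteration cap per batch; with a small `nu` and the correlation stop this rarely binds |
| `b_max` | 20000 | outer-loop safety cap |
| `b_stop` | 2 | validation patience, in batches |
| `m_max` | unlimited | optional fixed total-iteration budget (required if no validation set is given) |

`b_stop` counts *consecutive* batches without strict improvement of the
running best validation loss. The returned model is the best-validation
snapshot, not the final state, so the `b_stop` overshoot batches never
contaminate the returned coefficients. Validation loss is evaluated once
per completed batch: at very large batch sizes this checkpoint granularity
is coarse, which is why the package's batch-size comparison (below) holds
the total iteration budget fixed instead.

Genotype columns enter unstandardized: Pearson correlation is
scale-invariant for selection and the base-learner slope absorbs scale.
Zero-variance (monomorphic) columns are assigned correlation 0 and can
never be selected.

## Genotype input and the score file

PLINK 1 binary triples (`.bed/.bim/.fam`) are read with a bit-exact 2-bit
decoder; the effect allele is PLINK A1, so dosage is the A1 count and
exported coefficients are signed relative to A1. `filter_variants()`
applies the usual quality filters (folded minor allele frequency and
per-variant call rate; the conventional large-cohort choices are MAF
$\ge$ 0.1% and call rate $\ge$ 90%), and `impute_missing()` replaces
missing dosages by the per-variant mean of the observed genotypes (or by
the reference homozygote, dosage 0). MAF is folded for filtering but
dosages are never flipped.

A fitted model exports via `export_prs()` to a tab-delimited score file —
variant id, chromosome, position, both alleles, coefficient — plus header
lines carrying the intercept and any covariate coefficients: exactly the
information needed to apply the score elsewhere, and nothing
individual-level. Coefficients are serialized at full binary precision so
`import_prs(export_prs(m))` predicts bit-identically. At scoring time an
allele pair that is swapped relative to the model is handled by flipping
the dosage to $2-x$; any other mismatch is an error — no strand-flip
inference is attempted, which is deliberate and conservative.

For LDL cholesterol analyses, `adjust_ldl_statin()` multiplies measured
values by 0.684 for statin users. The literal multiplicative form is
implemented; the opposite convention (dividing to reconstruct an untreated
value) exists in the literature, and the ambiguity is flagged in the
function documentation rather than silently resolved.

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws per-variant effect-allele frequencies
uniformly from `maf_range` (default common variants, frequency 0.01–0.5)
and dosages as Binomial(2, f), optionally with block-structured linkage
disequilibrium: variants within a block share a latent Gaussian factor with
pairwise correlation `ld_rho` and are thresholded to Hardy–Weinberg
genotype frequencies. `simulate_phenotype()` picks `round(s * p)` causal
variants, draws their effects from a standard Gaussian, and adds Gaussian
noise. The noise is drawn, orthogonalized in-sample against the genetic
component, and rescaled so the realized variance ratio
$\mathrm{var}(g)/\mathrm{var}(y)$ equals the target heritability $h^2$
exactly — this makes small-sample simulation studies sharp instead of
adding an extra layer of sampling noise in the signal strength.
`simulate_binary_phenotype()` rescales $g$ so it explains $h^2$ of the
liability variance under a logistic model (residual variance $\pi^2/3$),
solves the intercept by root-finding to hit the target prevalence, and
draws Bernoulli outcomes.

Real cohort data differ in ways the simulator does not attempt to emulate:
population structure and relatedness, ascertainment, long-range and
irregular LD, frequency-dependent effect sizes, imputation dosage
uncertainty. Passing simulation tests therefore demonstrates algorithmic
correctness and statistical behaviour under the stated generative model,
not performance guarantees on any particular biobank. Effect sizes are
unscaled Gaussians (they do not shrink with allele frequency); this is a
simple, documented choice, and the selection metrics should be read with it
in mind.

## Numerical choices

* Probabilities inside the log loss are clipped to $[10^{-12}, 1-10^{-12}]$
  so saturated linear predictors give finite loss without materially
  altering gradients.
* All losses use the mean convention, making validation losses comparable
  across sample sizes.
* Ties in correlation ranking break toward the lowest variant index,
  everywhere, so fits are fully deterministic; identical inputs give
  bit-identical paths.
* Zero-variance residuals or columns map to correlation 0, never `NaN`; an
  all-zero screening round falls back to the first `p_batch` variants with
  a warning.
* Base-learners use the closed-form simple-regression solution when no
  covariates are present and a QR least-squares solve otherwise, with an
  explicit rank check naming the collinear column.
* The R-squared reported by `prediction_metrics()` is the squared Pearson
  correlation between prediction and phenotype (the PRS-field convention,
  affine-invariant); the $1-\mathrm{SSE}/\mathrm{SST}$ variant is also
  returned as `r2_sse`. AUC uses the Mann–Whitney midrank form, ties
  counting one half.

## Problem sizes used in the shipped studies

The package's tests and `scripts/acceptance.R` run everything at desk
scale, chosen so the whole suite completes in a few minutes: reduction and
orthogonality identities at $n = 300$, $p \le 150$; ordinary-least-squares
convergence at $n = 300$, $p = 5$, 50,000 iterations; parameter recovery at
$n = 4{,}000$, $p = 2{,}000$, $h^2 = 0.5$, $s = 1\%$, batch size 200,
over 20 simulation replicates (with a pure-noise control arm); the
batch-size comparison on one dataset at a fixed budget of 1,500 iterations
across `p_batch` $\in \{10, 100, 1000\}$ — fixing the budget, rather than
using validation stopping, isolates the effect of batching itself from the
once-per-batch checkpoint granularity; and the binary extension at
$n = 5{,}000$, $p = 1{,}000$, prevalence 0.2, liability $h^2 = 0.5$ over 20
replicates. These sizes are scaled-down analogues of large-cohort designs;
the algorithm itself streams batches and is not limited to them.

## Known limitations

* Boosting provides no closed-form standard errors or confidence intervals
  for the selected coefficients; the package deliberately does not invent
  any.
* Only linear, additive, single-variant base-learners are implemented — no
  dominance/recessive codings, interactions, or smooth effects.
* Losses are limited to squared error and log loss; count and
  time-to-event outcomes are out of scope.
* The PLINK reader supports PLINK 1 `.bed` (SNP-major) only — not PLINK 2
  `.pgen`, BGEN or VCF dosages.
* Duplicate variant identifiers are rejected outright rather than
  deduplicated or merged.
* Whether to standardize genotypes before fitting is a genuinely open
  choice; this implementation fits unstandardized dosages (selection is
  scale-free either way), and users comparing against pipelines that
  standardize should expect coefficient-scale differences.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n = 2000, p = 500, h2 = 0.5, s = 0.02, seed = 42)
G <- simulate_genotypes(cfg)
sim <- simulate_phenotype(G, cfg)
idx <- split_samples(cfg$n, cfg$split, seed = 42)
y <- sim$phenotype$pheno

fit <- prs_boost(G[idx$train, ], y[idx$train],
                 G[idx$validation, ], y[idx$validation],
                 control = boost_control(p_batch = 100))
glance(fit)
prediction_metrics(y[idx$test], predict(fit, G[idx$test, ]))
selection_metrics(fit, sim$truth)
autoplot(fit)                  # validation-loss trajectory
```
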
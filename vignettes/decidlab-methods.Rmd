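---
title: "Models and methods behind decidlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind decidlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

decidlab analyses case-control menstrual-effluent (ME) studies through
three tracks — cytometry composition, decidualization time courses, and
qPCR relative quantification — plus a synthetic-data generator that makes
every stage testable without subject-level data. This vignette documents
the models, the priors and tunable parameters, the numerical choices, and
the places where the design was genuinely open.

## Cytometry composition

### Normalization

Viable-cell counts live on a fixed gating tree. Rather than dividing every
population by total cells, each population is expressed as a fraction of
its designated *parent* gate: CD66b+ and CD66b− of CD45+; monocytes, T
cells, B cells and uterine NK (uNK) cells of the CD45+CD66b− compartment;
epithelial, endothelial, double-negative and SFC populations of CD45−.
Normalizing the lymphoid/monocyte subsets to CD66b− insulates them from
the highly variable granulocyte content of ME (granulocytes survive
collection poorly, so their fraction says more about sample handling than
about biology). A fraction whose denominator is zero or was not acquired
is recorded as *absent* (`NA`), never as 0, and the affected sample is
excluded from that population only.

The uNK denominator is the total CD66b− count, including the
CD14+/CD20+/CD3+ events themselves; whether those should be excluded from
the denominator is not determined by the gating scheme, and using the
total keeps all four subset fractions on a common, directly interpretable
scale.

### Mixed model

Each population is analysed separately (no pooling across populations).
For sample $i$ of subject $s$:

$$y_{is} = \beta_0 + \beta_1\,\mathrm{group}_s + \beta_2\,\mathrm{day}_{is}
  + \beta_3\,\mathrm{tod}_{is} + b_s + \varepsilon_{is},\qquad
  b_s \sim N(0,\sigma_b^2),\ \varepsilon_{is} \sim N(0,\sigma_e^2)$$

with collection covariates *day the collection started* (day 0 vs day
1–2 of menses) and *time of day* (evening vs overnight) as two-level
factors. The subject random intercept absorbs the correlation between
repeated collections (multiple cups, multiple cycles) from one subject; a
cycle-within-subject intercept is available via
`randomEffects = "subject_cycle"` when several samples per cycle exist.

Estimation is REML: for a given variance ratio
$\theta = \sigma_b^2/\sigma_e^2$ the restricted likelihood is profiled
analytically over the fixed effects and $\sigma_e^2$, and the 1-D (or 2-D,
with the cycle term) maximization over $\log\theta$ is done numerically,
always comparing against the boundary $\theta = 0$. The test suite checks
the optimum against a brute-force grid search on the error-contrast
likelihood and against lme4 on repeated-measures data.

**Inference for the group effect** uses the Wald statistic referred to a
$t$ distribution with residual degrees of freedom $n - \mathrm{rank}(X)$.
With the subject variance constrained to zero and no covariates this is
*exactly* the classical pooled-variance two-sample $t$ test, which is the
behaviour we want the model to collapse to; a plain normal reference
would lose that equivalence and be anti-conservative at these sample
sizes (around 22 samples). No Satterthwaite or Kenward-Roger correction
is applied — at one sample per subject the residual-df $t$ is exact, and
with few repeated samples it errs slightly anti-conservative; the
acceptance checks verify that the realized type-I rate at 0.05 stays
within [0.02, 0.09] under the null generator.

Fractions can be transformed (`none`, `log`, `arcsine_sqrt`). The default
is `none`: transformed and raw analyses rarely differ qualitatively for
these data, and raw fractions are easiest to interpret; `log` requires
strictly positive fractions and refuses zeros rather than silently
offsetting them. Per-population p-values are reported without multiplicity
correction — the screen is descriptive, population by population — but
`screenReport()` adds a Bonferroni column for transparency.

## Hierarchical decidualization model

### Model

IGFBP-1 (ELISA, normalized to lysate protein, hence strictly positive) is
log-transformed — the raw scale is strongly heteroscedastic, with
variability growing with the mean as cAMP induction proceeds. For
measurement $i$ in cell (treatment $t$, time $\tau$), case indicator
$g_i$, subject stratum $s(i)$:

$$\log y_i = \mu_{t\tau} + \delta_{t\tau}\, g_i + b_{s(i)} + \varepsilon_i,
\qquad b_s \sim N(0, \sigma_b^2),\ \varepsilon_i \sim N(0, \sigma_e^2)$$

$$\mu_{t\tau}, \delta_{t\tau} \sim N(0, s_{\mathrm{fixed}}^2),\qquad
  \sigma_b, \sigma_e \sim \mathrm{half\text{-}N}(s_{\mathrm{sd}})$$

Defaults $s_\mathrm{fixed} = 10$ and $s_\mathrm{sd} = 5$ are weakly
informative for log-scale protein data (log responses of magnitude a few
units); both are configurable, and $s_\mathrm{fixed} = \infty$ gives flat
fixed-effect priors.

Two genuinely open design points, both resolved as explicit options:

* **Subject coding.** "Subjects nested within treatments at each time
  point" can mean an independent subject effect per (subject, treatment,
  time) stratum (our default, `coding = "nested"`) or one intercept per
  subject reused across all cells (`coding = "shared"`). Both are
  implemented; neither is asserted as *the* original analysis. Under the
  nested coding with one well per cell, $\sigma_b$ and $\sigma_e$ are only
  jointly identified (each stratum holds a single observation), which is
  harmless for $\delta$ — only $\sigma_b^2 + \sigma_e^2$ enters its
  marginal posterior — and is handled by the sampler blocking below.
* **Granularity of the group effect.** The default is one $\delta_{t\tau}$
  per (treatment, time) cell, matching the per-condition reporting of the
  assay; `pooledDelta = TRUE` fits a single shared effect instead.

"Posterior probability of the group effect being zero" is operationalized
as the pair of tail probabilities $\Pr(\delta \ge 0)$ and
$\Pr(\delta \le 0)$ over the kept draws (a continuous prior puts zero mass
on $\{0\}$; draws exactly at zero count in both tails, so the pair sums to
at least 1). Under the null the smaller tail behaves like half a
two-sided p-value, which the acceptance checks verify by simulation.

### Sampler

The posterior is sampled by Gibbs over conditionally conjugate blocks —
a deliberate replacement of gradient-based Hamiltonian samplers: every
block has a closed form, the chain is deterministic given the seed, and
each block can be tested against analytic oracles. The scan is:

1. $(\mu_{t\tau}, \delta_{t\tau})$ jointly per cell from their bivariate
   normal conditional. Under the nested coding the subject effects are
   first integrated out analytically (the marginal covariance stays
   diagonal, with variance $\sigma_b^2 + \sigma_e^2$), which removes the
   ridge between cell parameters and per-stratum effects; $b$ is redrawn
   conditionally afterwards, so the pair of steps is an exact joint draw.
2. $(\sigma_b, \sigma_e, b)$. Under the nested coding the marginal
   likelihood and the equal-scale half-Normal priors both depend on
   $(\sigma_b, \sigma_e)$ only through $\sigma_M^2 = \sigma_b^2 +
   \sigma_e^2$, so in polar coordinates $\sigma_M$ follows a univariate
   marginal posterior — sampled with a slice step on $\log\sigma_M$ —
   and the angle is uniform on $(0, \pi/2)$; $b$ is then redrawn from its
   normal conditional. This makes the weakly separated SD pair mix as
   fast as the identified quantities. Under the shared coding (or when a
   SD is fixed) the SDs get individual slice steps on $\log\sigma$, whose
   half-Normal priors are not conjugate; the slice sampler
   (stepping-out + shrinkage) is exact and tuning-free.

Defaults: 4 chains from dispersed data-based starts, 4000 iterations,
2000 burn-in, no thinning — desk-scale (a few seconds per fit) with
effective sample sizes in the thousands. Convergence is monitored by
split-$\hat R$ (threshold 1.05) and effective sample size for every
parameter; a fit that fails the threshold is returned *with a prominent
warning* and a `converged = FALSE` flag, and `runPipeline(strict = TRUE)`
turns that into an error.

Numerical choices worth knowing:

* the SD samplers are floored at $\sigma \ge 10^{-8}$: data with zero
  variation otherwise push $\sigma_e$ into a non-integrable spike at 0
  where group-effect draws degenerate into floating-point noise;
* rows are put into a canonical order (treatment, time, subject) before
  indexing, so all results are invariant to input row order;
* natural log is used for the response transform (any base only rescales
  $\delta$);
* chain seeds are derived from the configured seed, so runs are
  bit-reproducible.

`generatedQuantities()` simulates, for every kept draw, a full replicate
dataset from the model at that draw (fresh subject effects and
residuals), and compares replicate cell-by-group means with the observed
ones (central 95% band, coverage flag, posterior-predictive p-style
value).

## qPCR: comparative Ct

Technical replicates are averaged (arithmetic mean of Ct) per sample
before anything else. $\Delta\mathrm{Ct} = \mathrm{Ct}_{\mathrm{target}} -
\mathrm{Ct}_{\mathrm{reference}}$; $\Delta\Delta\mathrm{Ct}$ is taken per
sample against the *mean* $\Delta$Ct of the calibrator samples; fold
change $= 2^{-\Delta\Delta\mathrm{Ct}}$, assuming exact base-2
amplification efficiency (no Pfaffl correction). The calibrator defaults
to the control-group vehicle condition — the natural baseline when case
vs control fold changes are reported per treatment condition — and is
configurable. The whole computation is invariant to plate-wide Ct shifts.

The Mann-Whitney test is implemented exactly: for $n_x + n_y \le 14$ the
permutation distribution of the rank-sum $U$ (mid-ranks under ties) is
enumerated over all $\binom{n_x+n_y}{n_x}$ assignments of the observed
values, so ties are handled by enumeration rather than approximation.
Larger samples use the normal approximation with tie and continuity
corrections. The two-sided p-value doubles the smaller tail (capped at
1, no mid-p) — stated explicitly because two-sided exact conventions
differ between implementations. Because the test is rank-based it applies
unchanged to any two-group continuous comparison (e.g. per-subject gMFI
values); `deltaDeltaCt()` reuses it per condition on the fold changes.

## The synthetic-data generator

The generator exists so that calibration and recovery claims can be made
against a known truth. Its defaults *are* the study conditions the
analyses assume:

* **Decidualization** (`decidSimParams`): 7 + 7 subjects, all 4
  treatments × 3 times, log-scale cell means rising over 6→48 h under
  cAMP above near-flat vehicles (illustrative values, not measured ones),
  case effect $\delta = -0.9$ in every cell, $\sigma_b = 0.4$,
  $\sigma_e = 0.3$. Subject effects are drawn per stratum (nested) by
  default, matching the model's default coding; a shared-per-subject
  option supports sensitivity analyses.
* **Cytometry** (`cytoSimParams`): 14 control vs 8 case subjects; leaf
  compositions Dirichlet-multinomial around a base composition chosen to
  reflect ME (CD45+ ≈ 98% of viable cells, granulocytes ≈ 55% of CD45+,
  T cells the largest CD66b− subset, CD45− ≈ 2% mostly double-negative);
  concentration 50 gives the strong between-sample overdispersion seen in
  such data; the case uNK leaf proportion is multiplied by 0.5 (set to 1
  for a null generator) and renormalized — which leaves the CD45−
  within-compartment fractions exactly null and perturbs the other
  CD66b− subsets only mildly; optional log-odds shifts attach
  collection-covariate effects. Internal gates are sums of their leaves,
  so the gate-tree invariants hold by construction.
* **qPCR** (`simulateQPCR`): target Ct = reference Ct + base ΔCt (8) +
  2·case + noise (SD 0.3), i.e. a four-fold expression reduction in
  cases, unaffected by condition by default.

What the generator deliberately does **not** emulate: non-normal
measurement error and detection limits of ELISA, gating/compensation
error in cytometry (inputs are post-gating counts), amplification
efficiency ≠ 2 and reference-gene instability in qPCR, and any
correlation between the three readouts within a subject. Passing
calibration tests on generated data therefore shows the *estimators are
correct under their assumed model*, not that the model is right for any
particular real dataset.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations for a
single CPU: the conjugate-oracle check uses 4 chains × 2000 kept draws;
credible-interval coverage uses 50 replicate studies at the full design
(25 in the faster acceptance script); null tail calibration uses 200
(100) replicates with shortened chains (2 × 700, burn-in 200 — tail
estimates need far fewer effective draws than interval endpoints); the
cytometry screen calibration uses 200 (100) simulated studies per
scenario. These are the package's own choices of simulation size, stated
here so results can be reproduced exactly.

## Known limitations

* The mixed-model $t$ reference with residual df is simple and exact only
  in the collapsed case; with many samples per subject a
  Satterthwaite-style correction would be preferable.
* Under the nested coding the $\sigma_b/\sigma_e$ split is informed only
  by the prior; report and interpret $\sigma_M = \sqrt{\sigma_b^2 +
  \sigma_e^2}$ when using one well per (subject, treatment, time) cell.
* The qPCR module implements plain ΔΔCt only (single reference gene, no
  efficiency correction).
* `mannWhitneyExact` enumerates up to $n_x + n_y = 14$ by default;
  beyond that the normal approximation is used even in the presence of
  heavy ties.
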
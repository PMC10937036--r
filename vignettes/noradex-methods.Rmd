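---
title: "Methods: negative-binomial DGE and multi-experiment meta-analysis in noradex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative-binomial DGE and multi-experiment meta-analysis in noradex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

noradex implements the statistical machinery needed to ask, across several
heterogeneous bulk RNA-seq experiments, which genes respond consistently to a
manipulation — the motivating application being the hippocampal transcriptomic
response to noradrenaline released under acute stress, probed by adrenergic
blockers (e.g. propranolol), agonists (yohimbine), and chemo-/optogenetic
stimulation, in both sexes. This vignette documents the models, the
estimators, the numerical choices, and what the simulation-based validation
does and does not establish.

## The count model

Counts for gene $g$ in sample $s$ are modelled as negative binomial,

$$y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
  \mathrm{Var}(y_{gs}) = \mu_{gs} + \phi_g \mu_{gs}^2,$$

with a log link,
$\log \mu_{gs} = o_s + x_s^\top \beta_g$, where the offset
$o_s$ is the log *effective library size* (library size times its TMM
normalization factor) and $x_s$ is the row of a treatment-coded design matrix
(character factors take their alphabetically first level as reference;
factors supplied as R factors keep their own level order). Coefficients are
estimated per gene by iteratively reweighted least squares (IRLS) with the
dispersion held fixed; iteration stops when the maximum relative change of
the linear predictor falls below $10^{-8}$ (at most 100 iterations).
Coefficients live on the natural-log scale internally and are reported as
log2 fold changes.

## Preprocessing

* **Filtering.** Genes with CPM $\ge$ `min_cpm` (default 1, computed on raw
  library sizes) in at least `min_samples` samples (default: the smallest
  group size) are kept. Removed genes are reported, not silently dropped —
  a lowly expressed but interesting gene should be visible as *filtered*,
  not just absent.
* **TMM.** The reference sample is the one whose 75th count percentile (as a
  fraction of its library) is closest to the mean such fraction. Per sample,
  gene-wise log2 ratios of library-normalized proportions (M) are doubly
  trimmed — 30% tails by M, 5% tails by average log2 abundance — and the
  factor is $2^{\bar M_w}$ with inverse-asymptotic-variance weights
  $1/(1/y_s - 1/N_s + 1/y_r - 1/N_r)$; factors are rescaled to geometric
  mean 1. When fewer than 10 genes survive trimming the untrimmed weighted
  mean is used, with a warning.
* **Variance stabilization.** `variance_stabilize()` is `log2(CPM + 4)`.
  Its only consumer is the surrogate-variable SVD, which needs approximate
  homoskedasticity across the expression range — a property the tests check
  directly (variance ratio between expression strata below 3) — not any
  particular parametric transform.

## Dispersion estimation

The Cox–Reid adjusted profile log-likelihood of gene $g$ at dispersion
$\phi$ is the NB log-likelihood at the IRLS-fitted means minus
$\tfrac12 \log\det(X^\top W X)$, $W = \mathrm{diag}(\mu/(1+\phi\mu))$.

* **Common dispersion** maximizes the across-gene sum of APLs over a
  log-spaced grid on $[10^{-4}, 10]$ followed by golden-section refinement
  to relative tolerance $10^{-4}$.
* **Tagwise dispersions** maximize
  $\mathrm{APL}_g(\phi) + (d_0/d_{res}) \cdot \overline{\mathrm{APL}}(\phi)$,
  a weighted-likelihood empirical-Bayes criterion with prior df $d_0 = 10$
  by default. The genewise term is evaluated exactly at every candidate;
  the pooled term is interpolated from a 21-point log-spaced grid by a
  natural cubic spline (it is an across-gene average, hence very smooth).
  All genes run a lockstep golden-section search, so the whole procedure is
  deterministic. $d_0 = 0$ returns genewise maximizers, $d_0 = \infty$ the
  common value.

There is deliberately no dispersion *trend*: common plus tagwise shrinkage
is sufficient for the factorial designs targeted here, and the validation
is by statistical behaviour (type-I error, recovery), not by matching any
other tool gene by gene.

**Which dispersion feeds which test.** The exact test uses the tagwise
estimates. The quasi-likelihood pipelines fit the GLM with the *common*
dispersion and leave gene-level dispersion variability to the
quasi-dispersion: feeding tagwise-shrunk values into the QL fit absorbs that
variability twice, which drives the moment-matched prior df to infinity and
makes the F-test mildly liberal on null data with heterogeneous true
dispersions — the calibration bands enforced in the test suite are met with
the common-dispersion pairing. This division of labour is also how the
quasi-likelihood methodology is meant to be used. `fit_glm()` itself accepts
a scalar, a per-gene vector, or a tagwise object, so either pairing can be
constructed explicitly.

## Testing

* **Two-group exact test.** Counts are proportionally rescaled (and rounded)
  to the geometric mean of effective library sizes. A sum of $n$ iid
  NB$(\mu, \phi)$ variables is NB with mean $n\mu$ and dispersion $\phi/n$;
  conditional on a gene's total, the two-sided "doubletail" p-value sums the
  probabilities of all group-one sums no more probable than the observed
  one. For totals above 10,000 the support is restricted to a window
  carrying all but $\sim 10^{-15}$ of the conditional mass. The reported
  log2FC uses group mean CPMs with prior count 0.125 — display only, never
  part of the test.
* **Quasi-likelihood F-test.** The genewise quasi-dispersion
  $s_g^2 = \text{residual deviance}/d_{res}$ is squeezed,
  $\tilde s_g^2 = (d_0 s_0^2 + d_{res} s_g^2)/(d_0 + d_{res})$, with prior
  df $d_0$ estimated by moment matching of $\log s_g^2$ against the
  scaled-F/log-chi-square theory (Newton inversion of the trigamma
  function); if the moment estimator is not finite, $d_0 = 10$. The
  statistic divides the per-df drop in deviance for the contrast by
  $\tilde s_g^2$ and is referred to $F(d_c,\; d_0 + d_{res})$. Contrasts
  may be coefficient names or arbitrary vectors in coefficient space (the
  reduced design spans the null space of the contrast).

## Multiple testing and the conditional interaction FDR

BH adjustment is the standard step-up procedure. For interaction terms the
package implements a *conditional* FDR: the conditioning set is the set of
genes whose main effect is significant (FDR < `alpha_main`, default 0.05,
the ubiquitous significance level in this setting), and BH is applied to the
interaction p-values restricted to that set with $m = |S|$. Genes outside
the set carry an explicit NA ("not tested") rather than an invented FDR of
1 — the semantics are that the interaction question was only asked of genes
that responded at all.

`shrink_logfc()` is a closed-form normal-prior posterior mean,
$\hat\tau^2 = \max(0, \mathrm{var}(\hat\beta) - \overline{SE^2})$,
$\tilde\beta_g = \hat\beta_g \tau^2/(\tau^2 + SE_g^2)$. It is deterministic
and desk-scale, chosen because its consumer — the sex meta-analysis — only
needs fold-change differences due to noisy coefficient estimates to be
discounted, not a full posterior.

## Surrogate variables and merged analyses

`estimate_surrogate_variables()` residualizes variance-stabilized expression
on the primary design by least squares and takes the top right singular
vectors of the residual matrix — one SVD pass, no iterative reweighting.
SVs are always appended to the design, never substituted for it.
`num_sv()` chooses the number by parallel analysis: residuals are rotated
into an orthonormal basis of the residual subspace (where null rows are
exchangeable, making within-row permutation an exact null), each gene's
entries are permuted independently, and the count of observed singular
values above their per-rank 95% permutation quantile is returned. How many
surrogate variables to keep, and whether to iterate with gene weights, are
free choices in practice; noradex commits to the one-step SVD with a
permutation-selected rank and validates it with batch-recovery and
null-calibration tests.

`combined_response_analysis()` merges experiments on their shared genes,
maps each experiment's group labels onto a common control/response variable,
refilters and renormalizes jointly, estimates SVs fresh on the merged data
(never per experiment), and QL-tests the response coefficient of
`~ response + SVs`. `sex_interaction_meta()` does the analogous merge with
`~ stress * sex + SVs`, tests the interaction under the conditional FDR
rule, and reports shrunken interaction fold changes.

## Cumulative rank aggregation

Within each analysis the gene with the smallest p-value gets rank 1 and the
largest rank N; ranks are summed across analyses, and a low cumulative rank
marks a consistently responsive gene. The gene universe is the
*intersection* of the analyses' genes — with differing filtered backgrounds
that is the only choice keeping ranks comparable. Ties receive average
ranks, which keep the total rank mass invariant. The table carries a log10
column for plotting, and
ordering ties are broken lexicographically by gene id so output is
deterministic.

## Report rules

* `heatmap_scale()`: values inside the central 98% interval (1st–99th
  percentiles, linearly interpolated order statistics) map linearly onto
  the colour range; values outside map ordinally, by within-tail rank, onto
  a small number of slots per tail (proportional to the tail fraction, at
  least one). This keeps rare extreme values from driving the scale while
  preserving monotonicity.
* `sort_rows_by_angle()`: rows are centred, projected onto their first two
  principal axes (each axis oriented so its largest-magnitude loading is
  positive, for determinism), and ordered by `atan2(PC2, PC1)`. A rank-1
  matrix falls back to ordering along the single component.

## The synthetic-data generator

`sim_config()` defaults encode the factorial designs the analyses target:
14,000 expressed genes; a stress × treatment layout with n = 6 per group
(the companion sex design uses n = 5–6); lognormal library sizes with
median 2×10⁷ reads; baseline log2 abundances N(4, 2); dispersions
$a/\mu + b$ with $a = 1$, $b = 0.05$ and lognormal gene noise (log-sd 0.3),
giving a median dispersion near 0.05–0.1 — common bulk-tissue practice, as
per-gene dispersions are not reported for the motivating data; 10% of genes
stress-responsive with |log2FC| ~ |N(1, 0.3)| and random sign; half of the
stress-responsive genes *blocked* (interaction coefficient exactly cancels
the stress effect, so the blocked response is a true null in the treated
condition); sex affecting baseline expression only; the drug alone doing
nothing at baseline; per-batch gene-wise log2 shifts N(0, 0.3) — the
magnitude of processing/batch differences between separately sequenced
experiments, large enough that ignoring them visibly distorts a merged
analysis. Everything above is configurable, including options
(`frac_treatment_de`, `frac_stress_sex_de`) that exist purely to test
false-positive control and interaction power.

What the generator deliberately does **not** emulate: transcript-level
structure, gene–gene correlation, GC/length bias, outlier samples, or
dispersion differences between batches (batch effects are mean shifts only —
sufficient to exercise surrogate-variable correction). Passing tests
therefore demonstrate calibration and recovery under a faithful NB factorial
world, not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* All optimizations are deterministic (grid + golden section); no seeds
  enter estimation, only simulation and the permutation step of `num_sv()`.
* IRLS clamps the linear predictor to ±50 and rescues singular weighted
  information with a tiny ridge; genes with an all-zero design cell are
  flagged `degenerate` but kept.
* Fractional transcript counts are summed per gene, then rounded
  half-to-even — rounding after summation minimizes bias relative to
  rounding each transcript first.
* `p = 1` ties in the exact test use a relative tolerance of $10^{-10}$
  when comparing point probabilities.
* Zero-total genes in the exact test get p = 1 and a prior-count log2FC.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen to make
the statistical assertions sharp while staying fast: 2,000 genes for type-I
calibration and dispersion recovery (n = 6 vs 6, dispersion 0.1), 4,000
genes for the factorial recovery study, 5,000 genes × 6 analyses × 20–50
seeds for rank aggregation, and 1,000–1,200 genes × 2–3 experiments for the
merged meta-analyses. These sizes reproduce the qualitative behaviour of
full-scale (~14,000-gene) runs; the generator defaults remain at full scale.

## Limitations

* The QL moment-matching uses a single pooled prior (no abundance trend),
  and the exact test equalizes libraries by proportional rescaling rather
  than quantile adjustment; both approximations are absorbed by the
  calibration bands the tests enforce.
* The conditional FDR controls the FDR *within the conditioning set*;
  genes outside the set are untested by construction.
* Rank aggregation treats analyses as exchangeable; no weighting by study
  size or quality is attempted.
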
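---
title: "Methods: a methylation classifier of chemoradiotherapy response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a methylation classifier of chemoradiotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methresp)
```

## The problem and the data model

Locally advanced rectal cancer is treated with neoadjuvant
chemoradiotherapy (nCRT) followed by surgery; pathological examination of
the resected specimen then classifies each patient as a complete responder
(pCR, no residual tumour) or incomplete responder (pIR). Because the
response is only known after surgery, a biomarker measurable in the
pretreatment biopsy is the object of interest. `methresp` works with the
standard representation of array methylation data: a probes-by-samples
matrix of beta values — the fraction of methylated signal at a CpG, in
(0, 1) — plus a probe manifest (coordinates, gene-region and CpG-island
context, exclusion flags) and a sample sheet (group: normal tissue NT, pCR,
pIR; preservation FF/FFPE; batch; cohort). The same container carries
bisulfite-pyrosequencing percent methylation on a 0–100 scale; a `scale`
tag keeps the two from mixing silently. Missing values are explicit (`NA`)
and never coerced to zero, because a failed pyrosequencing reaction is not
an unmethylated CpG.

The package assumes its input betas are already normalized and
batch-corrected upstream (the usual minfi/BMIQ/SVA chain); no IDAT or
normalization code is included by design.

## Differential methylation

Each two-group contrast uses a moderated t statistic. Per probe, the pooled
within-group variance $s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom
is shrunk toward a prior $(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
  t_g = \frac{\Delta\beta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to a t distribution on $d_0 + d_g$ degrees of freedom (capped at
the pooled total across probes, the same convention limma's `eBayes` uses).
The prior is fitted by method of moments on $\log s_g^2$, using the
digamma/trigamma moments of the log of a scaled F variable; when the
observed dispersion of the log variances does not exceed what sampling
alone explains, $d_0 = \infty$ and all probes share the mean variance. The
fit is implemented in `fit_variance_prior()` and is checked in the test
suite both against simulated ground truth ($d_0 = 4$ recovered within
$\pm 1$ at 10,000 probes) and against `limma::squeezeVar` on the same
input; $d_0 = 0$ exactly reproduces the ordinary pooled t test, which the
suite verifies against `t.test` to 1e-10.

Two choices deserve a note:

* **Betas, not M-values, by default.** The DM call combines a significance
  threshold with an effect threshold on $|\Delta\beta|$; running the test on
  the same scale as the effect filter keeps the joint criterion coherent.
  M-values (`use_mvalues = TRUE`) are available since their variance is more
  homogeneous, and the reported `delta_beta` stays on the beta scale either
  way.
* **Strict inequalities.** A probe is DM iff $q < 0.05$ and
  $|\Delta\beta| > 0.15$, read literally; a probe at exactly 0.15 is not
  called. FDR is computed per contrast, over testable probes only — probes
  with fewer than two usable samples in a group are excluded from the BH
  denominator and reported.

DM sets from pCR-vs-NT and pIR-vs-NT are partitioned with exact set algebra
(`venn_partition()`); the exclusive compartments characterise each response
group's methylome and supply classifier candidates. `context_summary()`
tabulates direction by gene-region and island context. For the unsupervised
view, `select_variable_probes()` keeps probes with SD > 0.2 (n−1
denominator, strict), and `cluster_samples()` runs average-linkage
agglomerative clustering on the 1 − Pearson-correlation distance — the
convention of the clustering tools traditional in this literature; distance
and linkage are configurable, and determinism follows from `stats::hclust`'s
input-order tie handling. Cluster enrichment for a group uses the two-sided
Fisher exact test (point-probability convention, via `stats::fisher.test`,
pinned in the suite to a full hypergeometric enumeration oracle for all
margins ≤ 12).

## Classifier construction and evaluation

`candidate_probes()` intersects the exclusive DM sets with a raw
p < 0.05, $|\Delta\beta| > 0.15$ screen between pCR and pIR. The
between-class screen deliberately uses unadjusted p: it selects candidates
rather than makes inferential claims, and the downstream cross-validation
is the arbiter. `select_features()` then (1) ranks candidates by
orientation-free Mann–Whitney AUC, keeping the top 10, and (2) removes
redundant probes by forward–backward stepwise OLS of the 0/1 class
indicator (partial-F entry at p ≤ 0.05, removal at p ≥ 0.10 — conventional
statistical-package defaults, configurable, since no canonical values exist
for this step).

The classifier is a diagonal linear discriminant (DLDA): a Gaussian
classifier with shared diagonal covariance and equal priors, reducing to

$$S(x) = \sum_j w_j x_j,\quad w_j = \frac{\mu_{pCR,j}-\mu_{pIR,j}}{s^2_{pool,j}},
  \quad \tau = \sum_j w_j \frac{\mu_{pCR,j}+\mu_{pIR,j}}{2}.$$

Equal priors despite the 11-vs-21 imbalance make $\tau$ a midpoint cut,
matching how published models of this form state their threshold; a
prior-weighted option exists. The test suite proves the decision rule
identical to a brute-force diagonal-Gaussian Bayes oracle on simulated
points. A sample missing any marker is a **no-call**, never imputed — on
the pyrosequencing side, low-quality reactions are excluded, and the
classifier should mirror that.

An imported published model carries an explicit `orientation` flag
(`pos_high`/`pos_low`): published score forms with negative weights and a
"greater than τ" response rule leave ambiguous which side of the cut is the
responder side once marker hypomethylation directions are considered, so the
package stores the convention as data instead of guessing. Training always
produces `pos_high` (with DLDA weights the positive class scores high by
construction).

`dlda_loocv()` retrains on each leave-one-out fold. The default
`classifier_only` mode refits the DLDA weights on a fixed panel — the
workflow that produces published headline numbers; `nested` mode reruns
feature selection inside every fold and is the honest generalization
estimate (the suite instruments it to prove the held-out sample never
reaches selection). Both are reported in analyses. A caveat the test suite
documents: the AUC of *pooled* LOOCV scores is a distorted statistic — under
label permutation with three null features at n = 22 it is biased upward by
about +0.04 — whereas cross-validated accuracy behaves as theory predicts
(at or slightly below chance). Per-fold confusion metrics are therefore the
primary outputs.

Cross-platform transfer keeps the weights and moves only the threshold:
`recalibrate_threshold()` scans all midpoints of adjacent distinct scores
(plus one candidate beyond each extreme) and picks the accuracy-maximising
cut, ties broken toward higher sensitivity, then the lower threshold —
sensitivity matters more than specificity when a false negative denies a
patient an organ-preserving option. The scan is its own oracle (it is
exhaustive by construction) and is checked against a dense grid.

## The synthetic cohort generator

`sim_config()`/`simulate_cohort()` emulate the statistical structure of a
three-group discovery study so every stage has a testbed:

* **Group sizes** default to 5 NT, 11 pCR, 21 pIR — the discovery design
  this pipeline targets; 20,000 probes stand in for a filtered EPIC array
  (722,807 probes) at desk scale. The vignette-level problem sizes used in
  tests (40–20,000 probes) are the package's choice of test geometry, small
  enough to iterate on and large enough for the Monte-Carlo checks quoted
  here.
* **Background betas** are Beta-distributed with moment-matched (mean, SD),
  conditioned on island context (islands mostly unmethylated, open sea
  mostly methylated), giving the familiar genome-wide bimodal mixture
  without logit-normal transform bookkeeping. All values are clamped to
  [0.001, 0.999] so logit/M-value transforms stay finite.
* **DM injection** shifts group means by ±0.30 (default), with the
  hypermethylated fraction 44% in the pCR-exclusive compartment versus 18%
  in pIR-exclusive, and island placement of hypermethylated probes 66%
  versus 36% — the direction and context biases that characterise the two
  response methylomes (pIR-dominant hypomethylation, pCR island-focused
  hypermethylation). A truth table records every injected effect; a
  completeness test proves nothing else differs.
* **Markers.** Three designated CpGs (ids cg01072658, cg03085846,
  cg13770628) are hypomethylated in pIR with NT ≈ pCR > pIR. Their
  per-marker separability is calibrated through the closed form
  $AUC = \Phi(\Delta\mu / (\sigma\sqrt2))$ to the reference AUCs
  0.706/0.754/0.697 at within-group SD 0.15. The SD itself is a calibration
  choice (no published within-group variance exists for these CpGs), flagged
  as such: the closed form fixes only the ratio $\Delta\mu/\sigma$.
* **Pyrosequencing replica**: $100\beta$ + Gaussian noise (SD 3.5
  percentage points), an additive offset (+5 points) on marker A in FFPE
  samples only — reproducing the preservation artifact seen for that CpG —
  and a 5% missing fraction emulating failed reactions. With these defaults
  the array-pyro Pearson r per marker stays ≥ 0.93, the concordance regime
  reported for this assay (r ≈ 0.93–0.97).
* **Expression links**: gene expression is generated from the normal scores
  of a marker's betas mixed with independent noise at the Pearson value
  $2\sin(\pi\rho_s/6)$ that a bivariate normal needs to realise a target
  Spearman $\rho_s$ — +0.52 for the marker-A gene (OBSL1), −0.42 for the
  marker-C gene (INSIG1), at n = 27 expression samples. A note on power:
  at $\rho_s = 0.52$, n = 27, the two-sided Spearman test detects in about
  80% of replicates (the suite checks the realised rate against a
  bivariate-normal Monte-Carlo oracle rather than a nominal figure).
* **Reproducibility**: one configured seed feeds fixed per-stage substreams
  (cohort / pyro / expression offsets), so a stage rerun in isolation
  reproduces bit for bit; identical configs give identical outputs.

What the generator does **not** emulate: type-I/II probe chemistry, batch
structure needing SVA-style correction, cell-type composition, spatial
correlation along the genome, and realistic linkage between probes (probes
are independent given their group means). Consequently, passing tests show
the *pipeline machinery* is correct and well-calibrated under the stated
statistical structure — they do not certify performance on real cohorts,
where correlated probes and technical artifacts make selection harder. The
scaled-down LOOCV replica (markers at $\Delta\beta = 0.30$, SD 0.05)
reaches 100% sensitivity by design of its separation, standing in
structurally for the discovery-cohort result; the corresponding published
specificity claim is covered only by a plausibility envelope at
pyrosequencing-study size (means across seeds ≥ 60%/50%), not reproduced
numerically, because that would require the original data.

## Numerical and degenerate-input conventions

* Thresholds are strict everywhere a reference value is stated as an
  inequality; boundary probes are excluded.
* Fisher two-sided p sums hypergeometric point probabilities ≤ the observed
  one up to a ~1e-7 relative tolerance, absorbing floating-point ties.
* Mann–Whitney: exact enumeration when $n_1 n_2 \le 10{,}000$ and tie-free,
  else normal approximation with tie and continuity correction (the two
  paths agree within 0.01 at n = 20+20).
* Spearman: average-rank ties; exact permutation p for n ≤ 10 without ties,
  t-approximation otherwise; constant input yields missing rho, not an
  error.
* Zero-variance markers abort DLDA training with the probe named; equal
  class means train a degenerate all-zero model with a warning; folds that
  would empty a class are skipped and counted.
* Interval arithmetic: manifest positions are 1-based points, BED intervals
  0-based half-open; conversion happens only inside `overlap_probes()`, and
  distances are signed on the plus-strand convention (strand is ignored, as
  upstream/downstream distances are conventionally reported unqualified).
* Threshold recalibration tie-breaks: accuracy, then sensitivity, then the
  lower threshold.

## Known limitations

Beyond the generator's idealisations: the stepwise entry/removal criteria
are conventions, not estimated; DLDA ignores inter-marker correlation by
construction (its diagonal assumption); the pooled-score AUC caveat above;
and the published model fixture carries its stated weights and threshold
only — the package reproduces the *form* and decision behaviour of that
model, not a refit of its original raw data.
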
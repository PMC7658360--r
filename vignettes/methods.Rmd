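---
title: "Methods: LLGMN-based mood-disorder screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LLGMN-based mood-disorder screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the tunable parameters, the
synthetic-data generator, and the numerical and design choices behind the
package. It is the reference for *why* the code does what it does; the
README shows *how* to run it.

## The model

Each mood disorder (post-stroke depression, apathy, anxiety) gets its own
two-class log-linearized Gaussian mixture network (LLGMN). The network
rests on one algebraic observation: after the quadratic expansion

$$\mathbf{x} = [\,1,\; z_1,\dots,z_D,\; z_1 z_1,\, z_1 z_2, \dots, z_D z_D\,]^\top,
\qquad H = 1 + \tfrac{D(D+3)}{2},$$

the logarithm of an unnormalized Gaussian density in $\mathbf{z}$ — with
arbitrary mean and covariance — is an exactly *linear* function of
$\mathbf{x}$. A linear layer $A = W^\top \mathbf{x}$ with one unit per
mixture component, a softmax across all $K = M_1 + M_2$ units, and a
per-class sum therefore computes the posterior probability of each class
under a Gaussian-mixture model of the two class-conditional densities,
with mixing weights and normalizing constants absorbed into the bias
weights. The last unit's weights are pinned to zero: the softmax is
invariant to adding a common vector to all columns of $W$, so without the
pin the parameterization is unidentifiable (this also anchors the loss
landscape without restricting the model family).

Training minimizes the cross-entropy $-\sum_n \log Y^{(n)}_{t(n)}$ by
full-batch gradient descent ("error backpropagation"). The gradient of the
loss in the pre-softmax activations has the closed form
$p_k (1 - \mathbb{1}[k \in t]/Y_t)$, so an epoch is two small matrix
products; nothing fancier (momentum, minibatching, second-order steps) is
used, keeping the training path exactly reproducible from the seed.

Assumptions worth stating: the model is a *density-ratio* classifier — it
assumes each class-conditional distribution is adequately described by a
mixture of $M$ Gaussians over the (standardized) indices. With $M = 1$ the
decision boundary is a general quadric; this is precisely why the network
can express interactions and curved boundaries that the three linear
reference methods cannot.

## Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `n_components` (M) | 1 per class | count; scalar or (absent, present) pair | Small tabular cohorts (~100 balanced patients) cannot support many mixture components per class; M is exposed because the right value is data-dependent. |
| `learning_rate` | 0.01 | step on the mean gradient | Conservative default that descends stably on standardized inputs; the test-scale experiments use 0.1, which converges in a few hundred epochs on these problem sizes. |
| `max_epochs` | 5000 | epochs | Cap for the conservative default rate. |
| `tol` | 1e-6 | change in mean cross-entropy | Stops training when an epoch no longer moves the loss at a meaningful scale. |
| `clip_eps` | 1e-12 | probability | Posteriors are clipped to [1e-12, 1-1e-12] before any logarithm (loss, KL information), so degenerate confident predictions cannot produce infinities. |
| weight init | uniform on [-0.01, 0.01] | seeded | Small symmetric start near the uninformative model (all posteriors 1/2). |
| standardization | per-index z-score, training split | — | Quadratic terms otherwise put indices on wildly different scales (a time in ms squared vs. a 0–1 flag); fitted on the training split only and reused at prediction time. |
| stepwise entry / removal | 0.05 / 0.10 | partial-F p-values | The classical forward–backward defaults. |
| logistic ridge `lambda` | 1e-4 | glmnet penalty | Near-maximum-likelihood, but finite coefficients under complete separation. |
| PLS `n_factors` | 3 | latent factors | The reference comparison fixes three factors. |

Missing values are rejected by default; `impute = TRUE` substitutes
training-split medians. The label thresholds are strict inequalities:
HADS-Depression and HADS-Anxiety above 9, apathy score above 16.

## Input-dimensionality reduction

The backward elimination treats the KL information
$I(\mathbf{Q},\mathbf{Y}) = \sum_{n'}\sum_k Q_k \log (Q_k/Y_k)$ (natural
logarithm, $0\log 0 = 0$) summed over a validation split as the measure of
fit, and removes at each step the dimension maximizing the partial KL
ratio $E = I_{\text{current}} / I_{\text{candidate}}$ — the dimension
whose removal least inflates the validation KL. Exactly $P-1$ steps are
taken; the subset with the largest recorded validation AUC (including the
full-input state) is adopted, ties resolved toward fewer dimensions.

Two points were genuinely open and are decided as follows:

* **Retrain vs. mask.** Whether the network should be retrained for each
  candidate subset or the inputs merely masked is not determined by the
  procedure's description. Because the expansion dimension $H$ changes
  with $D$, masking is not even well defined for this architecture, so a
  fresh network (same seed) is trained per candidate — $O(P^2)$ small
  trainings. This is the dominant computational cost and the reason the
  desk-scale experiments use ~10 indices rather than the full battery.
* **Where elimination runs.** The default runs the elimination *inside
  each CV fold*, scoring candidates on that fold's validation split —
  matching the train/validation wording of the procedure. This couples
  selection to the evaluation split; the `nested = TRUE` variant scores
  candidates on an inner 20% holdout of the training fold and refits the
  selected subset on the whole training fold, at the price of less data
  for selection. Both are exposed; per-fold selection means the selected
  set can differ between folds, so reports list the union with per-fold
  frequencies and use the modal set for ablation.
* **Ties in the removal criterion** go to the lowest column index, for
  determinism; a zero KL denominator is guarded by $\varepsilon =
  10^{-12}$ and flagged in the trace.

## Evaluation machinery

AUC is computed by midrank Mann–Whitney counting (ties count 1/2),
identical to the trapezoidal area of the empirical ROC; both routes exist
in the package and are required to agree to 1e-12 in the tests. The
operating point is the ROC vertex maximizing Youden's $J$ (the "maximum
AUC" operating point is not a defined threshold rule, so the standard
Youden criterion is adopted), with ties resolved toward higher
sensitivity; predictive values at degenerate vertices (no calls of one
kind) are `NA`. Class balancing undersamples the majority class without
replacement, seeded; folds are stratified so each fold sees both classes.
Whether the original analysis balanced once globally or per fold is not
recoverable; balancing here happens once per disorder, before the fold
plan, so all methods score identical balanced samples in identical folds —
the pairing the DeLong test requires. The DeLong variance uses placement
values; equal AUCs with zero variance return $p = 1$ by convention, and
the implementation is cross-checked against pROC in the tests. Holm
adjustment wraps `stats::p.adjust`.

The ablation percentage is *relative* by default
($100\,(A_{\text{sel}} - A_{\text{abl}})/A_{\text{sel}}$): a report of
"removing index X reduced the AUC by 20%" is read as a fifth of the
achieved AUC, not 20 percentage points; `ablation_denominator =
"absolute"` gives the other reading.

## The synthetic cohort generator

The published study's 274-patient dataset is not deposited, so every
experiment here runs on synthetic cohorts. The generator emulates the
*published group-level structure*: per group (control/depression/apathy/
anxiety, sizes 80/40/80/40), continuous indices are truncated Gaussians at
the printed means and SDs, binary indices are Bernoulli at the printed
rates, and the three psychological scores (HADS-D, HADS-A, apathy score)
are drawn the same way, rounded to integers, and thresholded into labels.
Two patient-level latent factors induce realistic cross-index correlation:
a "perceived stress" factor loading on JPSS and the psychological scores
(default loading 0.5) and a "processing speed" factor loading on the
timing indices (default 0.4). In the default `mix` mode the factor share
is carved out of the printed SD ($\sigma\,(\lambda f +
\sqrt{1-\lambda^2}\,\varepsilon)$), so the marginal means *and SDs* match
the published table; the `additive` mode adds the factor on top, which
inflates marginal variance and is the mode in which increasing the stress
loading raises disorder prevalence (under `mix` the marginals — and hence
prevalence — are loading-invariant by construction, so the
prevalence-response property is only meaningful there).

The exact 36-index battery of the original study is not enumerated
anywhere; the packaged schema is a documented reconstruction from the
published cohort table — 36 continuous indices (FIM, BRS, MMSE, BIT,
spans, cancellation, SDMT, memory updating, PASAT, Stroop, CPT, TMT,
RBMT, JPSS) plus 4 binary flags (ataxia, aphasia, TMT-A/B failure). What
the generator does *not* emulate: the real joint distribution beyond first
moments and one-factor correlation, floor/ceiling score distributions
(truncation only clips tails), lesion-location structure, and
label/feature dependence beyond the group means and the stress factor.
Passing tests on these cohorts therefore demonstrate correctness and the
qualitative behavior of the machinery (nonlinear superiority on nonlinear
signal, noise-dimension elimination, null calibration), not clinical
performance on real patients.

`planted_cohort()` is the fully controlled companion generator for
power/recovery experiments: known informative vs. noise dimensions, a
linear mean-shift mode, and an XOR-like quadratic mode
($y = \mathbb{1}[x_1 x_2 > 0]$, optional label noise) that carries no
linear signal at all.

## Numerical choices and degenerate inputs

* Softmax activations subtract the row maximum before exponentiation
  (overflow-safe; shift-invariant).
* Constant columns get unit scale during standardization (they become
  exactly zero after centering, carrying no information but breaking
  nothing).
* Truncated sampling rejects and re-draws only the idiosyncratic noise,
  preserving the latent-factor contribution; after 200 rounds stragglers
  are clamped to the bounds.
* `0 log 0 = 0` in the KL information; one-hot targets make it
  $-\sum \log Y_{\text{true}}$.
* Single-column logistic fits pad an all-zero column (glmnet requires two
  columns; the pad is inert under standardization).
* A candidate training failure inside the elimination is caught and that
  candidate skipped; only if all candidates fail does the step error.

## Problem sizes

The packaged experiments are sized for a single CPU: the acceptance script
analyses the 240-patient default cohort on a ten-index screening subset
(ten folds, per-fold elimination, ablation; a few minutes), and the test
suite uses cohorts of 100–800 samples with 3–6 indices, 300–400 training
epochs at learning rate 0.1, 20–50 seeded replicates for the power-style
properties, and 1000 replicates for the DeLong type-I calibration. The
elimination cost scales as $O(P^2)$ retrainings per fold, so analyses of
the full 40-index battery are possible but take correspondingly longer.

## Known limitations

* Backward elimination is greedy: it cannot undo a removal, and with
  per-fold selection the retained sets vary between folds; the modal set
  is a summary, not a guarantee.
* The default per-fold reduction scores candidates on the same split used
  for pooled evaluation — a deliberate mirroring of the described
  procedure that optimistically biases the pooled AUC; use
  `nested = TRUE` for an unbiased variant.
* The DeLong comparison is asymptotic; at very small balanced sizes
  (tens of patients) its type-I control degrades.
* Stepwise selection inherits the classical criticisms of stepwise
  methods; it is included as a reference method, not a recommendation.
* Synthetic cohorts share only first moments and a one-factor correlation
  with any real population; none of the numbers produced here are
  clinical results.
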
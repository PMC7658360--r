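# llgmn

Probabilistic screening of post-stroke mood disorders — depression (PSD),
apathy, and anxiety — from routine tabular evaluation indices (functional,
physical, and neuropsychological test scores), for rehabilitation
researchers who want a nonlinear, posterior-probability classifier together
with an interpretable account of *which* indices drive each disorder.

## The method

**Classifier.** One log-linearized Gaussian mixture network (LLGMN) per
disorder. An input vector **z** ∈ ℝᴰ of standardized evaluation indices is
expanded quadratically,

```
x = [1, z1, …, zD, z1z1, z1z2, …, zDzD]ᵀ,   H = 1 + D(D+3)/2,
```

so that a single linear layer followed by a softmax over K Gaussian-mixture
component units parameterizes log-component densities; summing the
component activations within each class yields the posterior probability
vector **Y** = (P(absent|z), P(present|z)). The last component unit's
weights are fixed at zero for identifiability, and the network is trained
by full-batch error backpropagation on the cross-entropy between **Y** and
the one-hot labels **Q**.

**Input-dimensionality reduction.** Starting from all P indices, the
partial Kullback–Leibler information ratio

```
E[I+ī] = I(Q, Y[I]) / I(Q, Y[I+ī]),    I(Q, Y) = Σn Σk Qk log(Qk / Yk)
```

is computed on a validation split for every remaining candidate dimension
ī; the dimension maximizing E (whose removal least degrades the validation
fit) is eliminated, and the loop repeats for exactly P−1 steps. The subset
whose model attains the largest validation AUC is adopted.

**Evaluation.** Classes are balanced by seeded undersampling; a stratified
ten-fold cross-validation plan is shared by all methods; validation
posteriors are pooled into one ROC per method (AUC = Mann–Whitney
probability); sensitivity/specificity/PPV/NPV are reported at the
Youden-optimal threshold; the LLGMN is compared against three linear
references — forward–backward stepwise linear regression, ridge-regularised
logistic regression, and 3-factor PLS regression — with the DeLong test and
Holm adjustment. A single-index ablation then ranks each retained index by
the percent AUC drop its removal causes.

Because the original 274-patient clinical dataset is not public, the
package ships a synthetic cohort generator (`generate_cohort()`) calibrated
to the published group-wise means/SDs, binary-index rates, group sizes
(80/40/80/40), and label thresholds (HADS subscales > 9, apathy score
> 16), with shared latent "stress" and "processing-speed" factors.

## Worked example

```r
library(llgmn)

co  <- generate_cohort(seed = 42)           # 240 synthetic patients, 40 indices
idx <- c("jpss", "rbmt_profile", "sdmt_achievement_rate",
         "pasat_2s_accuracy", "tmt_b_time", "digit_span_backward")
reports <- run_full_analysis(co$features[, idx], co$labels["psd"],
                             k = 10, seed = 7,
                             control = llgmn_control(max_epochs = 400,
                                                     learning_rate = 0.1))
print(reports$psd)
#> Disorder report: psd (n = 98 balanced, 10-fold CV)
#>   pooled AUC: proposed 0.830, stepwise_linear 0.719, logistic 0.669, pls 0.676
#>   proposed @ Youden: sens 0.878 spec 0.633 ppv 0.705 npv 0.838
#>   selected indices (modal set, 4): jpss, pasat_2s_accuracy, tmt_b_time, digit_span_backward
#>   top ablation: jpss 16.72%, tmt_b_time 8.79%, pasat_2s_accuracy 3.84%
reports$psd$delong
#>            method auc_proposed auc_baseline       p_raw     p_holm
#> 1 stepwise_linear    0.8304873    0.7188671 0.037220136 0.03722014
#> 2        logistic    0.8304873    0.6688880 0.005273325 0.01581998
#> 3             pls    0.8304873    0.6759683 0.006530430 0.01581998
```

Reading: on 98 balanced synthetic patients the quadratic network reaches a
pooled cross-validated AUC of 0.83, significantly above all three linear
baselines after Holm adjustment; the backward elimination most often keeps
four indices, and removing the perceived-stress scale (JPSS) costs the
most AUC (16.7% of the selected model's 0.83) — the same dominance pattern
the clinical study reports.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/llgmn-cli` (`simulate`, `run`, `ablate`, `report`
subcommands).

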
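---
title: "Predicting NCRT response from baseline MRI markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NCRT response from baseline MRI markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrtfusion)
```

## The problem

Neoadjuvant chemoradiotherapy (NCRT) followed by total mesorectal excision is
the standard of care for locally advanced rectal cancer, but response varies
widely: some patients achieve a pathological complete response while others
barely benefit. Response is graded post-operatively on the 4-level tumor
regression grade (TRG 0 = complete response … TRG 3 = poor response), which is
only known *after* surgery. A model that predicts response from **baseline**
(pre-treatment) MRI would support treatment planning before any therapy is
given.

`ncrtfusion` implements such a pipeline end to end, using only conventional
clinical MRI markers (no radiomics): tumor circumferential ratio, sagittal
longest tumor diameter (mm), apparent diffusion coefficient (ADC,
10⁻³ mm²/s), distance from tumor to anus (mm), lymph node number, maximal
lymph node diameter (mm), N stage (0/1/2), T stage (2/3/4), extramural
vascular invasion (EMVI, 0/1) and circumferential resection margin status
(CRM, 0/1).

The pipeline has five stages:

1. **Screening** — paired pre/post-NCRT tests identify which of the 10
   candidate markers actually change under therapy; those become the model
   features, conventionally numbered 1–7 (1 sagittal diameter, 2 ADC,
   3 lymph node number, 4 maximal node diameter, 5 N stage, 6 EMVI, 7 CRM).
2. **Standardization** — z-scoring, `z = (x − μ)/σ`, with μ and σ estimated
   from training rows only.
3. **Attention fusion** — a learnable attention layer fuses the standardized
   scalar features into one vector.
4. **Classification** — a soft-margin RBF SVM on the fused features,
   evaluated by leave-one-out cross-validation (LOOCV) with accuracy (ACC),
   rank AUC, sensitivity (SEN) and specificity (SPE).
5. **Ablation** — all `2⁷ − 1 = 127` non-empty feature subsets are evaluated
   under a shared seed schedule; per-feature proportions among the top-50
   subsets per metric summarize feature importance.

Because no patient-level data are publicly deposited for this problem, the
package includes a first-class synthetic-cohort generator calibrated to the
published summary statistics of a 149-patient cohort, so that every stage is
testable and the whole analysis is reproducible from a seed.

## The synthetic cohort generator

`default_config()` encodes the study conditions: n = 149 patients, TRG
strata drawn in the exact proportions 31/34/50/34, sex ratio 82 M / 67 F,
age 60.86 ± 9.70 years.

**Continuous markers.** Each marker's (pre, post) pair is bivariate normal
with the published marginal means/SDs (e.g. ADC 0.970 ± 0.251 before and
1.223 ± 0.292 after NCRT) and a paired correlation ρ. Published tables give
only marginals, so ρ is in principle free; we default to ρ = 0.6, a typical
test–retest correlation for clinical measurements. The one exception is the
tumor circumferential ratio: its published paired-t statistic (0.701 for a
−0.020 mean shift at n = 149) pins the SD of its differences at 0.348, which
implies ρ ≈ −0.23; using 0.6 would overstate the marker's pre/post power and
make it spuriously "significant" in roughly a fifth of cohorts, contrary to
the study it emulates. (The remaining printed t values are not jointly
feasible with the printed SDs under any ρ ∈ (−1, 1), so we do not chase them;
all markers that should screen in do so with overwhelming power at ρ = 0.6.)

Physiologic floors (diameters, counts and distances ≥ 0; ADC > 0) are
enforced by resampling. Truncation at a floor raises the mean of what
remains, so the generator compensates the latent pre-treatment mean (a
one-dimensional root-solve on the truncated-normal mean) so that the
**observed** pre marginals match the calibration targets exactly.
Post-treatment values are drawn conditionally on pre and resampled at the
floor without compensation; for markers whose post mean is near zero (lymph
node number, maximal node diameter) the realized post means therefore sit
slightly above the printed values. This is a deliberate asymmetry: baseline
marginals drive both the screening power and the prediction task, post
values only need the right pairwise-change structure.

**Categorical markers.** Pre states are drawn from the published frequency
splits (printed per 49 patients; used as proportions of n). Post states
follow per-marker transition matrices:

* **N stage** uses the comonotonic (rank-preserving, monotone-improvement)
  transport of (10, 20, 19) onto (33, 14, 2) — no patient worsens.
* **EMVI** moves 9 of 14 positives to negative and none upward; the
  discordant counts (9, 0) reproduce the published paired chi-square of
  exactly 9.000.
* **CRM** moves 9 of 18 positives down and 1 of 31 negatives up — the unique
  discordant pair (9, 1) consistent with the published marginal shift
  (31/18 → 39/10) and statistic 6.400. A purely monotone coupling cannot
  reproduce that value.
* **T stage** is the marker the study found *unchanged* (p = .094). Scaling
  its printed marginal shift from the 49 printed patients to n = 149 would
  triple the marginal-homogeneity statistic and make it strongly
  significant — the opposite of the study's finding. T-stage transitions
  therefore default to small balanced flows between adjacent stages that
  leave the marginal distribution stationary, keeping the marker genuinely
  null at any n.

**The response link.** TRG is drawn first; patients with TRG 0–1 are
responders. A configurable signal of strength δ (`signal_strength`, in units
of each marker's pre-treatment SD, default 1.0) separates responders from
non-responders at baseline on the markers in `signal_features` (default
{1, 2, 5}: responders have smaller tumors, higher ADC and lower N stage).
Continuous shifts are allocated as +δσ(1−π) to responders and −δσπ to
non-responders (π = responder fraction), so the mixture marginal mean is
unchanged and the calibration above survives the planted signal. Categorical
signal features use a linear probability tilt with a centred level score,
which preserves the mixture marginal exactly for moderate δ (cells are
clipped at 0 and renormalized beyond δ ≈ 2.3). δ = 0 produces genuinely
unpredictable cohorts (used by the null-calibration tests); δ = 1 is the
default study condition, chosen so that the realized LOOCV performance is in
the same qualitative band as the published model (AUC ≈ 0.8); δ = 2.5 is the
"strong signal" condition used to demonstrate near-ceiling recovery.

What the generator does *not* emulate: non-normal marginals (real ADC and
size distributions are skewed), inter-marker correlations at baseline
(markers are independent given response class), measurement error structure,
and missing data. Passing tests therefore demonstrate that the pipeline's
machinery is correct and calibrated — not that the published real-cohort
performance numbers are reproducible, which they are not without the
original data.

## Screening

Marker-appropriate paired tests, two-sided, α = 0.05, no multiplicity
correction (matching the emulated analysis):

* continuous — paired t-test, `t = mean(d)/(sd(d)/√n)`, `d = pre − post`,
  df = n − 1;
* binary — McNemar's chi-square on the per-patient discordant counts,
  `(b − c)²/(b + c)`, df = 1, **no continuity correction** (the uncorrected
  statistic is what reproduces the published EMVI value 9.000; the corrected
  one gives 7.11);
* k ≥ 3 categories — the Stuart–Maxwell marginal-homogeneity statistic
  `d′V⁻d` on the k×k cross-table, df = rank(V), with a generalized inverse
  (and a recorded note) when the difference covariance is rank-deficient.
  Two-level inputs are routed to McNemar. Ordinal stages are treated as
  unordered for testing, even though the generator moves them monotonically.

A marker whose test degenerates (zero-variance differences, no discordant
pairs) is recorded as untestable and not selected, rather than raising.

## Standardization, fusion, classifier

**Standardization** uses the sample SD (n − 1). Parameters are fitted per
training fold and applied unchanged to the held-out row; tests plant an
extreme sentinel in the test fold to prove nothing leaks.

**Attention fusion.** Each standardized scalar `z_i` is lifted to a value
vector `v_i = z_i e_i + b_i` with learnable embedding `e_i` and offset `b_i`
(dimension d_k = 8 by default). Scaled dot-product scores between a
learnable query `q` and per-feature keys `k_i`,
`s_i = q·k_i/√d_k`, softmax-normalized over the **active** feature subset
(max-subtraction for stability), give weights `w_i ≥ 0, Σw = 1`; the fused
representation is `Σ w_i v_i`. The scalar-to-vector lift is needed because a
weighted sum of raw scalars would collapse seven features to one number. A
`weighted-scalar` mode (`(w_i z_i)` over the active subset, i.e. the value
embeddings frozen at the standard basis) is provided for interpretability.

**Training the fusion layer.** How the attention parameters are trained is
genuinely open; we use a staged surrogate: minimize the L2-regularized
logistic loss of a linear head on the fused vector by full-batch gradient
descent (200 epochs, step 0.01, λ = 10⁻³, seeded N(0, 0.1²) initialization),
then discard the head and fit the SVM on the frozen fused features. The
descent halves its step within an epoch whenever the proposed update would
increase the loss, so the recorded loss trace is non-increasing (tolerance
10⁻⁸); everything is deterministic given the seed. Repeating the evaluation
over initialization seeds is also how the pipeline models run-to-run
variability (the ± SD in reports): the data stay fixed, only the
initialization varies.

**Classifier.** A soft-margin RBF SVM (`min ½‖w‖² + CΣξ` subject to
`y_i(w·φ(x_i) + b) ≥ 1 − ξ_i`), solved in the dual by libsvm via e1071.
Hyperparameters are not specified by the emulated analysis; defaults are
C = 1 and γ = 1/(d · var(fused)) computed per training fold. Tests verify the
box constraint |α_i y_i| ≤ C, the γ→0 (near-constant) and γ→∞
(interpolating) limits, and that the attained dual objective matches an
independent interior-point QP solve to 10⁻⁴. Decision scores are computed
directly from the stored support vectors and oriented so positive =
predicted responder, independent of libsvm's internal label ordering.

## Evaluation

The binary endpoint is configurable and never hard-coded:
`good_vs_poor` (default; TRG 0–1 vs 2–3, the 65/84 split at the default
strata) or `pcr_vs_rest` (TRG 0 vs 1–3). LOOCV runs exactly n folds over
patients sorted by `patient_id` (making every metric invariant to row
order); each fold refits standardization, fusion and SVM from scratch on the
n − 1 training rows. The confusion table thresholds the decision score at 0
(no post-hoc threshold tuning, which would leak under LOOCV); AUC is the
Mann–Whitney rank estimator (ties ½) on the pooled n held-out scores —
per-fold AUC is undefined for single-patient folds. ACC/SEN/SPE are reported
in percent; undefined ratios (no positives/negatives) become NA with a
recorded reason, never a silent zero.

## Ablation and feature proportions

All 127 subsets are evaluated with an identical seed schedule — one shared
parameter initialization per repeat, of which each subset takes its rows —
so subset comparisons are paired and differ only in the features. Results
can be cached per subset (JSON) and resumed. Ranking is by metric mean,
descending, with deterministic tie-breaks (smaller subset first, then
lexicographic index order). Per-feature proportions among the top-K
(K = 50) default to the **slot-share** definition — feature occurrences
divided by all feature occurrences in the top-K masks, so each metric's
shares sum to 1 (over the full powerset every feature appears in 64/127
subsets and the share is uniform 1/7); the subset-membership fraction is
available as an option. Both definitions are offered because published
"proportion" figures are consistent with either reading.

## Numerical choices and degenerate inputs

* Softmax with max-subtraction; attention weights sum to 1 within 10⁻¹².
* GD monotonicity via step-halving; tolerance 10⁻⁸ on the recorded trace.
* KKT box tolerance 10⁻⁶; QP-oracle agreement 10⁻⁴.
* Zero-variance feature in any training fold, single-class folds, empty
  subsets, K larger than available results, undefined metric denominators:
  all are named errors or flagged NAs, tested explicitly.
* Cohort CSVs serialize doubles with 17 significant digits, so
  `read_cohort(write_cohort(x))` is value-exact and repeated writes are
  byte-identical; report files round to 6 significant digits.
* libsvm's SMO solution varies at ~10⁻³ with row order (working-set order at
  its default tolerance); sorting by patient id inside LOOCV makes results
  exactly reproducible.

## Problem sizes used by the test suite

The suite exercises the full study scale where it matters and smaller
cohorts where only the mechanics are under test: calibration and screening
run at n = 149 (200 cohorts for the 4·SE calibration check; 10 cohorts for
the 7-marker selection check); type-I calibration uses 500 effect-free
cohorts at n = 50; the null-AUC and permutation-null checks use 20
seeds/permutations at n = 149; signal recovery runs the complete 127-subset
ablation at n = 149 on 10 seeds with E = 1; unit tests of the operations use
cohorts of 16–60 patients. The complete integration-scale ablation
(127 subsets, n = 149, E = 5) costs about 6 minutes on one CPU core at the
default settings; the suite verifies this budget by timing one subset and
extrapolating.

## Known limitations

* The published real-cohort performance (best subset 87.53% ACC, AUC 0.85)
  is **not** a reproduction target: the patient data are not deposited, and
  the synthetic cohorts match summary statistics, not the joint
  distribution. The package reproduces formats, calibration anchors and
  qualitative behavior (which features dominate, how performance scales with
  signal).
* The fusion layer's training procedure is a surrogate for an unspecified
  one; conclusions about the attention mechanism itself should rest on the
  configurable pieces (mode, d_k, schedule), not on the specific optimizer.
* LOOCV on permuted or signal-free data shows the well-known pessimistic
  (anti-learning) bias of near-chance classifiers; the null calibration
  bands (AUC 0.5 ± 0.1) account for it.
* Stuart–Maxwell is an asymptotic test; at very thin discordance its χ²
  reference (like McNemar's) is conservative.
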
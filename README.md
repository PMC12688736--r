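# ncrtfusion

Attention-fusion SVM modelling of neoadjuvant chemoradiotherapy (NCRT)
response in locally advanced rectal cancer, from baseline clinical MRI
markers.

## What this is for

Response to NCRT in locally advanced rectal cancer is graded
post-operatively by the tumor regression grade (TRG 0 = complete response …
TRG 3 = poor response), but treatment decisions have to be made *before*
therapy. `ncrtfusion` is a reproducible pipeline for building and stress-
testing a baseline predictor of that response from ten conventional MRI
markers (tumor circumferential ratio, sagittal longest diameter, ADC,
distance to anus, lymph node number and maximal diameter, N stage, T stage,
EMVI, CRM). It is aimed at biostatisticians and imaging researchers who want
the full analysis chain — screening, fusion, classification, validation and
feature ablation — as tested, seedable code rather than a one-off analysis.

The stages, each an exported function:

1. **Paired screening** (`screen_features`): paired t-tests for continuous
   markers, McNemar's chi-square `(b − c)²/(b + c)` (no continuity
   correction) for binary markers, Stuart–Maxwell marginal homogeneity for
   k ≥ 3 stages; markers with *p* < .05 become model features 1–7.
2. **Standardization** (`standardize_fit` / `standardize_apply`):
   `z = (x − μ)/σ`, training rows only.
3. **Attention fusion** (`train_fusion`, `fuse`): each scalar feature is
   lifted to a value vector `v_i = z_i e_i + b_i`; softmax-normalized scaled
   dot-product scores `q·k_i/√d_k` between a learnable query and per-feature
   keys weight the values, `fused = Σ w_i v_i`.
4. **RBF SVM** (`fit_svm`, `decision_score`): soft-margin dual
   (`min ½‖w‖² + CΣξ_i`) with Gaussian kernel, via libsvm/e1071.
5. **Leave-one-out evaluation** (`loocv_evaluate`, `repeat_evaluate`):
   per-fold refits, pooled ACC/SEN/SPE (%) and Mann–Whitney AUC, mean ± SD
   over fusion-initialization seeds.
6. **Exhaustive ablation** (`run_ablation`, `rank_topk`,
   `feature_proportions`): all 127 feature subsets under a paired seed
   schedule, ranked per metric, with top-50 per-feature proportion tables.

Because no patient-level data are deposited for this problem, the package
ships a calibrated synthetic-cohort generator (`default_config`,
`generate_cohort`): 149 patients, TRG strata 31/34/50/34, published pre/post
means/SDs and category frequencies, monotone-improvement transitions, and a
configurable baseline-signal → response link. See the vignette
(`vignettes/ncrt-response-pipeline.Rmd`) for the model, the calibration
choices and their rationale.

## Worked example

```r
library(ncrtfusion)

cohort <- generate_cohort(default_config(), seed = 1)
screen_features(cohort)
```

```
<screening_result> alpha = 0.05
                      marker feature_index                 test statistic  df   p_value significant
1      circumferential_ratio            NA             paired_t    0.6432 148 5.211e-01       FALSE
2  sagittal_longest_diameter             1             paired_t    5.5189 148 1.488e-07        TRUE
3                  adc_value             2             paired_t  -14.0382 148 5.367e-29        TRUE
4           distance_to_anus            NA             paired_t    0.6841 148 4.950e-01       FALSE
5          lymph_node_number             3             paired_t   13.0552 148 2.112e-26        TRUE
6    max_lymph_node_diameter             4             paired_t    6.8764 148 1.604e-10        TRUE
7                    n_stage             5 marginal_homogeneity  104.8969   2 1.667e-23        TRUE
8                    t_stage            NA marginal_homogeneity    5.0000   2 8.208e-02       FALSE
9                       emvi             6              mcnemar   35.0000   1 3.297e-09        TRUE
10                       crm             7              mcnemar   23.4390   1 1.289e-06        TRUE
selected model features: 1 + 2 + 3 + 4 + 5 + 6 + 7
```

Seven of the ten candidates change significantly under therapy — exactly the
markers that carry feature labels 1–7 — while the circumferential ratio,
distance to anus and T stage do not. Evaluating one feature combination
(sagittal diameter + ADC + N stage) by repeated LOOCV:

```r
repeat_evaluate(cohort, subset = c(1, 2, 5), E = 5, seed_base = 0)
```

```
<metrics_report> features 1 + 2 + 5 (E = 5, good_vs_poor)
  ACC 72.89 +/- 1.02%  AUC 0.80 +/- 0.01  SEN 58.15 +/- 3.34%  SPE 84.29 +/- 1.96%
```

i.e. on this synthetic cohort (default planted signal on features 1, 2 and
5), the three-marker model classifies 72.9% of patients correctly and ranks
a random responder above a random non-responder with probability 0.80; the
± values are SDs over the five fusion-initialization seeds. The full
ablation and its feature-importance summary:

```r
results <- run_ablation(cohort, model_config(E = 1, seed_base = 1))  # 127 subsets
round(feature_proportions(rank_topk(results, "acc", K = 50)), 3)
```

```
    1     2     3     4     5     6     7
0.249 0.139 0.134 0.109 0.134 0.119 0.114
```

one slot-share per feature (summing to 1): the sagittal diameter (feature 1)
clearly dominates the top-50 combinations on this cohort, with ADC
(feature 2) second and N stage (feature 5) tied for third. Across cohort
seeds, the three planted signal features {1, 2, 5} take the three largest
shares in the majority of runs — the property the acceptance suite checks.

The same pipeline is scriptable from a shell via the installed `ncrtfusion`
executable (`simulate`, `screen`, `evaluate`, `ablate`, `report`
subcommands), writing CSV/JSON reports with full config/seed audit headers.

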
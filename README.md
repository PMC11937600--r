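# mcnnrf

Multimodal binary neurodiagnosis from tabular EEG- and structural-MRI-derived
feature vectors, for methodologists and applied researchers who want a fully
reproducible, testable implementation of a three-stage fusion pipeline:

1. **Modality-specific convolutional branches** — each subject's feature
   vector is reshaped into a `1 × D × D` map and passed through stride-1
   same-padded convolutions, per-channel *matrix-product fusions*
   (`S = X₁X₂`, true matrix products of the `H × W` channel slices), and
   multi-pooling blocks (`avg-pool` and `max-pool` in parallel, each
   convolved, then matrix-multiplied), ending in a dense tanh head with a
   sigmoid unit trained under mean binary cross-entropy +
   `½·λ·Σ‖Wₖ‖²`.
2. **Joint attention fusion (MJA)** — per branch, 1×1 projections produce
   query/key (channels reduced to `max(1, ⌊G/8⌋)`) and value (full `G`)
   matrices over the flattened spatial grid; sigmoid spatial attention maps
   `S_A = σ(Q_Aᵀ K_A)` are computed per branch, and each branch's values are
   routed by the **other** branch's map (`C_A = V_A S_B`, `C_B = V_B S_A`),
   then concatenated onto the originals.
3. **Stacked random forest** — level-1 forests produce out-of-fold class
   probabilities that augment a level-2 forest's input.

Evaluation reports sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
precision `tp/(tp+fp)`, accuracy, the Matthews correlation coefficient
`(tp·tn − fp·fn)/√((tp+fn)(tp+fp)(tn+fn)(tn+fp))` and ROC/AUC, under a
stratified 80/20 holdout with optional 10-fold cross-validation on the
training partition. A seeded synthetic cohort generator plants a known,
partly complementary class signal (class-conditional Gaussian mean shifts
plus a latent factor shared across modalities) so every stage is testable
without clinical data; an ablation harness compares the fusion ladder
(unimodal branches, plain concatenation, self-attention, cross-attention).

## Worked example

```r
library(mcnnrf)

spec <- cohort_spec(n_subjects = 120, p_eeg = 64, p_smri = 64,
                    effect_size = 1.5, shared_factor_weight = 0.5,
                    missing_rate = 0.02, seed = 7)
cohort <- generate_cohort(spec)
cohort
#> <cohort> 120 subjects | eeg: 64 features | smri: 64 features | 60 cases / 60 controls

config <- pipeline_config(strategy = "mcnnrf", n_filters = 4, seed = 7)
report <- evaluate_holdout(cohort, config)
report
#> <holdout_report> strategy=mcnnrf seed=7 n_test=24 acc=0.708 auc=0.771

glance(report$report)
#> # A tibble: 1 × 11
#>      sn    sp   pre   acc   mcc   auc    tp    tn    fp    fn threshold
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <int> <int> <int> <int>     <dbl>
#> 1 0.583 0.833 0.778 0.708 0.430 0.771     7    10     2     5       0.5
```

The cohort plants a standardized effect of 1.5 on one eighth of the
features in each modality, half of it carried by a latent factor shared
across modalities. On the untouched 24-subject test set the fused pipeline
reaches 70.8% accuracy and AUC 0.771; `sn`/`sp`/`pre`/`mcc` are the usual
confusion-matrix diagnostics at threshold 0.5. `autoplot(report$report)`
draws the ROC curve; `run_ablation()` repeats the experiment across fusion
strategies on identical splits, and `tidy()`/`glance()` return everything
as tibbles.

A thin command-line front end over the same functions lives at
`inst/cli/mcnnrf.R` (`simulate`, `preprocess`, `train`, `evaluate`,
`ablate` subcommands).

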
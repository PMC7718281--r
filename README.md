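# attnmod

ROI-based event-related fMRI analysis of endogenous and exogenous covert
spatial attention in human visual cortex — implemented end-to-end as a
testable R pipeline, together with a synthetic-data generator that
emulates the study design so every stage can be validated without any
imaging data.

## The problem

Endogenous (voluntary, central-cue) and exogenous (involuntary,
peripheral-cue) covert attention both improve 2-AFC orientation
discrimination, whether the cue precedes the stimulus (pre-cue, acting
on encoding) or follows it (post-cue, acting on read-out). The analytic
question is how the attentional modulation of stimulus-evoked BOLD
responses is distributed along the visual hierarchy (V1, V2, V3, V3A,
hV4, LO1) for each attention type and cue epoch. Modulation is
quantified per participant, ROI, attention type and cue epoch by the
**Attentional Modulation Index**

    AMI = (Vc + k) / mean(Vc + k, Ic + k, Vi + k, Ii + k)

with `Vc`, `Ic` the valid/invalid response amplitudes contralateral to
the cue, `Vi`, `Ii` the ipsilateral (distractor) ones, and `k` a
constant (default 0.2) that keeps all terms positive. AMI = 1 means no
modulation. Inference combines per-ROI paired one-tailed t-tests
(valid > invalid), OLS regressions of the group-mean valid−invalid
difference on hierarchy rank (F(1, 4) on six ROI means), and linear
mixed models (difference ~ rank × attention, by-participant random
intercepts and slopes, likelihood-ratio p-values).

The pipeline stages, each an exported module:

1. `generate_session()` — exactly counterbalanced trial sequences
   (40/40/10/10% pre/post/cue-only/blank; 75% valid endogenous, 50%
   exogenous; SOAs 117/317 ms; TR 1.75 s).
2. `observer_model()`, `run_staircase()`, `simulate_responses()`,
   `summarize_behavior()`, `behavior_anova()` — a cumulative-Gaussian
   2-AFC observer, 3-down-1-up titration to ~80% correct, d′/median-RT
   summaries and the 2×2×2 repeated-measures ANOVA.
3. `ground_truth_effects()`, `simulate_attention_run()`,
   `simulate_localizer_run()` — synthetic BOLD with known condition
   amplitudes, linear drift and AR(1) noise.
4. `fit_sinusoid()`, `select_voxels()` — sinusoid fits of the
   block-design localizer; voxels kept with coherence > 0.2 and phase
   in (0, π), both strict.
5. `preprocess_run()`, `build_design_matrix()`,
   `estimate_amplitudes()`, `condition_amplitudes()` — discard 8
   volumes, detrend, 0.01 Hz high-pass (DCT projection, applied
   identically to the design), percent signal change, and the
   twelve-regressor event-related GLM (8 conditions, 2 cue-only, blank,
   eye-movement; incorrect trials as a nuisance column).
6. `compute_ami()`, `ami_table()`, `per_roi_validity_tests()`,
   `hierarchy_regression()`, `fit_attention_lmm()`,
   `laterality_anova()`, `ami_vs_one_test()`, `ami_sensitivity()` —
   the AMI and all group-level inference.
7. `run_pipeline()` / `pipeline_config()` — orchestration with full
   seeding and provenance; `import_amplitude_table()` ingests externally
   supplied condition-amplitude tables (CSV) into the same statistics.

## Worked example

```r
library(attnmod)
cfg <- pipeline_config(participants = 5, n_runs = 2,
                       n_voxels_per_roi = 12, seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
attnmod pipeline results
  5 participants, config hash 8777ab8137c6ac64af2f75a3efd7e96a

Hierarchy regressions (valid - invalid AMI difference on rank):
  attention_type cue_epoch     slope intercept        F df1 df2 p_value r_squared
1     endogenous      post -0.002760    0.1806  0.16630   1   4 0.70430   0.03992
2      exogenous      post  0.000667   -0.0268  0.00697   1   4 0.93750   0.00174
3     endogenous       pre  0.056540    0.0353 30.79593   1   4 0.00516   0.88504
4      exogenous       pre -0.006793    0.1803  1.49645   1   4 0.28835   0.27226

AMI vs 1: t(4) = 34.14, p = 4.39e-06, Cohen's d = 15.27
```

Reading the output: under the default four-regime ground truth
(endogenous-pre increasing, exogenous-pre flat, endogenous-post flat,
exogenous-post null), only the endogenous pre-cue regression is
significant — the valid−invalid AMI difference grows by ~0.06 per
hierarchy rank (R² = 0.89) — while the exogenous pre-cue and endogenous
post-cue conditions show flat positive intercepts and the exogenous
post-cue condition shows nothing, and the overall AMI is reliably above
1 (attention boosts valid-trial responses). `res$roi_tests`,
`res$lmm_pre`, `res$lmm_post`, `res$behavior` hold the per-ROI tests,
the mixed models and the behavioral d′/RT summaries and ANOVAs.

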
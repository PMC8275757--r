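# pupilcontrol

An R package for pupillometry analyses of self-control experiments. It turns
continuous pupil-diameter recordings from an emotion-reappraisal task into a
per-participant **Pupil Dilation Index (PDI)** — the mean Reappraise > View
pupil contrast inside a significance-tested time window — and relates that
index to emotion-regulation success and to dietary self-control, including
out-of-sample prediction. A fully parameterised synthetic-cohort generator
makes every stage of the pipeline testable without any raw recordings.

## Who it is for

Researchers in psychophysiology / cognitive neuroscience who want a tested,
scriptable implementation of:

* blink/loss handling: binary loss mask widened by a Gaussian window
  (FWHM 200 ms, truncated at ±3σ) and linearly interpolated;
* within-run z-scoring and event-locked epoching with pre-stimulus
  (−500–0 ms) baseline correction;
* the Reappraise > View contrast and a **max-cluster sign-flip permutation
  test** (cluster-forming threshold *T* = 3, 1000 iterations, largest-cluster
  null — the conservative Nichols–Holmes construction);
* behavioural outcomes: reappraisal success
  (`RS = reappraise − view` for negative stimuli, `view − reappraise` for
  positive, averaged within valence then across valences), affective
  distance (mean |view rating − 5| on the 9-point SAM scale), and dietary
  health-challenge success (HCS, % of self-controlled challenge choices);
* flat-prior Bayesian linear regression
  (`RS = β₀ + β₁·PDI + β₂·AffectiveDistance + β₃·PDI×AffectiveDistance + e`,
  and `HCS = PDI + TaskOrder + e`) with JZS Bayes factors against the
  intercept-only model;
* Bayesian rank correlation (PDI vs HCS) and a BEST-style paired shift test;
* **leave-2-participants-out** pairwise prediction of regulation success with
  a sign-flip permutation null for the accuracy.

## Worked example

```r
library(pupilcontrol)

cfg <- cohort_config(n_participants = 34, sampling_rate = 100, seed = 7)
cohort  <- generate_cohort(cfg)              # 34 participants, 5 blocks x 20 trials
epochs  <- preprocess_cohort(cohort)         # interpolate -> z-score -> epoch
con     <- build_contrast(epochs)            # Reappraise > View, participants x bins
ct      <- cluster_test(con, threshold = 3, n_iter = 1000, seed = 8)
print(ct)
#> <cluster_test_result> threshold T = 3, 1000 iterations (per_participant flips)
#>   largest cluster: 356 bins, 2.58-6.14 s, max |t| = 5.26, p < 0.001
#>   significant window: [2.58, 6.14] s

pdi    <- compute_pdi(con, ct)               # or compute_pdi(con, NULL) for 3.4-5.6 s
scores <- build_score_table(cohort, pdi)
print(fit_success_model(scores))
#> <pdi_regression> RS ~ PDI * AffectiveDistance  [engine: bayes, n = 34]
#>                   term estimate     sd            ci95
#>            (Intercept)   1.9881 0.0477  [1.894; 2.082]
#>                    PDI   0.2939 0.0480  [0.199; 0.389]
#>      AffectiveDistance   0.1405 0.0488  [0.044; 0.237]
#>  PDI:AffectiveDistance  -0.0248 0.0706 [-0.164; 0.115]
#> Bayes factor vs intercept-only: 4562 (jzs engine)

print(rank_correlation(scores$PDI, scores$HCS))
#> <rank_correlation> rho = 0.826, 95% CI [0.671; 0.912], PP(rho>0) = 1.0000,
#>   BF = 1.34e+08, R^2 = 0.682 (n = 34, fisher engine)

print(accuracy_permutation_null(scores, n_iter = 1000, seed = 9))
#> <loo2_prediction> accuracy = 0.7647 (429/561 splits correct, 9 ties)
#>   permutation null (1000 iterations): p = 0.012
```

Read: the cluster test finds a window of extra dilation during reappraisal;
each participant's mean contrast in that window is their PDI (z-units); a
1-SD-higher PDI predicts ~0.29 more SAM points of regulation success in this
simulated cohort; the PDI also rank-correlates with dietary health-challenge
success; and a model trained on 32 participants orders the two held-out
participants' success correctly in 76% of the 561 splits, above the
permutation chance level (p = 0.012). (The synthetic cohort is driven by a single latent
capacity, so its cross-domain associations are tighter than typical
empirical ones; see the vignette.)

The same pipeline runs from the shell:

```sh
Rscript -e 'pupilcontrol::pupil_cli()' run-all --simulate --seed 7 --out out/
Rscript -e 'pupilcontrol::pupil_cli()' simulate --seed 7 --out data/
Rscript -e 'pupilcontrol::pupil_cli()' pdi --input-dir data/ --out out/ --window-mode fixed_paper
```

Exit codes: 0 ok, 1 configuration error, 2 data error. CSV schemas (pupil
samples, events, ratings, choices, participants, scores) are documented in
`?read_pupil_csv` and friends; real recordings (e.g. EyeLink ASC sample
exports) are ingested by mapping their columns onto the pupil-sample schema.

## Documentation

The methods vignette (`vignettes/pupil-dilation-index.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the numerical
choices and limitations.
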
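# moodsig

Classifying weekly self-report mood streams into diagnostic groups when the
*absence* of a response is itself a signal.

## The problem

Mobile mood-monitoring platforms collect weekly questionnaires — ASRM
(mania), QIDS (depression, 0–27), EQ-5D (quality of life, 0–100) and GAD-7
(anxiety, 0–21) — from people with bipolar disorder (BD), borderline
personality disorder (BPD) and healthy controls (HC). Missing weeks are
ubiquitous, are unevenly distributed across diagnostic groups, and may be
caused by the current mood state itself (missing not at random). Standard
practice either drops missing weeks or imputes them, discarding the
information carried by the missingness pattern.

`moodsig` instead treats missing responses as a fifth channel. For a weekly
score stream with sentinel `-1` marking missing responses:

1. **Encode**: each missing entry is feed-forward filled (replaced by the
   nearest past valid value in its channel), and a cumulative missing-count
   channel *m<sub>t</sub>* = #\{missing responses up to week *t*\} is
   appended.
2. **Normalise and accumulate**: score channels are divided by their
   instrument maxima and cumulatively summed, giving a scale-free
   five-dimensional piecewise-linear path *X* : [0, W] → ℝ⁵ started at the
   origin.
3. **Windows**: overlapping ten-week windows are cut (stride 1), each
   re-based to the origin.
4. **Log-signature features**: each window path is summarised by its
   truncated log-signature *lS(X) = log S(X)*, where
   *S(X) = (1, S¹, …, S⁵, S¹¹, S¹², …)* is the collection of iterated
   integrals *S^{i₁…i_k} = ∫…∫ dX^{i₁}⋯dX^{i_k}* truncated at level
   *p* = 3, expressed on the Lyndon-word basis of the free Lie algebra —
   55 coordinates for 5 channels at level 3. Level-1 coordinates are the
   per-channel increments ("incremental effects"); higher words capture
   order-of-events interactions, including interactions with the missing
   signal.
5. **Classify and vote**: a random forest predicts window-level class
   probabilities under participant-level stratified 3-fold cross-validation
   (no participant ever appears on both sides of a split); participant
   diagnoses come from hard (majority) or soft (summed-probability) voting
   over their windows.

The package also implements the comparison baselines (naive per-window mean
scores; KNN and probabilistic-PCA imputation feeding flattened window
vectors; an external-imputer pathway), a synthetic three-group cohort
generator with group-dependent dynamics and missingness, and ternary-simplex
"spectrum" plots of participant probability vectors with highest-density
contours.

The signature core is written from first principles (truncated tensor
algebra, Chen products, tensor logarithm, Lyndon basis) and is verified
against a brute-force nested-Riemann iterated-integral oracle.

## Worked example

```r
library(moodsig)

coh <- simulate_cohort(cohort_config(n_per_group = c(BD = 10, HC = 10, BPD = 10),
                                     weeks = 20), seed = 1)
missing_rate(coh)
#>    BD    HC   BPD
#> 0.215 0.030 0.400

fit <- mrlsm(coh, rf = rf_control(ntree = 150), boot_B = 100, seed = 2)
summary(fit)
#> Mood-stream diagnostic classifier: missing-response-incorporated
#> log-signature features, level 3, 3-fold participant-level CV
#>   30 participants, 330 windows of 10 weeks
#>   accuracy: hard voting 93.3%, soft voting 93.3%
#>
#>   F1 by class:
#>         BD HC   BPD
#>  hard 0.889  1 0.909
#>
#>   one-vs-rest AUC (95% CI):
#>     BD: 0.985 (0.928-1.000)
#>     HC: 1.000 (1.000-1.000)
#>     BPD: 0.975 (0.918-1.000)
#>
#> Top features:
#>  rank feature importance                            interpretation
#>     1      L4     0.1562              Incremental effects of GAD-7
#>     2      L2     0.1004               Incremental effects of QIDS
#>     3      L3     0.1000              Incremental effects of EQ-5D
#>     4      L1     0.0568               Incremental effects of ASRM
#>     5      L5     0.0534 Incremental effects of the missing signal
```

The missingness rates show the generated group gradient (HC misses least,
BPD most). The fitted model classifies 28 of 30 held-out participants
correctly; the feature ranking says most of the discrimination comes from
the accumulated per-channel increments (equivalent information to mean
scores) plus the missing-signal channel and its interactions — the
information the naive mean-score model cannot see.

Compare against a baseline with the same folds (paired design):

```r
fit_naive <- mrlsm(coh, method = "naive", folds = fit$folds, seed = 2)
plot(fit)            # probability-simplex spectrum with density contours
predict(fit, coh)    # per-participant labels and soft probabilities
write_report(fit, "report/")   # JSON metrics + CSV confusion/importance
```

## Package tour

| Area | Functions |
|---|---|
| Signature core | `path_signature`, `tensor_mul`, `tensor_log`, `logsig`, `lyndon_words`, `brute_force_coefficient` |
| Encoding & windows | `encode_missing`, `normalize_accumulate`, `cut_windows`, `window_spec` |
| Cohorts & I/O | `mood_stream`, `mood_cohort`, `read_cohort`, `write_cohort`, `align_weekly`, `apply_exclusions`, `cohort_summary` |
| Model & metrics | `mrlsm`, `make_folds`, `fit_predict_cv`, `vote_hard`, `vote_soft`, `evaluate_predictions`, `importance_report` |
| Baselines | `naive_features`, `knn_impute`, `ppca_impute`, `flatten_features` |
| Simulation | `cohort_config`, `generate_cohort`, `inject_missing`, `simulate_cohort`, `missing_rate` |
| Spectrum | `simplex_project`, `simplex_barycentric`, `density_contours`, `plot_spectrum` |

The methods vignette (`vignettes/mood-signatures.Rmd`) documents the model,
its assumptions, the synthetic-data generator and the numerical design
choices in detail.
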
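---
title: "Log-signature features for mood streams with informative missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-signature features for mood streams with informative missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodsig)
```

## The model

`moodsig` classifies participants into three diagnostic groups — bipolar
disorder (BD), healthy control (HC), borderline personality disorder
(BPD) — from weekly self-report questionnaires: ASRM (mania), QIDS
(depression, 0–27), EQ-5D (quality of life, 0–100) and GAD-7 (anxiety,
0–21). The central idea is that *missing* responses are not noise to be
imputed away but a clinically informative channel: people miss more weeks
when unwell, and the three groups miss at very different rates.

The difficulty with treating omissions as data is that the resulting stream
is asynchronous — a score and the omission of a score never happen at the
same instant. Path signatures handle exactly this. For a piecewise-linear
path $X : [a, b] \to \mathbb{R}^d$, the signature is the collection of
iterated integrals

$$S(X)^{\,i_1,\dots,i_k} \;=\;
  \int_{a<t_1<\dots<t_k<b} dX^{i_1}_{t_1} \cdots dX^{i_k}_{t_k},$$

over all words $(i_1,\dots,i_k)$ in the channels. Level 1 collects total
increments, level 2 ordered-area (which channel moved before which), and so
on. The signature is invariant to reparameterisation, so irregular response
timing within a channel does not distort it. We truncate at level $p = 3$
and take the tensor logarithm: the *log-signature* removes the algebraic
redundancy of the signature (the shuffle relations) and lives in the free
Lie algebra, which we coordinatise by Lyndon words. For $d = 5$ channels at
$p = 3$ this gives $5 + 10 + 40 = 55$ coordinates per window (the Witt
formula).

The pipeline, per participant:

1. **Weekly alignment** (`align_weekly`): responses are binned into
   Monday-based calendar weeks from the first to the last task-active week;
   exact duplicates are dropped and only the first response of a week is
   kept. Unanswered weeks get the sentinel `-1`. Participants with fewer
   than ten weeks are excluded (`apply_exclusions`) — one window's worth of
   data is the minimum the method can use.
2. **Missing encoding** (`encode_missing`): sentinels are feed-forward
   filled, and a cumulative count of missing responses (summed across the
   four instruments) becomes a fifth channel. The fill does not pretend the
   missing value equals the last seen one; it makes the increments of both
   the score channels and the counting channel well defined, which is all
   the signature consumes.
3. **Normalise and accumulate** (`normalize_accumulate`): each score
   channel is divided by its instrument maximum, the count channel's weekly
   increments by the largest possible window total (4 × width), and the
   weekly values are cumulatively summed with an origin basepoint — the
   scale-free path convention for signature features.
4. **Ten-week windows** (`cut_windows`): overlapping windows (stride 1)
   are cut and each is re-based to start at the origin, so windows are
   translation-comparable and every participant contributes
   $W - 9$ windows.
5. **Classification** (`mrlsm`): a random forest on the 55 log-signature
   features predicts window-level class probabilities under stratified
   participant-level $k$-fold cross-validation ($k = 3$); participant
   labels come from hard (majority) or soft (summed-probability) voting.

### Why participant-level folds

Windows overlap heavily within a participant, so window-level
cross-validation would leak near-duplicates between training and test sets.
Folds are therefore drawn over participants, stratified by diagnosis, and
the train/test participant disjointness is asserted (not assumed) inside
the CV loop on every fold.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| truncation level `level` | 3 | — | captures up to three-way order interactions; 55 features keeps the forest well-conditioned on cohort-scale data |
| window `width` | 10 | weeks | short enough to keep short participants, long enough to show dynamics |
| window `stride` | 1 | weeks | overlapping windows maximise use of small cohorts |
| folds `k` | 3 | — | every participant held out exactly once |
| `rf_control(ntree)` | 500 | trees | stable importances; unlimited depth and $\sqrt{F}$ feature subsampling, the standard classification defaults |
| ASRM maximum | 20 | score | the instrument's published maximum; QIDS 27, GAD-7 21, EQ-5D 100 are fixed by their instruments |
| `knn_k` | 5 | neighbours | usual small-$k$ default for weekly observations |
| `ppca_components` | 2 | factors | fewer than the 4 observed variables; two factors (distress, mania) explain most variance in practice |

Two behaviours deserve explicit mention because no convention fully
determines them:

* **Leading missing weeks** have no "nearest past" value; they are
  back-filled with the first subsequent valid value. Like feed-forward,
  back-fill contributes *zero increment* across the filled span, so it adds
  no spurious signature mass.
* **Missing counts cross window boundaries**: encoding happens on the full
  stream before windowing, then each window is re-based. A window therefore
  sees its own local missing increments, while the fill values keep their
  full-stream context.
* **Vote ties**: a hard-vote tie falls back to the participant's soft vote
  (it uses the probability information instead of an arbitrary pick); an
  exact soft tie resolves to the lowest class index in the fixed order
  BD < HC < BPD, the class order used everywhere (probability vectors,
  confusion matrices, simplex vertices).

## Numerical design choices

* **Chen products, not quadrature**: signatures of piecewise-linear paths
  are computed exactly as products of segment tensor-exponentials
  ($\Delta^{\otimes k} / k!$ per level). The brute-force oracle
  (`brute_force_coefficient`) evaluates the nested integrals by left-Riemann
  sums on a uniform grid whose points include the segment endpoints
  (eliminating discretisation bias at kinks); its $O(1/n)$ bias is why
  oracle comparisons use tolerance $10^{-3}$ at 20\,000 subdivisions while
  exact algebraic identities (Chen, shuffle, subdivision invariance,
  $\exp\circ\log$) are tested at $10^{-10}$.
* **Lyndon coordinates by triangular solve**: each Lyndon word's standard
  bracketing is expanded into tensor coordinates once per $(d, p)$ and the
  per-level systems are QR-factorised and cached; the log-signature's
  coordinates are then linear solves. This is simpler than direct free-Lie
  arithmetic and exact at the levels used ($p \le 4$ in tests).
* **Degenerate paths**: a window whose accumulated path never leaves the
  origin (all scores zero, nothing missing) is legitimate and yields the
  zero feature vector, not an error.
* **PPCA-EM**: the probabilistic-PCA imputer runs exact EM with the missing
  entries and factor scores treated jointly as latent variables (posterior
  moments per missingness pattern; joint closed-form M-step for mean,
  loadings and noise), so the observed-data log-likelihood is provably
  non-decreasing — a property the tests check. Initialisation is
  deterministic (SVD of the mean-filled matrix); the noise floor is
  $10^{-12}$ so exactly low-rank inputs cannot divide by zero.
* **KNN imputation** uses missing-aware Euclidean distances (squared
  differences over mutually observed channels, rescaled by the fraction
  used). A fully missing week has no distances and falls back to pool
  column means.
* **Leakage-free imputation**: by default the imputers are fit within each
  training fold and applied to the held-out rows; a `transductive = TRUE`
  switch reproduces the impute-once-on-everything protocol.
* **Determinism**: every stochastic step (fold draw, forests, bootstrap,
  generator) flows from explicit seeds through an RNG-state-preserving
  helper; identical inputs and seeds give identical reports.
* **Highest-density contours**: the simplex spectrum estimates a 2-D
  Gaussian KDE (Scott's-rule bandwidth) on the projected points and picks
  thresholds whose super-level sets enclose 25/50/75 % of the estimated
  mass. If a group's points coincide exactly, a degenerate-density warning
  is raised and the point is drawn instead.

## What the synthetic generator does and does not emulate

No real cohort ships with the package, so `simulate_cohort` generates one
with the structure the method needs to be testable:

* latent per-instrument trajectories are mean-reverting first-order
  autoregressive processes around group baselines — stable and low for HC,
  high-variance for BPD;
* BD participants carry a semi-Markov episode process (weekly start hazard
  0.08, geometric durations with mean 4 weeks) that shifts ASRM up in manic
  episodes or QIDS/GAD-7 up and EQ-5D down in depressive ones;
* scores are clipped to instrument ranges and rounded to integers;
* weekly missingness has group base rates ordered HC (0.05) < BD (0.25) <
  BPD (0.40), blanking whole weeks by default, with an optional MNAR
  coefficient that raises the missingness odds with latent distress;
* the `"amoss-like"` preset uses 52 weeks and group sizes 53/52/34 for
  shape realism; the `"missingness-only"` preset gives all groups identical
  HC dynamics so that missingness is the *only* group signal.

This is the simplest process exhibiting the qualitative contrasts the
method targets; it is not a claim about the true generative process of any
real cohort. Passing tests on it show that the pipeline *can* recover group
structure from dynamics and missingness of this kind and that the missing
channel alone carries recoverable signal; they do not certify accuracy
levels on real data, where dynamics are richer, missingness mechanisms are
mixed, and labels are imperfect. One observation from the missingness-only
experiments: the naive mean-score baseline is not fully blind to
missingness, because heavier missingness makes window means noisier; the
log-signature model's advantage there is the direct, ordered encoding of
the missing events, and the gap (averaged over seeds) is what the tests
monitor.

## Problem sizes used by the tests

The test and verification suites were sized to run comfortably on one CPU:
algebra checks use 50 random paths with up to 5 segments in 2–3 dimensions;
end-to-end recovery and the missingness-only comparison use 30/30/30
participants over 52 weeks, averaged over 5 seeds; the permutation null
uses 20 label shuffles of a 26-week cohort with features extracted once
(only labels change between repeats). `scripts/acceptance.R` runs the
study-scale preset (139 participants, ~6\,000 windows) once end to end.

## Limitations

* The generator's parameters are chosen for qualitative realism, not fitted
  to any real cohort's summary statistics.
* Analysis is at the total-score level; item-level structure within
  questionnaires is not modelled.
* The external-imputer pathway accepts any completed cohort but the package
  does not implement multiple-imputation pooling — each completed dataset
  is evaluated singly.
* Log-signatures lose the universality property of full signatures, which
  is why they are paired with a non-linear classifier (the random forest)
  rather than a linear model.
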
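---
title: "Methods: synthetic motor-imagery EEG, ERD, CSP classification and transfer-entropy connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic motor-imagery EEG, ERD, CSP classification and transfer-entropy connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and numerical
choices: what the synthetic generator emulates, how each analysis stage is
defined, which parameters matter, and where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The paradigm and the synthetic generator

The package targets a three-condition, two-hand motor-imagery (MI) design.
Every trial consists of a fixation stage (−2–0 s), an imagery stage
(0–10 s) and a rest stage (10–13 s); each of the three conditions (`tMI`,
`rmMI`, `bcMI`) is performed 20 times per hand, i.e. 120 trials per session,
recorded at a native 1000 Hz. Epochs therefore span the full −2 to +13 s
around imagery onset. `synth_config()` encodes exactly these values as its
defaults.

Since no public recordings accompany this design, `generate_session()`
produces sessions with *planted, parameterized ground truth*:

* **Background activity** on every channel is broadband Gaussian noise plus
  a weak 1/f-shaped component (spectral amplitude ∝ f^(−1/2), mixed at half
  the broadband amplitude and renormalized). This gives an EEG-like
  spectral tilt without modelling artifacts — eye-blink/EMG removal by ICA
  is a manual step in real pipelines and deliberately out of scope here
  (`run_experiment()` simply has no artifact stage; synthetic data are
  artifact-free).
* **The mu/alpha rhythm** on the two motor channels (C3, C4) is narrowband
  noise: white noise band-passed to 10 ± 2.5 Hz and scaled to RMS amplitude
  `alpha_amp` (default 2, i.e. twice the broadband noise SD). A filtered-
  noise rhythm has realistic bandwidth and natural amplitude modulation,
  which a pure sinusoid would not; ERD estimation on it behaves like ERD
  estimation on data.
* **The planted ERD**: during the MI stage only, the oscillation on the
  channel contralateral to the imagined hand (left→C4, right→C3) is
  multiplied by `erd_depth` ∈ (0,1]. Band power scales with amplitude
  squared, so a depth *a* plants an expected ERD of `100·(a² − 1)` percent;
  the default 0.5 plants −75%, a strong but entirely plausible
  desynchronization for a good imager.
* **Directed couplings**: each `coupling()` adds to its sink channel a
  copy of the source channel, band-limited to the coupling's band, delayed
  by `lag` samples and scaled by `strength`, restricted to the MI stage of
  the listed conditions. Band-limiting before injection matters because
  the connectivity contrasts are evaluated per band. The defaults plant two
  beta-band edges (Pz→Cz, P3→F4; lag 8 samples, strength 0.8) active only
  in `bcMI`, mimicking condition-specific parieto-central/frontal flow.
* **Seeding**: a single session seed deterministically spawns one seed per
  trial through a fixed linear-congruential counter scheme, so single
  trials are reproducible independently of session length and order.

The trial order is randomized once per session from the session seed.

What the generator does **not** emulate: volume conduction and a head
model, realistic 32-channel topographies beyond the nine analysis channels,
ocular/muscular artifacts, inter-trial nonstationarity and learning
effects, and realistic inter-subject variability (synthetic "subjects"
differ only by seed). Passing tests on these data therefore demonstrate
*algorithmic correctness and recoverability of known effects at realistic
SNR* — not performance on any particular human dataset. In particular the
published headline accuracies of comparable studies depend on their actual
recordings and are not reproduction targets here.

The default `noise_sd` (1, with `alpha_amp` 2) was calibrated once so that
contralateral-vs-ipsilateral lateralization is detectable with a
14-subject synthetic cohort — the cohort size of the motivating design —
and was not revisited.

## Preprocessing

`bandpass()` uses a Hamming windowed-sinc FIR filter, the standard,
fully reproducible choice. The order follows the Hamming design rule
`N ≈ 3.3 / Δf_norm` with transition width `min(2 Hz, 0.25·lo)`, capped at a
third of the available samples. Zero phase is obtained by running the
symmetric (linear-phase) kernel once and removing its constant group
delay — equivalent in phase to forward–backward filtering but with
single-pass magnitude response (≈0.02 dB passband ripple, ≈53 dB stopband
attenuation, comfortably beyond a 1 dB/40 dB requirement). Edges are
reflect-padded by one kernel length so epoch boundaries carry no
transients. Filtering never mutates its input.

`downsample()` low-passes at 80% of the target Nyquist rate and keeps every
ratio-th sample; the ratio must be an integer. Event indices are rescaled
rounding toward zero — a deterministic, documented convention; at 1000→250
Hz the worst-case onset shift is 3 ms, an order of magnitude below the
smoothing length used by the ERD stage.

The pipeline order is filter → decimate → epoch. `epoch_trials()` cuts
`round((t1 − t0)·fs)` samples per event and groups epochs by
condition × hand; a window that leaves any event without enough samples is
an error naming that event.

## ERD/ERS

`erd_timecourse()` implements the classical band-power procedure: band-pass
each trial, square the samples, average across trials, smooth with a moving
average, and express each time point as `100·(A − R)/R` against the mean
smoothed baseline power `R` (fixation window, default −2–0 s). The
smoothing length (0.25 s) is a design choice: longer than one alpha cycle
(0.1 s), shorter than ERD dynamics. `erd_summary()` averages the
time course over an analysis window, by default 0–5 s — the early MI stage;
the full 0–10 s window is available through the argument since the
convention is ambiguous in the field. ERD is invariant to global amplitude
rescaling (both `A` and `R` scale), and bounded below by −100% because
power is nonnegative.

`lateralization_test()` compares paired per-subject contralateral and
ipsilateral summaries with the exact two-sided Wilcoxon signed-rank test.
All tests in the package are two-sided; directionality statements are
derived afterwards from the sign of the median difference.

## Sub-band CSP and LDA

`fit_csp()` averages per-trial channel covariances `S Sᵀ/t` — each
*trace-normalized* first, a robustness choice against slow amplitude drift
that leaves the noiseless definition unchanged — and solves the two-class
generalized eigenproblem by whitening with the class-2 covariance, so the
returned filters satisfy `EᵀR₁E = D` (descending) and `EᵀR₂E = I` by
construction. Rank-deficient covariances are an explicit error advising the
`ridge` argument rather than a silent pseudo-inverse.

The feature map after projection is the standard normalized log-variance of
the first and last `m` components, concatenated over the sub-bands of the
filter bank (defaults: alpha 8–13 Hz and beta 13–30 Hz). This feature
definition is an assumption of this package — recorded here prominently —
as is the classification window (the full 0–10 s MI stage).

`fit_lda()` is the Fisher discriminant `w = S_w⁻¹(μ₁ − μ₂)` with the
decision threshold at the midpoint of the projected class means, and an
optional shrinkage of the scatter toward its diagonal mean for singular
cases.

`cross_validate()` runs repeated stratified k-fold cross-validation
(defaults k = 10, 100 repeats) with the CSP models refitted *inside every
training fold* — the only reading of repeated CV that is free of
training-to-test leakage — and per-repeat reshuffling from a spawned seed,
making every accuracy vector reproducible. `select_m()` sweeps m over 1–8
and breaks ties toward the smaller m (fewer filters, less overfitting).

## Transfer entropy

`te_knn()` estimates `TE(Y→X)` — the information the source's past adds
about the sink's next value beyond the sink's own past — as the
four-entropy combination
`H(x^d, y^m) − H(x_{+u}, x^d, y^m) + H(x_{+u}, x^d) − H(x^d)`
with every joint entropy estimated by Kraskov-style k-nearest-neighbour
estimation. The implementation uses the digamma form of this combination
(the Frenzel–Pompe conditional mutual information), in which the four
Kraskov bias terms cancel analytically: one k-NN search in the full joint
space fixes a per-point radius, and neighbour counts within that radius in
the three marginal spaces enter as `ψ(K) + ⟨ψ(n_z+1) − ψ(n_xz+1) −
ψ(n_yz+1)⟩`. This is the estimator the established EEG-TE toolchains use;
it is equivalent in target quantity but far lower in bias than summing four
independently estimated entropies. Defaults follow the operative setting of
the motivating design: K = 4, prediction time u = 1, Theiler window 1
sample (excluding temporally adjacent points from both the search and the
counts, within trials only). Distances are max-norm after per-dimension
standardization, which makes estimates invariant to affine rescaling of
either series. Values are in nats; small negative estimates under
independence are ordinary estimator noise and are not clipped.

**Embedding selection.** The delay τ is the first lag at which the
autocorrelation drops below 1/e (bounded to 1–20) — the standard
decorrelation-time proxy. The dimension d uses Cao's statistics: E2 flat at
1 across dimensions identifies a purely stochastic series, for which d = 1
is returned (a deeper embedding of noise only dilutes the neighbour
statistics); otherwise the smallest d with saturating E1
(`E1(d)/E1(d+1) > 0.95`) is chosen, capped by `d_max`. The cap defaults to
3 in `te_matrix()`: band-limited EEG-like signals rarely support more, and
the k-NN estimator's data demand grows exponentially in total embedding
dimension. The source embedding m equals the sink's d, and both series
share the sink's τ — a deliberate simplification; the two roles (Cao for
dimension, autocorrelation decay for delay) are the methodologically
conventional assignment, and both are overridable via `embedding_params()`.

**Trial handling.** `te_matrix()` embeds each trial separately and pools
the embedded points across trials before the neighbour search (the Theiler
exclusion never crosses trial boundaries). Pooling is essential for the
2 s fixation baseline, which is far too short per trial for stable k-NN
estimation; per-trial estimation with averaging would be unusable there.
Pooled point sets are capped (`max_points`, deterministic even
subsampling) to bound the quadratic neighbour search.

`relative_te()` subtracts the fixation-stage matrix from the MI-stage
matrix element-wise; negative relative values (below-baseline coupling) are
retained on purpose.

The estimator is validated against the linear-Gaussian closed form: for
`Y_t = c·X_{t−lag} + ε`, `TE(X→Y) = ½·ln(1 + c²/σ²)` nats and
`TE(Y→X) = 0`. `generate_coupled_ar()` produces exactly this pair with the
population value attached, and the test suite checks bias, direction
recovery and consistency (shrinking error over n = 500/2000/8000) against
it.

## Group statistics

`wilcoxon_signed_rank()` computes the paired signed-rank test with an
*exact* null for n ≤ 25: zero differences are dropped (and counted), ties
are mid-ranked, the mid-ranks are doubled to integers, and the distribution
of the positive-rank sum over all 2ⁿ sign assignments is built by integer
convolution — so ties do not force an approximation. Above n = 25 the
normal approximation with continuity and tie corrections is used. Base R's
implementation switches to the approximation whenever ties occur, which is
why the exact-with-ties variant is implemented here; the tie-free paths of
the two agree exactly and are cross-checked in the tests.

`fdr_adjust()` is the Benjamini–Hochberg step-up adjustment (delegating to
`stats::p.adjust`; the tests verify it against a brute-force implementation
of the step-up definition). BH rather than BY is a design choice: the
72 tests in a panel are positively dependent at worst.

`contrast_conditions()` compares per-subject relative-TE values between two
conditions for each of the 72 directed pairs, adjusts within the family of
one band × hand × contrast panel, and retains edges with adjusted p < 0.05.
The family definition is open in principle (per panel vs across panels
jointly); per panel matches how such results are presented and is recorded
in the output attributes. The reported effect direction is the sign of the
median paired difference, attached after the two-sided retention decision.

A consequence worth knowing: with n subjects the smallest attainable exact
two-sided p is `2/2ⁿ`, so a 72-pair family needs n ≥ ~12 before *any* edge
can survive BH at α = 0.05. The motivating cohort size of 14 is just above
this floor, and the package's end-to-end recovery checks use exactly 14
synthetic subjects.

## Problem sizes used by the tests and the acceptance script

Scaled-down study conditions keep the full pipeline exercisable in minutes
while leaving every contract intact; the scales below are the package's
validation choices:

* Miniature sessions for structural tests: 250 Hz native rate, 4 trials
  per condition and hand, 2 s MI stage.
* Estimator oracle checks: n = 5000 samples, 20 independent-pair seeds for
  the null level, 100 (tests) / 50 (script) seeds for the closed-form
  comparison; pooled-point caps of 400–2000 in matrix computations.
* End-to-end recovery: 14 synthetic subjects, one hand, two conditions,
  beta band, 4 trials per cell, 2 s MI stage; 20 replicates in the tests
  and 12 in the acceptance script, for both the planted and the null
  configuration. Recall is the fraction of planted edges retained with the
  correct direction; FDR control is the mean retained fraction under the
  null plant.

## Known limitations

* The k-NN TE estimator is biased at small sample sizes; relative TE
  (task − baseline with the same estimator settings) cancels much of the
  common bias but not all sample-size dependence. Comparing windows of very
  different lengths at small `max_points` is not recommended.
* Embedding selection on band-limited noise usually returns d = 1; genuinely
  higher-order dynamics in real EEG may be under-embedded at the default
  `d_max = 3`.
* The exact Wilcoxon null is computed by convolution in O(n³) doubled-rank
  space — instant for n ≤ 25, which is the regime it is restricted to.
* `read_session()`/`write_session()` round-trip signals at 7 significant
  digits in a delimited text format; it is an interchange format for small
  sessions and fixtures, not a bulk storage format.
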
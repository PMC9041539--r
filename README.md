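# micnet

Motor-imagery EEG analysis in R: event-related desynchronization (ERD),
sub-band common-spatial-pattern (CSP) classification, and directed
effective-connectivity inference with k-nearest-neighbour transfer entropy.

## The problem

Motor-imagery brain–computer interface (MI-BCI) studies compare task
conditions — here three visual-feedback variants of hand-rotation imagery
(`tMI`, `rmMI`, `bcMI`), each performed with the left and the right hand —
and ask three questions of the multichannel EEG:

1. **Does imagery happen at all?** Imagining a hand movement suppresses the
   mu/alpha rhythm (8–13 Hz) over the contralateral motor cortex. The ERD
   time course quantifies this as a percentage band-power change against the
   pre-stimulus fixation baseline:

   `ERD% = 100 · (A − R) / R`

   with `A` the trial-averaged, smoothed band power after imagery onset and
   `R` the baseline power. Negative values are desynchronization.

2. **Are the two hands separable?** Sub-band CSP finds spatial filters `w`
   maximizing `‖w S₁‖² / ‖w S₂‖²` between the left- and right-hand trial
   covariances `R₁, R₂` via the generalized eigenproblem
   `Eᵀ R₁ E = D`, `Eᵀ R₂ E = I`; normalized log-variance features of the
   first and last `m` filters per frequency sub-band feed a Fisher linear
   discriminant, evaluated with repeated stratified 10-fold cross-validation
   (CSP refitted inside every training fold).

3. **How do brain regions drive each other?** Transfer entropy
   `TE(Y→X) = Σ P(x_{t+u}, x_t^d, y_t^m) · log [ P(x_{t+u} | x_t^d, y_t^m) /
   P(x_{t+u} | x_t^d) ]`
   measures the directed, model-free information flow from a source channel
   to a sink channel over delay-embedded states. It is estimated with a
   Kraskov-style k-nearest-neighbour estimator (K = 4, prediction horizon
   u = 1, Theiler window 1), embeddings chosen per channel (delay from
   autocorrelation decay, dimension from Cao's criterion). MI-stage TE minus
   fixation-stage TE ("relative TE") is contrasted between conditions across
   subjects with exact Wilcoxon signed-rank tests and Benjamini–Hochberg FDR
   control over the 72 directed pairs of a nine-electrode montage
   (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4).

Because such recordings are rarely shared, the package ships a synthetic
session generator with planted ground truth — contralateral alpha
attenuation of known depth and condition-specific directed couplings — so
the entire pipeline is testable end to end and its operating characteristics
(recall, false-discovery rate, estimator bias) are measurable.

## Worked example

Generate a two-condition session with the default planted ground truth
(ERD depth 0.5 on the contralateral motor channel; beta-band couplings
Pz→Cz and P3→F4 active only during `bcMI`), then recover both:

```r
library(micnet)

cfg <- synth_config(fs_native = 250, n_trials_per_hand = 10,
                    stage_durations = c(fixation = 2, mi = 4, rest = 1),
                    conditions = c("rmMI", "bcMI"), seed = 42)
sess <- generate_session(cfg)
sess$recording
#> <eeg_recording> 9 channels x 70000 samples @ 250 Hz (280.0 s), 40 events
#>   channels: F3, Fz, F4, C3, Cz, C4, P3, Pz, P4

trials <- epoch_trials(sess$recording, c(-2, 5))
left <- trials[["bcMI.left"]]

## ERD: left-hand imagery suppresses alpha power at the contralateral C4
sm <- erd_summary(erd_timecourse(left), window = c(0, 4))
dplyr::filter(sm, channel %in% c("C3", "C4"))
#>   channel    erd condition hand  band
#> 1 C3        6.75 bcMI      left  alpha
#> 2 C4      -76.3  bcMI      left  alpha
```

The planted attenuation 0.5 corresponds to `100·(0.5² − 1) = −75%`; the
estimate at C4 is −76.3% while the ipsilateral C3 stays near baseline.

```r
## relative transfer entropy: MI window minus fixation baseline, beta band
beta <- band_definition("beta", 14, 30)
task <- te_matrix(left, beta, window = c(0, 4), max_points = 1200)
base <- te_matrix(left, beta, window = "baseline", max_points = 1200)
rel  <- relative_te(task, base)
dplyr::arrange(tidy(rel), dplyr::desc(te))
#>   source sink      te band  condition hand  window
#> 1 P3     F4    0.124  beta  bcMI      left  relative
#> 2 Pz     Cz    0.110  beta  bcMI      left  relative
#> 3 F4     P3    0.0874 beta  bcMI      left  relative
#> ...
```

The two largest of the 72 directed relative-TE values are exactly the two
planted couplings. A full multi-subject study — generation, preprocessing,
ERD, classification, connectivity and FDR-corrected condition contrasts —
runs through `experiment_config()` + `run_experiment()`, which returns tidy
tables (`edges`, `erd`, `lateralization`, `accuracy`) and writes
reproducible CSVs. Result objects have `tidy()`, `glance()` and `autoplot()`
methods.

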
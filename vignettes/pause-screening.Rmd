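---
title: "Pause-based speech screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pause-based speech screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Speakers with Alzheimer's disease (AD) tend to pause more often and for
longer during spontaneous speech — picture-description tasks in particular —
because lexical retrieval becomes effortful. pausekit operationalizes that
observation as an acoustic-only screening pipeline: no transcription, no
linguistic content, just the temporal structure of silence. A recording is
encoded as a binary sequence of 0.03 s frames (1 = voiced, 0 = non-voiced),
fixed-length windows of that sequence are classified, and a subject's label
is the majority vote over their windows.

## The voice activity detector

Every 0.03 s frame is Hann-windowed and its power spectrum is split into six
sub-bands chosen to cover the phonetically informative range:
80–250, 250–500, 500–1000, 1000–2000, 2000–3000 and 3000–4000 Hz.
Band energies are log-scale,

$$E_i = 10 \log_{10}\Big(\sum_{f \in \text{band } i} |X(f)|^2 +
\varepsilon\Big), \qquad \varepsilon = 10^{-12},$$

and the total energy $E_t$ spans 80–4000 Hz. Working in dB matters: Gaussian
mixtures over raw linear energy are pathologically scaled, while log-energy
distributions of speech are close to bimodal-normal, which is what the model
assumes.

Each band's energy is scored under two two-component univariate Gaussian
mixtures — one for the silent state $H_0$, one for the voiced state $H_1$:

$$P(E_i \mid H_s) = w_{s1}\,\mathcal N(E_i;\mu_{s1},\sigma_{s1})
 + w_{s2}\,\mathcal N(E_i;\mu_{s2},\sigma_{s2}).$$

The per-band evidence is the base-2 log-likelihood ratio
$L_i = \log_2 \frac{P(E_i\mid H_1)}{P(E_i\mid H_0)}$, and the pooled
evidence is the weighted sum $L_t = \sum_{i=1}^6 K_i L_i$ with nonnegative
band weights $K_i$ summing to one (uniform by default). A frame is voiced
when

$$E_t > T_m \quad\text{and}\quad \big(\exists i:\ L_i > T_\tau
\ \ \text{or}\ \ L_t > T_a\big).$$

The energy gate $T_m$ cheaply rejects frames with essentially no energy
before any mixture is evaluated; gated frames report zero ratios.

### Numerical choices

* Both densities in the ratio are floored at $\varepsilon = 10^{-12}$, so
  $L_i$ stays bounded without branching even deep in a mixture's tail.
* Sub-band energies come from direct FFT bin summation over half-open
  intervals $[f_{\text{low}}, f_{\text{high}})$ — simple, and exactly
  reproducible by an independent periodogram oracle, which the test suite
  exploits. Frames are processed at 44,100 Hz directly; no internal
  resampling or filterbank is involved.
* The per-band condition is read existentially (*any* band above
  $T_\tau$). With six bands, a single strongly voiced band (e.g. a vowel's
  first-formant region) should be able to fire the detector on its own;
  requiring all bands would make the per-band test redundant with the
  pooled one.
* An all-zero frame lands exactly on the energy floor
  $10\log_{10}\varepsilon = -120$ dB in every band and is handled by the
  gate, not by an exception.

### Fitting the mixtures

No published parameter values exist for this detector family, so pausekit
fits them from calibration audio (typically the corpus under analysis
itself, requiring at least 10 s in total). Per band, the pooled frame
energies are fit with a four-component EM whose means start at the
10th/30th/70th/90th energy percentiles; after convergence the two
lowest-mean components form the silent mixture and the two highest the
voiced mixture. The state assignment is therefore fixed by energy ordering,
never by label supervision. The EM is fully deterministic (quantile
initialization, no random restarts), standard deviations are floored at
$10^{-3}$ dB, and calibration pooling is capped at 20,000 evenly spaced
frames — enough for 12 stable parameters per band at a fraction of the
cost. Constant-energy calibration audio is rejected explicitly.

Default thresholds are $T_\tau = 1.0$, $T_a = 0.5$ (in log2 units: a single
band must be twice as likely under the voiced model, or the pooled evidence
$\sqrt 2$ as likely) and $T_m$ = 5th percentile of calibration $E_t$ + 6 dB.
All of them are plain arguments, and fitted models serialize to JSON.

Two deliberate simplifications, both configurable by replacing the model
object: mixture parameters are static (no online adaptation), and frame
labels are not smoothed — the pause sequence shows raw per-frame decisions,
which is also what the visual comparisons plot.

## Pause encoding and segmentation

The frame labels become a `pause_sequence`; windows of
$\lfloor 4.0 / 0.03 \rfloor = 133$ frames are the classifier inputs.
Trailing remainders (of framing and of segmentation) are dropped rather
than zero-padded: padding would fabricate silent frames at the end of every
recording, which is exactly the signal the classifiers look for. Each
segment inherits its subject's diagnosis label for training — the standard
multiple-instance shortcut behind segment-level classification — and
subject-level prediction undoes the approximation by majority vote.

## Acoustic feature profiles

For comparison and for the ensemble, pausekit extracts functional acoustic
profiles per 4 s segment: short-time descriptors on 25 ms / 10 ms frames
(mel-band energies, MFCCs, F0 and voicing by autocorrelation, energy,
jitter/shimmer-style perturbation proxies, spectral moments, slopes,
rolloffs and band ratios), collapsed by statistical functionals (moments,
percentiles, regression coefficients, level-crossing and peak statistics).
The `"compare2013"` profile is 65 descriptors × 2 (contour and delta) × 49
functionals + 3 global descriptors = 6373 features; the `"egemaps"` profile
is 20 descriptors × 4 functionals + 8 temporal descriptors = 88 features.
The profile sizes match the published ComParE 2013 and eGeMAPS set
cardinalities, so downstream code sees the dimensionalities it would with
the standard toolkit sets; the individual descriptors are this package's
own native implementations, not a reimplementation of those exact sets.
Non-finite values are imputed to zero with a warning. Standardization uses
training-set statistics only and is applied for distance/margin classifiers
(LDA, KNN, SVM), not for trees.

## Classification and voting

Five classic classifiers are supported, with hyperparameters fixed and
recorded in each model's config: LDA; CART decision tree (Gini); KNN with
$k=5$, Euclidean; linear-kernel SVM with $C=1$ (libsvm's SMO-type solver);
and a tree bagger (100 bootstrap-aggregated trees, implemented as a random
forest with `mtry = p`, which makes each tree a plain bagged tree). When
features outnumber segments — the 6373-dimensional stream — classic LDA is
singular, so the discriminant switches to a diagonal-shrinkage variant:
pooled within-class variances shrunk toward their mean with intensity
$p/(p+n)$. That keeps the module's LDA surface meaningful on every stream
without pretending a full covariance estimate exists.

A subject's label is the majority vote over their segment predictions. The
ensemble pools the *segment-level* votes of all requested feature streams
into one vote set before voting, so streams weigh in proportionally to
their segment counts; fusing at the subject level instead would guarantee
uninformative ties whenever two streams disagree. Exact ties resolve to the
positive (AD) class — in a screening context the sensitive direction is the
defensible default — and the rule is explicit, tested, and trivially
changed by thresholding `vote_fraction`.

`run_experiment()` repeats the whole procedure over shuffled
subject-disjoint splits (70% of subjects per class for training, stratified
per run from a run-derived seed). Subject-disjointness is non-negotiable:
letting a subject contribute segments to both sides leaks identity, not
pathology.

## Evaluation

Confusion counts treat AD as positive; accuracy, precision, recall and F1
follow the standard formulas. Metrics with zero denominators are reported
as missing with a warning rather than coerced to zero — coercion would
silently bias averages across runs. Per-run accuracies feed a two-way
ANOVA with feature and classifier as factors (type-II sums of squares;
the design is required to be balanced, so they coincide with type-I).
Constant tables — zero residual *and* zero effect variance — are reported as
$F = 0$, $p = 1$ rather than NaN. A significant interaction triggers a
Tukey HSD over the feature × classifier cells, flagging the best cell and
the cells not significantly below it; Tukey is the declared choice of
follow-up procedure for all-pairs cell comparison at family-wise
$\alpha = 0.05$.

## The synthetic corpus generator

The generator emulates exactly one thing: a two-group contrast in pause
structure. Recordings alternate voiced and pause intervals with
exponentially distributed durations (memoryless, one parameter per state
per group). Voiced intervals are equal-amplitude harmonic complexes —
a random fundamental in 100–220 Hz per interval, partials up to 4 kHz,
synthesized in closed form via the Dirichlet kernel with a random phase —
over a noise floor; pauses carry only the floor. The floor is white noise
drawn at 8 kHz and linearly interpolated to 44.1 kHz, which band-limits it
below 4 kHz by construction. Ground-truth frame labels are defined on the
0.03 s grid by majority overlap with voiced intervals, so detector accuracy
is exactly scorable. All randomness flows from one corpus seed through
per-recording derived seeds.

Defaults encode the study conditions: both groups share a 1.5 s mean voiced
interval; the control group pauses for 0.5 s on average and the AD-like
group for 1.5 s (a 3:1 ratio, the contrast magnitude used in the recovery
checks), with a voiced amplitude of 0.5 and a −54 dB noise floor. Where a
check needs other sizes it says so explicitly: the contrast-recovery suite
uses 20 + 20 subjects with 120 s recordings over five corpus seeds for the
3:1 condition, and 10 + 10 subjects with 60 s recordings for the null and
1.5:1 conditions — the smaller legs only need to locate chance level and an
intermediate point, and these sizes keep the whole suite comfortably
re-runnable on a laptop.

What the generator does *not* emulate is as important as what it does: no
intelligible phones, no prosody, no dialect, no filled pauses ("uh"/"um"),
no channel noise or reverberation, no demographic structure. Passing the
recovery checks therefore shows that the pipeline detects pause-structure
differences when they exist and finds nothing when they do not; it says
nothing about effect sizes in clinical recordings, where the group contrast
is far subtler and other acoustic differences co-vary.

## Known limitations

* The detector's mixtures are fit on the corpus being analyzed; with very
  little silence (or very little speech) the four-component EM can place
  both low components inside one physical state. The 10 s calibration
  minimum and the percentile initialization make this rare but not
  impossible.
* The pause encoding deliberately discards everything except voicing: two
  recordings with identical pause structure but different content are
  identical to the classifier.
* Filled-pause detection and pause-duration discretization are out of
  scope by design; the binary sequence keeps the full temporal pattern
  instead.
* The ensemble's proportional pooling favours streams with more segments;
  with equal segmentation (the default) this reduces to equal weighting.
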
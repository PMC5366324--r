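---
title: "Predicting picture-naming errors in aphasia from single-trial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting picture-naming errors in aphasia from single-trial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Word-retrieval failure is near-universal in aphasia, and picture-naming
therapy sits between two philosophies: errorless learning (prevent errors by
maximal cueing) and retrieval practice (force effortful attempts, errors
included). A system that could predict, trial by trial, whether a client is
about to name correctly would let a clinician intervene with errorless
support only when an error is likely. The statistical core of such a system
is a within-participant model that maps single-trial EEG spectral features to
naming outcome and generalizes across sessions.

`eegnaming` implements that pipeline end to end: a synthetic multi-session
EEG generator with a planted, participant-specific link between band-limited
amplitude and accuracy; autoregressive spectral feature extraction; an
elastic-net solver with embedded cross-validation; session-based train/test
evaluation; scalp topographies of feature-outcome correlations; and the
behavioral tabulation and repeated-measures ANOVA that accompany such a
study.

## Study design assumed by the defaults

The canonical design is three sessions of 300 naming trials per participant
(900 total), recorded from 16 scalp electrodes (10-20 system, right-ear
reference) at 256 Hz. Each photograph is displayed for 10 s with at most 5 s
between trials; responses are scored live into ten categories (correct, six
error types, and three self-corrected variants). Stimuli come from a normed
photograph pool filtered to at least 20% naming agreement and a familiarity
rating of at least 3.75/5, then split at random into nine sets of 100 with
repeat names traded out of each session's three sets.

```{r, eval = FALSE}
library(eegnaming)
sig <- generate_signature(seed = 3, profile = "broca_moderate")
cfg <- generator_config(seed = 11)
sessions <- generate_participant(sig, cfg)
```

## The generative model

The generator is a stand-in for undeposited patient EEG; it reproduces the
statistical structure the analysis assumes, not aphasic physiology.

**Background.** Each channel is an independent AR(2) resonance (default peak
10 Hz, 2 Hz bandwidth — a stylized alpha rhythm) plus a white-noise floor,
in microvolts. Channels are independent; no volume conduction, eye blinks,
EMG or drifts are simulated.

**Outcome link.** Each participant signature draws a small set of effect
cells (channel, band), restricted to the 9-channel fronto-centro-parietal
grid, with weights `w`. Per trial, a latent state `s_t ~ N(0, 1)` drives
both sides of the link:

* accuracy: `P(correct) = plogis(a + b * sum(w) * s_t)`, with `a` the
  logit of the profile's first-attempt accuracy and `b = 1.5` by default;
* EEG: band-limited Gaussian noise added at each effect cell during the
  stimulus epoch, with RMS `effect_rms * max(0, 1 + g * s_t)`
  (`effect_rms = 14` uV, `g = 0.35`).

These defaults were fixed once, on the grounds that they produce
feature-outcome correlations in the 0.2-0.4 range typical of single-trial
EEG prediction studies of this kind; they are the study conditions for every
property test, not tuning knobs.

**Outcomes.** Incorrect trials draw an error type from the profile's
mixture over the six uncorrected categories; fragment, semantic and
phonological errors are promoted to their self-corrected variant with the
profile's per-family self-correction probability. The eight built-in
profiles span 26-94% first-attempt accuracy, from severe nonfluent
(frequent no-responses) to circumlocution-heavy conduction presentations.

**Latency.** Response latency is lognormal (median 2.5 s, sdlog 0.4),
truncated to (0.25 s, 10 s]. This distribution is invented — no latencies
are reported for this task — and was chosen so that essentially all epochs
(~99%) contain at least one full analysis window, matching the near-full
trial counts such studies report. No-response trials have no response onset
and use the full 10-s display epoch.

**Reproducibility.** Each session derives a single RNG stream from
`config$seed` and the session index; identical inputs give byte-identical
signals and event tables. Sessions serialize to EDF (16-bit) plus a TSV
event table; the generator seed is recorded as a comment line in the TSV.

## Spectral features

Each trial's feature epoch runs from stimulus onset to immediately before
the response onset (the full 10-s display for no-response trials), as
half-open sample intervals. Within the epoch, 1000-ms windows advance every
62.5 ms (256 and 16 samples at 256 Hz); only complete windows count, so an
epoch of `L` samples yields `floor((L - 256)/16) + 1` windows and a 10-s
epoch yields 145. Epochs shorter than one window mark the trial excluded
(flagged and logged, never silently dropped).

Each window is demeaned (no detrending, no prefiltering) and fitted with an
order-40 autoregressive model by Burg's lattice recursion, which is stable
(all reflection coefficients inside (-1, 1)) and well-behaved on 256-sample
windows where Yule-Walker estimates of order 40 would be badly biased. The
amplitude spectrum is

    amplitude(f) = sqrt( sigma^2 / fs ) / | 1 - sum_k a_k exp(-i 2 pi f k / fs) |

and band amplitude is the mean amplitude over an inclusive 0.25-Hz grid
across each of the six 4-Hz bands (6-9, 10-13, ..., 26-29 Hz). "Amplitude"
(square root of power density, averaged across the band grid) is a fixed
convention here; the alternative (root of the band-mean power) differs only
through Jensen's inequality and is what the test-suite periodogram oracle
uses, with a 10% agreement tolerance on long stationary signals. Features
are the per-(channel, band) means across the epoch's windows; windows are
anchored at stimulus onset, not a global grid, because the feature period is
trial-defined.

The 3-channel analysis uses Fz, Cz, Pz (18 features); the 9-channel
analysis adds F3, F4, C3, C4, P3, P4 (54 features). Whether windows
partially overlapping the response should count is not specified by the
design this package follows; only fully contained windows are used.

## The elastic net

The solver minimizes exactly

    || y - X b ||^2 + lambda2 || b ||^2 + lambda1 || b ||_1

with no per-observation (1/2n) factor, on column-standardized X (population
SD) and centered y; zero-variance columns are dropped and restored with zero
coefficients. Cyclic coordinate descent uses the soft-threshold update
`b_j <- S(x_j' r_(-j), lambda1/2) / (x_j' x_j + lambda2)`, a convergence
tolerance of 1e-7 on the largest coefficient change per sweep, warm starts
along a descending penalty ladder, and (in debug mode) an assertion that the
penalized objective never increases. With
`lambda1 >= 2 max_j |x_j' y_c|` the solution is exactly zero.

Because the popular per-observation parameterization differs, the test
suite's oracle mapping is documented here: a fit at `(lambda1, lambda2)`
equals a `glmnet` fit on the same standardized data at
`alpha = lambda1 / (lambda1 + 2 lambda2 s_y)` and
`lambda = (lambda1 + 2 lambda2 s_y) / (2n)`, where `s_y` is the population
SD of centered y (glmnet's internal response scaling enters its ridge term).
This mapping is used only for testing, never by the implementation.

**Embedded cross-validation.** Both penalties are chosen on the training
set by 10-fold CV, stratified on the outcome (sorted-cyclic fold assignment
after a seeded shuffle; folds with constant training outcome are re-drawn a
bounded number of times). The grid crosses 10 mixing ratios `alpha`
(`lambda1 = alpha * Lambda`, `lambda2 = (1 - alpha) * Lambda`) with a
50-point `Lambda` ladder per ratio, log-spaced from the kill threshold down
four decades. The winning cell minimizes mean held-out squared error; ties
within 1e-12 go to the largest `lambda1`, then largest `lambda2` — the
sparsest, smoothest candidate. Fold count and grid are package decisions
(the design this mirrors names neither). Note that minimum-CV selection
admits a few spurious features under a pure-noise outcome; the tests treat
"at most 2 of 8 candidates" as the null's near-zero selection behavior.

## Outcome coding, split and evaluation

Two outcome codings are analyzed. *Accuracy*: correct on the first
production attempt = 1, everything else (including self-corrections) = 0; a
total function over the schema. *Error correction*: correct = 2,
self-corrected = 1, uncorrected fragment/semantic/phonological error = 0;
no-response, circumlocution and perseveration trials are excluded from both
fitting and evaluation. Because quality is measured by Pearson correlation,
any increasing affine recoding of the ordinal levels gives identical r —
equal spacing is immaterial, though genuinely unequal spacings would not be.

Sessions 1-2 form the training set, session 3 the test set. The reported
training r is in-sample (and labeled so). Fits are evaluated by Pearson r
between predicted and observed values with residual degrees of freedom
`n - k - 1`, `k` the number of selected (nonzero) features; two-sided p
from `t = r sqrt(df / (1 - r^2))`; significance tiers * p<0.05 through
**** p<0.0001 (the four-star convention is an assumption, stated in report
footnotes). No multiplicity correction is applied across participants or
modes, mirroring the single-participant reporting style; a constant
prediction vector (the empty model) is recorded as r = 0. Scalp
topographies report the point-biserial correlation between each single-trial
(channel, band) amplitude and accuracy, positive = higher amplitude on
correct trials (blue in the plot method); constant columns are flagged and
recorded as 0.

## Behavioral statistics

`tabulate_responses()` produces per-category counts and percentages
(headline accuracy counts only first-attempt correct responses).
`rm_anova_one_way()` implements the one-way within-subject decomposition
(SS_total = SS_subjects + SS_conditions + SS_error, F on (c-1, (c-1)(s-1))
df), Mauchly's W with its chi-square approximation on c(c-1)/2 - 1 df from
orthonormalized Helmert contrasts of the condition covariance, and the
Greenhouse-Geisser epsilon = tr(T)^2 / ((c-1) tr(T^2)), which deflates both
df when sphericity is rejected at alpha = 0.05. Exactly identical columns
leave zero error variance (F would be 0/0) and raise an explicit error
rather than reporting F = 0.

## Numerical and design choices, in brief

* Sample indices are 0-based and epochs half-open, so window arithmetic has
  no off-by-one ambiguity; R-side indexing converts at the signal boundary.
* EDF was chosen as the signal container (the original acquisition format is
  a real-time BCI platform's; not re-implemented). The true sample count is
  stored in a reserved header field because EDF pads to whole 1-s records.
  Physical ranges are rounded to whole microvolts so the 8-byte ASCII header
  fields are exact; quantization is 16-bit. The writer is cross-checked
  against an independent Python EDF reader in the test suite.
* Keypad values 0-9 are assigned to the ten categories in schema row order;
  the published listing this mirrors never states them.
* A coefficient listing of two previously reported 3-channel models ships in
  `extdata/reference_models.tsv`; the nominal feature labels there ("8Hz_Fz")
  map to band edges as 8 -> 6-9, 12 -> 10-13, ..., 28 -> 26-29, a convention
  this package documents because the original labeling never states it.
* Degenerate inputs: zero-variance windows yield a flagged degenerate AR
  model with an identically zero spectrum; constant observed outcomes are an
  error in evaluation; constant feature columns are dropped (solver) or
  flagged (topography).

## What the tests do and do not show

Property tests run at the study design (3 x 300 trials, 16 channels,
256 Hz): with the default planted effect, the session-3 correlation is
significantly positive in at least 80% of 20 seeded runs and the topography
arg-max lands on a planted cell in at least 90%; with null signatures the
mean test r over 50 runs is within two standard errors of zero. The power
runs plant their effect cells within the fitted midline montage
(`effect_channels = channel_subset("3")`): a signature whose cells all fall
off the analyzed channels carries no recoverable signal there, so leaving
placement fully random would measure scalp coverage (about 56% of random
2-cell signatures touch the midline) rather than the pipeline's power. Solver and
ANOVA components are verified against independent oracles (OLS/ridge closed
forms, glmnet, car) at 1e-6 or better; spectral estimates against a
periodogram oracle at 10%. The acceptance script reports single-participant
runs plus a 10-run null calibration to stay lightweight.

Passing these tests shows the pipeline is correct and has power under the
generator's idealized conditions. It does not show that real aphasic EEG
carries such signal: the generator omits artifacts, non-stationarity,
cross-channel correlation, session-to-session drift, and any true
neurophysiology of error production, all of which make real prediction
harder. The per-participant heterogeneity of real data is represented only
through the behavioral profiles and randomized effect cells.

## Known limitations

* Strictly within-participant: no pooled or transfer models.
* Amplitude features only; phase features are out of scope.
* No artifact rejection is implemented (none is assumed by the design);
  optional per-trial exclusion enters only through the too-short-epoch rule.
* The error-correction model's ordinal coding is a convention; results are
  affine-invariant but not invariant to reordering or unequal spacing.
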
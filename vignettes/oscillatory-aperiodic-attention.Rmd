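---
title: "Separating oscillatory and aperiodic alpha activity and decoding visuospatial attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating oscillatory and aperiodic alpha activity and decoding visuospatial attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdecode)
```

## The analysis problem

Posterior alpha power (8-13 Hz) decreases over the hemisphere contralateral
to an attended visual location. Raw ("mixed") alpha power, however,
confounds two physiologically distinct components: a rhythmic alpha
oscillation and the broadband aperiodic background whose power spectrum
falls off approximately as $f^{-\beta}$. `specdecode` implements a pipeline
that separates the two with irregular-resampling auto-spectral analysis
(IRASA), derives five per-trial signals from the decomposition --
oscillatory alpha, aperiodic alpha, mixed alpha, aperiodic slope and
aperiodic intercept -- and quantifies how much information about the
attended location each signal carries, via multivariate decoding and a
lateralisation modulation index. A rhythmic-versus-arrhythmic TMS contrast
over a right posterior electrode cluster and a small statistical layer
complete the pipeline.

Because the package is validated end-to-end on synthetic EEG with known
ground truth, a first-class generator is part of the package rather than a
test fixture.

## The IRASA decomposition

For an epoch $x(t)$ the mixed spectrum is a Hann-tapered power spectrum
evaluated exactly at a 1 Hz grid from 1 to 35 Hz (the evaluation is a
discrete-time Fourier transform at the grid frequencies, i.e. the limit of
zero-padding; short 600 ms windows therefore pose no gridding problem,
only their intrinsic ~1.7 Hz resolution). The grid deliberately extends
beyond the bands of interest: the outermost bins act as buffers against
edge effects, and band-level statements use 3-30 Hz (broadband) and
8-13 Hz (alpha).

For each resampling factor $h \in \{1.10, 1.15, \ldots, 1.90\}$ the series
is fractionally resampled by $h$ and $1/h$. Resampling is performed in the
Fourier domain (spectrum truncation/zero-padding), which is exact sinc
interpolation of the band-limited signal with ideal anti-aliasing; the
effective factors $\mathrm{round}(nh)/n$ match the nominal ones to better
than 0.4% at the default 150-sample window, and the up/down pair is matched
so the geometric-mean cancellation below is preserved. Reading both
resampled spectra on the common grid displaces an oscillatory peak in
opposite directions while a power law $c f^{-\beta}$ stays exactly in
place: $\sqrt{c(hf)^{-\beta} \cdot c(f/h)^{-\beta}} = c f^{-\beta}$. The
geometric mean over each $(h, 1/h)$ pair therefore suppresses oscillations,
and the median across the 17 factors rejects what leaks through. The
oscillatory spectrum is the mixed minus the aperiodic spectrum, *not*
floored at zero -- off-peak values are legitimately negative and band means
may be too.

Implementation note: every step from raw samples to branch power spectra is
linear until the final squared modulus, so the whole decomposition of an
epoch set is precomposed into per-factor operator matrices and executed as
BLAS matrix products over all trials and channels at once. This is why
decomposing ~10,000 trial-channel windows takes seconds rather than hours
in pure R.

### Estimator degrees of freedom: the single-window caveat

A single tapered periodogram has ~2 degrees of freedom per frequency
regardless of window length, and the geometric-mean/median chain is a
concave function of those noisy values: its expectation is biased low by a
factor of roughly 0.65-0.87. The oscillatory spectrum (mixed minus
aperiodic) consequently carries a spurious *positive* offset of some tens
of percent of the local background. This is a property of the method
variant, not of any particular implementation -- an independent
reimplementation with polyphase resampling and single-window Welch spectra
reproduces the same numbers.

Two consequences shape the package design:

* **Per-trial features** (600 ms windows) necessarily use single-window
  spectra. The multiplicative bias is common to all trials, channels and
  conditions, so every measure the pipeline reports downstream --
  decoding accuracy, the modulation index, TMS contrasts, the log-log
  slope -- is insensitive to it. Absolute per-trial oscillatory power
  levels should not be interpreted.
* **Spectrum-level claims** (exponent recovery, oscillation/aperiodic
  separation) are only well-posed with more estimator degrees of freedom.
  `compute_psd()`, `irasa_aperiodic()` and `irasa_decompose()` therefore
  take a `seg_s` argument enabling Welch averaging over 50%-overlapping
  Hann segments; the validation suite uses 16 s realisations with 2 s
  segments (~13-28 dof per frequency), where the aperiodic estimate is
  accurate to a few percent and the oscillatory residual of a pure power
  law drops to ~1% of the aperiodic alpha power.

```{r welch-demo}
set.seed(1)
x <- generate_aperiodic_background(beta = 1.5, offset_log10 = 1.5,
                                   n_samples = 4000, srate = 250) +
  3 * sin(2 * pi * 10 * (0:3999) / 250)
ap <- irasa_aperiodic(x, 250, seg_s = 2)
osc <- compute_psd(x, 250, seg_s = 2) - ap
round(rbind(aperiodic = ap[8:13], oscillatory = osc[8:13]), 2)
fit_aperiodic(ap)  # slope ~ -1.5
```

## The synthetic generator and what it emulates

Each trial is the sum of

* an aperiodic background synthesised by spectral shaping of white
  Gaussian noise, so its expected one-sided spectrum is exactly
  $10^{\mathrm{offset}} f^{-\beta}$ (a construction that makes the
  spectral claims of the test suite analytically checkable);
* an alpha sinusoid with a fresh uniform phase per trial and channel
  (induced, not evoked, so per-condition ERP removal does not cancel it);
* optionally a time-locked evoked component identical across trials, to
  exercise ERP removal;
* white measurement noise.

Attention is encoded by cosine tuning of the posterior alpha amplitude:
for a cue at polar angle $\theta$ (clockwise from 12 o'clock) the lateral
factor is $g = |\sin\theta|$, so the 3 and 9 o'clock locations get full
modulation and vertical locations none. Over the posterior electrode
groups the amplitude is $a(1 - d\,g)$ contralateral and $a(1 + d\,g)$
ipsilateral to the cue (depth $d$ = `osc_mod_depth`); a second knob,
`ap_mod_depth`, scales the linear aperiodic power the same way. The
aperiodic knob is a synthetic device for exercising the pipeline, not a
claim about physiology. With both depths zero the label distribution is
exchangeable by construction, which the test suite verifies by permutation.

Defaults were fixed once, on realism grounds: $\beta = 1.5$ and
$\mathrm{offset} = 1.5$ put the aperiodic floor at 1 (unit$^2$)/Hz at
10 Hz; `alpha_amp = 3` makes the alpha peak roughly twice the floor (a
typical posterior alpha prominence); 30 channels, 600 ms epochs at 250 Hz
and 40 trials per condition mirror the montage and trial counts of the
multi-session attention recordings the pipeline emulates. The generator
does not simulate volume conduction, TMS pulse artifacts, eye movements or
realistic head geometry -- so passing tests certify the *analysis* under
the stated signal model, not robustness to those nuisances.

## Decoding

Within each condition, random groups of 4 trials are averaged into
pseudo-trials (leftovers dropped), raising feature signal-to-noise.
Features (one signal type across all channels -- signals are never mixed
in one decoder) are z-scored across *all* pseudo-trials with the
population denominator before the folds are drawn; this reproduces the
standardise-then-split convention of the original analysis, and the mild
train/test leakage it implies is label-independent, so chance-level
calibration is unaffected (a fold-wise mode, `per_fold = TRUE`, is
available). A stratified five-fold cross-validation trains one-vs-rest
linear SVMs (cost 1; the one-vs-rest scheme and cost are declared
defaults, since only "linear SVM" is fixed by the source analysis) and
scores the held-out fold with balanced accuracy (macro-averaged recall).
The whole construction is repeated 25 times with fresh pseudo-trial
partitions, each repetition's RNG derived deterministically from the
master seed and repetition index, and the grand mean is reported.

Null calibration on the generator's null mode (no modulation, randomly
permuted balanced labels) gives mean balanced accuracies within about
0.005 of the theoretical chance levels 0.125 (8-way) and 0.5 (2-way)
across 20 synthetic subjects. One caveat worth knowing: per-subject
cross-validated accuracy on a fixed finite trial sample has a variance
floor that repetition averaging cannot remove (~0.025 sd for the 8-way
configuration, ~0.06 for the 2-way), so a 20-subject mean is itself a
stochastic quantity with SE up to ~0.013.

## Lateralisation and TMS contrast

For signal $S$, hemisphere group $g$ and cue condition $c$, the index per
hemisphere is $(S_g^{left} - S_g^{right}) / \tfrac12 (S_g^{left} +
S_g^{right})$, and the combined index subtracts the right-hemisphere from
the left-hemisphere value, cancelling hemisphere-unspecific asymmetries.
Positive combined MI = contralateral decrease. The index is computed from
raw delay-period features averaged over trials before entering the
formula; baseline correction (plain linear subtraction in power units) is
applied only for topographic difference maps, where it is tied to
visualisation. For eight-location designs only the two horizontal
conditions enter the MI. Slope and intercept are signed quantities, so
negative MI values for them are expected and no positivity is enforced.

The TMS modulation statistic is the mean over trials and the 15-electrode
right posterior stimulation cluster of the rhythmic-minus-arrhythmic
difference per signal, and the frequency-resolved variant tests that
difference per 1 Hz bin over 3-30 Hz with one-sample t-tests and
Benjamini-Hochberg correction across bins.

## Statistical layer

One-sample t-tests (one-tailed for decoding against chance, two-tailed
for MI and TMS effects against zero), Benjamini-Hochberg FDR (step-up;
rejection iff adjusted p <= q), Holm step-down adjustment,
one-way repeated-measures ANOVA ($F = MS_{cond} / MS_{cond \times subj}$,
no sphericity correction -- none was used in the source analysis), and
partial Spearman correlation: ranks with average ties, categorical
covariates (dataset identity) encoded as drop-one indicators after rank
transformation, residualised by least squares, with a t-approximation on
$n - 2 - c$ degrees of freedom. All of these delegate the numerics to base
R (`t.test`, `p.adjust`, `aov`, `lm.fit`) behind validated interfaces; the
test suite checks each against an independent brute-force implementation
to 1e-10.

## Numerical and design choices

* **Half-open analysis windows** `[start, end)` with 0-based sample
  indexing; `round((end - start) * srate)` samples.
* **Degenerate inputs**: zero-variance feature columns, empty conditions,
  missing electrodes, non-positive fit-range power, and out-of-range
  p-values all raise immediate errors naming the offender. The pipeline's
  group-stats stage is the one place a degenerate sample is tolerated
  (accuracies saturating across a smoke run's few subjects), where the
  limiting p-value is reported instead.
* **Tie-breaks**: average ranks everywhere; argmax ties resolve to the
  first index; `derive_seed()` keeps every derived seed inside the 32-bit
  range.
* **Median across factors** uses one radix sort over all
  trial-channel-frequency cells, which keeps the median step O(n log n)
  overall rather than per-cell.
* **Greenhouse-Geisser correction** is deliberately absent (matching the
  source analysis); the ANOVA documents this.
* **Serialisation** is plain text (JSON metadata + CSV matrices) for
  epochs and tidy CSV for results; configurations round-trip through YAML.

## Validation problem sizes

The shipped suite validates, among other properties: exponent recovery
for $\beta \in \{0.5, 1, 1.5, 2, 2.5\}$ (20 seeds each, 16 s @ 250 Hz,
2 s Welch segments; mean slope within 0.15 of $-\beta$); paired-seed
oscillation injection (100 seeds; oscillatory argmax at 9-11 Hz,
aperiodic alpha shift < 10%); MI recovery at `osc_mod_depth` 0.3 and null
calibration of MI at depth 0 (100 seeds each, 100 trials/condition);
8-way and 2-way null decoding calibration (20 subjects at the generator
defaults); and decoding sensitivity at depth 0.3 across 20 subjects.
These sizes are the package's chosen validation conditions; the same code
paths scale to larger runs unchanged.
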
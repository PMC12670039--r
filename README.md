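# specdecode

Oscillatory-aperiodic decomposition and multivariate decoding of EEG
visuospatial-attention signals.

Posterior alpha power (8-13 Hz) lateralises when attention is directed to
one visual hemifield, but raw alpha power mixes two distinct components: a
rhythmic alpha oscillation and the broadband aperiodic background whose
power spectrum falls off as *f*<sup>-&beta;</sup>. `specdecode` is for
EEG researchers who want to know which of the two carries the attentional
signal. It provides:

* **IRASA decomposition** — irregular-resampling auto-spectral analysis:
  for each resampling factor *h* in 1.10-1.90 (step 0.05) the signal is
  fractionally resampled by *h* and 1/*h*; the geometric mean of each
  pair's power spectra cancels oscillatory peaks while leaving the
  *f*<sup>-&beta;</sup> background in place (&radic;(*c*(hf)<sup>-&beta;</sup> &middot;
  *c*(f/h)<sup>-&beta;</sup>) = *c f*<sup>-&beta;</sup>), and the median
  across factors gives the aperiodic spectrum; oscillatory = mixed &minus;
  aperiodic. Five per-trial signals are extracted: oscillatory alpha,
  aperiodic alpha, mixed alpha, aperiodic slope and intercept (log-log
  least squares over 3-30 Hz), plus aperiodic broadband power.
* **Pseudo-trial decoding** — random groups of 4 same-condition trials are
  averaged, z-scored across all epochs, and classified with stratified
  five-fold one-vs-rest linear SVMs scored by balanced accuracy
  (macro-averaged recall), averaged over 25 repetitions.
* **Lateralisation modulation index** — per hemisphere
  MI = (S<sup>left</sup> &minus; S<sup>right</sup>) / (&frac12;(S<sup>left</sup> + S<sup>right</sup>))
  over the posterior electrode groups, combined as MI<sub>left</sub> &minus;
  MI<sub>right</sub>; positive values mean the signal decreases
  contralateral to the attended side.
* **TMS contrast** — rhythmic-minus-arrhythmic TMS differences over a
  15-electrode right posterior cluster, including a frequency-resolved
  variant over 3-30 Hz with FDR control.
* **Statistics** — one/two-tailed one-sample t-tests, Benjamini-Hochberg
  FDR, Holm correction, one-way repeated-measures ANOVA, and partial
  Spearman correlation with a categorical covariate.
* **A synthetic EEG generator** with known aperiodic exponent and offset,
  condition-lateralised alpha modulation (cosine-tuned by cue angle),
  evoked components and noise — so the whole pipeline is validated against
  ground truth.

## Worked example

Simulate one subject with a 30% contralateral alpha-amplitude decrease,
decompose, and quantify the attentional signal:

```r
library(specdecode)

montage <- default_montage()                      # 30-channel posterior layout
cfg <- ground_truth_config(n_conditions = 2, n_trials_per_condition = 40,
                           osc_mod_depth = 0.3, seed = 42)
epochs  <- remove_erp(generate_attention_epochs(cfg, montage))
spectra <- irasa_decompose(epochs)
#> <spectrum_set> sim-seed42: 80 trials x 30 channels, 1-35 Hz (35 bins),
#>                17 resampling factors
features <- extract_features(spectra)

modulation_index(features, montage, left_label = 1, right_label = 2)
#>       signal mi_left mi_right mi_combined
#>    osc_alpha  0.6940  -0.6748       1.369
#>     ap_alpha  0.1272  -0.0967       0.224
#>    mix_alpha  0.4273  -0.3990       0.826
#> ap_broadband  0.1005  -0.1274       0.228
#>        slope  0.0530  -0.0716       0.125
#>    intercept  0.0892  -0.1128       0.202

repeat_decode(features, "osc_alpha", seed = 1)
#>    signal balanced_accuracy chance_level
#> osc_alpha             0.916          0.5
```

The oscillatory-alpha MI of 1.37 says the injected contralateral decrease
is recovered with the expected positive sign (alpha decreases contralateral
to the cue), and is much larger than the aperiodic-alpha MI of 0.22 — the
lateralisation here is carried mainly by the oscillation, as it should be
for a generator that modulates only the alpha amplitude. Decoding the cued
side from oscillatory-alpha features across all 30 channels reaches a
balanced accuracy of 0.92 against a two-way chance level of 0.5.

`run_pipeline(pipeline_config(...))` chains all stages over many synthetic
subjects and writes tidy CSVs plus a provenance log;
`inst/scripts/run_pipeline.R` is a command-line wrapper around it driven by
a YAML configuration.

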
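#' Ground-truth configuration for the synthetic EEG generator
#'
#' Collects every knob of the generator in one validated list. The defaults
#' emulate the multi-session covert-attention recordings the pipeline targets:
#' 30 channels, 600 ms analysis epochs at 250 Hz, an aperiodic background
#' with exponent 1.5 and log10 offset 1.5 (so the 10 Hz aperiodic floor is
#' about 1 (unit^2)/Hz), a 10 Hz alpha rhythm of amplitude 3 whose posterior
#' amplitude is modulated by the attended side, and unit white measurement
#' noise.
#'
#' @param n_trials_per_condition Trials per condition.
#' @param n_conditions Number of cued locations: 2 (left/right) or 8 (clock
#'   positions; location 3 is 3 o'clock = attend right, location 7 is
#'   9 o'clock = attend left).
#' @param n_channels Channel count; must match the montage used.
#' @param srate Sampling rate (Hz).
#' @param window_s Epoch length (seconds); `window_s * srate` must be a whole
#'   number of samples, at least 64.
#' @param beta Aperiodic exponent: background power spectrum proportional to
#'   `f^(-beta)`; non-negative.
#' @param offset_log10 Aperiodic offset, log10 power units: the background
#'   spectrum is `10^offset_log10 * f^(-beta)` (power per Hz).
#' @param alpha_freq Alpha oscillation frequency (Hz), in 8-13.
#' @param alpha_amp Alpha sinusoid amplitude (signal units).
#' @param osc_mod_depth Fractional contralateral decrease / ipsilateral
#'   increase of the posterior alpha amplitude, in `[0, 1)`.
#' @param ap_mod_depth Fractional condition-dependent change of the linear
#'   aperiodic power of posterior channels, in `[0, 1)` (same contralateral
#'   decrease convention).
#' @param erp_amp Amplitude of a time-locked evoked component added
#'   identically to every trial (0 disables); exercised by [remove_erp()].
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param seed Integer seed; identical configs generate bit-identical data.
#' @return A validated list of class `"ground_truth_config"`.
#' @export
ground_truth_config <- function(n_trials_per_condition = 40,
                                n_conditions = 8,
                                n_channels = 30,
                                srate = 250,
                                window_s = 0.6,
                                beta = 1.5,
                                offset_log10 = 1.5,
                                alpha_freq = 10,
                                alpha_amp = 3,
                                osc_mod_depth = 0.2,
                                ap_mod_depth = 0,
                                erp_amp = 1,
                                noise_sd = 1,
                                seed = 1L) {
  n_samples <- window_s * srate
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("window_s * srate must be an integer sample count")
  if (round(n_samples) < 64)
    stop("window_s * srate must be at least 64 samples")
  if (!n_conditions %in% c(2L, 8L))
    stop("n_conditions must be 2 or 8")
  if (beta < 0) stop("beta must be non-negative")
  for (nm in c("osc_mod_depth", "ap_mod_depth")) {
    v <- get(nm)
    if (v < 0 || v >= 1) stop(nm, " must lie in [0, 1)")
  }
  if (alpha_freq < 8 || alpha_freq > 13)
    stop("alpha_freq must lie in the 8-13 Hz alpha band")
  if (n_trials_per_condition < 1) stop("need at least one trial per condition")
  structure(
    list(n_trials_per_condition = as.integer(n_trials_per_condition),
         n_conditions = as.integer(n_conditions),
         n_channels = as.integer(n_channels),
         srate = srate, window_s = window_s,
         beta = beta, offset_log10 = offset_log10,
         alpha_freq = alpha_freq, alpha_amp = alpha_amp,
         osc_mod_depth = osc_mod_depth, ap_mod_depth = ap_mod_depth,
         erp_amp = erp_amp, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "ground_truth_config")
}

#' Cued-location geometry
#'
#' Maps condition labels to the polar angle of the cued location (degrees
#' clockwise from 12 o'clock). For 8 conditions these are the 8 clock
#' positions (label 1 = 12 o'clock, label 3 = 3 o'clock, ...); for 2
#' conditions label 1 is 9 o'clock (attend left) and label 2 is 3 o'clock
#' (attend right). The lateral tuning factor is `g = |sin(theta)|` (the
#' cosine of the angle from the horizontal meridian), so purely horizontal
#' locations get full modulation and vertical ones none; `side` is +1 for
#' right-of-midline cues, -1 for left, 0 on the vertical meridian.
#'
#' @param n_conditions 2 or 8.
#' @return Data frame with `label`, `angle_deg`, `g`, `side`.
#' @export
condition_geometry <- function(n_conditions) {
  if (n_conditions == 2L) {
    angle <- c(270, 90)  # left, right
  } else if (n_conditions == 8L) {
    angle <- (seq_len(8) - 1) * 45
  } else stop("n_conditions must be 2 or 8")
  s <- sinpi(angle / 180)
  data.frame(label = seq_len(n_conditions), angle_deg = angle,
             g = abs(s), side = sign(round(s, 12)))
}

#' Labels of the two horizontal (pure left/right) conditions
#'
#' @param n_conditions 2 or 8.
#' @return Named integer vector `c(left = ..., right = ...)`.
#' @export
horizontal_labels <- function(n_conditions) {
  geom <- condition_geometry(n_conditions)
  c(left = geom$label[geom$side < 0 & geom$g == 1],
    right = geom$label[geom$side > 0 & geom$g == 1])
}

# Draw n_series aperiodic background series (columns) from the current RNG.
# amp_scale multiplies the *amplitude* of each column (power scales by its
# square). Expected one-sided PSD of column j: amp_scale[j]^2 * 10^offset *
# f^(-beta), by construction of the Fourier bin amplitudes.
.background_matrix <- function(beta, offset_log10, n_samples, srate,
                               n_series = 1L, amp_scale = 1) {
  n <- as.integer(n_samples)
  half <- (n - 1L) %/% 2L             # strictly-positive non-Nyquist bins
  f <- (1:half) * srate / n
  a <- sqrt(srate * 10^offset_log10 * f^(-beta) / (2 * n))
  amp_scale <- rep_len(amp_scale, n_series)
  X <- matrix(0 + 0i, n, n_series)
  re <- matrix(stats::rnorm(half * n_series), half, n_series)
  im <- matrix(stats::rnorm(half * n_series), half, n_series)
  X[2:(half + 1L), ] <- a * (re + 1i * im) / sqrt(2)
  if (n %% 2L == 0L) {                # real Nyquist bin
    a_nyq <- sqrt(srate * 10^offset_log10 * (srate / 2)^(-beta) / (2 * n))
    X[n / 2L + 1L, ] <- a_nyq * stats::rnorm(n_series)
  }
  X[n:(n - half + 1L), ] <- Conj(X[2:(half + 1L), ])
  x <- Re(stats::mvfft(X, inverse = TRUE))
  sweep(x, 2, amp_scale, `*`)
}

#' Generate an aperiodic (1/f) background series
#'
#' Synthesises a real-valued series whose expected one-sided power spectrum
#' is `10^offset_log10 * f^(-beta)` (power per Hz), by scaling independent
#' Gaussian Fourier amplitudes by `f^(-beta/2)` and inverse-transforming;
#' the DC component is fixed to 0.
#'
#' @param beta Aperiodic exponent (>= 0).
#' @param offset_log10 log10 of the spectral offset.
#' @param n_samples Series length (>= 64).
#' @param srate Sampling rate (Hz).
#' @param seed Optional integer seed; `NULL` draws from the current RNG.
#' @param n_series Number of independent series (returned as columns when
#'   greater than 1).
#' @return Numeric vector (or `n_samples` x `n_series` matrix).
#' @examples
#' x <- generate_aperiodic_background(1.5, 0, 512, 250, seed = 1)
#' @export
generate_aperiodic_background <- function(beta, offset_log10, n_samples,
                                          srate, seed = NULL, n_series = 1L) {
  if (n_samples < 64) stop("n_samples must be at least 64")
  if (beta < 0) stop("beta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  x <- .background_matrix(beta, offset_log10, n_samples, srate, n_series)
  if (n_series == 1L) drop(x) else x
}

# Shared generator core: builds the trials x channels x samples array for a
# given per-trial label vector. Used by both the attention and null variants.
.generate_epochs <- function(config, montage, labels) {
  cf <- config
  n <- as.integer(round(cf$window_s * cf$srate))
  n_tr <- length(labels)
  n_ch <- cf$n_channels
  geom <- condition_geometry(cf$n_conditions)
  g <- geom$g[labels]
  side <- geom$side[labels]

  side_of <- rep(0, n_ch)  # +1 right-posterior group, -1 left-posterior
  side_of[match(montage$left_posterior, montage$channel_names)] <- -1
  side_of[match(montage$right_posterior, montage$channel_names)] <- 1

  # trial x channel modulation sign: +1 where the channel is ipsilateral to
  # the cue (increase), -1 where contralateral (decrease), 0 unmodulated.
  ipsi <- outer(side, side_of)          # +1 ipsilateral, -1 contralateral
  osc_amp <- cf$alpha_amp * (1 + cf$osc_mod_depth * g * ipsi)
  ap_pow <- 1 + cf$ap_mod_depth * g * ipsi
  t_s <- (0:(n - 1)) / cf$srate

  set.seed(cf$seed)
  phases <- matrix(stats::runif(n_tr * n_ch, 0, 2 * pi), n_tr, n_ch)
  bg <- .background_matrix(cf$beta, cf$offset_log10, n, cf$srate,
                           n_series = n_tr * n_ch,
                           amp_scale = sqrt(as.vector(ap_pow)))
  noise <- matrix(stats::rnorm(n * n_tr * n_ch, sd = cf$noise_sd),
                  n, n_tr * n_ch)
  erp <- if (cf$erp_amp != 0) {
    cf$erp_amp * sin(2 * pi * 3 * t_s) * .hann(n)
  } else rep(0, n)

  # alpha sinusoid, random phase per trial x channel (induced, not evoked)
  osc <- sin(outer(2 * pi * cf$alpha_freq * t_s, as.vector(phases), `+`))
  osc <- sweep(osc, 2, as.vector(osc_amp), `*`)
  flat <- bg + noise + osc + erp
  data <- aperm(array(flat, c(n, n_tr, n_ch)), c(2, 3, 1))
  epoch_set(data, srate = cf$srate, labels = labels,
            channels = montage$channel_names,
            subject_id = sprintf("sim-seed%d", cf$seed))
}

.check_config_montage <- function(config, montage) {
  if (!inherits(montage, "montage")) stop("montage must be a 'montage' object")
  if (length(montage$channel_names) != config$n_channels)
    stop("montage channel count (", length(montage$channel_names),
         ") does not match config n_channels (", config$n_channels, ")")
}

#' Generate synthetic attention epochs with known ground truth
#'
#' Each trial is an aperiodic `1/f` background plus an alpha sinusoid with
#' random phase, an optional evoked component common to all trials, and
#' white noise. Over the posterior electrode groups of the montage the alpha
#' amplitude is `alpha_amp * (1 - osc_mod_depth * g)` contralateral and
#' `alpha_amp * (1 + osc_mod_depth * g)` ipsilateral to the cued side, where
#' `g` is the lateral tuning factor of [condition_geometry()]; the linear
#' aperiodic power is scaled by `1 -/+ ap_mod_depth * g` in the same way.
#' Midline and non-posterior channels are unmodulated. With both modulation
#' depths 0 the trial distribution is identical across conditions.
#'
#' @param config A [ground_truth_config()].
#' @param montage A [make_montage()] whose channel count matches the config.
#' @return An [epoch_set()] with per-trial labels `1..n_conditions`,
#'   `n_trials_per_condition` trials each.
#' @export
generate_attention_epochs <- function(config, montage) {
  .check_config_montage(config, montage)
  labels <- rep(seq_len(config$n_conditions),
                each = config$n_trials_per_condition)
  .generate_epochs(config, montage, labels)
}

#' Generate null epochs (no condition effect, random labels)
#'
#' Identical to [generate_attention_epochs()] with both modulation depths
#' forced to zero; labels are a random permutation of the balanced label
#' vector, so they carry no information about the data.
#'
#' @inheritParams generate_attention_epochs
#' @return An [epoch_set()] with exchangeable labels.
#' @export
generate_null_epochs <- function(config, montage) {
  .check_config_montage(config, montage)
  cf <- config
  cf$osc_mod_depth <- 0
  cf$ap_mod_depth <- 0
  set.seed(cf$seed)
  labels <- sample(rep(seq_len(cf$n_conditions),
                       each = cf$n_trials_per_condition))
  cf$seed <- as.integer((as.double(cf$seed) * 7919 + 1) %% 2147483647)
  .generate_epochs(cf, montage, labels)
}
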
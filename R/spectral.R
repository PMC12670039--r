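# Spectral decomposition: tapered DTFT power spectra, Fourier resampling,
# and the IRASA oscillatory/aperiodic separation.
#
# All per-trial spectra reduce to linear operators applied to the raw series
# (or to its DFT), so the whole decomposition of an epoch set runs as a few
# BLAS matrix products over trials x channels series at once. Operators are
# cached per (length, srate, grid, h).

.op_cache <- new.env(parent = emptyenv())

# periodic Hann window; taper used by every spectral estimate
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

.cache_get <- function(key, build) {
  if (!exists(key, envir = .op_cache)) assign(key, build(), envir = .op_cache)
  get(key, envir = .op_cache)
}

# Complex DTFT-evaluation operator for a Hann-tapered series of length n at
# arbitrary frequencies (Hz): P(f) = scale * |B %*% x|^2, one-sided,
# (units)^2/Hz. Equivalent to an infinitely zero-padded tapered periodogram
# read off at exactly the requested frequencies.
.psd_op <- function(n, srate, freqs) {
  key <- paste("psd", n, srate, paste(freqs, collapse = ","), sep = "|")
  .cache_get(key, function() {
    w <- .hann(n)
    E <- exp(-2i * pi * outer(freqs / srate, 0:(n - 1)))
    B <- E * rep(w, each = length(freqs))
    list(Br = Re(B), Bi = Im(B), scale = 2 / (srate * sum(w^2)))
  })
}

# series in columns -> freqs x n_series power matrix
.psd_matrix <- function(X, srate, freqs) {
  op <- .psd_op(nrow(X), srate, freqs)
  op$scale * ((op$Br %*% X)^2 + (op$Bi %*% X)^2)
}

# Welch variant: average the tapered power spectra of 50%-overlapping
# segments of length seg_len (per column). Falls back to the single-window
# estimate when the series is not longer than one segment.
.welch_matrix <- function(X, srate, freqs, seg_len = NULL) {
  n <- nrow(X)
  if (is.null(seg_len) || seg_len >= n) return(.psd_matrix(X, srate, freqs))
  seg_len <- as.integer(seg_len)
  if (seg_len < 64) stop("Welch segments must have at least 64 samples")
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  segs <- do.call(cbind, lapply(starts, function(s)
    X[s:(s + seg_len - 1L), , drop = FALSE]))
  P <- .psd_matrix(segs, srate, freqs)
  arr <- array(P, c(length(freqs), ncol(X), length(starts)))
  rowMeans(arr, dims = 2)
}

.check_freq_grid <- function(freqs, srate) {
  if (any(freqs <= 0) || any(freqs >= srate / 2))
    stop("frequency grid must lie strictly inside (0, srate/2)")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
}

#' Default frequency grid: 1 to 35 Hz in 1 Hz steps
#' @return Numeric vector `1:35`.
#' @export
default_freq_grid <- function() as.numeric(1:35)

#' Default IRASA resampling factors: 1.10 to 1.90 in steps of 0.05
#' @return Numeric vector of 17 factors.
#' @export
default_h_set <- function() seq(1.10, 1.90, by = 0.05)

#' Power spectral density on a fixed frequency grid
#'
#' Hann-tapered FFT-based power spectrum of a series, evaluated exactly at
#' the requested grid frequencies (the limit of a zero-padded periodogram,
#' so the 1 Hz grid is meaningful even for 600 ms windows). Power is
#' one-sided, in (signal units)^2 per Hz.
#'
#' @param series Numeric vector, at least 64 samples.
#' @param srate Sampling rate (Hz).
#' @param freq_grid Frequencies (Hz) at which to evaluate; default 1-35 Hz in
#'   1 Hz steps. Must lie strictly inside (0, srate/2).
#' @param seg_s Optional Welch segment length in seconds: when set (and
#'   shorter than the series) the spectrum is the average over Hann-tapered
#'   50%-overlapping segments of this length, trading frequency resolution
#'   for estimator degrees of freedom. The default `NULL` uses the whole
#'   window as a single segment.
#' @return Named numeric vector of power values, one per grid frequency.
#' @examples
#' x <- sin(2 * pi * 10 * (0:499) / 250)
#' p <- compute_psd(x, 250)
#' which.max(p)  # 10 Hz
#' @export
compute_psd <- function(series, srate, freq_grid = default_freq_grid(),
                        seg_s = NULL) {
  if (length(series) < 64) stop("series must have at least 64 samples")
  .check_freq_grid(freq_grid, srate)
  seg_len <- if (is.null(seg_s)) NULL else round(seg_s * srate)
  p <- drop(.welch_matrix(matrix(series, ncol = 1), srate, freq_grid,
                          seg_len))
  names(p) <- freq_grid
  p
}

# Spectrum index map for Fourier resampling n_in -> n_out: triples
# (dst, src, coef) with Y[dst] += coef * X[src]; Nyquist bin split on
# upsampling and folded on downsampling so the result stays real.
.spectrum_map <- function(n_in, n_out) {
  N <- min(n_in, n_out)
  half <- N %/% 2L
  kmax <- if (N %% 2L == 0L) half - 1L else half
  dst <- 1L; src <- 1L; coef <- 1  # DC
  if (kmax >= 1L) {
    k <- 1:kmax
    dst <- c(dst, k + 1L, n_out + 1L - k)
    src <- c(src, k + 1L, n_in + 1L - k)
    coef <- c(coef, rep(1, 2 * kmax))
  }
  if (N %% 2L == 0L) {
    if (n_out == n_in) {
      dst <- c(dst, half + 1L); src <- c(src, half + 1L); coef <- c(coef, 1)
    } else if (n_out < n_in) {  # downsample: fold +/- Nyquist components
      dst <- c(dst, half + 1L, half + 1L)
      src <- c(src, half + 1L, n_in + 1L - half)
      coef <- c(coef, 1, 1)
    } else {                    # upsample: split the real Nyquist bin
      dst <- c(dst, half + 1L, n_out + 1L - half)
      src <- c(src, half + 1L, half + 1L)
      coef <- c(coef, 0.5, 0.5)
    }
  }
  list(dst = dst, src = src, coef = coef)
}

#' Fourier (band-limited) resampling to a new length
#'
#' Resamples a series (or each column of a matrix) to `n_out` samples by
#' truncating or zero-padding its discrete spectrum: exact sinc interpolation
#' of the periodic band-limited signal, with ideal anti-aliasing on
#' downsampling. Used for the non-integer resampling factor pairs of
#' [irasa_aperiodic()].
#'
#' @param x Numeric vector or matrix (series in columns).
#' @param n_out Target length (>= 2).
#' @return Vector or matrix of length/row count `n_out`.
#' @export
resample_fourier <- function(x, n_out) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n_in <- nrow(x)
  if (n_out < 2) stop("n_out must be at least 2")
  X <- stats::mvfft(x)
  Y <- matrix(0 + 0i, n_out, ncol(x))
  map <- .spectrum_map(n_in, n_out)
  for (j in seq_along(map$dst))
    Y[map$dst[j], ] <- Y[map$dst[j], ] + map$coef[j] * X[map$src[j], ]
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n_in
  if (vec) drop(y) else y
}

# Composite IRASA operator for one resampled length m given input length n:
# resample (spectrum map, 1/n inverse DFT) -> Hann taper -> DTFT at the grid.
# Returns freqs x n complex operator split into real/imag parts plus the PSD
# scale for length m.
.irasa_branch_op <- function(n, m, srate, freqs) {
  key <- paste("branch", n, m, srate,
               paste(c(range(freqs), length(freqs)), collapse = ":"),
               sep = "|")
  .cache_get(key, function() {
    w <- .hann(m)
    B <- exp(-2i * pi * outer(freqs / srate, 0:(m - 1))) *
      rep(w, each = length(freqs))
    G <- exp(2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
    BG <- B %*% G                      # freqs x m, in resampled-bin space
    map <- .spectrum_map(n, m)
    M <- matrix(0 + 0i, length(freqs), n)
    for (j in seq_along(map$dst))
      M[, map$src[j]] <- M[, map$src[j]] + map$coef[j] * BG[, map$dst[j]]
    M <- M / n
    list(Mr = Re(M), Mi = Im(M), scale = 2 / (srate * sum(w^2)))
  })
}

# IRASA aperiodic spectra for series in columns of X (samples x n_series):
# for each h, geometric mean of the PSDs of the h- and 1/h-resampled series
# evaluated on the common grid, then the median across factors. With
# seg_len set, each branch spectrum is Welch-averaged over segments of the
# corresponding resampled length (same true time span per segment);
# otherwise the branch operators are precomposed and applied via BLAS.
.irasa_matrix <- function(X, srate, h_set, freqs, seg_len = NULL) {
  n <- nrow(X)
  if (any(h_set <= 1)) stop("all resampling factors h must exceed 1")
  m_up <- as.integer(round(n * h_set))
  m_dn <- as.integer(round(n / h_set))
  if (any(m_dn < 64))
    stop("series too short: downsampled versions fall below 64 samples")
  q <- ncol(X)
  welch <- !is.null(seg_len) && seg_len < n
  if (!welch) {
    XF <- stats::mvfft(X)
    Xr <- Re(XF); Xi <- Im(XF)
  }
  pairs <- matrix(0, length(h_set), length(freqs) * q)
  for (i in seq_along(h_set)) {
    if (welch) {
      p_up <- .welch_matrix(resample_fourier(X, m_up[i]), srate, freqs,
                            round(seg_len * m_up[i] / n))
      p_dn <- .welch_matrix(resample_fourier(X, m_dn[i]), srate, freqs,
                            round(seg_len * m_dn[i] / n))
    } else {
      up <- .irasa_branch_op(n, m_up[i], srate, freqs)
      dn <- .irasa_branch_op(n, m_dn[i], srate, freqs)
      p_up <- up$scale * ((up$Mr %*% Xr - up$Mi %*% Xi)^2 +
                          (up$Mr %*% Xi + up$Mi %*% Xr)^2)
      p_dn <- dn$scale * ((dn$Mr %*% Xr - dn$Mi %*% Xi)^2 +
                          (dn$Mr %*% Xi + dn$Mi %*% Xr)^2)
    }
    pairs[i, ] <- sqrt(as.vector(p_up) * as.vector(p_dn))
  }
  med <- .col_median(pairs)
  matrix(med, length(freqs), q)
}

# column-wise median of a matrix via one radix sort (fast for many columns)
.col_median <- function(A) {
  k <- nrow(A)
  As <- matrix(A[order(col(A), A)], k, ncol(A))
  if (k %% 2L == 1L) As[(k + 1L) / 2L, ]
  else (As[k / 2L, ] + As[k / 2L + 1L, ]) / 2
}

#' IRASA estimate of the aperiodic power spectrum
#'
#' For each resampling factor `h` the series is fractionally resampled by
#' `h` and `1/h` ([resample_fourier()]); the Hann-tapered power spectra of
#' the two resampled versions, read on the common frequency grid, displace
#' any oscillatory peak in opposite directions while leaving the broadband
#' `1/f` component in place, so their geometric mean suppresses oscillations.
#' The median across all factors gives the final, strictly positive
#' aperiodic spectrum.
#'
#' @param series Numeric vector; every resampled version must keep at least
#'   64 samples.
#' @param srate Sampling rate (Hz).
#' @param h_set Resampling factors, all > 1; default 1.10-1.90 in steps of
#'   0.05 (17 factors).
#' @param freq_grid Output grid (Hz), default 1-35 in 1 Hz steps.
#' @param seg_s Optional Welch segment length in seconds applied to every
#'   branch spectrum (see [compute_psd()]); segment counts match across
#'   branches because segment lengths scale with the resampling factor.
#'   Single-window spectra (the `NULL` default) carry a known multiplicative
#'   small-sample bias through the geometric-mean/median chain, so
#'   segment averaging is recommended whenever the series is several times
#'   longer than the analysis windows of interest.
#' @return Named numeric vector of aperiodic power per grid frequency.
#' @export
irasa_aperiodic <- function(series, srate, h_set = default_h_set(),
                            freq_grid = default_freq_grid(), seg_s = NULL) {
  if (length(series) < 64) stop("series must have at least 64 samples")
  .check_freq_grid(freq_grid, srate)
  seg_len <- if (is.null(seg_s)) NULL else round(seg_s * srate)
  p <- drop(.irasa_matrix(matrix(series, ncol = 1), srate, h_set, freq_grid,
                          seg_len))
  names(p) <- freq_grid
  p
}

#' Decompose an epoch set into mixed, aperiodic and oscillatory spectra
#'
#' Per trial and channel: the mixed spectrum is the tapered power spectrum of
#' the analysis window ([compute_psd()]), the aperiodic spectrum is the IRASA
#' estimate ([irasa_aperiodic()]), and the oscillatory spectrum is their
#' difference (not floored at zero: off-peak values may be negative).
#'
#' @param epochs An [epoch_set()].
#' @param h_set Resampling factors (> 1).
#' @param freq_grid Common output grid (Hz).
#' @param seg_s Optional Welch segment length in seconds (see
#'   [irasa_aperiodic()]); the default single-window mode is what short
#'   per-trial analysis windows require.
#' @return An object of class `"spectrum_set"`: list with `freqs` and the
#'   three trials x channels x frequencies arrays `mixed`, `aperiodic`,
#'   `oscillatory`, plus `h_set`, `labels`, `channels`, `subject_id`.
#' @export
irasa_decompose <- function(epochs, h_set = default_h_set(),
                            freq_grid = default_freq_grid(), seg_s = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  .check_freq_grid(freq_grid, epochs$srate)
  d <- dim(epochs$data)
  seg_len <- if (is.null(seg_s)) NULL else round(seg_s * epochs$srate)
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  mixed <- .welch_matrix(X, epochs$srate, freq_grid, seg_len)
  aper <- .irasa_matrix(X, epochs$srate, h_set, freq_grid, seg_len)
  to_arr <- function(P) aperm(array(P, c(length(freq_grid), d[1], d[2])),
                              c(2, 3, 1))
  mixed <- to_arr(mixed); aper <- to_arr(aper)
  structure(
    list(freqs = freq_grid, mixed = mixed, aperiodic = aper,
         oscillatory = mixed - aper, h_set = h_set,
         labels = epochs$labels, channels = epochs$channels,
         subject_id = epochs$subject_id, srate = epochs$srate),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  d <- dim(x$mixed)
  cat(sprintf(paste0("<spectrum_set> %s: %d trials x %d channels, ",
                     "%g-%g Hz (%d bins), %d resampling factors\n"),
              x$subject_id, d[1], d[2], min(x$freqs), max(x$freqs),
              length(x$freqs), length(x$h_set)))
  invisible(x)
}

.band_index <- function(freqs, lo, hi) {
  if (lo >= hi) stop("band limits must satisfy lo < hi")
  if (lo < min(freqs) || hi > max(freqs))
    stop("band [", lo, ", ", hi, "] outside the frequency grid")
  which(freqs >= lo & freqs <= hi)
}

#' Mean band power
#'
#' Arithmetic mean of power at the grid frequencies falling in `[lo, hi]`
#' (endpoints inclusive).
#'
#' @param power Numeric vector of power per grid frequency; frequencies are
#'   taken from `freqs`, or from `names(power)` when `freqs` is `NULL`.
#' @param lo,hi Band limits (Hz), `lo < hi`, inside the grid span.
#' @param freqs Optional numeric grid matching `power`.
#' @return Scalar mean power.
#' @export
band_power <- function(power, lo, hi, freqs = NULL) {
  if (is.null(freqs)) {
    if (is.null(names(power))) stop("freqs missing and power is unnamed")
    freqs <- as.numeric(names(power))
  }
  mean(power[.band_index(freqs, lo, hi)])
}

#' Least-squares aperiodic slope and intercept in log-log coordinates
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` over the
#' grid points inside `[fit_lo, fit_hi]`. The slope approximates `-beta` for
#' a `f^(-beta)` spectrum; the intercept is the log10 power at
#' `log10(f) = 0`.
#'
#' @inheritParams band_power
#' @param fit_lo,fit_hi Fit range (Hz); default 3-30 Hz, matching the
#'   broadband-power definition.
#' @return Named numeric vector `c(slope = ..., intercept = ...)`.
#' @export
fit_aperiodic <- function(power, fit_lo = 3, fit_hi = 30, freqs = NULL) {
  if (is.null(freqs)) {
    if (is.null(names(power))) stop("freqs missing and power is unnamed")
    freqs <- as.numeric(names(power))
  }
  idx <- .band_index(freqs, fit_lo, fit_hi)
  p <- power[idx]
  if (any(p <= 0))
    stop("power must be strictly positive over the fit range")
  lx <- log10(freqs[idx]); ly <- log10(p)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  c(slope = slope, intercept = mean(ly) - slope * mean(lx))
}

#' Extract per-trial spectral features
#'
#' Per trial and channel, six features: mean oscillatory, aperiodic and
#' mixed power over the alpha band (8-13 Hz), mean aperiodic broadband power
#' (3-30 Hz), and the slope and intercept of the log-log least-squares fit
#' to the aperiodic spectrum. Condition labels are carried through.
#'
#' @param spectra A `"spectrum_set"` from [irasa_decompose()].
#' @param alpha_band,broadband Band limits (Hz).
#' @param fit_range Range (Hz) of the log-log slope/intercept fit.
#' @return A data frame of class `"feature_table"`, one row per trial x
#'   channel, columns `trial`, `channel`, `label`, `osc_alpha`, `ap_alpha`,
#'   `mix_alpha`, `ap_broadband`, `slope`, `intercept`.
#' @export
extract_features <- function(spectra, alpha_band = c(8, 13),
                             broadband = c(3, 30), fit_range = c(3, 30)) {
  stopifnot(inherits(spectra, "spectrum_set"))
  freqs <- spectra$freqs
  d <- dim(spectra$mixed)
  nf <- length(freqs)
  flat <- function(A) matrix(A, d[1] * d[2], nf)  # (trial,channel) x freq
  mx <- flat(spectra$mixed); ap <- flat(spectra$aperiodic)
  os <- flat(spectra$oscillatory)
  ai <- .band_index(freqs, alpha_band[1], alpha_band[2])
  bi <- .band_index(freqs, broadband[1], broadband[2])
  fi <- .band_index(freqs, fit_range[1], fit_range[2])
  if (any(ap[, fi] <= 0))
    stop("aperiodic spectrum must be strictly positive over the fit range")
  lx <- log10(freqs[fi])
  ly <- log10(ap[, fi, drop = FALSE])
  xc <- lx - mean(lx)
  slope <- as.vector(ly %*% xc) / sum(xc^2)
  intercept <- rowMeans(ly) - slope * mean(lx)
  out <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2]),
    channel = rep(spectra$channels, each = d[1]),
    label = rep(spectra$labels, times = d[2]),
    osc_alpha = rowMeans(os[, ai, drop = FALSE]),
    ap_alpha = rowMeans(ap[, ai, drop = FALSE]),
    mix_alpha = rowMeans(mx[, ai, drop = FALSE]),
    ap_broadband = rowMeans(ap[, bi, drop = FALSE]),
    slope = slope, intercept = intercept,
    stringsAsFactors = FALSE)
  structure(out, class = c("feature_table", "data.frame"),
            channels = spectra$channels, n_trials = d[1],
            subject_id = spectra$subject_id)
}

#' Signal names available in a feature table
#' @return Character vector of the six per-channel feature columns.
#' @export
feature_signals <- function() {
  c("osc_alpha", "ap_alpha", "mix_alpha", "ap_broadband",
    "slope", "intercept")
}

#' Trials x channels matrix of one signal from a feature table
#'
#' @param features A `"feature_table"` from [extract_features()].
#' @param signal One of [feature_signals()].
#' @return Numeric matrix, trials in rows and channels in columns, with the
#'   per-trial labels attached as attribute `"labels"`.
#' @export
feature_matrix <- function(features, signal) {
  signal <- match.arg(signal, feature_signals())
  channels <- attr(features, "channels")
  n_tr <- attr(features, "n_trials")
  m <- matrix(features[[signal]], n_tr, length(channels),
              dimnames = list(NULL, channels))
  attr(m, "labels") <- features$label[seq_len(n_tr)]
  m
}
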
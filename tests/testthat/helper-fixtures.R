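# Shared fixtures: a compact montage and feature tables built in code.

small_montage <- function() {
  make_montage(
    channel_names = c("F3", "F4", "Cz", "Pz", "O1", "P3", "PO3",
                      "O2", "P4", "PO4"),
    left_posterior = c("O1", "P3", "PO3"),
    right_posterior = c("O2", "P4", "PO4"),
    stim_cluster = c("O2", "P4", "PO4"))
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_trials_per_condition = 8, n_conditions = 2, n_channels = 10,
         srate = 250, window_s = 0.6, erp_amp = 0),
    list(...))
  do.call(ground_truth_config, args)
}

# Build a feature_table from per-signal trials x channels matrices.
make_feature_table <- function(labels, channels, ...) {
  mats <- list(...)
  n_tr <- length(labels)
  stopifnot(all(vapply(mats, function(m)
    all(dim(m) == c(n_tr, length(channels))), logical(1))))
  base <- matrix(1, n_tr, length(channels))
  cols <- lapply(feature_signals(), function(sig)
    as.vector(if (!is.null(mats[[sig]])) mats[[sig]] else base))
  names(cols) <- feature_signals()
  out <- data.frame(trial = rep(seq_len(n_tr), times = length(channels)),
                    channel = rep(channels, each = n_tr),
                    label = rep(labels, times = length(channels)),
                    cols, stringsAsFactors = FALSE)
  structure(out, class = c("feature_table", "data.frame"),
            channels = channels, n_trials = n_tr, subject_id = "fixture")
}

# Golden regression values for the tiny pipeline run in test-workflow.R
# (mi_combined for 2 subjects x {osc_alpha, ap_alpha}), frozen from a
# verified build of the full generate -> decompose -> MI path.
golden_mi_combined <- c(0.940011076333983, -0.110589951302518,
                        1.14780287100088, 0.25673782372588)

# Raw boxcar periodogram at exact DFT bins: an estimator independent of the
# package's tapered-DTFT path, used as a spectral oracle.
boxcar_periodogram <- function(x, srate) {
  n <- length(x)
  p <- (2 / (srate * n)) * Mod(stats::fft(x))^2
  k <- 1:(n %/% 2)
  structure(p[k + 1], freqs = k * srate / n)
}
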
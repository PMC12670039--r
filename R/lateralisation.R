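#' Hemispheric lateralisation modulation index
#'
#' For each signal, `S_g^c` is the signal averaged over trials of cue
#' condition `c` and the posterior electrodes of hemisphere group `g`. The
#' per-hemisphere index is the attend-left-minus-attend-right difference
#' normalised by the mean,
#' `MI_L = (S_L^left - S_L^right) / (0.5 * (S_L^left + S_L^right))`
#' (analogously for the right group), and the combined index is
#' `MI = MI_L - MI_R`, which cancels hemisphere-unspecific asymmetries.
#' Positive combined MI means the signal decreases contralateral to the
#' attended side; slope- and intercept-type signals may legitimately give
#' negative values.
#'
#' @param features A `"feature_table"` from [extract_features()].
#' @param montage A [make_montage()] supplying the posterior groups.
#' @param left_label,right_label Condition labels of the attend-left and
#'   attend-right (9 and 3 o'clock) conditions; see [horizontal_labels()].
#' @param signals Feature columns to evaluate; defaults to all of
#'   [feature_signals()].
#' @return Data frame with one row per signal: `subject_id`, `signal`,
#'   `mi_left`, `mi_right`, `mi_combined` (`mi_combined = mi_left -
#'   mi_right` exactly).
#' @export
modulation_index <- function(features, montage, left_label, right_label,
                             signals = feature_signals()) {
  stopifnot(inherits(features, "feature_table"))
  for (lab in c(left_label, right_label))
    if (!any(features$label == lab))
      stop("condition label ", lab, " absent from the feature table")
  groups <- list(left = montage$left_posterior,
                 right = montage$right_posterior)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop(g, " posterior electrode group is empty")
    miss <- setdiff(groups[[g]], unique(features$channel))
    if (length(miss))
      stop(g, " posterior electrodes missing from features: ",
           paste(miss, collapse = ", "))
  }
  res <- lapply(signals, function(sig) {
    s_mean <- function(grp, lab)
      mean(features[[sig]][features$channel %in% grp &
                             features$label == lab])
    hemi_mi <- function(grp, hemi) {
      s_l <- s_mean(grp, left_label)
      s_r <- s_mean(grp, right_label)
      denom <- (s_l + s_r) / 2
      if (denom == 0)
        stop("zero denominator in ", hemi, "-hemisphere MI for ", sig)
      (s_l - s_r) / denom
    }
    mi_l <- hemi_mi(groups$left, "left")
    mi_r <- hemi_mi(groups$right, "right")
    data.frame(subject_id = attr(features, "subject_id") %||% NA_character_,
               signal = sig, mi_left = mi_l, mi_right = mi_r,
               mi_combined = mi_l - mi_r, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-corrected topographic condition difference
#'
#' Per channel: `(A - baseline_A) - (B - baseline_B)`, in linear power
#' units — the attend-left-minus-attend-right map after subtracting each
#' condition's pre-cue baseline.
#'
#' @param cond_a,cond_b Named numeric vectors of per-channel values for the
#'   two conditions (equal channel sets).
#' @param baseline_a,baseline_b Per-channel baselines (same channels);
#'   default 0 (no baseline correction).
#' @return Named numeric vector of per-channel differences, in the channel
#'   order of `cond_a`.
#' @export
topographic_difference <- function(cond_a, cond_b,
                                   baseline_a = 0, baseline_b = 0) {
  chans <- names(cond_a)
  if (is.null(chans)) stop("cond_a must be a named per-channel vector")
  align <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) return(rep(x, length(chans)))
    if (!setequal(names(x), chans))
      stop("channel mismatch between cond_a and ", what)
    x[chans]
  }
  (cond_a - align(baseline_a, "baseline_a")) -
    (align(cond_b, "cond_b") - align(baseline_b, "baseline_b"))
}

#' TMS modulation over the stimulation cluster (rhythmic minus arrhythmic)
#'
#' For each signal, the mean over trials and stimulation-cluster electrodes
#' of the rhythmic-TMS feature table minus the same mean of the
#' arrhythmic-TMS table.
#'
#' @param features_rh,features_ar `"feature_table"`s for the rhythmic and
#'   arrhythmic TMS conditions.
#' @param montage A [make_montage()] with a non-empty `stim_cluster`.
#' @param signals Feature columns to evaluate.
#' @return Data frame with columns `signal` and `modulation`.
#' @export
tms_modulation <- function(features_rh, features_ar, montage,
                           signals = feature_signals()) {
  cluster <- montage$stim_cluster
  if (!length(cluster)) stop("montage stim_cluster is empty")
  for (tab in list(rh = features_rh, ar = features_ar)) {
    miss <- setdiff(cluster, unique(tab$channel))
    if (length(miss))
      stop("stim cluster electrodes missing from features: ",
           paste(miss, collapse = ", "))
  }
  vals <- vapply(signals, function(sig) {
    mean(features_rh[[sig]][features_rh$channel %in% cluster]) -
      mean(features_ar[[sig]][features_ar$channel %in% cluster])
  }, numeric(1))
  data.frame(signal = signals, modulation = unname(vals),
             stringsAsFactors = FALSE)
}
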
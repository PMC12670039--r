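#' Electrode montage with hemispheric electrode groups
#'
#' A montage declares the channel order of an [epoch_set()] together with the
#' electrode groups used by the lateralisation and TMS analyses: the left and
#' right posterior groups entering the modulation index, and the stimulation
#' cluster over which TMS modulation effects are averaged.
#'
#' @param channel_names Character vector of channel labels, in recording order.
#' @param left_posterior,right_posterior Labels of the posterior electrodes of
#'   each hemisphere used by [modulation_index()]. Must be disjoint subsets of
#'   `channel_names`.
#' @param stim_cluster Labels of the electrode cluster near the stimulation
#'   site used by [tms_modulation()]; may be empty when no TMS contrast is run.
#' @param channel_side Optional character vector (same length as
#'   `channel_names`) with entries `"left"`, `"right"` or `"midline"`. When
#'   `NULL` the side is inferred from the 10-20 label: a trailing `z` means
#'   midline, an odd trailing number left, an even one right.
#' @return An object of class `"montage"`: a list with fields
#'   `channel_names`, `left_posterior`, `right_posterior`, `stim_cluster`,
#'   `channel_side`.
#' @seealso [default_montage()]
#' @export
make_montage <- function(channel_names, left_posterior, right_posterior,
                         stim_cluster = character(), channel_side = NULL) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("duplicated channel names in montage")
  for (grp in list(left_posterior, right_posterior, stim_cluster)) {
    missing <- setdiff(grp, channel_names)
    if (length(missing))
      stop("montage group members not in channel_names: ",
           paste(missing, collapse = ", "))
  }
  if (length(intersect(left_posterior, right_posterior)))
    stop("left_posterior and right_posterior must be disjoint")
  if (is.null(channel_side)) {
    channel_side <- infer_channel_side(channel_names)
  } else {
    if (length(channel_side) != length(channel_names))
      stop("channel_side must match channel_names in length")
    if (!all(channel_side %in% c("left", "right", "midline")))
      stop("channel_side entries must be 'left', 'right' or 'midline'")
  }
  structure(
    list(channel_names = channel_names,
         left_posterior = as.character(left_posterior),
         right_posterior = as.character(right_posterior),
         stim_cluster = as.character(stim_cluster),
         channel_side = channel_side),
    class = "montage")
}

#' Infer hemispheric side from 10-20 channel labels
#'
#' Trailing `z`/`Z` is midline; otherwise an odd trailing number is left and
#' an even one right (standard 10-20 numbering).
#'
#' @param channel_names Character vector of labels.
#' @return Character vector of `"left"`, `"right"`, `"midline"`.
#' @export
infer_channel_side <- function(channel_names) {
  vapply(channel_names, function(ch) {
    if (grepl("[zZ]$", ch)) return("midline")
    num <- regmatches(ch, regexpr("[0-9]+$", ch))
    if (!length(num)) return("midline")
    if (as.integer(num) %% 2L == 1L) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}

#' Default 30-channel montage
#'
#' A 30-channel posterior-weighted layout mirroring the montage of the
#' multi-session attention datasets the pipeline emulates. The posterior
#' modulation-index groups are O1, P3, P7, PO3, PO7 (left) and O2, P4, P8,
#' PO4, PO8 (right); the stimulation cluster is the 15-electrode right
#' posterior set P2, P4, P6, P8, PO4, PO8, O2, CP2, CP4, CP6, TP8, C2, C4,
#' C6, T8.
#'
#' @return A `"montage"` object with 30 channels.
#' @export
default_montage <- function() {
  channels <- c("Fp1", "Fp2", "F3", "F4", "Fz",
                "C3", "C4", "Cz", "C2", "C6", "T8",
                "CP2", "CP4", "CP6", "TP8",
                "P3", "P4", "P7", "P8", "Pz", "P2", "P6",
                "PO3", "PO4", "PO7", "PO8", "POz",
                "O1", "O2", "Oz")
  make_montage(
    channel_names = channels,
    left_posterior = c("O1", "P3", "P7", "PO3", "PO7"),
    right_posterior = c("O2", "P4", "P8", "PO4", "PO8"),
    stim_cluster = c("P2", "P4", "P6", "P8", "PO4", "PO8", "O2",
                     "CP2", "CP4", "CP6", "TP8", "C2", "C4", "C6", "T8"))
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels\n", sep = "")
  cat("  left posterior : ", paste(x$left_posterior, collapse = ", "), "\n",
      sep = "")
  cat("  right posterior: ", paste(x$right_posterior, collapse = ", "), "\n",
      sep = "")
  if (length(x$stim_cluster))
    cat("  stim cluster   : ", paste(x$stim_cluster, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
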
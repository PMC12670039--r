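#' Epoched multichannel EEG container
#'
#' The universal input of the pipeline: a trials x channels x samples array
#' together with the sampling rate, per-trial condition labels and channel
#' names. All trials share the channel order, epoch length and sampling rate.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param srate Sampling rate in Hz.
#' @param labels Integer (or factor) vector of per-trial condition labels,
#'   length `dim(data)[1]`. Every label must occur at least once.
#' @param channels Character vector of channel names, length `dim(data)[2]`.
#' @param time_zero_s Time (seconds) of sample 1 relative to the alignment
#'   event; defaults to 0.
#' @param subject_id Identifier carried through to result tables.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(data, srate, labels, channels, time_zero_s = 0,
                      subject_id = "S01") {
  if (length(dim(data)) != 3L)
    stop("data must be a trials x channels x samples array")
  n_trials <- dim(data)[1]
  if (length(labels) != n_trials)
    stop("labels must have one entry per trial")
  if (length(channels) != dim(data)[2])
    stop("channels must have one entry per channel")
  if (!is.numeric(srate) || srate <= 0)
    stop("srate must be a positive number")
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integer-coercible")
  structure(
    list(data = data, srate = srate, labels = labels,
         channels = as.character(channels),
         time_zero_s = time_zero_s, subject_id = subject_id),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$srate))
  tab <- table(x$labels)
  cat("  conditions: ",
      paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]
n_samples <- function(epochs) dim(epochs$data)[3]

#' Write an epoch set as plain text
#'
#' Serialises an [epoch_set()] to a directory holding `meta.json` (sampling
#' rate, labels, channels, subject id, time origin) and `data.csv` (one row
#' per trial x channel, sample values as columns). The same schema is read
#' back by [read_epochs()].
#'
#' @param epochs An `"epoch_set"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(srate = epochs$srate, labels = epochs$labels,
               channels = epochs$channels,
               time_zero_s = epochs$time_zero_s,
               subject_id = epochs$subject_id,
               n_trials = n_trials(epochs), n_samples = n_samples(epochs))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])  # samples x (trial, channel)
  tab <- data.frame(trial = rep(seq_len(d[1]), times = d[2]),
                    channel = rep(epochs$channels, each = d[1]),
                    t(flat), check.names = FALSE)
  utils::write.csv(tab, file.path(dir, "data.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param dir Directory holding `meta.json` and `data.csv`.
#' @return An `"epoch_set"`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "data.csv"), check.names = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  arr <- aperm(array(t(vals), c(meta$n_samples, meta$n_trials,
                                length(meta$channels))), c(2, 3, 1))
  epoch_set(arr, srate = meta$srate, labels = meta$labels,
            channels = meta$channels, time_zero_s = meta$time_zero_s,
            subject_id = meta$subject_id)
}
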
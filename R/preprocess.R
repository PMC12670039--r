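#' Remove time-locked evoked components (per-condition ERP subtraction)
#'
#' For each condition and channel, subtracts the across-trial mean time
#' course from every trial of that condition, isolating induced activity:
#' after the operation the per-condition trial mean is the zero series (to
#' numerical precision). Idempotent.
#'
#' @param epochs An [epoch_set()]; every condition needs at least one trial.
#' @return An [epoch_set()] of the same shape.
#' @export
remove_erp <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- epochs$data
  for (cond in unique(epochs$labels)) {
    idx <- which(epochs$labels == cond)
    if (!length(idx)) stop("condition ", cond, " has no trials")
    erp <- colMeans(epochs$data[idx, , , drop = FALSE])  # channels x samples
    for (i in idx) out[i, , ] <- out[i, , ] - erp
  }
  epochs$data <- out
  epochs
}

#' Crop epochs to an analysis window
#'
#' Returns the epochs restricted to the half-open interval
#' `[t_start_s, t_end_s)` (0-based sample indexing relative to
#' `time_zero_s`); the output has `round((t_end_s - t_start_s) * srate)`
#' samples.
#'
#' @param epochs An [epoch_set()].
#' @param t_start_s,t_end_s Window limits in seconds, `t_end_s > t_start_s`,
#'   inside the epoch's time span.
#' @return A cropped [epoch_set()] with `time_zero_s = t_start_s`.
#' @export
select_window <- function(epochs, t_start_s, t_end_s) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (t_end_s <= t_start_s) stop("t_end_s must exceed t_start_s")
  i0 <- round((t_start_s - epochs$time_zero_s) * epochs$srate)
  len <- round((t_end_s - t_start_s) * epochs$srate)
  if (i0 < 0 || i0 + len > n_samples(epochs))
    stop("window [", t_start_s, ", ", t_end_s,
         ") outside the epoch time span")
  epochs$data <- epochs$data[, , (i0 + 1):(i0 + len), drop = FALSE]
  epochs$time_zero_s <- t_start_s
  epochs
}

#' Standardise feature columns (z-score across all rows)
#'
#' Each column is centred and scaled to unit variance across *all* rows,
#' computed once over the full set with the population denominator `n` (so a
#' two-row column `c(1, 3)` maps to `c(-1, 1)`). For cross-validated
#' decoding this matches the convention of standardising across all epochs
#' before the folds are drawn; `per_fold = TRUE` in [crossval_decode()]
#' restricts it to training folds instead.
#'
#' @param x Numeric matrix or all-numeric data frame with at least 2 rows.
#' @return Object of the same shape with column means 0 and population
#'   standard deviations 1.
#' @export
zscore_features <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric")
  if (nrow(m) < 2) stop("need at least 2 rows to standardise")
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  bad <- which(sd_pop == 0)
  if (length(bad)) {
    nm <- colnames(m)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  z <- sweep(sweep(m, 2, mu), 2, sd_pop, `/`)
  if (is.data.frame(x)) as.data.frame(z) else z
}
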
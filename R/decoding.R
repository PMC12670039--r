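#' Average random groups of trials into pseudo-trials
#'
#' Within each condition, trials are randomly partitioned (without
#' replacement) into groups of `group_size`; each pseudo-trial is the
#' per-feature, per-channel mean of its group. Leftover trials (fewer than
#' `group_size`) are dropped. Raises the signal-to-noise ratio of the
#' decoding features.
#'
#' @param features A `"feature_table"` from [extract_features()].
#' @param group_size Trials per pseudo-trial (default 4).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A `"feature_table"` of pseudo-trials with condition labels
#'   carried through.
#' @export
make_pseudotrials <- function(features, group_size = 4, seed = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (!is.null(seed)) set.seed(seed)
  channels <- attr(features, "channels")
  n_tr <- attr(features, "n_trials")
  labels <- features$label[seq_len(n_tr)]
  group <- integer(n_tr)               # 0 = dropped
  next_id <- 0L
  for (cond in unique(labels)) {
    idx <- which(labels == cond)
    if (length(idx) < group_size)
      stop("condition ", cond, " has ", length(idx),
           " trials, fewer than group_size = ", group_size)
    idx <- sample(idx)
    n_grp <- as.integer(length(idx) %/% group_size)
    keep <- idx[seq_len(n_grp * group_size)]
    group[keep] <- next_id + rep(seq_len(n_grp), each = group_size)
    next_id <- next_id + n_grp
    next_id <- as.integer(next_id)
  }
  sig_cols <- feature_signals()
  full_group <- rep(group, times = length(channels))  # row order: trial fastest
  keep_rows <- full_group > 0L
  key <- interaction(full_group[keep_rows], features$channel[keep_rows],
                     drop = FALSE, lex.order = FALSE)
  agg <- rowsum(as.matrix(features[keep_rows, sig_cols]), key,
                reorder = TRUE) / group_size
  parts <- strsplit(rownames(agg), ".", fixed = TRUE)
  grp_id <- as.integer(vapply(parts, `[`, "", 1L))
  chan <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
  label_of <- labels[match(seq_len(next_id), group)]
  ord <- order(match(chan, channels), grp_id)
  out <- data.frame(trial = grp_id[ord], channel = chan[ord],
                    label = label_of[grp_id[ord]],
                    agg[ord, , drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("feature_table", "data.frame"),
            channels = channels, n_trials = next_id,
            subject_id = attr(features, "subject_id"))
}

#' Balanced accuracy (macro-averaged recall)
#'
#' Mean of the per-class recalls over the classes present in `true`; for two
#' classes this is the arithmetic mean of sensitivity and specificity, which
#' is robust to class imbalance.
#'
#' @param true,predicted Equal-length label vectors; every predicted label
#'   must belong to the class set of `true`.
#' @return Proportion in `[0, 1]`.
#' @export
balanced_accuracy <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  classes <- unique(true)
  extra <- setdiff(unique(predicted), classes)
  if (length(extra))
    stop("predicted labels outside the class set: ",
         paste(extra, collapse = ", "))
  recalls <- vapply(classes, function(k)
    mean(predicted[true == k] == k), numeric(1))
  mean(recalls)
}

# One-vs-rest linear SVM over binary e1071 fits; predicts by the largest
# oriented decision value.
.ovr_fit <- function(x, y, cost) {
  lapply(levels(y), function(k) {
    yk <- factor(ifelse(y == k, "pos", "neg"), levels = c("neg", "pos"))
    e1071::svm(x, yk, kernel = "linear", cost = cost, scale = FALSE)
  })
}

.ovr_predict <- function(models, classes, x) {
  scores <- vapply(models, function(m) {
    d <- attr(stats::predict(m, x, decision.values = TRUE),
              "decision.values")
    sgn <- if (startsWith(colnames(d)[1], "pos")) 1 else -1
    sgn * d[, 1]
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  classes[max.col(scores, ties.method = "first")]
}

#' Cross-validated linear decoding with balanced accuracy
#'
#' Standardises the pseudo-trial features ([zscore_features()], across all
#' rows before splitting, unless `per_fold`), draws stratified `n_folds`
#' folds, trains a one-vs-rest linear support vector machine (cost `cost`)
#' on `n_folds - 1` parts and scores the held-out part with
#' [balanced_accuracy()]; returns the mean over folds.
#'
#' @param x Numeric matrix, pseudo-trials x features.
#' @param labels Per-row condition labels; every class needs at least
#'   `n_folds` rows.
#' @param n_folds Number of folds (default 5).
#' @param seed Optional integer seed for the fold assignment.
#' @param cost SVM regularisation constant (default 1).
#' @param per_fold If `TRUE`, standardisation parameters are estimated on
#'   the training folds only and applied to the test fold (off by default;
#'   the default reproduces whole-set standardisation).
#' @return Mean balanced accuracy over folds.
#' @export
crossval_decode <- function(x, labels, n_folds = 5, seed = NULL, cost = 1,
                            per_fold = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  if (nrow(x) != length(labels))
    stop("labels must have one entry per row of x")
  y <- factor(labels)
  counts <- table(y)
  if (any(counts < n_folds))
    stop("every class needs at least n_folds = ", n_folds,
         " pseudo-trials (smallest has ", min(counts), ")")
  if (!per_fold) x <- zscore_features(x)
  fold <- integer(nrow(x))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  accs <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (per_fold) {
      mu <- colMeans(xtr)
      sd_pop <- sqrt(colMeans(sweep(xtr, 2, mu)^2))
      if (any(sd_pop == 0)) stop("zero-variance feature in training fold")
      xtr <- sweep(sweep(xtr, 2, mu), 2, sd_pop, `/`)
      xte <- sweep(sweep(xte, 2, mu), 2, sd_pop, `/`)
    }
    models <- .ovr_fit(xtr, droplevels(y[tr]), cost)
    pred <- .ovr_predict(models, levels(droplevels(y[tr])), xte)
    balanced_accuracy(as.character(y[te]), pred)
  }, numeric(1))
  mean(accs)
}

#' Repeated pseudo-trial decoding of one signal
#'
#' Runs `n_repetitions` independent pseudo-trial constructions (the RNG for
#' repetition `r` is derived deterministically from `seed` and `r`), each
#' followed by standardisation and [crossval_decode()]; the reported
#' balanced accuracy is the grand mean over repetitions and folds.
#'
#' @param features A `"feature_table"` of single trials.
#' @param signal Which signal to decode; one of [feature_signals()].
#' @param group_size Trials per pseudo-trial (default 4).
#' @param n_folds Cross-validation folds (default 5).
#' @param n_repetitions Pseudo-trial repetitions (default 25).
#' @param seed Integer master seed.
#' @param cost SVM regularisation constant (default 1).
#' @return One-row data frame of class `"decoding_result"`: `subject_id`,
#'   `signal`, `balanced_accuracy`, `n_repetitions`, `n_folds`,
#'   `chance_level` (1 / number of classes).
#' @export
repeat_decode <- function(features, signal, group_size = 4, n_folds = 5,
                          n_repetitions = 25, seed = 1, cost = 1) {
  signal <- match.arg(signal, feature_signals())
  n_classes <- length(unique(features$label))
  accs <- vapply(seq_len(n_repetitions), function(r) {
    set.seed(derive_seed(seed, r))
    pt <- make_pseudotrials(features, group_size = group_size)
    x <- feature_matrix(pt, signal)
    crossval_decode(x, attr(x, "labels"), n_folds = n_folds, cost = cost)
  }, numeric(1))
  structure(
    data.frame(subject_id = attr(features, "subject_id") %||% NA_character_,
               signal = signal, balanced_accuracy = mean(accs),
               n_repetitions = as.integer(n_repetitions),
               n_folds = as.integer(n_folds),
               chance_level = 1 / n_classes, stringsAsFactors = FALSE),
    class = c("decoding_result", "data.frame"))
}

#' Derive a stream seed from a master seed and an index
#'
#' Deterministic counter-based derivation keeping the result inside the
#' 32-bit integer range, so repetitions and subjects get reproducible,
#' mutually independent RNG streams.
#'
#' @param seed Master integer seed.
#' @param index Positive counter (repetition, subject, ...).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 65537) %%
               2147483629)
}
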
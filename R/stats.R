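# Statistical layer: one-sample t-tests, BH-FDR, Holm adjustment, one-way
# repeated-measures ANOVA, and partial Spearman correlation. Thin, validated
# wrappers around base R fitting routines, returning a common result shape.

new_test_result <- function(statistic, p_value, df, n, tails, method,
                            estimate = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = unname(df), n = n, tails = tails, method = method,
                 estimate = estimate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s-tailed, n = %d)\n",
              x$method, x$statistic, df_txt, x$p_value, x$tails, x$n))
  if (!is.null(x$estimate))
    cat(sprintf("  estimate = %.4g\n", x$estimate))
  invisible(x)
}

.check_p <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
}

#' One-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with the sample standard deviation
#' (denominator `n - 1`), `n - 1` degrees of freedom. The one-tailed variant
#' tests the greater-than direction (as used for decoding accuracy against
#' chance); the two-tailed variant is the default for modulation indices and
#' TMS effects against zero.
#'
#' @param values Numeric vector, `n >= 2`, non-zero variance.
#' @param mu0 Reference value (chance level or 0).
#' @param tails `"two"` or `"one"` (greater).
#' @return A `"test_result"` with `statistic`, `p_value`, `df`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) stop("values have zero variance")
  ht <- stats::t.test(values, mu = mu0,
                      alternative = if (tails == "one") "greater"
                                    else "two.sided")
  new_test_result(ht$statistic, ht$p.value, ht$parameter, n, tails,
                  "one-sample t-test", estimate = unname(ht$estimate))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with sorted p-values, rejects hypotheses `1..k` where
#' `k` is the largest `i` with `p_(i) <= i * q / m`; equivalently a
#' hypothesis is rejected when its BH-adjusted p-value is at most `q`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level in (0, 1), default 0.05.
#' @return List with `reject` (logical, input order), `p_adjusted`
#'   (BH-adjusted p-values) and `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  .check_p(p_values)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(reject = adj <= q, p_adjusted = adj, q = q)
}

#' Holm step-down adjusted p-values
#'
#' `adjusted p_(i) = max_{j <= i} (m - j + 1) * p_(j)`, capped at 1, mapped
#' back to the input order; controls the family-wise error rate for post hoc
#' comparisons.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p_values) {
  .check_p(p_values)
  stats::p.adjust(p_values, method = "holm")
}

#' One-way repeated-measures ANOVA
#'
#' `F = MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(k - 1, (k - 1)(n - 1))`. Fitted as the additive two-way model
#' `value ~ condition + subject`, whose residual mean square equals the
#' condition-by-subject interaction mean square when there is one
#' observation per cell. No sphericity correction is applied.
#'
#' @param values Complete numeric matrix (or data frame), subjects in rows
#'   and conditions in columns; at least 2 of each.
#' @return A `"test_result"` with the F statistic, `df = c(df1, df2)` and
#'   the p-value from the F distribution.
#' @export
rm_anova_oneway <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("values must be complete (no missing cells)")
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 subjects and 2 conditions")
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
                  cond = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  # a perfect additive fit (identical conditions) is handled explicitly
  # below, so the fit-quality warning from anova() is uninformative here
  tab <- suppressWarnings(stats::anova(stats::aov(y ~ cond + subject,
                                                  data = d)))
  f <- tab["cond", "F value"]
  df1 <- tab["cond", "Df"]; df2 <- tab["Residuals", "Df"]
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  if (tab["cond", "Mean Sq"] <= 1e-12 * mean(d$y^2 + 1)) { f <- 0; p <- 1 }
  new_test_result(f, p, c(df1, df2), nrow(m), "two",
                  "repeated-measures ANOVA (one-way)")
}

.rank_covariate <- function(covariate, n) {
  if (is.data.frame(covariate)) covariate <- as.matrix(covariate)
  if (is.matrix(covariate)) {
    if (nrow(covariate) != n) stop("covariate must have length n")
    return(apply(covariate, 2, rank))
  }
  if (length(covariate) != n) stop("covariate must have length n")
  if (is.factor(covariate) || is.character(covariate)) {
    f <- factor(covariate)
    if (nlevels(f) < 2) return(matrix(numeric(0), n, 0))
    stats::model.matrix(~f)[, -1, drop = FALSE]  # drop-one indicators
  } else {
    matrix(rank(covariate), ncol = 1)
  }
}

#' Partial Spearman correlation controlling for a covariate
#'
#' Rank-transforms `x` and `y` (average ranks for ties), encodes the
#' covariate (categorical covariates such as dataset identity become
#' drop-one indicator columns; numeric covariates are rank-transformed),
#' residualises the ranked `x` and `y` on the encoded covariate by least
#' squares, and returns the Pearson correlation of the residuals with a
#' t-approximation p-value on `n - 2 - c` degrees of freedom (`c` covariate
#' columns).
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param covariate Vector (numeric, factor or character), matrix or data
#'   frame of covariates.
#' @param tails `"two"` or `"one"` (positive direction).
#' @return A `"test_result"` with `estimate` = partial rank correlation.
#' @export
partial_spearman <- function(x, y, covariate, tails = c("two", "one")) {
  tails <- match.arg(tails)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  C <- .rank_covariate(covariate, n)
  design <- cbind(1, C)
  res <- function(v) stats::lm.fit(design, v)$residuals
  rx <- res(rank(x)); ry <- res(rank(y))
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop("constant residuals after rank transformation and residualisation")
  r <- stats::cor(rx, ry)
  df <- n - 2 - ncol(C)
  if (df < 1) stop("too few observations for the covariate columns")
  tstat <- if (1 - r^2 < 1e-15) sign(r) * Inf
           else r * sqrt(df / (1 - r^2))
  p <- if (tails == "two") 2 * stats::pt(-abs(tstat), df)
       else stats::pt(tstat, df, lower.tail = FALSE)
  new_test_result(tstat, min(p, 1), df, n, tails,
                  "partial Spearman correlation", estimate = r)
}
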
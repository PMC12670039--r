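# Independent brute-force implementations of the statistical layer, written
# from the textbook definitions without reference to the package internals.

oracle_one_sample_t <- function(values, mu0 = 0, tails = "two") {
  n <- length(values)
  s <- sqrt(sum((values - mean(values))^2) / (n - 1))
  t <- (mean(values) - mu0) / (s / sqrt(n))
  p <- if (tails == "two") 2 * stats::pt(-abs(t), n - 1)
       else stats::pt(t, n - 1, lower.tail = FALSE)
  list(statistic = t, p_value = p)
}

oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  reject_sorted <- rep(FALSE, m)
  if (is.finite(k)) reject_sorted[seq_len(k)] <- TRUE
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  reject <- adj <- numeric(m)
  reject[o] <- reject_sorted
  adj[o] <- adj_sorted
  list(reject = as.logical(reject), p_adjusted = adj)
}

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  run_max <- 0
  for (i in seq_len(m)) {
    run_max <- max(run_max, (m - i + 1) * ps[i])
    adj_sorted[i] <- min(1, run_max)
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Full sums-of-squares decomposition for the subjects x conditions design.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Explicit rank residual regression then Pearson correlation of residuals.
oracle_partial_spearman <- function(x, y, covariate, tails = "two") {
  n <- length(x)
  C <- if (is.factor(covariate) || is.character(covariate)) {
    f <- factor(covariate)
    sapply(levels(f)[-1], function(l) as.numeric(f == l))
  } else matrix(rank(covariate), ncol = 1)
  D <- cbind(1, C)
  proj <- function(v) v - D %*% solve(crossprod(D), crossprod(D, v))
  rx <- proj(rank(x)); ry <- proj(rank(y))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - ncol(C)
  t <- r * sqrt(df / (1 - r^2))
  p <- if (tails == "two") 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  list(estimate = r, statistic = t, p_value = p)
}
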
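#' @title Reported statistics
#'
#' @description The tests used for the behavioral summaries: one-sample t
#' from (mean, sd, n) triples as printed in results tables, t tests on raw
#' vectors, one-way repeated-measures ANOVA with Greenhouse-Geisser (GG)
#' correction and partial eta squared, Tukey post-hoc comparisons on the
#' within-participant error term, and Bonferroni adjustment. All tests are
#' two-tailed.
#' @name stats-tests
NULL

new_test_result <- function(statistic, df, p.value, effect = NA_real_,
                            method = "") {
  structure(list(statistic = statistic, df = df, p.value = p.value,
                 effect = effect, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 5), collapse = ", ")
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.4g", x$method,
              x$statistic, dfs, x$p.value))
  if (!is.na(x$effect)) cat(sprintf(", partial eta^2 = %.3f", x$effect))
  cat("\n")
  invisible(x)
}

#' One-sample t test from summary statistics
#'
#' Recomputes a one-sample t directly from a printed (mean, sd, n) triple,
#' e.g. testing whether a first-trial |TE| exceeds the 7.5 mm target radius:
#' t = (mean - mu0) / (sd / sqrt(n)), df = n - 1, two-tailed p.
#'
#' @param mean,sd,n Summary statistics (sd >= 0, n >= 2).
#' @param mu0 Null value, same units as `mean`.
#' @return A `test_result`.
#' @export
#' @examples
#' t_one_sample_summary(112.6, 38.0, 15, mu0 = 7.5)  # t(14) = 10.7
t_one_sample_summary <- function(mean, sd, n, mu0 = 0) {
  stopifnot(sd >= 0, n >= 2, n == round(n))
  se <- sd / sqrt(n)
  if (se == 0) {
    t <- if (mean == mu0) 0 else Inf * sign(mean - mu0)
    warning("zero standard deviation: degenerate t statistic")
  } else t <- (mean - mu0) / se
  df <- n - 1
  new_test_result(t, df, 2 * stats::pt(abs(t), df, lower.tail = FALSE),
                  method = "one-sample t (summary statistics)")
}

#' t tests on raw vectors
#'
#' One-sample, paired or unpaired (Student) two-tailed t test; a thin wrapper
#' over [stats::t.test()] returning the package's uniform `test_result`.
#'
#' @param x Numeric vector.
#' @param y Second vector (paired/unpaired modes).
#' @param mode `"one_sample"`, `"paired"` or `"unpaired"`.
#' @param mu0 Null value (one-sample mode).
#' @param var.equal Pool variances in unpaired mode.
#' @return A `test_result`.
#' @export
t_test_vec <- function(x, y = NULL,
                       mode = c("one_sample", "paired", "unpaired"),
                       mu0 = 0, var.equal = TRUE) {
  mode <- match.arg(mode)
  ht <- switch(mode,
    one_sample = stats::t.test(x, mu = mu0),
    paired = stats::t.test(x, y, paired = TRUE),
    unpaired = stats::t.test(x, y, var.equal = var.equal))
  new_test_result(unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, method = paste(mode, "t"))
}

# within-participant sums of squares of an n x k matrix
rm_anova_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       n = n, k = k)
}

# Box / Greenhouse-Geisser epsilon from the sample covariance of condition
# scores.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(m)
  dbar <- mean(diag(S))
  sbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-participant one-way ANOVA on a complete participants-by-conditions
#' matrix. Degrees of freedom are multiplied by the Box/GG epsilon estimated
#' from the covariance of condition scores, and the effect size is partial
#' eta squared, SS_cond / (SS_cond + SS_error).
#'
#' @param m Numeric matrix, rows = participants (>= 3), columns = conditions
#'   (>= 2), no missing cells.
#' @return A `test_result` with fractional `df = c(df1, df2)` and an
#'   `epsilon` element.
#' @export
rm_anova_gg <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not supported")
  stopifnot(nrow(m) >= 3, ncol(m) >= 2)
  ss <- rm_anova_ss(m)
  df_cond <- ss$k - 1
  df_err <- (ss$k - 1) * (ss$n - 1)
  f <- if (ss$ss_cond == 0) 0
       else (ss$ss_cond / df_cond) / (ss$ss_err / df_err)
  eps <- gg_epsilon(m)
  df1 <- eps * df_cond
  df2 <- eps * df_err
  out <- new_test_result(f, c(df1, df2),
                         stats::pf(f, df1, df2, lower.tail = FALSE),
                         effect = ss$ss_cond / (ss$ss_cond + ss$ss_err),
                         method = "repeated-measures ANOVA (GG-corrected)")
  out$epsilon <- eps
  out
}

#' Tukey pairwise comparisons for repeated measures
#'
#' Studentized-range comparisons of all condition pairs using the
#' within-participant error term of the repeated-measures ANOVA.
#'
#' @inheritParams rm_anova_gg
#' @return Data frame with one row per pair: `i`, `j`, `diff` (mean_i -
#'   mean_j), `q` and Tukey-adjusted `p`.
#' @export
tukey_pairwise <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not supported")
  ss <- rm_anova_ss(m)
  ms_err <- ss$ss_err / ((ss$k - 1) * (ss$n - 1))
  se <- sqrt(ms_err / ss$n)
  means <- colMeans(m)
  pairs <- utils::combn(ss$k, 2L)
  d <- means[pairs[1L, ]] - means[pairs[2L, ]]
  q <- abs(d) / se
  p <- stats::ptukey(q, nmeans = ss$k, df = (ss$k - 1) * (ss$n - 1),
                     lower.tail = FALSE)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("c", seq_len(ss$k))
  data.frame(i = nm[pairs[1L, ]], j = nm[pairs[2L, ]],
             diff = unname(d), q = unname(q), p = unname(p))
}

#' Bonferroni adjustment
#'
#' @param p P-values.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}
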
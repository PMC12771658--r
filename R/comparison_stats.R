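# Period and method contrasts: Wilcoxon rank-sum with r effect size,
# binomial period models with optional per-bird random intercept, and
# Welch two-tailed t-tests with Cohen's d.

new_test_result <- function(statistic, p_value, effect_size, effect_type,
                            n, method, flagged = FALSE) {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_size = effect_size, effect_type = effect_type,
                 n = n, method = method, flagged = flagged),
            class = "divebudget_test")
}

#' @export
print.divebudget_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", signif(x$statistic, 4),
      ", p = ", format.pval(x$p_value, digits = 3),
      ", ", x$effect_type, " = ", signif(x$effect_size, 3),
      ", n = ", paste(x$n, collapse = "/"),
      if (x$flagged) "  [flagged]" else "", "\n", sep = "")
  invisible(x)
}

#' Wilcoxon rank-sum test with r effect size
#'
#' Two-sided Mann-Whitney/Wilcoxon test. The p-value is exact for small
#' tie-free samples and otherwise uses the normal approximation with tie
#' correction and continuity correction; the effect size is
#' `r = |Z| / sqrt(n_a + n_b)` from the (tie-corrected) normal
#' approximation. Two fully tied groups yield p = 1, r = 0, flagged.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @return a `divebudget_test` with the Mann-Whitney U statistic.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) stop_db("each group needs n >= 3")
  n1 <- length(a); n2 <- length(b); nn <- n1 + n2
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(new_test_result(n1 * n2 / 2, 1, 0, "r", c(n1, n2),
                           "Wilcoxon rank sum (all values tied)",
                           flagged = TRUE))
  }
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term))
  z <- (u - n1 * n2 / 2)
  z <- (z - sign(z) * 0.5) / sigma
  p <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided")$p.value)
  new_test_result(u, p, abs(z) / sqrt(nn), "r", c(n1, n2),
                  "Wilcoxon rank sum test")
}

#' Binomial model for a period (or method) effect on a behavior
#'
#' Logistic regression of per-group behavior counts on period, optionally
#' with a per-bird random intercept (via a mixed model). The reported
#' coefficient is the log-odds difference for `"diurnal"` relative to the
#' other period (positive when the behavior is more frequent by day), with
#' its two-sided p-value. Complete separation is flagged and no p-value is
#' reported.
#'
#' @param data data frame with columns `bird_id`, `period`, `successes`
#'   (count of bursts showing the behavior) and `failures`.
#' @param random_intercept add `(1 | bird_id)`; requires >= 5 birds.
#' @return list with `coefficient`, `p_value`, `term`, `flagged` and the
#'   fitted model in `fit`.
#' @export
binomial_period_model <- function(data, random_intercept = TRUE) {
  need <- c("bird_id", "period", "successes", "failures")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_db("data missing column(s): ",
                            paste(miss, collapse = ", "))
  periods <- unique(data$period)
  if (length(periods) < 2) stop_db("need >= 2 periods")
  lev <- if ("diurnal" %in% periods) {
    c(sort(setdiff(periods, "diurnal")), "diurnal")
  } else sort(periods)
  data$period <- factor(data$period, levels = lev)
  if (random_intercept) {
    if (length(unique(data$bird_id)) < 5) {
      stop_db("random intercept requires >= 5 birds")
    }
    fit <- lme4::glmer(cbind(successes, failures) ~ period + (1 | bird_id),
                       data = data, family = stats::binomial())
    co <- summary(fit)$coefficients
  } else {
    fit <- stats::glm(cbind(successes, failures) ~ period, data = data,
                      family = stats::binomial())
    co <- summary(fit)$coefficients
  }
  term <- rownames(co)[2]
  est <- co[2, 1]
  separated <- !is.finite(est) || abs(est) > 15
  list(coefficient = est,
       p_value = if (separated) NA_real_ else co[2, 4],
       term = term, flagged = separated, fit = fit)
}

#' Welch two-tailed t-test with Cohen's d
#'
#' Welch's unequal-variance t-test (two-sided) plus Cohen's d with pooled
#' SD. Two zero-variance samples are flagged with no p-value.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a `divebudget_test`.
#' @export
two_tailed_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_db("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0) {
    return(new_test_result(NA_real_, NA_real_, NA_real_, "cohens_d",
                           c(length(a), length(b)),
                           "Welch two-tailed t-test (zero variance)",
                           flagged = TRUE))
  }
  tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp == 0) Inf else (mean(a) - mean(b)) / sp
  new_test_result(unname(tt$statistic), tt$p.value, d, "cohens_d",
                  c(length(a), length(b)), "Welch two-tailed t-test")
}
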
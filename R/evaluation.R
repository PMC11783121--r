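#' Prediction-performance metrics
#'
#' Standard external-evaluation metrics for paired model predictions and
#' observed concentrations:
#' \itemize{
#'   \item MAPE — central absolute relative prediction error,
#'     \eqn{100\,\mathrm{center}(|p - o| / o)};
#'   \item relative bias — signed central relative error,
#'     \eqn{100\,\mathrm{center}((p - o)/o)} (negative = underprediction);
#'   \item RMSE — \eqn{\sqrt{\mathrm{mean}((p - o)^2)}} in nM;
#'   \item F80-125 — percentage of prediction/observation ratios inside
#'     \[0.80, 1.25\] (bounds inclusive).
#' }
#' The central tendency defaults to the median (so "MAPE" reads as *median*
#' absolute prediction error); `center = "mean"` is also available.
#'
#' @param predicted,observed numeric vectors of equal length; `observed`
#'   must be strictly positive.
#' @param center `"median"` (default) or `"mean"`.
#' @return list with `mape`, `relative_bias` (both %), `rmse` (nM),
#'   `f80_125` (%) and `n`.
#' @examples
#' prediction_metrics(c(20, 9, 15), c(16, 12, 15))
#' @export
prediction_metrics <- function(predicted, observed,
                               center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(predicted) == 0) stop_domain("no prediction pairs supplied")
  if (length(predicted) != length(observed)) {
    stop_domain("predicted and observed must have equal length")
  }
  if (any(observed <= 0)) {
    stop_domain("observed concentrations must be > 0 for ratio-based metrics")
  }
  cfun <- if (center == "median") stats::median else mean
  rel <- (predicted - observed) / observed
  ratio <- predicted / observed
  list(
    mape = 100 * cfun(abs(rel)),
    relative_bias = 100 * cfun(rel),
    rmse = sqrt(mean((predicted - observed)^2)),
    f80_125 = 100 * mean(ratio >= 0.8 & ratio <= 1.25),
    n = length(predicted)
  )
}

#' Sub-therapeutic counts per group
#'
#' Tabulates, per group (cohort, dose category or activity bin), how many
#' observed steady-state levels fall below the threshold, with the
#' percentage rounded to one decimal (half up). Empty groups are reported
#' with n = 0 and an undefined (NA) percentage.
#'
#' @param observed observed steady-state concentrations (nM).
#' @param group group label per observation (factor or character; factor
#'   level order is preserved).
#' @param threshold therapeutic threshold (nM).
#' @return data frame with `group`, `n_below`, `n_total`, `pct_below`.
#' @export
attainment_table <- function(observed, group, threshold = 16) {
  if (length(observed) != length(group)) {
    stop_domain("observed and group must have equal length")
  }
  group <- if (is.factor(group)) group else factor(group)
  below <- !classify_attainment(observed, threshold)
  n_below <- as.vector(tapply(below, group, sum, default = 0L))
  n_total <- as.vector(table(group))
  data.frame(
    group = levels(group),
    n_below = as.integer(n_below),
    n_total = as.integer(n_total),
    pct_below = ifelse(n_total > 0,
                       round_half_up(100 * n_below / pmax(n_total, 1), 1),
                       NA_real_),
    stringsAsFactors = FALSE
  )
}

as_2x2 <- function(x, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) x <- matrix(c(x, b, c, d), 2, 2, byrow = TRUE)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) stop_domain("a 2x2 table is required")
  if (any(x < 0) || any(x != round(x))) {
    stop_domain("cell counts must be non-negative integers")
  }
  if (sum(x) == 0) stop_domain("table total must be > 0")
  storage.mode(x) <- "double" # cross-products overflow integer arithmetic
  x
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Computes the Pearson statistic
#' \eqn{N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with df = 1. The Yates
#' continuity correction is *off* by default; cohort comparisons in this
#' package are reported uncorrected.
#'
#' @param x 2x2 matrix of counts (rows = cohorts, columns = below /
#'   at-or-above threshold), or the count `a` with `b`, `c`, `d` given
#'   separately (row-wise).
#' @param b,c,d optional remaining cell counts when `x` is scalar.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic` and `p.value`.
#' @examples
#' chisq_2x2(89, 17, 345, 98) # statistic 1.91, p 0.167
#' @export
chisq_2x2 <- function(x, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  x <- as_2x2(x, b, c, d)
  a <- x[1, 1]; bb <- x[1, 2]; cc <- x[2, 1]; dd <- x[2, 2]
  n <- sum(x)
  margins <- c(a + bb, cc + dd, a + cc, bb + dd)
  if (any(margins == 0)) {
    stop_domain("chi-squared statistic undefined: a table margin is zero")
  }
  num <- abs(a * dd - bb * cc)
  if (correct) num <- max(0, num - n / 2)
  statistic <- n * num^2 / prod(margins)
  list(statistic = statistic,
       p.value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Enumerates the hypergeometric support with the table margins fixed and
#' sums the probabilities of all tables no more probable than the observed
#' one (the probability-ordering convention for the two-sided p-value).
#'
#' @inheritParams chisq_2x2
#' @return two-sided p-value.
#' @examples
#' fisher_2x2(0, 5, 21, 3) # ~5.5e-4
#' @export
fisher_2x2 <- function(x, b = NULL, c = NULL, d = NULL) {
  x <- as_2x2(x, b, c, d)
  a <- x[1, 1]
  m <- x[1, 1] + x[2, 1]   # column-1 total
  n2 <- x[1, 2] + x[2, 2]  # column-2 total
  k <- x[1, 1] + x[1, 2]   # row-1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  # relative tolerance guards against ties lost to floating point
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Analytic power of the two-proportion comparison
#'
#' Normal approximation with a pooled-variance null: the power to detect
#' `p_intervention` vs `p_control` at two-sided level `alpha` with cohort
#' sizes `n_intervention` and `n_control`.
#'
#' @param p_control,p_intervention true attainment proportions.
#' @param n_control,n_intervention cohort sizes.
#' @param alpha two-sided significance level.
#' @return power as a fraction in (0, 1).
#' @export
analytic_power <- function(p_control, p_intervention, n_control,
                           n_intervention, alpha = 0.05) {
  if (p_control == p_intervention) {
    stop_domain("no effect: p_control equals p_intervention")
  }
  delta <- abs(p_intervention - p_control)
  pbar <- (p_intervention * n_intervention + p_control * n_control) /
    (n_intervention + n_control)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n_intervention + 1 / n_control))
  se1 <- sqrt(p_intervention * (1 - p_intervention) / n_intervention +
              p_control * (1 - p_control) / n_control)
  z <- (delta - stats::qnorm(1 - alpha / 2) * se0) / se1
  stats::pnorm(z)
}

#' Smallest intervention cohort reaching a target power
#'
#' Smallest `n_intervention` whose [analytic_power()] against a fixed
#' control cohort reaches `power_target`.
#'
#' @inheritParams analytic_power
#' @param power_target required power (fraction).
#' @param n_max search bound.
#' @return integer sample size.
#' @export
required_sample_size <- function(p_control, p_intervention, n_control,
                                 alpha = 0.05, power_target = 0.80,
                                 n_max = 1e6) {
  if (p_control == p_intervention) {
    stop_domain("no effect: p_control equals p_intervention")
  }
  n <- 2:n_max
  pow <- analytic_power(p_control, p_intervention, n_control, n, alpha)
  hit <- which(pow >= power_target)
  if (length(hit) == 0) stop_domain("power target not reachable by n = ", n_max)
  n[hit[1]]
}

# vectorised uncorrected Pearson statistic over many 2x2 tables;
# degenerate tables (zero margin) get statistic 0.
# doubles throughout: the margin product overflows integer arithmetic
chisq_stat_vec <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
  stat
}

#' Monte-Carlo power of the uncorrected chi-squared test
#'
#' Simulates binomial attainment counts for both cohorts `reps` times and
#' reports the fraction of replicates in which the uncorrected Pearson
#' chi-squared test rejects at two-sided level `alpha`.
#'
#' @inheritParams analytic_power
#' @param reps number of Monte-Carlo replicates (>= 1000).
#' @param seed optional RNG seed.
#' @return rejection fraction in [0, 1].
#' @examples
#' empirical_power(0.78, 0.90, 443, 106, reps = 2000, seed = 1)
#' @export
empirical_power <- function(p_control, p_intervention, n_control,
                            n_intervention, alpha = 0.05, reps = 20000,
                            seed = NULL) {
  if (p_control == p_intervention) {
    stop_domain("no effect: p_control equals p_intervention")
  }
  if (reps < 1000) stop_domain("reps must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  xi <- stats::rbinom(reps, n_intervention, p_intervention)
  xc <- stats::rbinom(reps, n_control, p_control)
  stat <- chisq_stat_vec(xi, n_intervention - xi, xc, n_control - xc)
  crit <- stats::qchisq(1 - alpha, df = 1)
  mean(stat > crit)
}

#' Minimal clinically important difference comparison
#'
#' A change in a questionnaire score is clinically relevant only when its
#' absolute value strictly exceeds the scale's MCID (4.4 points for the
#' ES19 endocrine-symptom scale, 6.98 points for HR-QOL).
#'
#' @param baseline_mean,followup_mean mean scores (points).
#' @param mcid minimal clinically important difference (> 0).
#' @return logical: clinically relevant change.
#' @examples
#' mcid_compare(64.8, 61.3, mcid = 4.4)  # FALSE: |-3.5| <= 4.4
#' @export
mcid_compare <- function(baseline_mean, followup_mean, mcid) {
  if (any(mcid <= 0)) stop_domain("mcid must be > 0")
  abs(followup_mean - baseline_mean) > mcid
}
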
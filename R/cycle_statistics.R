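#' Phase durations of cell-cycle records
#'
#' Mitotic length is the time between mitotic entry (cyclin Clb2 rise) and
#' anaphase onset (Clb2 fall); cell-cycle length is the time between two
#' subsequent budding events. Censored records (death or end of imaging
#' before the terminal event) return whatever durations their landmarks
#' allow, with the censored flag propagated.
#'
#' @param records A data frame with columns `t_bud`, `t_mito`, `t_ana`,
#'   `t_nextbud` (minutes; `NA` where unobserved) and logical `censored`.
#'   For censored rows `t_nextbud`, when present, holds the censoring time.
#' @return A data frame `mitotic_length_min`, `cell_cycle_length_min`,
#'   `censored`, one row per record.
#' @export
phase_durations <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("t_bud", "t_mito", "t_ana", "t_nextbud") %in% names(records)))
  censored <- if ("censored" %in% names(records)) {
    as.logical(records$censored)
  } else rep(FALSE, nrow(records))
  bad <- !is.na(records$t_ana) & !is.na(records$t_mito) &
    records$t_ana < records$t_mito
  if (any(bad)) stop("anaphase onset before mitotic entry in record(s) ",
                     paste(which(bad), collapse = ", "))
  data.frame(
    mitotic_length_min = records$t_ana - records$t_mito,
    cell_cycle_length_min = records$t_nextbud - records$t_bud,
    censored = censored)
}

#' Summarize phase durations for one condition
#'
#' @param durations Output of [phase_durations()] (or a compatible data
#'   frame).
#' @param condition Condition label.
#' @return An object of class `"condition_summary"`: a list with
#'   `condition`, `m_mitosis`, `m_cellcycle` (median minutes over the rows
#'   where the duration is observed), `n`, `n_censored`.
#' @export
condition_summary <- function(durations, condition = "condition") {
  stopifnot(is.data.frame(durations))
  structure(list(
    condition = condition,
    m_mitosis = stats::median(durations$mitotic_length_min, na.rm = TRUE),
    m_cellcycle = stats::median(durations$cell_cycle_length_min[
      !durations$censored], na.rm = TRUE),
    n = nrow(durations),
    n_censored = sum(durations$censored)), class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s: median mitosis %.1f min, median cell cycle %.1f min (n = %d, %d censored)\n",
              x$condition, x$m_mitosis, x$m_cellcycle, x$n, x$n_censored))
  invisible(x)
}

#' Fold increases of the mitotic and non-mitotic phases
#'
#' `FOLD_mitosis = m_mit^SAC / m_mit^unp` and
#' `FOLD_notmitosis = (m_cc^SAC - m_mit^SAC) / (m_cc^unp - m_mit^unp)`,
#' where `m_mit` and `m_cc` are the median mitotic and cell-cycle lengths
#' of each condition. The non-mitotic fold is a ratio of differences, so
#' it is not invariant to shifting the medians jointly.
#'
#' @param sac,unp [condition_summary()] objects (or lists with
#'   `m_mitosis`, `m_cellcycle`) for the SAC-active and unperturbed
#'   conditions.
#' @return A list `fold_mitosis`, `fold_notmitosis`.
#' @examples
#' sac <- list(m_mitosis = 159, m_cellcycle = 400)
#' unp <- list(m_mitosis = 30, m_cellcycle = 100)
#' fold_changes(sac, unp)
#' @export
fold_changes <- function(sac, unp) {
  for (s in list(sac, unp)) {
    stopifnot(is.numeric(s$m_mitosis), is.numeric(s$m_cellcycle))
    if (s$m_mitosis <= 0 || s$m_cellcycle <= s$m_mitosis) {
      stop("medians must be positive with cell-cycle median exceeding mitotic median")
    }
  }
  list(fold_mitosis = sac$m_mitosis / unp$m_mitosis,
       fold_notmitosis = (sac$m_cellcycle - sac$m_mitosis) /
         (unp$m_cellcycle - unp$m_mitosis))
}

#' Relative size gain during mitosis
#'
#' `G_mitosis = ln(A_ANA / A_PM)`: the log-ratio of the area at anaphase
#' onset to the area at mitotic entry. Scale-invariant: it depends only on
#' the ratio of the two sizes.
#'
#' @param A_PM Area at mitotic entry (prometaphase), um^2.
#' @param A_ANA Area at anaphase onset, um^2.
#' @return `log(A_ANA / A_PM)`, vectorized.
#' @export
size_growth_stat <- function(A_PM, A_ANA) {
  stopifnot(is.numeric(A_PM), is.numeric(A_ANA))
  if (any(A_PM <= 0) || any(A_ANA <= 0)) stop("sizes must be positive")
  log(A_ANA / A_PM)
}

#' Slope of the size-growth plot
#'
#' Ordinary least-squares regression of `G_mitosis = ln(A_ANA/A_PM)` on
#' `ln(A_PM)`. The slope `lambda` quantifies size control during mitosis:
#' 0 for a pure timer (growth independent of entry size), -1 for a perfect
#' sizer (exit size independent of entry size).
#'
#' @param records Data frame with columns `A_pm`, `A_ana` (um^2) and
#'   optionally `censored` (censored rows are dropped).
#' @param alpha Significance level attached to the returned test.
#'   Default 0.05.
#' @return A list `lambda`, `p_value` (slope t-test), `n`, `significant`.
#' @export
size_growth_slope <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), all(c("A_pm", "A_ana") %in% names(records)))
  if ("censored" %in% names(records)) {
    records <- records[!records$censored, , drop = FALSE]
  }
  records <- records[stats::complete.cases(records[, c("A_pm", "A_ana")]), ,
                     drop = FALSE]
  if (nrow(records) < 3L) stop("at least three uncensored records are required")
  x <- log(records$A_pm)
  if (diff(range(x)) < 1e-12) stop("degenerate regressor: all entry sizes equal")
  g <- size_growth_stat(records$A_pm, records$A_ana)
  fit <- stats::lm(g ~ x)
  co <- summary(fit)$coefficients
  p <- if (nrow(co) >= 2L && ncol(co) >= 4L) co[2L, 4L] else NA_real_
  list(lambda = unname(stats::coef(fit)[2L]), p_value = p,
       n = nrow(records), significant = isTRUE(p < alpha))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by sample mean.
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) stop("CV is undefined for zero mean")
  stats::sd(values) / m
}

# Jarque-Bera normality test (skewness/excess-kurtosis chi-square, df = 2).
# Written here because no installed package provides it.
.jarque_bera <- function(x) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- mean(z^2); m3 <- mean(z^3); m4 <- mean(z^4)
  s <- m3 / m2^1.5
  k <- m4 / m2^2
  stat <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = stat, p.value = stats::pchisq(stat, 2, lower.tail = FALSE))
}

#' Four-test normality verdict
#'
#' Runs Lilliefors, Anderson-Darling, Jarque-Bera and one-sample
#' Kolmogorov-Smirnov (against a Normal with the sample mean and SD) and
#' declares the sample compatible with normality when at least three of
#' the four p-values exceed `alpha`.
#'
#' @param x Numeric sample, `n >= 8`.
#' @param alpha Significance level. Default 0.05.
#' @return A list `normal` (logical), `p_values` (named length-4 vector).
#' @export
normality_verdict <- function(x, alpha = 0.05) {
  stopifnot(is.numeric(x))
  if (length(x) < 8L) stop("the normality battery needs at least 8 observations")
  p <- c(
    lilliefors = nortest::lillie.test(x)$p.value,
    anderson_darling = nortest::ad.test(x)$p.value,
    jarque_bera = .jarque_bera(x)$p.value,
    kolmogorov_smirnov = suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value))
  list(normal = sum(p > alpha) >= 3L, p_values = p)
}

#' Normality-gated correlation
#'
#' Pearson's correlation when both variables pass the four-test normality
#' verdict ([normality_verdict()]), Spearman's rank correlation otherwise.
#'
#' @param x,y Equal-length numeric vectors, `n >= 8`.
#' @param alpha Significance level for the normality gate and reported
#'   test. Default 0.05.
#' @return A list `method` (`"pearson"`/`"spearman"`), `estimate`,
#'   `p_value`, `normal_x`, `normal_y`.
#' @export
choose_correlation <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  nx <- normality_verdict(x, alpha)
  ny <- normality_verdict(y, alpha)
  method <- if (nx$normal && ny$normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, normal_x = nx$normal, normal_y = ny$normal)
}

#' Overlap of two probability densities
#'
#' Kernel density estimates of both samples on one shared grid (512
#' points spanning both supports extended by three bandwidths; Scott's
#' reference bandwidth per sample), then the overlap coefficient
#' `O = integral of min(f, g)` by trapezoidal quadrature, clipped to
#' [0, 1]. Identical distributions give O near 1, disjoint ones near 0.
#'
#' @param samples_f,samples_g Numeric samples, `n >= 10` each.
#' @param n_grid Number of grid points. Default 512.
#' @return The overlap coefficient in [0, 1].
#' @examples
#' set.seed(1)
#' density_overlap(rnorm(5000), rnorm(5000, 2))  # ~2 * pnorm(-1) = 0.317
#' @export
density_overlap <- function(samples_f, samples_g, n_grid = 512L) {
  stopifnot(is.numeric(samples_f), is.numeric(samples_g))
  if (length(samples_f) < 10L || length(samples_g) < 10L) {
    stop("each sample needs at least 10 observations")
  }
  hf <- stats::bw.nrd(samples_f)
  hg <- stats::bw.nrd(samples_g)
  lo <- min(min(samples_f) - 3 * hf, min(samples_g) - 3 * hg)
  hi <- max(max(samples_f) + 3 * hf, max(samples_g) + 3 * hg)
  f <- stats::density(samples_f, bw = hf, from = lo, to = hi, n = n_grid)
  g <- stats::density(samples_g, bw = hg, from = lo, to = hi, n = n_grid)
  mn <- pmin(f$y, g$y)
  o <- sum((mn[-1L] + mn[-n_grid]) / 2 * diff(f$x))
  min(max(o, 0), 1)
}

#' Log-rank comparison of censored durations
#'
#' Compares two groups of (possibly right-censored) durations with the
#' log-rank test, delegated to [survival::survdiff()].
#'
#' @param durations_a,durations_b Durations in minutes.
#' @param censored_a,censored_b Logical censoring flags (default: none
#'   censored).
#' @return A list `chisq`, `p_value`, `n`.
#' @export
compare_durations <- function(durations_a, durations_b,
                              censored_a = rep(FALSE, length(durations_a)),
                              censored_b = rep(FALSE, length(durations_b))) {
  stopifnot(length(durations_a) >= 1L, length(durations_b) >= 1L,
            length(censored_a) == length(durations_a),
            length(censored_b) == length(durations_b))
  if (all(censored_a) || all(censored_b)) {
    stop("a group with no observed events cannot be compared")
  }
  time <- c(durations_a, durations_b)
  event <- c(!censored_a, !censored_b)
  group <- rep(c("a", "b"), c(length(durations_a), length(durations_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p, n = length(time))
}

#' Normality-gated two-group location test
#'
#' Welch's two-sample t test when both groups pass the four-test normality
#' verdict, two-sided Mann-Whitney otherwise.
#'
#' @param x,y Numeric samples, `n >= 8` each.
#' @param alpha Significance level. Default 0.05.
#' @return A list `method` (`"welch_t"`/`"mann_whitney"`), `p_value`.
#' @export
compare_locations <- function(x, y, alpha = 0.05) {
  normal <- normality_verdict(x, alpha)$normal &&
    normality_verdict(y, alpha)$normal
  if (normal) {
    list(method = "welch_t", p_value = stats::t.test(x, y)$p.value)
  } else {
    list(method = "mann_whitney",
         p_value = suppressWarnings(stats::wilcox.test(x, y)$p.value))
  }
}
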
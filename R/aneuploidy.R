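#' Chromosome mis-segregation rate from scored counts
#'
#' The rate `R` of mis-segregation of the marked chromosome: the number of
#' mis-segregating cells over the total number of scored cells.
#'
#' @param n_missegregating Count of mis-segregating cells (vectorized).
#' @param n_total Total scored cells, `>= 1`.
#' @return Fraction(s) in [0, 1].
#' @examples
#' misseg_rate(2, 91)   # 0.0220
#' misseg_rate(16, 238) # 0.0672
#' @export
misseg_rate <- function(n_missegregating, n_total) {
  stopifnot(is.numeric(n_missegregating), is.numeric(n_total),
            length(n_missegregating) == length(n_total))
  if (any(n_total < 1)) stop("'n_total' must be at least 1")
  if (any(n_missegregating < 0 | n_missegregating > n_total)) {
    stop("'n_missegregating' must lie in [0, n_total]")
  }
  n_missegregating / n_total
}

#' Probability of at least one aneuploid chromosome
#'
#' Assuming every one of the `n_chromosomes` chromosomes mis-segregates
#' independently with the same per-chromosome rate `R` measured on the
#' marked chromosome, the probability that a cell ends up with at least
#' one aneuploid chromosome is `P = 1 - (1 - R)^n_chromosomes`
#' (16 chromosomes in S. cerevisiae).
#'
#' @param R Per-chromosome mis-segregation rate(s) in [0, 1].
#' @param n_chromosomes Number of chromosomes. Default 16.
#' @return Probability(ies) in [0, 1].
#' @examples
#' aneuploidy_probability(misseg_rate(16, 238))
#' @export
aneuploidy_probability <- function(R, n_chromosomes = 16L) {
  stopifnot(is.numeric(R), n_chromosomes >= 1)
  if (any(R < 0 | R > 1)) stop("'R' must lie in [0, 1]")
  1 - (1 - R)^n_chromosomes
}

#' Aneuploidy estimates for a table of replicate counts
#'
#' Computes per-replicate mis-segregation rates and aneuploidy
#' probabilities, then aggregates per condition either by averaging the
#' per-replicate probabilities (`"mean_p"`, default — replicates are
#' independent scorings and are reported as separate points) or by pooling
#' the counts before the probability map (`"pooled"`).
#'
#' @param counts Data frame with columns `condition`, `n_missegregating`,
#'   `n_total` (and optionally `replicate`).
#' @param aggregate `"mean_p"` or `"pooled"`.
#' @param n_chromosomes Number of chromosomes. Default 16.
#' @return A list with `per_replicate` (the input plus `rate` and
#'   `p_aneuploid`) and `per_condition` (data frame `condition`,
#'   `p_aneuploid`).
#' @export
aneuploidy_summary <- function(counts, aggregate = c("mean_p", "pooled"),
                               n_chromosomes = 16L) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(counts),
            all(c("condition", "n_missegregating", "n_total") %in% names(counts)))
  counts$rate <- misseg_rate(counts$n_missegregating, counts$n_total)
  counts$p_aneuploid <- aneuploidy_probability(counts$rate, n_chromosomes)
  conds <- unique(counts$condition)
  p <- vapply(conds, function(cc) {
    rows <- counts[counts$condition == cc, , drop = FALSE]
    if (aggregate == "mean_p") {
      mean(rows$p_aneuploid)
    } else {
      aneuploidy_probability(
        misseg_rate(sum(rows$n_missegregating), sum(rows$n_total)),
        n_chromosomes)
    }
  }, numeric(1))
  list(per_replicate = counts,
       per_condition = data.frame(condition = conds, p_aneuploid = unname(p)))
}

#' Simulate scored mis-segregation counts
#'
#' Binomial draw of mis-segregating cells among `n_total` scored cells;
#' [misseg_rate()] of the result is an unbiased estimator of `true_R`.
#'
#' @param true_R True per-cell mis-segregation probability in [0, 1].
#' @param n_total Number of scored cells.
#' @param condition Condition label attached to the output.
#' @return A one-row data frame `condition`, `n_missegregating`,
#'   `n_total`.
#' @export
simulate_misseg_counts <- function(true_R, n_total, condition = "synthetic") {
  stopifnot(true_R >= 0, true_R <= 1, n_total >= 1)
  data.frame(condition = condition,
             n_missegregating = stats::rbinom(1L, n_total, true_R),
             n_total = as.integer(n_total))
}
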
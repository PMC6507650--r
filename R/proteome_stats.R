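#' Gene-wise fold-change profile with ESR annotation
#'
#' Log2 fold changes annotated with each gene's role in the environmental
#' stress response (ESR): `induced`, `repressed`, or `unrelated`. The
#' package ships no gene lists; any user-supplied annotation (for example
#' the canonical ESR sets) can be used.
#'
#' @param gene Gene identifiers.
#' @param log2fc Finite log2 fold changes, same length.
#' @param esr_class Per-gene class in `{"induced", "repressed",
#'   "unrelated"}`.
#' @return An object of class `"fold_change_profile"` (a data frame).
#' @export
fold_change_profile <- function(gene, log2fc, esr_class) {
  stopifnot(length(gene) == length(log2fc),
            length(gene) == length(esr_class),
            all(is.finite(log2fc)),
            all(esr_class %in% c("induced", "repressed", "unrelated")))
  if (!any(esr_class == "induced") || !any(esr_class == "repressed")) {
    stop("the profile needs at least one ESR-induced and one ESR-repressed gene")
  }
  structure(data.frame(gene = gene, log2fc = log2fc, esr_class = esr_class,
                       stringsAsFactors = FALSE),
            class = c("fold_change_profile", "data.frame"))
}

#' Stress response intensity
#'
#' Signed, normalized aggregate of the ESR genes' fold changes:
#' `SRI = (sum(x_i) + sum(-y_j)) / (sum(|x_i|) + sum(|y_j|))`, where `x`
#' are the fold changes of ESR-induced genes and `y` those of
#' ESR-repressed genes. SRI is +1 exactly when every induced gene is up
#' and every repressed gene down, -1 for the exact reversal, and lies in
#' [-1, 1] always; genes unrelated to the ESR are ignored, as is any
#' common positive rescaling of the fold changes.
#'
#' @param profile A [fold_change_profile()].
#' @return The SRI, a number in [-1, 1].
#' @examples
#' p <- fold_change_profile(c("g1", "g2", "g3"),
#'                          c(2, -1, -1),
#'                          c("induced", "induced", "repressed"))
#' sri(p)  # 0.5
#' @export
sri <- function(profile) {
  stopifnot(inherits(profile, "fold_change_profile"))
  x <- profile$log2fc[profile$esr_class == "induced"]
  y <- profile$log2fc[profile$esr_class == "repressed"]
  den <- sum(abs(x)) + sum(abs(y))
  if (den == 0) stop("SRI is undefined when every ESR gene has zero fold change")
  (sum(x) - sum(y)) / den
}

#' Z-normalize a vector
#'
#' Subtracts the mean and divides by the sample SD, the standardization
#' applied to each expression profile before cross-data-set clustering.
#'
#' @param values Numeric vector, `n >= 2`, non-zero SD.
#' @return A vector with mean 0 and SD 1.
#' @export
znormalize <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (s == 0) stop("z-normalization is undefined for a constant vector")
  (values - mean(values)) / s
}

#' Spearman correlation-distance matrix between profiles
#'
#' Pairwise distances `d_ij = 1 - Spearman(profile_i, profile_j)` between
#' the columns of a profile matrix, the dissimilarity used for
#' complete-linkage hierarchical clustering of expression profiles.
#' Distances lie in [0, 2]: 0 for identically ranked profiles, 2 for
#' perfectly anti-ranked ones.
#'
#' @param profiles Numeric matrix, genes in rows and profiles in columns
#'   (at least 2 columns, 3 rows); constant columns are rejected because
#'   their rank correlation is undefined.
#' @return A symmetric distance matrix with zero diagonal; pass through
#'   [stats::as.dist()] into [stats::hclust()] for clustering.
#' @export
correlation_distance_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  stopifnot(is.numeric(profiles), ncol(profiles) >= 2L, nrow(profiles) >= 3L)
  if (any(apply(profiles, 2L, function(v) stats::sd(v) == 0))) {
    stop("constant profile: Spearman correlation is undefined")
  }
  d <- 1 - stats::cor(profiles, method = "spearman")
  diag(d) <- 0
  d
}

#' Complete-linkage clustering of profiles by correlation distance
#'
#' @param profiles As in [correlation_distance_matrix()].
#' @return An [stats::hclust()] tree (method `"complete"`).
#' @export
cluster_profiles <- function(profiles) {
  stats::hclust(stats::as.dist(correlation_distance_matrix(profiles)),
                method = "complete")
}

#' Simulate an ESR-structured fold-change profile
#'
#' Induced genes are drawn around `+strength`, repressed genes around
#' `-strength`, unrelated genes around 0, all with Gaussian noise of SD
#' `noise_sd` — a profile whose true SRI sign and magnitude are known.
#'
#' @param strength Mean absolute log2 fold change of the ESR genes; 0
#'   gives a null profile, negative values an inverted ESR.
#' @param n_induced,n_repressed,n_unrelated Gene counts (`>= 1` for the
#'   two ESR classes).
#' @param noise_sd Noise SD, `>= 0`. Default 0.3.
#' @return A [fold_change_profile()].
#' @export
simulate_esr_profile <- function(strength, n_induced = 100L,
                                 n_repressed = 100L, n_unrelated = 100L,
                                 noise_sd = 0.3) {
  stopifnot(n_induced >= 1L, n_repressed >= 1L, n_unrelated >= 0L,
            noise_sd >= 0)
  cls <- rep(c("induced", "repressed", "unrelated"),
             c(n_induced, n_repressed, n_unrelated))
  mu <- rep(c(strength, -strength, 0), c(n_induced, n_repressed, n_unrelated))
  fold_change_profile(
    gene = sprintf("gene_%04d", seq_along(cls)),
    log2fc = stats::rnorm(length(cls), mu, noise_sd),
    esr_class = cls)
}
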
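#' Single-cell size trajectory
#'
#' A time/area series for one cell, with per-point flags recording which
#' values were replaced by the outlier filter.
#'
#' @param times Strictly increasing sampling times in minutes.
#' @param areas Cell areas in um^2, same length as `times`.
#' @param cell_id Identifier. Default `"cell"`.
#' @param condition One of `"gen0_unperturbed"`, `"unperturbed"`,
#'   `"gen0_sac"`, `"sac"`; selects the default smoothing window
#'   (3 points for unperturbed conditions, 8 for SAC conditions).
#' @param censored Logical: does the series end before the cycle does?
#' @return An object of class `"size_trajectory"`.
#' @export
size_trajectory <- function(times, areas, cell_id = "cell",
                            condition = c("unperturbed", "gen0_unperturbed",
                                          "sac", "gen0_sac"),
                            censored = FALSE) {
  condition <- match.arg(condition)
  stopifnot(length(times) == length(areas), length(times) >= 1L,
            all(diff(times) > 0), all(areas > 0))
  structure(list(times = as.numeric(times), areas = as.numeric(areas),
                 adjusted = logical(length(areas)),
                 cell_id = cell_id, condition = condition,
                 censored = censored),
            class = "size_trajectory")
}

#' @export
print.size_trajectory <- function(x, ...) {
  cat(sprintf("Size trajectory '%s' (%s): %d points, %d adjusted%s\n",
              x$cell_id, x$condition, length(x$areas), sum(x$adjusted),
              if (x$censored) ", censored" else ""))
  invisible(x)
}

.areas_of <- function(traj) {
  if (inherits(traj, "size_trajectory")) traj$areas else as.numeric(traj)
}

#' Local size variations of a trajectory
#'
#' First differences `dA_i = A_{i+1} - A_i`, the quantity on which the
#' outlier filter operates. Variation `i` is paired with the size `A_i` it
#' starts from.
#'
#' @param traj A [size_trajectory()] or numeric vector of areas (length
#'   >= 2).
#' @return Numeric vector of length `N - 1`.
#' @export
local_variations <- function(traj) {
  a <- .areas_of(traj)
  if (length(a) < 2L) stop("at least two points are needed for local variations")
  diff(a)
}

#' Fit per-size-cluster outlier bounds for local variations
#'
#' Pools the `(A_i, dA_i)` pairs of a group of trajectories, splits them
#' into size clusters (default edges 0-40, 40-80, 80-120 um^2, clusters
#' closed on the right), and sets Tukey fences per cluster:
#' `lower = Q1 - 1.5 IQR`, `upper = Q3 + 1.5 IQR` of the cluster's dA
#' distribution. Quartiles use linear interpolation (R's default type 7).
#' Clusters with fewer than `min_n` pairs are left unset and never flag
#' points; sizes above the last edge fall outside all clusters.
#'
#' @param trajs A list of [size_trajectory()]s (or numeric vectors), or a
#'   single trajectory.
#' @param edges Cluster edges in um^2. Default `c(0, 40, 80, 120)`.
#' @param min_n Minimum pairs per cluster to fit its bounds. Default 4.
#' @return An object of class `"cluster_thresholds"`: a data frame with
#'   columns `size_lo`, `size_hi`, `lower`, `upper`, `n`.
#' @export
fit_thresholds <- function(trajs, edges = c(0, 40, 80, 120), min_n = 4L) {
  if (inherits(trajs, "size_trajectory") || is.numeric(trajs)) {
    trajs <- list(trajs)
  }
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  A <- unlist(lapply(trajs, function(tr) {
    a <- .areas_of(tr); a[-length(a)]
  }))
  dA <- unlist(lapply(trajs, local_variations))
  k <- length(edges) - 1L
  out <- data.frame(size_lo = edges[-length(edges)], size_hi = edges[-1L],
                    lower = NA_real_, upper = NA_real_, n = 0L)
  # clusters are (lo, hi] except the first, which includes its left edge
  cl <- findInterval(A, edges, left.open = TRUE)
  cl[A >= edges[1L] & A <= edges[2L]] <- 1L
  for (j in seq_len(k)) {
    dj <- dA[!is.na(cl) & cl == j]
    out$n[j] <- length(dj)
    if (length(dj) >= min_n) {
      q <- stats::quantile(dj, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2L] - q[1L]
      out$lower[j] <- q[1L] - 1.5 * iqr
      out$upper[j] <- q[2L] + 1.5 * iqr
    }
  }
  structure(out, class = c("cluster_thresholds", "data.frame"))
}

#' Construct cluster thresholds directly
#'
#' @param edges Cluster edges (length `k + 1`).
#' @param lower,upper Per-cluster bounds on the local variation (length
#'   `k`), `lower < upper` where set.
#' @return A `"cluster_thresholds"` object.
#' @export
cluster_thresholds <- function(edges, lower, upper) {
  k <- length(edges) - 1L
  stopifnot(length(lower) == k, length(upper) == k,
            all(is.na(lower) | is.na(upper) | lower < upper))
  structure(data.frame(size_lo = edges[-length(edges)], size_hi = edges[-1L],
                       lower = lower, upper = upper, n = NA_integer_),
            class = c("cluster_thresholds", "data.frame"))
}

# cluster index of each size under the thresholds' edges; 0 = no cluster
.cluster_of <- function(thr, A) {
  edges <- c(thr$size_lo, thr$size_hi[nrow(thr)])
  cl <- findInterval(A, edges, left.open = TRUE)
  cl[A >= edges[1L] & A <= edges[2L]] <- 1L
  cl[A < edges[1L] | A > edges[length(edges)]] <- 0L
  cl
}

# TRUE where variation dA (paired with starting size A) violates its
# cluster's fences; FALSE where the cluster is unset or A is unclustered.
.violates <- function(thr, A, dA) {
  cl <- .cluster_of(thr, A)
  v <- logical(length(dA))
  ok <- cl > 0L
  lo <- thr$lower[cl[ok]]; hi <- thr$upper[cl[ok]]
  v[ok] <- !is.na(lo) & !is.na(hi) & (dA[ok] < lo | dA[ok] > hi)
  v
}

#' Iteratively replace outlier points in a size trajectory
#'
#' Points whose local variation leaves the fitted cluster fences are
#' replaced by the mean of their two neighbours; the pass repeats until no
#' point is replaced or `max_iter` passes have run. Endpoints are never
#' replaced. The thresholds are fitted once and held fixed across passes.
#'
#' Which variation condemns a point is set by `flag_rule`:
#' \describe{
#'   \item{`"both"` (default)}{point `i` is flagged only when the
#'     variation into it (`dA_{i-1}`) and the variation out of it
#'     (`dA_i`) both leave their fences. This pins exactly the isolated
#'     single-frame spikes the filter targets: the spike is replaced by
#'     the mean of its two clean neighbours in one pass, and no clean
#'     neighbour is dragged in.}
#'   \item{`"outgoing"`}{flagged when `dA_i = A_{i+1} - A_i` (one
#'     variation per point) violates the fence of the cluster containing
#'     `A_i`. A spike then also condemns its predecessor, whose
#'     replacement is computed from the still-spiked value, so a
#'     decaying copy of the spike walks backwards over subsequent
#'     passes before dying out.}
#'   \item{`"either"`}{flagged when the incoming or the outgoing
#'     variation violates its fence; spikes smear into both neighbours
#'     and tight fences can make the passes oscillate.}
#' }
#' Each variation is assessed against the fence of the size cluster of
#' the point it starts from.
#'
#' @param traj A [size_trajectory()].
#' @param thr A [fit_thresholds()] / [cluster_thresholds()] object.
#' @param max_iter Maximum replacement passes. Default 10.
#' @param flag_rule `"both"`, `"outgoing"` or `"either"`.
#' @return The trajectory with outliers replaced, `adjusted` flags marking
#'   every point that was replaced at least once, and attribute
#'   `"iterations"` giving the number of passes that replaced something.
#' @export
adjust_trajectory <- function(traj, thr, max_iter = 10L,
                              flag_rule = c("both", "outgoing", "either")) {
  stopifnot(inherits(traj, "size_trajectory"),
            inherits(thr, "cluster_thresholds"), max_iter >= 1L)
  flag_rule <- match.arg(flag_rule)
  a <- traj$areas
  n <- length(a)
  flags <- traj$adjusted
  iters <- 0L
  if (n >= 3L) {
    for (it in seq_len(max_iter)) {
      dA <- diff(a)
      v <- .violates(thr, a[-n], dA)  # v[i]: variation out of point i
      idx <- 2:(n - 1L)
      hit <- switch(flag_rule,
        outgoing = v[idx],
        either   = v[idx] | v[idx - 1L],
        both     = v[idx] & v[idx - 1L])
      if (!any(hit)) break
      i <- idx[hit]
      a[i] <- (a[i - 1L] + a[i + 1L]) / 2
      flags[i] <- TRUE
      iters <- it
    }
  }
  traj$areas <- a
  traj$adjusted <- flags
  attr(traj, "iterations") <- iters
  traj
}

#' Moving-average smoothing of a size trajectory
#'
#' Centered moving average with a window that shrinks symmetrically at the
#' edges. The default window follows the trajectory's condition: 3 points
#' for unperturbed conditions, 8 for SAC conditions (whose longer, noisier
#' cycles need heavier smoothing).
#'
#' @param traj A [size_trajectory()].
#' @param window Window size in points (`>= 1`, `<= N`); `NULL` picks the
#'   condition default.
#' @return The smoothed trajectory.
#' @export
smooth_trajectory <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "size_trajectory"))
  if (is.null(window)) {
    window <- if (traj$condition %in% c("sac", "gen0_sac")) 8L else 3L
  }
  n <- length(traj$areas)
  if (window < 1L || window > n) {
    stop("'window' must be between 1 and the trajectory length")
  }
  hl <- (window - 1L) %/% 2L   # even windows take one extra trailing point
  hr <- window %/% 2L
  a <- traj$areas
  traj$areas <- vapply(seq_len(n), function(i) {
    if (i - hl >= 1L && i + hr <= n) {
      mean(a[(i - hl):(i + hr)])
    } else {
      # shrink to the widest symmetric window that fits
      h <- min(i - 1L, n - i)
      mean(a[(i - h):(i + h)])
    }
  }, numeric(1))
  traj
}

#' Local growth rate by central finite differences
#'
#' First derivative of a (smoothed) size trajectory: interior points use
#' the centered difference `(A_{i+1} - A_{i-1}) / (t_{i+1} - t_{i-1})`,
#' endpoints one-sided differences. Each rate is paired with the local
#' area for downstream size-binning.
#'
#' @param traj A [size_trajectory()] with at least 3 points.
#' @return A data frame `time_min`, `area_um2`, `growth_rate` (um^2/min).
#' @export
local_growth_rate <- function(traj) {
  stopifnot(inherits(traj, "size_trajectory"))
  t <- traj$times; a <- traj$areas; n <- length(a)
  if (n < 3L) stop("at least three points are needed for central differences")
  gaps <- diff(t)
  if (diff(range(gaps)) > 1e-8 * mean(gaps)) {
    warning("non-uniform time spacing; differences use the actual time gaps",
            call. = FALSE)
  }
  rate <- numeric(n)
  rate[1L] <- (a[2L] - a[1L]) / (t[2L] - t[1L])
  rate[n] <- (a[n] - a[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2:(n - 1L)
  rate[i] <- (a[i + 1L] - a[i - 1L]) / (t[i + 1L] - t[i - 1L])
  data.frame(time_min = t, area_um2 = a, growth_rate = rate)
}

#' Bin one variable by another and average within bins
#'
#' Half-open bins `[k w, (k+1) w)` on `x`; per non-empty bin the mean of
#' `x`, the mean of `y` and the count. Used with 10-um^2 size bins for
#' growth-rate-versus-size curves and with 70/100 a.u. bins for
#' cyclin-level abscissas.
#'
#' @param x,y Equal-length numeric vectors.
#' @param bin_width Positive bin width in units of `x`.
#' @return A data frame `bin_lo`, `bin_hi`, `x_mean`, `y_mean`, `n`,
#'   ordered by bin.
#' @export
bin_means <- function(x, y, bin_width) {
  stopifnot(length(x) == length(y), bin_width > 0)
  if (length(x) == 0L) stop("empty input")
  k <- floor(x / bin_width)
  ks <- sort(unique(k))
  data.frame(bin_lo = ks * bin_width, bin_hi = (ks + 1) * bin_width,
             x_mean = as.numeric(tapply(x, factor(k, levels = ks), mean)),
             y_mean = as.numeric(tapply(y, factor(k, levels = ks), mean)),
             n = as.integer(tapply(x, factor(k, levels = ks), length)),
             row.names = NULL)
}

#' Mean trajectory of a cell population
#'
#' Trajectories are aligned on their own first timepoint (budding or G1
#' release, depending on condition); the population mean is reported only
#' at timepoints supported by strictly more than `min_support`
#' trajectories.
#'
#' @param trajs List of [size_trajectory()]s sharing a sampling interval.
#' @param min_support Support threshold; a timepoint is kept when more
#'   than this many trajectories contribute. Default 5.
#' @return A data frame `time_min`, `mean_area_um2`, `n` (possibly empty).
#' @export
mean_trajectory <- function(trajs, min_support = 5L) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  rel <- lapply(trajs, function(tr) {
    data.frame(time_min = tr$times - tr$times[1L], area = tr$areas)
  })
  all_t <- sort(unique(unlist(lapply(rel, `[[`, "time_min"))))
  rows <- lapply(all_t, function(tt) {
    v <- unlist(lapply(rel, function(d) d$area[abs(d$time_min - tt) < 1e-9]))
    if (length(v) > min_support) {
      data.frame(time_min = tt, mean_area_um2 = mean(v), n = length(v))
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time_min = numeric(0), mean_area_um2 = numeric(0),
                      n = integer(0))
  }
  out
}

#' Convert a segmented pixel count to an area
#'
#' Uses the imaging calibration 1 pixel ~ 0.05 um^2.
#'
#' @param pixels Non-negative pixel count(s).
#' @return Area(s) in um^2.
#' @examples
#' pixels_to_area(400)  # 20 um^2
#' @export
pixels_to_area <- function(pixels) {
  stopifnot(is.numeric(pixels))
  if (any(pixels < 0)) stop("pixel counts must be non-negative")
  0.05 * pixels
}
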
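#' Growth-curve parameters
#'
#' Bundles the constants of the combined exponential-to-linear single-cell
#' growth curve together with the reference unperturbed cycle length. The
#' exponential rate `r` is, by default, calibrated with
#' [compute_growth_rate()] so that an unperturbed cell exactly doubles in
#' size over `T_unperturbed` minutes when `m = 0`.
#'
#' @param A0 Cell area at `t = 0`, in um^2. Default 20.
#' @param Amax Transition scale between exponential and linear growth, in
#'   um^2. Must exceed `2 * A0`. Default 120.
#' @param T_unperturbed Reference unperturbed cycle length in minutes,
#'   used to calibrate `r`. Default 100.
#' @param m Asymptotic linear slope in um^2/min. Not constrained by the
#'   published parameter set; the default 0.3 places the SAC-active steady
#'   entry size a few-fold above `A0`. Set `m = 0` for a purely logistic
#'   (saturating) curve.
#' @param r Exponential growth rate in 1/min. If `NULL` (default) it is
#'   computed from `A0`, `Amax` and `T_unperturbed`.
#'
#' @return An object of class `"growth_params"`: a list with elements
#'   `A0`, `Amax`, `r`, `m`, `T_unperturbed`.
#' @seealso [growth_curve()], [compute_growth_rate()], [simulate_lineage()]
#' @examples
#' p <- growth_params()
#' growth_curve(p, c(0, 100))
#' @export
growth_params <- function(A0 = 20, Amax = 120, T_unperturbed = 100,
                          m = 0.3, r = NULL) {
  stopifnot(is.numeric(A0), length(A0) == 1L, A0 > 0,
            is.numeric(Amax), length(Amax) == 1L,
            is.numeric(m), length(m) == 1L, m >= 0,
            is.numeric(T_unperturbed), length(T_unperturbed) == 1L,
            T_unperturbed > 0)
  if (Amax <= 2 * A0) {
    stop("'Amax' must exceed 2 * A0; the doubling calibration is undefined otherwise")
  }
  if (is.null(r)) {
    r <- compute_growth_rate(A0, Amax, T_unperturbed)
  }
  stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  structure(list(A0 = A0, Amax = Amax, r = r, m = m,
                 T_unperturbed = T_unperturbed),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth-curve parameters:\n")
  cat(sprintf("  A0   = %g um^2   Amax = %g um^2\n", x$A0, x$Amax))
  cat(sprintf("  r    = %.6f /min   m = %g um^2/min\n", x$r, x$m))
  cat(sprintf("  T_unperturbed = %g min\n", x$T_unperturbed))
  invisible(x)
}

#' Calibrate the exponential growth rate from the doubling condition
#'
#' Solves `A(T) = 2 * A0` for the logistic part of the growth curve
#' (`m = 0`), giving the closed form
#' `r = (log(2 * (Amax - A0)) - log(Amax - 2 * A0)) / T`.
#'
#' @param A0 Area at time zero (um^2).
#' @param Amax Exponential-to-linear transition scale (um^2); must exceed
#'   `2 * A0`.
#' @param T Doubling time in minutes.
#' @return The growth rate `r` in 1/min.
#' @examples
#' compute_growth_rate(20, 120, 100)  # ~0.0092 /min
#' @export
compute_growth_rate <- function(A0, Amax, T) {
  stopifnot(is.numeric(A0), A0 > 0, is.numeric(T), T > 0)
  if (Amax <= 2 * A0) {
    stop("'Amax' must exceed 2 * A0 for the doubling calibration")
  }
  (log(2 * (Amax - A0)) - log(Amax - 2 * A0)) / T
}

#' Evaluate the combined exponential-to-linear growth curve
#'
#' Cell area as a function of time on the curve: a logistic term
#' `A0 * Amax * exp(r t) / (Amax + A0 * (exp(r t) - 1))`, which is
#' exponential for small `t` and saturates at `Amax`, multiplied by the
#' linear factor `1 + (m / Amax) * t`, so that for large `t` the curve
#' approaches a straight line of slope `m`.
#'
#' @param params A [growth_params()] object.
#' @param t Time(s) on the curve, in minutes; must be non-negative.
#' @return Area(s) in um^2, same length as `t`.
#' @examples
#' p <- growth_params(m = 0)
#' growth_curve(p, 100)  # 2 * A0 by calibration
#' @export
growth_curve <- function(params, t) {
  stopifnot(inherits(params, "growth_params"), is.numeric(t))
  if (any(t < 0)) stop("negative times are outside the growth curve's domain")
  et <- exp(params$r * t)
  logistic <- params$A0 * params$Amax * et /
    (params$Amax + params$A0 * (et - 1))
  logistic * (1 + params$m / params$Amax * t)
}

#' Invert the growth curve: time at which a given size is reached
#'
#' The curve is strictly increasing, so the inverse is found by a bracketed
#' root search (analytically for `m = 0`). For `m = 0` only sizes in
#' `[A0, Amax)` are attainable; for `m > 0` any size `>= A0` is.
#'
#' @param params A [growth_params()] object.
#' @param A Target area(s) in um^2.
#' @param tol Relative tolerance on the recovered area. Default `1e-9`.
#' @return Time(s) in minutes such that `growth_curve(params, t) == A`
#'   within `tol * A`.
#' @examples
#' p <- growth_params(m = 0)
#' time_at_size(p, 40)  # 100 min
#' @export
time_at_size <- function(params, A, tol = 1e-9) {
  stopifnot(inherits(params, "growth_params"), is.numeric(A))
  vapply(A, function(a) .time_at_size1(params, a, tol), numeric(1))
}

.time_at_size1 <- function(params, A, tol = 1e-9) {
  A0 <- params$A0; Amax <- params$Amax; r <- params$r; m <- params$m
  if (A < A0 * (1 - 1e-12)) {
    stop(sprintf("size %.4g um^2 is below the curve origin A0 = %g um^2", A, A0))
  }
  if (A <= A0) return(0)
  if (m == 0) {
    if (A >= Amax) {
      stop(sprintf("size %.4g um^2 is unreachable: the m = 0 curve saturates at Amax = %g um^2",
                   A, Amax))
    }
    # closed-form inverse of the logistic part
    return(log(A * (Amax - A0) / (A0 * (Amax - A))) / r)
  }
  hi <- params$T_unperturbed
  while (growth_curve(params, hi) < A) hi <- hi * 2
  stats::uniroot(function(t) growth_curve(params, t) - A,
                 lower = 0, upper = hi,
                 tol = min(tol * A / max(m, r * A0), 1e-8))$root
}

#' Cycle-length distribution for a proliferation regime
#'
#' Unperturbed cycles are Normal (mean 100 min, SD 10 min by default);
#' SAC-active cycles are a fixed delay plus an Exponential tail (delay
#' 200 min, exponential mean 200 min by default), reflecting the memoryless
#' waiting time to mitotic slippage after a deterministic arrest.
#'
#' @param regime `"unperturbed"` or `"sac_active"`.
#' @param mean Mean of the Normal (unperturbed) or of the Exponential tail
#'   (SAC-active), in minutes.
#' @param sd Standard deviation in minutes (unperturbed regime only).
#' @param delay Fixed delay in minutes (SAC-active regime only).
#' @return An object of class `"cycle_time_model"`.
#' @examples
#' cycle_time_model("unperturbed")
#' cycle_time_model("sac_active")
#' @export
cycle_time_model <- function(regime = c("unperturbed", "sac_active"),
                             mean = NULL, sd = NULL, delay = NULL) {
  regime <- match.arg(regime)
  if (regime == "unperturbed") {
    if (is.null(mean)) mean <- 100
    if (is.null(sd)) sd <- 10
    stopifnot(mean > 0, sd > 0)
    out <- list(regime = regime, mean = mean, sd = sd)
  } else {
    if (is.null(mean)) mean <- 200
    if (is.null(delay)) delay <- 200
    stopifnot(mean > 0, delay > 0)
    out <- list(regime = regime, mean = mean, delay = delay)
  }
  structure(out, class = "cycle_time_model")
}

#' Draw cycle lengths from a regime's distribution
#'
#' Unperturbed draws are Normal; the astronomically rare negative draw is
#' rejected and redrawn so the stated mean and SD are preserved.
#' SAC-active draws are `delay + Exponential(mean)`. Randomness comes from
#' R's global RNG; call [set.seed()] for reproducibility.
#'
#' @param model A [cycle_time_model()] object.
#' @param n Number of draws.
#' @return A numeric vector of `n` strictly positive durations (minutes).
#' @examples
#' set.seed(1)
#' mean(draw_cycle_length(cycle_time_model("sac_active"), 1e4))  # ~400
#' @export
draw_cycle_length <- function(model, n = 1) {
  stopifnot(inherits(model, "cycle_time_model"), n >= 1)
  if (model$regime == "unperturbed") {
    d <- stats::rnorm(n, model$mean, model$sd)
    while (any(bad <- d <= 0)) {
      d[bad] <- stats::rnorm(sum(bad), model$mean, model$sd)
    }
    d
  } else {
    model$delay + stats::rexp(n, rate = 1 / model$mean)
  }
}

#' Divide a cell and reposition it on the growth curve
#'
#' Division instantaneously halves the cell area; the daughter then "jumps"
#' back to the point of the growth curve corresponding to its new size and
#' resumes growth from there. If the halved size falls below `A0` the
#' restart time is clamped to 0 (restart at `A0`) with a warning; this
#' cannot occur at the default parameters once a lineage has equilibrated.
#'
#' @param params A [growth_params()] object.
#' @param pre_area Area just before division (um^2).
#' @return A list with `post_area` (= `pre_area / 2`) and `restart_time`,
#'   the curve time from which growth resumes.
#' @examples
#' p <- growth_params(m = 0)
#' divide(p, 80)  # post_area 40, restart_time 100
#' @export
divide <- function(params, pre_area) {
  stopifnot(inherits(params, "growth_params"),
            is.numeric(pre_area), length(pre_area) == 1L, pre_area > 0)
  post <- pre_area / 2
  if (post < params$A0) {
    warning(sprintf(
      "post-division size %.3g um^2 below curve origin A0 = %g um^2; restarting at A0",
      post, params$A0), call. = FALSE)
    return(list(post_area = post, restart_time = 0))
  }
  list(post_area = post, restart_time = time_at_size(params, post))
}

# One cycle: grow from curve position tau for d minutes, divide, return the
# new curve position. law = "exponential" replaces the combined curve by
# pure A0 * exp(r t) growth (used for the homeostasis contrast); that law
# never clamps because it is unbounded above and below-A0 sizes keep a
# well-defined (negative) curve time, handled by direct log inversion.
.advance_cycle <- function(params, tau, d, law = "combined") {
  if (law == "exponential") {
    pre <- params$A0 * exp(params$r * (tau + d))
    post <- pre / 2
    return(list(pre = pre, post = post,
                tau = log(post / params$A0) / params$r, clamped = FALSE))
  }
  pre <- growth_curve(params, tau + d)
  post <- pre / 2
  if (post < params$A0) {
    list(pre = pre, post = post, tau = 0, clamped = TRUE)
  } else {
    list(pre = pre, post = post, tau = .time_at_size1(params, post),
         clamped = FALSE)
  }
}

# Regime in force at absolute time t under a switch schedule.
.regime_at <- function(schedule, t) {
  i <- findInterval(t, schedule$switch_time)
  if (i < 1L) schedule$regime[1L] else schedule$regime[i]
}

#' Build a regime switch schedule
#'
#' @param switch_time Non-decreasing vector of absolute switch times
#'   (minutes); the first entry is conventionally `-Inf` or `0` and defines
#'   the initial regime.
#' @param regime Character vector of regime labels
#'   (`"unperturbed"`/`"sac_active"`), same length as `switch_time`.
#' @return A data frame usable as the `schedule` of [simulate_lineage()].
#' @export
regime_schedule <- function(switch_time, regime) {
  stopifnot(length(switch_time) == length(regime),
            !is.unsorted(switch_time),
            all(regime %in% c("unperturbed", "sac_active")))
  data.frame(switch_time = switch_time, regime = regime,
             stringsAsFactors = FALSE)
}

#' Simulate a single growing-and-dividing lineage
#'
#' Between divisions the cell follows the growth curve from its current
#' curve position; at each division the area halves and the daughter jumps
#' back along the same curve. The length of each cycle is drawn, at the
#' moment the cycle starts, from the distribution of the regime in force at
#' that instant, so a regime switch applies from the next drawn duration
#' onwards.
#'
#' @param params A [growth_params()] object.
#' @param schedule A [regime_schedule()] (or data frame with columns
#'   `switch_time`, `regime`).
#' @param models Named list of [cycle_time_model()]s, one per regime
#'   appearing in the schedule. Defaults to the standard unperturbed and
#'   SAC-active models.
#' @param n_cycles Number of cycles to simulate.
#' @param dt Sampling interval of the recorded trace, minutes. Default 10,
#'   matching a typical time-lapse imaging interval.
#' @param start_area Area at time zero; default `A0`.
#' @param cycle_lengths Optional vector of fixed cycle lengths (minutes)
#'   overriding the stochastic draws, for deterministic checks.
#' @return An object of class `"lineage_trace"`: a list with
#'   \describe{
#'     \item{trace}{data frame `time_min`, `area_um2`, `regime`,
#'       `generation` sampled at multiples of `dt`;}
#'     \item{divisions}{data frame `time_min`, `pre_area_um2`,
#'       `post_area_um2`, `cycle_length_min`, `regime`, `generation`;}
#'     \item{n_clamped}{number of divisions whose restart was clamped at
#'       `A0`.}
#'   }
#' @examples
#' set.seed(1)
#' tr <- simulate_lineage(growth_params(),
#'                        regime_schedule(-Inf, "unperturbed"), n_cycles = 5)
#' head(tr$divisions)
#' @export
simulate_lineage <- function(params, schedule,
                             models = list(
                               unperturbed = cycle_time_model("unperturbed"),
                               sac_active = cycle_time_model("sac_active")),
                             n_cycles = 20, dt = 10,
                             start_area = params$A0,
                             cycle_lengths = NULL) {
  stopifnot(inherits(params, "growth_params"), n_cycles >= 1, dt > 0,
            start_area >= params$A0)
  if (!is.null(cycle_lengths)) stopifnot(length(cycle_lengths) == n_cycles)

  tau <- .time_at_size1(params, start_area)
  t_abs <- 0
  n_clamped <- 0L
  grid_t <- numeric(0); grid_a <- numeric(0)
  grid_reg <- character(0); grid_gen <- integer(0)
  div <- vector("list", n_cycles)

  for (k in seq_len(n_cycles)) {
    reg <- .regime_at(schedule, t_abs)
    d <- if (is.null(cycle_lengths)) {
      draw_cycle_length(models[[reg]], 1)
    } else cycle_lengths[k]
    # record the trace on the global dt grid within [t_abs, t_abs + d)
    tg <- seq(ceiling(t_abs / dt) * dt, t_abs + d, by = dt)
    tg <- tg[tg < t_abs + d - 1e-9 | abs(tg - (t_abs + d)) < 1e-9]
    if (length(tg)) {
      grid_t <- c(grid_t, tg)
      grid_a <- c(grid_a, growth_curve(params, tau + (tg - t_abs)))
      grid_reg <- c(grid_reg, rep(reg, length(tg)))
      grid_gen <- c(grid_gen, rep(k - 1L, length(tg)))
    }
    adv <- .advance_cycle(params, tau, d)
    if (adv$clamped) n_clamped <- n_clamped + 1L
    div[[k]] <- data.frame(time_min = t_abs + d, pre_area_um2 = adv$pre,
                           post_area_um2 = adv$post, cycle_length_min = d,
                           regime = reg, generation = k - 1L,
                           stringsAsFactors = FALSE)
    tau <- adv$tau
    t_abs <- t_abs + d
  }
  if (n_clamped > 0L) {
    warning(sprintf("%d division(s) restarted at A0 (post-division size below curve origin)",
                    n_clamped), call. = FALSE)
  }
  structure(list(
    trace = data.frame(time_min = grid_t, area_um2 = grid_a,
                       regime = grid_reg, generation = grid_gen,
                       stringsAsFactors = FALSE),
    divisions = do.call(rbind, div),
    n_clamped = n_clamped), class = "lineage_trace")
}

#' @export
print.lineage_trace <- function(x, ...) {
  cat(sprintf("Lineage trace: %d cycles, %d trace points, %d clamped restart(s)\n",
              nrow(x$divisions), nrow(x$trace), x$n_clamped))
  invisible(x)
}

#' Entry sizes of independent lineages over successive cycles
#'
#' Runs `n_cells` independent single-cell lineages for `n_cycles` cycles
#' under one regime and records the size right after each division (the
#' "entry size" of the next cycle). `law = "exponential"` replaces the
#' combined curve by unbounded exponential growth `A0 * exp(r t)` with the
#' same rate, the comparison under which entry-size variance grows without
#' bound instead of stabilizing.
#'
#' @param params A [growth_params()] object.
#' @param model A [cycle_time_model()].
#' @param n_cells Number of independent lineages.
#' @param n_cycles Number of cycles per lineage.
#' @param law `"combined"` (default) or `"exponential"`.
#' @param start_area Starting area of every lineage; default `A0`.
#' @return A `n_cells x n_cycles` matrix of post-division sizes (um^2);
#'   column `k` is the entry-size distribution after the k-th division.
#' @examples
#' set.seed(1)
#' es <- simulate_entry_sizes(growth_params(),
#'                            cycle_time_model("sac_active"),
#'                            n_cells = 50, n_cycles = 10)
#' apply(es, 2, stats::median)
#' @export
simulate_entry_sizes <- function(params, model, n_cells, n_cycles,
                                 law = c("combined", "exponential"),
                                 start_area = params$A0) {
  law <- match.arg(law)
  stopifnot(n_cells >= 1, n_cycles >= 1)
  out <- matrix(NA_real_, n_cells, n_cycles)
  for (i in seq_len(n_cells)) {
    tau <- if (law == "exponential") {
      log(start_area / params$A0) / params$r
    } else .time_at_size1(params, start_area)
    d <- draw_cycle_length(model, n_cycles)
    for (k in seq_len(n_cycles)) {
      adv <- .advance_cycle(params, tau, d[k], law = law)
      out[i, k] <- adv$post
      tau <- adv$tau
    }
  }
  out
}

#' In-silico checkpoint-withdrawal experiment
#'
#' Lineages first proliferate under chronic SAC activation until their
#' entry-size distribution is stationary; at time zero the cycle-length
#' distribution switches back to the unperturbed one, and the size at entry
#' (right after division) is recorded for each of the first
#' `n_cycles_after` recovery cycles. Large SAC-adapted cells shrink back
#' toward the unperturbed steady size over a few divisions.
#'
#' @param params A [growth_params()] object.
#' @param n_cells Number of independent lineages (200 matches the scale of
#'   the published simulation).
#' @param n_cycles_before SAC-active burn-in cycles before withdrawal.
#' @param n_cycles_after Recovery cycles recorded after withdrawal. If 0,
#'   only the SAC-active steady entry sizes are returned.
#' @param models Named list with `unperturbed` and `sac_active`
#'   [cycle_time_model()]s.
#' @return A list with `entry_sizes` (`n_cells x n_cycles_after` matrix of
#'   post-division sizes after withdrawal, or `NULL` when
#'   `n_cycles_after = 0`) and `sac_steady` (entry sizes at the last
#'   pre-withdrawal division).
#' @examples
#' set.seed(1)
#' w <- simulate_withdrawal(growth_params(), n_cells = 50,
#'                          n_cycles_before = 8, n_cycles_after = 5)
#' apply(w$entry_sizes, 2, stats::median)
#' @export
simulate_withdrawal <- function(params, n_cells = 200,
                                n_cycles_before = 15, n_cycles_after = 5,
                                models = list(
                                  unperturbed = cycle_time_model("unperturbed"),
                                  sac_active = cycle_time_model("sac_active"))) {
  stopifnot(n_cells >= 1, n_cycles_before >= 1, n_cycles_after >= 0)
  sac_steady <- numeric(n_cells)
  entry <- if (n_cycles_after > 0) {
    matrix(NA_real_, n_cells, n_cycles_after)
  } else NULL
  for (i in seq_len(n_cells)) {
    tau <- 0
    d <- draw_cycle_length(models$sac_active, n_cycles_before)
    for (k in seq_len(n_cycles_before)) {
      adv <- .advance_cycle(params, tau, d[k])
      tau <- adv$tau
    }
    sac_steady[i] <- adv$post
    if (n_cycles_after > 0) {
      du <- draw_cycle_length(models$unperturbed, n_cycles_after)
      for (k in seq_len(n_cycles_after)) {
        adv <- .advance_cycle(params, tau, du[k])
        entry[i, k] <- adv$post
        tau <- adv$tau
      }
    }
  }
  list(entry_sizes = entry, sac_steady = sac_steady)
}
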
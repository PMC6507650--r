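#' Measurement-corruption model for synthetic trajectories
#'
#' Emulates the two failure modes of segmented time-lapse areas:
#' small multiplicative measurement noise on every point, and occasional
#' isolated segmentation spikes (a grossly wrong area at a single frame).
#'
#' @param spike_probability Per-interior-point probability of a spike.
#'   Default 0.02.
#' @param spike_amplitude Range (um^2) from which a spike's absolute
#'   amplitude is drawn uniformly; the sign is random. Default
#'   `c(30, 80)`: a failed segmentation (merged neighbour, half-lost
#'   cell) is wrong by the order of the cell's own area.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   Gaussian noise. Default 0.01.
#' @param censor_prob Per-cycle censoring probability used by the
#'   cycle-record generator. Default 0.
#' @return An object of class `"corruption_model"`.
#' @export
corruption_model <- function(spike_probability = 0.02,
                             spike_amplitude = c(30, 80),
                             noise_cv = 0.01, censor_prob = 0) {
  stopifnot(spike_probability >= 0, spike_probability <= 1,
            length(spike_amplitude) == 2L,
            all(is.finite(spike_amplitude)),
            spike_amplitude[1L] <= spike_amplitude[2L],
            noise_cv >= 0, censor_prob >= 0, censor_prob <= 1)
  structure(list(spike_probability = spike_probability,
                 spike_amplitude = spike_amplitude,
                 noise_cv = noise_cv, censor_prob = censor_prob),
            class = "corruption_model")
}

#' Generate clean and corrupted single-cycle size trajectories
#'
#' Each cell starts at a random position on the growth curve (entry size
#' uniform between `A0` and `2 A0` plus the regime's typical extent), its
#' cycle length is drawn from `model`, and its area is sampled every `dt`
#' minutes along the curve. The corrupted copy multiplies every point by
#' `1 + Normal(0, noise_cv)` noise and adds isolated spikes at interior
#' points with the model's probability; the truth record lists every
#' spiked point.
#'
#' @param params A [growth_params()] object.
#' @param model A [cycle_time_model()] (sets the condition label: SAC
#'   models produce `"sac"` trajectories).
#' @param corruption A [corruption_model()].
#' @param n_cells Number of cells.
#' @param dt Sampling interval, minutes. Default 10.
#' @return A list with `clean` and `corrupted` (lists of
#'   [size_trajectory()]s) and `truth` (data frame `cell_id`, `index`,
#'   `spike` amplitude actually added).
#' @export
generate_trajectories <- function(params, model, corruption,
                                  n_cells = 50L, dt = 10) {
  stopifnot(inherits(params, "growth_params"),
            inherits(model, "cycle_time_model"),
            inherits(corruption, "corruption_model"), n_cells >= 1L)
  condition <- if (model$regime == "sac_active") "sac" else "unperturbed"
  clean <- vector("list", n_cells)
  corrupted <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    id <- sprintf("cell_%03d", i)
    start <- stats::runif(1L, params$A0, 2 * params$A0)
    tau0 <- time_at_size(params, start)
    d <- draw_cycle_length(model, 1L)
    tt <- seq(0, d, by = dt)
    a <- growth_curve(params, tau0 + tt)
    clean[[i]] <- size_trajectory(tt, a, cell_id = id, condition = condition)
    noisy <- a * (1 + stats::rnorm(length(a), 0, corruption$noise_cv))
    spike <- numeric(length(a))
    if (corruption$spike_probability > 0 && length(a) > 2L) {
      interior <- 2:(length(a) - 1L)
      hit <- interior[stats::runif(length(interior)) <
                        corruption$spike_probability]
      # keep spikes isolated: drop hits adjacent to an earlier hit
      if (length(hit) > 1L) hit <- hit[c(TRUE, diff(hit) > 1L)]
      if (length(hit)) {
        amp <- stats::runif(length(hit), corruption$spike_amplitude[1L],
                            corruption$spike_amplitude[2L]) *
          sample(c(-1, 1), length(hit), replace = TRUE)
        # areas must stay positive
        amp <- ifelse(noisy[hit] + amp <= 0.5, abs(amp), amp)
        spike[hit] <- amp
        noisy[hit] <- noisy[hit] + amp
      }
    }
    corrupted[[i]] <- size_trajectory(tt, noisy, cell_id = id,
                                      condition = condition)
    truth[[i]] <- data.frame(cell_id = id, index = seq_along(a),
                             spike = spike)
  }
  list(clean = clean, corrupted = corrupted, truth = do.call(rbind, truth))
}

#' Generate cell-cycle record tables with known ground truth
#'
#' For each cell and regime, cycles are laid down back-to-back on the
#' growth curve: the cycle length is drawn from the regime's model, the
#' mitotic length is a fixed fraction of it (the generator's knob, not a
#' measured quantity), anaphase onset sits just before the next budding,
#' and the landmark sizes are read off the curve. Censoring cuts a cycle
#' at a uniform time before its end: later landmarks are lost and
#' `t_nextbud` then holds the censoring time.
#'
#' @param params A [growth_params()] object.
#' @param models Named list of [cycle_time_model()]s keyed by regime.
#' @param n_cells Cells per regime.
#' @param n_cycles Cycles per cell. Default 1.
#' @param censor_prob Per-cycle censoring probability. Default 0.
#' @param mitotic_frac Named fractions of the cycle spent in mitosis per
#'   regime. Default `c(unperturbed = 0.3, sac_active = 0.5)`: SAC-active
#'   cycles are dominated by the mitotic arrest.
#' @param ana_gap_frac Fraction of the cycle between anaphase onset and
#'   the next budding. Default 0.05.
#' @return A data frame with one row per cycle: `cell_id`, `regime`,
#'   `cycle`, `t_bud`, `t_mito`, `t_ana`, `t_nextbud`, `censored`,
#'   `A_alpha`, `A_bud`, `A_pm`, `A_ana` (times in minutes, areas in
#'   um^2), plus attribute `"mitotic_frac"` echoing the ground truth.
#' @export
generate_cycle_records <- function(params,
                                   models = list(
                                     unperturbed = cycle_time_model("unperturbed"),
                                     sac_active = cycle_time_model("sac_active")),
                                   n_cells = 50L, n_cycles = 1L,
                                   censor_prob = 0,
                                   mitotic_frac = c(unperturbed = 0.3,
                                                    sac_active = 0.5),
                                   ana_gap_frac = 0.05) {
  stopifnot(inherits(params, "growth_params"), n_cells >= 1L, n_cycles >= 1L,
            censor_prob >= 0, censor_prob <= 1,
            all(mitotic_frac > 0),
            all(mitotic_frac + ana_gap_frac < 1))
  rows <- list()
  for (reg in names(models)) {
    frac <- mitotic_frac[[reg]]
    for (i in seq_len(n_cells)) {
      id <- sprintf("%s_cell_%03d", reg, i)
      tau <- time_at_size(params, stats::runif(1L, params$A0, 2 * params$A0))
      t_abs <- 0
      for (k in seq_len(n_cycles)) {
        L <- draw_cycle_length(models[[reg]], 1L)
        t_bud <- t_abs
        t_nextbud <- t_abs + L
        t_ana <- t_nextbud - ana_gap_frac * L
        t_mito <- t_ana - frac * L
        sizes <- growth_curve(params, tau + c(0, t_mito - t_bud,
                                              t_ana - t_bud))
        censored <- stats::runif(1L) < censor_prob
        if (censored) {
          t_cens <- t_bud + stats::runif(1L) * L
          row <- data.frame(
            cell_id = id, regime = reg, cycle = k, t_bud = t_bud,
            t_mito = if (t_mito <= t_cens) t_mito else NA_real_,
            t_ana = if (t_ana <= t_cens) t_ana else NA_real_,
            t_nextbud = t_cens, censored = TRUE,
            A_alpha = sizes[1L], A_bud = sizes[1L],
            A_pm = if (t_mito <= t_cens) sizes[2L] else NA_real_,
            A_ana = if (t_ana <= t_cens) sizes[3L] else NA_real_,
            stringsAsFactors = FALSE)
        } else {
          row <- data.frame(
            cell_id = id, regime = reg, cycle = k, t_bud = t_bud,
            t_mito = t_mito, t_ana = t_ana, t_nextbud = t_nextbud,
            censored = FALSE,
            A_alpha = sizes[1L], A_bud = sizes[1L],
            A_pm = sizes[2L], A_ana = sizes[3L],
            stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- row
        adv <- .advance_cycle(params, tau, L)
        tau <- adv$tau
        t_abs <- t_abs + L
        if (censored) break  # a censored cell is not followed further
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mitotic_frac") <- mitotic_frac
  out
}

#' Write trajectories as a tidy delimited table
#'
#' @param trajs List of [size_trajectory()]s.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(trajs, path) {
  tab <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(cell_id = tr$cell_id, condition = tr$condition,
               frame = seq_along(tr$times), time_min = tr$times,
               area_um2 = tr$areas, adjusted = tr$adjusted,
               censored = tr$censored, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory table back into trajectory objects
#'
#' @param path Tab-separated file written by [write_trajectory_table()]
#'   (or any table with columns `cell_id`, `condition`, `time_min` and
#'   either `area_um2` or `area_px`).
#' @return A list of [size_trajectory()]s.
#' @export
read_trajectory_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "condition", "time_min") %in% names(tab)))
  if (!"area_um2" %in% names(tab)) {
    stopifnot("area_px" %in% names(tab))
    tab$area_um2 <- pixels_to_area(tab$area_px)
  }
  lapply(split(tab, tab$cell_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    size_trajectory(d$time_min, d$area_um2, cell_id = d$cell_id[1L],
                    condition = d$condition[1L],
                    censored = isTRUE(as.logical(d$censored[1L])))
  })
}
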
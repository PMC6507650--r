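# Shared fixtures: default parameter sets and small simulation helpers.

default_params <- function(...) growth_params(...)

logistic_params <- function() growth_params(m = 0)

unp_model <- function() cycle_time_model("unperturbed")
sac_model <- function() cycle_time_model("sac_active")

# RMSE between two equal-length area vectors
rmse <- function(a, b) sqrt(mean((a - b)^2))

# run the standard corrupted-trajectory recovery experiment once
run_recovery <- function(seed = 42, n_cells = 50) {
  set.seed(seed)
  p <- default_params()
  gen <- generate_trajectories(p, sac_model(), corruption_model(),
                               n_cells = n_cells)
  top <- max(vapply(gen$corrupted, function(x) max(x$areas), numeric(1)))
  thr <- fit_thresholds(gen$corrupted, edges = seq(0, 40 * ceiling(top / 40), 40))
  adj <- lapply(gen$corrupted, adjust_trajectory, thr = thr)
  list(gen = gen, thr = thr, adj = adj,
       rmse_corrupted = mapply(function(a, b) rmse(a$areas, b$areas),
                               gen$clean, gen$corrupted),
       rmse_adjusted = mapply(function(a, b) rmse(a$areas, b$areas),
                              gen$clean, adj),
       flags = unlist(lapply(adj, function(x) x$adjusted)),
       spikes = gen$truth$spike != 0)
}
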
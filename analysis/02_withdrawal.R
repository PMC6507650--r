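#!/usr/bin/env Rscript
# Checkpoint-withdrawal experiment: 200 independent lineages equilibrate
# under chronic SAC activation, then at time zero the cycle-length
# distribution reverts to the unperturbed one. The size at entry (right
# after division) is tracked over the first five recovery cycles and
# compared, by density overlap, with the unperturbed steady state.

library(sacsize)
set.seed(20260922)
dir.create("results", showWarnings = FALSE)

p <- growth_params()
w <- simulate_withdrawal(p, n_cells = 200, n_cycles_before = 15,
                         n_cycles_after = 5)
steady <- simulate_entry_sizes(p, cycle_time_model("unperturbed"),
                               n_cells = 200, n_cycles = 20)[, 20]

entries <- data.frame(
  cell = rep(seq_len(nrow(w$entry_sizes)), 5),
  cycle_after_withdrawal = rep(1:5, each = nrow(w$entry_sizes)),
  entry_size_um2 = as.vector(w$entry_sizes))
write.csv(entries, "results/withdrawal_entry_sizes.csv", row.names = FALSE)

med <- apply(w$entry_sizes, 2, median)
ov <- vapply(1:5, function(k) density_overlap(w$entry_sizes[, k], steady),
             numeric(1))
prog <- data.frame(cycle_after_withdrawal = 1:5,
                   median_entry_um2 = med,
                   overlap_with_unperturbed = ov)
write.csv(prog, "results/withdrawal_convergence.csv", row.names = FALSE)

message(sprintf(
  "Entry-size medians over recovery cycles 1-5: %s um^2 (unperturbed steady median %.1f).",
  paste(sprintf("%.1f", med), collapse = ", "), median(steady)))
message(sprintf(
  "Density overlap with the unperturbed steady state rises from %.2f (cycle 1) to %.2f (cycle 5).",
  ov[1], ov[5]))
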
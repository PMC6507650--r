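test_that("growth curve evaluates the closed form and its calibration", {
  p0 <- logistic_params()
  expect_equal(growth_curve(p0, 0), 20)
  # calibration: unperturbed cells double over T_unperturbed when m = 0
  expect_equal(growth_curve(p0, 100), 40, tolerance = 1e-12)
  # with a linear slope the curve is the logistic part times (1 + m t / Amax)
  pm <- growth_params(m = 0.05)
  expect_equal(growth_curve(pm, 100), 40 * (1 + 0.05 * 100 / 120),
               tolerance = 1e-12)
  expect_error(growth_curve(p0, -1), "negative")
  # strict monotonicity on a fine grid, with and without the linear term
  for (p in list(p0, default_params())) {
    expect_true(all(diff(growth_curve(p, seq(0, 2000, by = 5))) > 0))
  }
})

test_that("growth-rate calibration matches its closed form and limits", {
  expect_equal(compute_growth_rate(20, 120, 100), log(2.5) / 100)
  expect_equal(compute_growth_rate(10, 100, 50), log(180 / 80) / 50)
  expect_equal(compute_growth_rate(10, 100, 50), 0.016219, tolerance = 1e-4)
  # for Amax >> A0 the curve is exponential and r tends to ln(2)/T
  expect_equal(compute_growth_rate(10, 1e9, 80), log(2) / 80,
               tolerance = 1e-6)
  expect_error(compute_growth_rate(20, 40, 100), "Amax")
})

test_that("time_at_size inverts the curve and rejects unreachable sizes", {
  p0 <- logistic_params()
  expect_equal(time_at_size(p0, 20), 0)
  expect_equal(time_at_size(p0, 40), 100, tolerance = 1e-6)
  expect_error(time_at_size(p0, 10), "below")
  expect_error(time_at_size(p0, 120), "unreachable")
  # round-trip t -> A -> t for random times, both curve shapes
  set.seed(7)
  for (p in list(p0, default_params())) {
    t <- runif(100, 0, 1000)
    expect_equal(time_at_size(p, growth_curve(p, t)), t, tolerance = 1e-6)
  }
})

test_that("cycle-length draws have the stated moments per regime", {
  set.seed(11)
  du <- draw_cycle_length(unp_model(), 1e5)
  expect_true(all(du > 0))
  expect_equal(mean(du), 100, tolerance = 0.5 / 100)
  expect_equal(sd(du), 10, tolerance = 0.02)
  ds <- draw_cycle_length(sac_model(), 1e5)
  expect_true(all(ds > 200))
  expect_equal(mean(ds), 400, tolerance = 3 / 400)
  # delay adds to the mean only: CV = 200 / 400
  expect_equal(sd(ds) / mean(ds), 0.5, tolerance = 0.02)
  # reproducible under a fixed seed
  set.seed(5); a <- draw_cycle_length(sac_model(), 10)
  set.seed(5); b <- draw_cycle_length(sac_model(), 10)
  expect_identical(a, b)
})

test_that("division halves the size and repositions on the curve", {
  p0 <- logistic_params()
  expect_equal(divide(p0, 40), list(post_area = 20, restart_time = 0))
  d <- divide(p0, 80)
  expect_equal(d$post_area, 40)
  expect_equal(d$restart_time, 100, tolerance = 1e-6)
  # the restart point round-trips: growing back to the pre-division size
  # takes exactly time_at_size(80) - time_at_size(40) on the curve
  expect_equal(growth_curve(p0, time_at_size(p0, 80)), 80, tolerance = 1e-6)
  expect_warning(divide(p0, 30), "below curve origin")
})

test_that("lineage simulation follows the curve and the active regime", {
  p0 <- logistic_params()
  # one deterministic cycle of exactly T_unperturbed doubles the size
  tr <- simulate_lineage(p0, regime_schedule(-Inf, "unperturbed"),
                         n_cycles = 1, cycle_lengths = 100)
  expect_equal(tr$divisions$pre_area_um2, 40, tolerance = 1e-9)
  expect_equal(tr$divisions$post_area_um2, 20, tolerance = 1e-9)
  expect_equal(tr$trace$area_um2[1], 20)
  # trace areas sit on the growth curve between divisions
  expect_equal(tr$trace$area_um2,
               growth_curve(p0, tr$trace$time_min), tolerance = 1e-9)

  # near-periodic doubling: division sizes have small CV over 50 cycles
  set.seed(3)
  tr2 <- suppressWarnings(
    simulate_lineage(p0, regime_schedule(-Inf, "unperturbed"), n_cycles = 50))
  expect_lt(coefficient_of_variation(tr2$divisions$pre_area_um2), 0.15)

  # the switch applies to the next drawn duration
  set.seed(4)
  tr3 <- simulate_lineage(default_params(),
                          regime_schedule(c(-Inf, 0), c("unperturbed", "sac_active")),
                          n_cycles = 25)
  expect_true(all(tr3$divisions$regime == "sac_active"))
  expect_true(all(tr3$divisions$cycle_length_min > 200))

  # fixed seed => bit-identical traces
  set.seed(9); a <- simulate_lineage(default_params(),
                                     regime_schedule(-Inf, "sac_active"),
                                     n_cycles = 10)
  set.seed(9); b <- simulate_lineage(default_params(),
                                     regime_schedule(-Inf, "sac_active"),
                                     n_cycles = 10)
  expect_identical(a, b)
})

test_that("SAC-active cycling times vary more than division sizes", {
  set.seed(21)
  tr <- simulate_lineage(default_params(), regime_schedule(-Inf, "sac_active"),
                         n_cycles = 20)
  d <- tr$divisions[3:20, ]
  expect_gt(coefficient_of_variation(d$cycle_length_min),
            coefficient_of_variation(d$pre_area_um2))
})

test_that("entry-size variance stabilizes on the combined curve but not under pure exponential growth", {
  set.seed(31)
  es <- simulate_entry_sizes(default_params(), sac_model(),
                             n_cells = 200, n_cycles = 30)
  ee <- simulate_entry_sizes(default_params(), sac_model(),
                             n_cells = 200, n_cycles = 30, law = "exponential")
  expect_lte(var(es[, 30]), 1.5 * var(es[, 10]))
  expect_gte(var(ee[, 30]), 3 * var(ee[, 10]))
})

test_that("checkpoint withdrawal relaxes entry sizes toward the unperturbed steady state", {
  set.seed(41)
  w <- simulate_withdrawal(default_params(), n_cells = 100,
                           n_cycles_before = 12, n_cycles_after = 5)
  med <- apply(w$entry_sizes, 2, median)
  expect_true(all(diff(med) < 0))
  # n_cycles_after = 0 returns only the SAC-active steady distribution
  set.seed(41)
  w0 <- simulate_withdrawal(default_params(), n_cells = 50,
                            n_cycles_before = 12, n_cycles_after = 0)
  expect_null(w0$entry_sizes)
  expect_length(w0$sac_steady, 50)
  # later recovery cycles overlap the unperturbed steady state more
  set.seed(42)
  eu <- simulate_entry_sizes(default_params(), unp_model(),
                             n_cells = 100, n_cycles = 20)
  steady <- eu[, 20]
  expect_gt(density_overlap(w$entry_sizes[, 5], steady),
            density_overlap(w$entry_sizes[, 1], steady))
})
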
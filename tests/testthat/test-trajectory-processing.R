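test_that("local variations are first differences with the telescoping identity", {
  expect_equal(local_variations(c(20, 22, 25)), c(2, 3))
  expect_equal(local_variations(rep(7, 5)), rep(0, 4))
  set.seed(1)
  a <- cumsum(runif(40, -2, 4)) + 30
  expect_equal(sum(local_variations(a)), a[length(a)] - a[1])
  expect_error(local_variations(5), "two points")
})

test_that("cluster fences are Tukey fences of the pooled variation distribution", {
  # zero-IQR cluster: any non-zero variation violates
  tr <- size_trajectory(seq(0, 990, 10), c(rep(20, 99), 30))
  thr <- fit_thresholds(tr)
  expect_equal(thr$lower[1], 0)
  expect_equal(thr$upper[1], 0)
  # type-7 quartiles on 1..8 (areas arranged to keep every pair in cluster 1)
  a <- cumsum(c(10, 1:8))
  thr2 <- fit_thresholds(size_trajectory(seq_along(a), a))
  expect_equal(thr2$lower[1], 2.75 - 1.5 * 3.5)
  expect_equal(thr2$upper[1], 6.25 + 1.5 * 3.5)
  # symmetric variations give fences symmetric about the median
  b <- 25 + cumsum(c(0, -3, 3, -2, 2, -1, 1, 3, -3))
  thr3 <- fit_thresholds(size_trajectory(seq_along(b), b))
  expect_equal(thr3$lower[1] + thr3$upper[1], 2 * median(local_variations(b)))
  # clusters with too few pairs stay unset and never flag
  thr4 <- fit_thresholds(size_trajectory(1:3, c(20, 22, 24)))
  expect_true(all(is.na(thr4$lower)))
})

test_that("outlier adjustment replaces spikes by neighbour means and converges", {
  thr <- cluster_thresholds(c(0, 40, 80, 120), rep(-3, 3), rep(3, 3))
  # clean trajectory is a fixed point
  clean <- size_trajectory(seq(0, 30, 10), c(20, 21, 22, 23))
  adj0 <- adjust_trajectory(clean, thr)
  expect_equal(adj0$areas, clean$areas)
  expect_false(any(adj0$adjusted))
  # isolated spike: replaced by the mean of its neighbours in one pass
  spiked <- size_trajectory(seq(0, 40, 10), c(20, 21, 50, 23, 24))
  adj1 <- adjust_trajectory(spiked, thr)
  expect_equal(adj1$areas, c(20, 21, 22, 23, 24))
  expect_equal(which(adj1$adjusted), 3L)
  expect_equal(attr(adj1, "iterations"), 1L)
  # two adjacent spikes: both replaced within the 10-pass budget
  double <- size_trajectory(seq(0, 50, 10), c(20, 21, 50, 55, 24, 25))
  adj2 <- adjust_trajectory(double, thr)
  expect_lte(attr(adj2, "iterations"), 10L)
  expect_true(all(adj2$adjusted[3:4]))
  expect_true(all(adj2$areas[3:4] < 45))
  # idempotent once converged; endpoints and length preserved
  adj1b <- adjust_trajectory(adj1, thr)
  expect_equal(adj1b$areas, adj1$areas)
  expect_length(adj2$areas, 6L)
  expect_equal(adj2$areas[c(1, 6)], c(20, 25))
})

test_that("points outside all clusters are never flagged", {
  thr <- cluster_thresholds(c(0, 40, 80, 120), rep(-3, 3), rep(3, 3))
  # spike at 200 um^2: its variations start from sizes > 120, unclustered
  tr <- size_trajectory(seq(0, 40, 10), c(150, 152, 200, 156, 158))
  adj <- adjust_trajectory(tr, thr)
  expect_equal(adj$areas, tr$areas)
  expect_false(any(adj$adjusted))
})

test_that("moving-average smoothing has the stated window behaviour", {
  tr <- size_trajectory(1:5, c(1, 2, 3, 4, 5) + 20)
  expect_equal(smooth_trajectory(tr, window = 1)$areas, tr$areas)
  expect_equal(smooth_trajectory(tr, window = 3)$areas[2:4], c(2, 3, 4) + 20)
  const <- size_trajectory(1:10, rep(33, 10))
  expect_equal(smooth_trajectory(const, window = 8)$areas, rep(33, 10))
  expect_error(smooth_trajectory(tr, window = 9), "window")
  # condition defaults: 3 points unperturbed, 8 points SAC
  set.seed(2)
  noise <- rnorm(60)
  un <- size_trajectory(1:60, 50 + noise, condition = "unperturbed")
  sa <- size_trajectory(1:60, 50 + noise, condition = "sac")
  expect_equal(smooth_trajectory(un)$areas, smooth_trajectory(un, 3)$areas)
  expect_equal(smooth_trajectory(sa)$areas, smooth_trajectory(sa, 8)$areas)
  # smoothing commutes with adding a constant and shrinks noise variance
  shifted <- size_trajectory(1:60, un$areas + 11)
  expect_equal(smooth_trajectory(shifted, 3)$areas,
               smooth_trajectory(un, 3)$areas + 11)
  expect_lt(var(diff(smooth_trajectory(un, 3)$areas)), var(diff(un$areas)))
})

test_that("local growth rate matches closed forms for linear and exponential input", {
  tt <- seq(0, 100, 10)
  lin <- size_trajectory(tt, 30 + 0.25 * tt)
  expect_equal(local_growth_rate(lin)$growth_rate, rep(0.25, length(tt)))
  const <- size_trajectory(tt, rep(42, length(tt)))
  expect_equal(local_growth_rate(const)$growth_rate, rep(0, length(tt)))
  r <- 0.009
  ex <- size_trajectory(tt, exp(r * tt) * 25)
  lg <- local_growth_rate(ex)
  i <- 2:(length(tt) - 1)
  expect_equal(lg$growth_rate[i], 25 * exp(r * tt[i]) * sinh(r * 10) / 10,
               tolerance = 1e-12)
  expect_warning(
    local_growth_rate(size_trajectory(c(0, 10, 25), c(20, 21, 22))),
    "non-uniform")
})

test_that("binned means agree with a brute-force grouping oracle", {
  expect_equal(bin_means(c(5, 15), c(1, 3), 10)$y_mean, c(1, 3))
  one <- bin_means(c(1, 2, 3), c(4, 5, 9), 10)
  expect_equal(nrow(one), 1L)
  expect_equal(one$y_mean, 6)
  set.seed(13)
  x <- runif(500, 0, 173)
  y <- rnorm(500)
  got <- bin_means(x, y, 10)
  oracle <- do.call(rbind, lapply(split(seq_along(x), floor(x / 10)), function(i) {
    data.frame(x_mean = mean(x[i]), y_mean = mean(y[i]), n = length(i))
  }))
  oracle <- oracle[order(oracle$x_mean), ]
  expect_equal(got$x_mean, oracle$x_mean)
  expect_equal(got$y_mean, oracle$y_mean)
  expect_equal(got$n, oracle$n)
  expect_error(bin_means(numeric(0), numeric(0), 10), "empty")
})

test_that("mean trajectory requires strictly more than the support threshold", {
  mk <- function(n_pts) size_trajectory(seq(0, by = 10, length.out = n_pts),
                                        rep(30, n_pts))
  expect_equal(nrow(mean_trajectory(replicate(5, mk(10), simplify = FALSE))), 0L)
  m6 <- mean_trajectory(replicate(6, mk(10), simplify = FALSE))
  expect_equal(m6$mean_area_um2, rep(30, 10))
  expect_equal(m6$n, rep(6L, 10))
  # mixed support: only timepoints with >5 contributors survive
  mixed <- c(replicate(6, mk(10), simplify = FALSE),
             replicate(3, mk(20), simplify = FALSE))
  mm <- mean_trajectory(mixed)
  expect_equal(mm$time_min, seq(0, 90, 10))
})

test_that("pixel-to-area conversion uses the imaging calibration", {
  expect_equal(pixels_to_area(0), 0)
  expect_equal(pixels_to_area(400), 20)
  expect_equal(pixels_to_area(2400), 120)
  expect_error(pixels_to_area(-1), "non-negative")
})

test_that("filtering recovers spiked synthetic trajectories", {
  rec <- run_recovery(seed = 42, n_cells = 50)
  expect_lte(sum(rec$rmse_adjusted) / sum(rec$rmse_corrupted), 0.25)
  expect_gte(mean(rec$flags[rec$spikes]), 0.8)
  expect_lt(mean(rec$flags[!rec$spikes]), 0.05)
  expect_lte(max(vapply(rec$adj, attr, integer(1), "iterations")), 10L)
})

test_that("trajectory tables round-trip through the tidy text format", {
  set.seed(8)
  gen <- generate_trajectories(default_params(), unp_model(),
                               corruption_model(spike_probability = 0),
                               n_cells = 3)
  path <- tempfile(fileext = ".tsv")
  write_trajectory_table(gen$clean, path)
  back <- read_trajectory_table(path)
  expect_length(back, 3L)
  expect_equal(back[[1]]$areas, gen$clean[[1]]$areas, tolerance = 1e-6)
  expect_equal(back[[2]]$times, gen$clean[[2]]$times)
  unlink(path)
})
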
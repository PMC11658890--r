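# Exponential kinetics: cleaved fractions, model fits, nd rules,
# replicate aggregation and fold changes.

test_that("fraction cleaved is density over total density", {
  expect_equal(fraction_cleaved(0, 50), 0)
  expect_equal(fraction_cleaved(50, 50), 0.5)
  expect_equal(fraction_cleaved(30, 70), 0.3)
  expect_error(fraction_cleaved(0, 0), "empty lane")
  expect_error(fraction_cleaved(-1, 5), "non-negative")
})

test_that("noiseless cleavage data round-trips through the fit", {
  tc <- simulate_cleavage_timecourse(k = 0.1, ymax = 0.8)
  fit <- fit_cleavage(tc)
  expect_false(fit$nd)
  expect_equal(fit$k_obs, 0.1, tolerance = 1e-4)
  expect_equal(fit$ymax, 0.8, tolerance = 1e-4)
  expect_equal(fit$n_points, 9L)
  # a fast and a slow rate on the same nine-point schedule
  for (k in c(0.02, 0.4)) {
    f <- fit_cleavage(simulate_cleavage_timecourse(k, 0.9))
    expect_equal(f$k_obs, k, tolerance = 1e-4)
  }
})

test_that("noiseless 2AP data round-trips with Y0 fixed to the blank", {
  s <- simulate_2ap_trace(k = 0.03, ymax = 4000, y0 = 500, duration = 300)
  fits <- fit_2ap(s$trace)
  expect_length(fits, 1L)
  f <- fits[[1]]
  expect_false(f$nd)
  expect_equal(f$k_obs, 0.03, tolerance = 1e-4)
  expect_equal(f$ymax, 4000, tolerance = 1e-3)
  expect_equal(f$y0, 500)
  expect_error(fit_2ap(structure(s$trace, blank_mean = NULL)),
               "blank_mean")
})

test_that("nd rules fire at and below the amplitude floors", {
  # cleavage floor: Ymax <= 0.05, boundary included
  at_floor <- simulate_cleavage_timecourse(k = 0.5, ymax = 0.05)
  f <- fit_cleavage(at_floor)
  expect_equal(f$ymax, 0.05, tolerance = 1e-6)
  expect_true(f$nd)
  below <- fit_cleavage(simulate_cleavage_timecourse(k = 0.5, ymax = 0.03))
  expect_true(below$nd)
  above <- fit_cleavage(simulate_cleavage_timecourse(k = 0.5, ymax = 0.06))
  expect_false(above$nd)
  expect_gt(above$k_obs, 0)
  # 2AP floor: Ymax <= 100 AU
  s <- simulate_2ap_trace(k = 0.03, ymax = 100, y0 = 500, duration = 300)
  expect_true(fit_2ap(s$trace)[[1]]$nd)
  s80 <- simulate_2ap_trace(k = 0.03, ymax = 80, y0 = 500, duration = 300)
  expect_true(fit_2ap(s80$trace)[[1]]$nd)
  s150 <- simulate_2ap_trace(k = 0.03, ymax = 150, y0 = 500, duration = 300)
  expect_false(fit_2ap(s150$trace)[[1]]$nd)
})

test_that("degenerate traces collapse to zero amplitude and nd", {
  flat <- time_course(data.frame(replicate = 1, time = c(0, 1, 2, 5, 10),
                                 value = 0),
                      time_unit = "minute", assay = "cleavage_fraction")
  f <- fit_cleavage(flat)
  expect_true(f$nd)
  expect_lt(f$ymax, 1e-6)
  # grid oracle confirms the least-squares optimum sits at ymax = 0
  g <- grid_rss(c(0, 1, 2, 5, 10), rep(0, 5), k_range = c(1e-3, 10),
                ymax_range = c(0, 1))
  expect_lte(f$rss, g + 1e-12)
  # constant 2AP trace at the blank level
  const <- time_course(data.frame(replicate = 1,
                                  time = seq(0, 100, 20), value = 500),
                       time_unit = "second", assay = "fluorescence_AU",
                       blank_mean = 500)
  expect_true(fit_2ap(const)[[1]]$nd)
})

test_that("fitted RSS beats a 200x200 grid search on small inputs", {
  set.seed(17)
  for (i in 1:5) {
    t <- sort(c(0, stats::runif(4, 0.2, 30)))
    y <- pmin(pmax(0.7 * (1 - exp(-0.15 * t)) +
                     stats::rnorm(5, 0, 0.05), 0), 1)
    fit <- fit_cleavage(time_course(
      data.frame(replicate = 1, time = t, value = y),
      time_unit = "minute", assay = "cleavage_fraction"))
    g <- grid_rss(t, y, k_range = c(1e-3, 5), ymax_range = c(0, 1))
    expect_lte(fit$rss, g + 1e-9)
  }
})

test_that("fewer than 3 distinct time points is an error", {
  two <- time_course(data.frame(replicate = 1, time = c(0, 5),
                                value = c(0, 0.5)),
                     time_unit = "minute", assay = "cleavage_fraction")
  expect_error(fit_cleavage(two), "3 distinct")
})

test_that("minute-to-second conversion divides the rate by exactly 60", {
  tc <- simulate_cleavage_timecourse(k = 0.3, ymax = 0.9)
  f_min <- fit_cleavage(tc)
  f_sec <- fit_cleavage(convert_time_unit(tc, "second"))
  expect_equal(f_sec$k_obs, f_min$k_obs / 60, tolerance = 1e-6)
})

test_that("replicate aggregation reports mean +/- sample SD of non-nd fits", {
  mk <- function(k, nd = FALSE) {
    pamkin:::new_exp_fit("cleavage", k_obs = k, ymax = 0.8, y0 = NULL,
                         nd = nd, rss = 0, n_points = 9L)
  }
  same <- aggregate_replicates(list(mk(0.2), mk(0.2), mk(0.2)))
  expect_equal(same$mean_k, 0.2)
  expect_equal(same$sd_k, 0)
  expect_equal(same$n, 3L)
  spread <- aggregate_replicates(list(mk(1), mk(2), mk(3)))
  expect_equal(spread$mean_k, 2)
  expect_equal(spread$sd_k, 1)
  mixed <- aggregate_replicates(list(mk(1), mk(2), mk(99, nd = TRUE)))
  expect_equal(mixed$n, 2L)
  expect_true(mixed$any_nd)
  expect_false(mixed$nd)
  all_nd <- aggregate_replicates(list(mk(1, TRUE), mk(2, TRUE)))
  expect_true(all_nd$nd)
})

test_that("fold change is the rate ratio and refuses nd inputs", {
  expect_equal(fold_change(0.2, 0.04), 5)
  expect_equal(fold_change(0.3, 0.3), 1)
  expect_equal(fold_change(0.4, 0.04), 10)
  f1 <- fit_cleavage(simulate_cleavage_timecourse(0.4, 0.9))
  f2 <- fit_cleavage(simulate_cleavage_timecourse(0.04, 0.9))
  expect_equal(fold_change(f1, f2), 10, tolerance = 1e-4)
  nd_fit <- fit_cleavage(simulate_cleavage_timecourse(0.5, 0.03))
  expect_error(fold_change(f1, nd_fit), "nd")
})
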
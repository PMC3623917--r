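test_that("pearson_r is exact on linear dependence and guards zero variance", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1, tolerance = 1e-12)
  expect_true(is.na(pearson_r(c(2, 2, 2), c(1, 2, 3))))
  expect_true(is.na(pearson_r(c(1, 2, 3), c(5, 5, 5))))
  expect_error(pearson_r(1:3, 1:4), class = "roughscape_size_error")
  expect_error(pearson_r(1, 2), class = "roughscape_size_error")
  # agrees with the standard estimator wherever both are defined
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(2:100, 1))
    y <- rnorm(length(x))
    expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("mean sample r over iid 64-point windows matches the bias-adjusted expectation", {
  # E[r] ~= rho * (1 - (1 - rho^2) / (2 n)) = -0.49707 for rho = -0.5, n = 64;
  # the adjustment was confirmed against a 1e5-window Monte Carlo.
  set.seed(64)
  rho <- -0.5
  n <- 64
  rs <- replicate(2000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    pearson_r(x, y)
  })
  expect_lt(abs(mean(rs) - (-0.49707)), 0.02)
})

test_that("sigma_pop is the population standard deviation", {
  expect_identical(sigma_pop(c(0, 2)), 1)
  expect_identical(sigma_pop(rep(3.7, 10)), 0)
  expect_error(sigma_pop(1), class = "roughscape_size_error")
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(64, sd = runif(1, 0.1, 50), mean = runif(1, -100, 100))
    expect_equal(sigma_pop(x), loop_sigma(x), tolerance = 1e-12)
    expect_equal(sigma_pop(x), sd(x) * sqrt(63 / 64), tolerance = 1e-12)
  }
})

test_that("window statistics reproduce the limiting cases", {
  set.seed(9)
  e_p <- rnorm(32)
  # pure-protein limit: water term flat
  ws <- window_pair_stats(e_p, rep(0, 32))
  expect_identical(ws$sigma_pw, 0)
  expect_equal(ws$sigma_tot, ws$sigma_p, tolerance = 1e-12)
  expect_equal(ws$delta_sigma, 0, tolerance = 1e-12)
  expect_true(is.na(ws$r))
  expect_true(is.na(ws$quadrant))
  # perfect compensation: water smooths (quadrant III)
  ws <- window_pair_stats(e_p, -0.5 * e_p)
  expect_equal(ws$r, -1, tolerance = 1e-12)
  expect_equal(ws$sigma_tot, 0.5 * ws$sigma_p, tolerance = 1e-12)
  expect_lt(ws$delta_sigma, 0)
  expect_equal(as.character(ws$quadrant), "III")
  # reinforcement: water roughens (quadrant I)
  ws <- window_pair_stats(e_p, e_p)
  expect_equal(ws$r, 1, tolerance = 1e-12)
  expect_equal(ws$sigma_tot, 2 * ws$sigma_p, tolerance = 1e-12)
  expect_equal(as.character(ws$quadrant), "I")
  # overcompensation: r = -1 but water still roughens (quadrant IV)
  ws <- window_pair_stats(e_p, -3 * e_p)
  expect_equal(ws$r, -1, tolerance = 1e-12)
  expect_equal(ws$sigma_tot, 2 * ws$sigma_p, tolerance = 1e-12)
  expect_equal(as.character(ws$quadrant), "IV")
})

test_that("the variance decomposition identity holds for every window", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(2:128, 1)
    scale_p <- 10^runif(1, -3, 3)
    scale_w <- 10^runif(1, -3, 3)
    e_p <- rnorm(n, mean = runif(1, -1e3, 1e3), sd = scale_p)
    e_pw <- runif(1, -1, 1) * e_p + rnorm(n, sd = scale_w)
    ws <- window_pair_stats(e_p, e_pw)
    if (is.na(ws$r)) next
    lhs <- ws$sigma_tot^2
    rhs <- ws$sigma_p^2 + ws$sigma_pw^2 + 2 * ws$r * ws$sigma_p * ws$sigma_pw
    expect_lte(abs(lhs - rhs), 1e-9 * max(1, lhs))
  }
})

test_that("scale summaries count smoothing, roughening and quadrants correctly", {
  e_p <- rnorm(16)
  smooth_w <- window_pair_stats(e_p, -0.5 * e_p)  # quadrant III
  rough_w <- window_pair_stats(e_p, e_p)          # quadrant I
  s1 <- summarize_scale(smooth_w, tau = 1, m = 4)
  expect_equal(s1$p_smooth, 1)
  expect_equal(s1$p_rough, 0)
  expect_equal(c(s1$pct_I, s1$pct_III, s1$pct_IV), c(0, 100, 0))
  s2 <- summarize_scale(dplyr::bind_rows(smooth_w, rough_w), tau = 1, m = 4)
  expect_equal(s2$p_smooth, 0.5)
  expect_equal(s2$p_rough + s2$p_smooth, 1)
  expect_equal(c(s2$pct_I, s2$pct_III, s2$pct_IV), c(50, 50, 0))
  expect_equal(s2$pct_I + s2$pct_III + s2$pct_IV, 100)
  expect_error(summarize_scale(smooth_w[0, ], tau = 1, m = 4),
               class = "roughscape_size_error")
})

test_that("histograms span the data and preserve total counts", {
  set.seed(3)
  es <- simulate_series(one_ou_model(10, 1, 2, -0.5, n_steps = 2e4, seed = 5))
  plan <- plan_windows(es, tau = 1, m = 5, max_windows = 500)
  sm <- summarize_scale(window_stats(es, plan), tau = 1, m = 5, hist_bins = 40)
  h <- sm$histograms[[1]]
  for (stat in c("r", "sigma_p", "sigma_pw", "sigma_tot")) {
    expect_length(h[[stat]]$breaks, 41L)
    expect_equal(sum(h[[stat]]$counts), sm$window_count)
    expect_true(all(diff(h[[stat]]$breaks) > 0))
  }
})

test_that("uncorrelated components give mean r near zero and mostly roughening", {
  es <- simulate_series(one_ou_model(10, 1, 1, 0, n_steps = 2e5, seed = 17))
  plan <- plan_windows(es, tau = 1, m = 6, max_windows = 2000)
  sm <- summarize_scale(window_stats(es, plan), tau = 1, m = 6)
  expect_lt(abs(sm$mean_r), 0.02)
  expect_lt(sm$p_smooth, 0.5)
})

test_that("affine smoothing dichotomy is exact on OU draws", {
  # rho = -1, B/A < 2: every window smooths; B/A > 2: none does
  es <- simulate_series(one_ou_model(10, 1, 0.5, -1, n_steps = 5e4, seed = 23))
  plan <- plan_windows(es, tau = 1, m = 6, max_windows = 1000)
  sm <- summarize_scale(window_stats(es, plan), tau = 1, m = 6)
  expect_equal(sm$p_smooth, 1)
  expect_equal(sm$pct_III, 100)
  es <- simulate_series(one_ou_model(10, 1, 3, -1, n_steps = 5e4, seed = 24))
  sm <- summarize_scale(window_stats(es, plan_windows(es, 1, 6, 1000)),
                        tau = 1, m = 6)
  expect_equal(sm$p_smooth, 0)
  expect_equal(sm$pct_IV, 100)
})

test_that("windowed anticorrelation is recovered when tau is well below theta", {
  # theta = 10 delta keeps the window span comparable to the relaxation
  # time, so the finite-window attenuation of sample r stays small.
  rs <- vapply(1:2, function(s) {
    es <- simulate_series(one_ou_model(10, 1, 1, -0.6, n_steps = 4e5,
                                       seed = 600 + s))
    plan <- plan_windows(es, tau = 1, m = 6, max_windows = 2000)
    summarize_scale(window_stats(es, plan), tau = 1, m = 6)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs) - (-0.6)), 0.03)
})

test_that("windowed roughness grows with time scale below theta", {
  sig <- vapply(1:3, function(s) {
    es <- simulate_series(one_ou_model(1000, 1, 0.5, -0.3, n_steps = 3e5,
                                       seed = 700 + s))
    vapply(c(1, 4, 16, 64), function(tau) {
      plan <- plan_windows(es, tau = tau, m = 5, max_windows = 1000)
      summarize_scale(window_stats(es, plan), tau = tau, m = 5)$mean_sigma_p
    }, numeric(1))
  }, numeric(4))
  means <- rowMeans(sig)
  expect_true(all(diff(means) > 0))
  # and each matches the windowed-variance oracle direction: below the
  # stationary sigma of 1
  expect_true(all(means < 1))
})
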
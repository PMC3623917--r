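test_that("zero-amplitude water component pins e_pw to its baseline exactly", {
  m <- synthetic_model(ou_component(10, a = 1, b = 0, rho = -0.3),
                       mu_w = 5, n_steps = 500, seed = 11)
  es <- simulate_series(m)
  expect_true(all(es$e_pw == 5))
  expect_identical(sigma_pop(es$e_pw), 0)
  expect_gt(sigma_pop(es$e_p), 0)
})

test_that("rho = -1 makes the two series affinely related (r = -1)", {
  m <- one_ou_model(theta = 10, a = 1, b = 1, rho = -1,
                    n_steps = 1e5, seed = 3)
  es <- simulate_series(m)
  expect_equal(pearson_r(es$e_p, es$e_pw), -1, tolerance = 1e-12)
  expect_equal(es$e_pw, -es$e_p, tolerance = 1e-12)
})

test_that("sample covariance matches the closed form rho*A*B over replicate seeds", {
  covs <- vapply(1:20, function(s) {
    es <- simulate_series(one_ou_model(50, a = 2, b = 3, rho = -0.5,
                                       n_steps = 2e5, seed = 100 + s))
    n <- nrow(es)
    mean((es$e_p - mean(es$e_p)) * (es$e_pw - mean(es$e_pw)))
  }, numeric(1))
  se <- sd(covs) / sqrt(length(covs))
  expect_lt(abs(mean(covs) - (-3)), 3 * se)
})

test_that("expected_window_variance matches its closed-form limits", {
  # stride >> theta: points are effectively independent
  expect_equal(expected_window_variance(theta = 1e-6, v = 2, n = 64, stride = 1),
               2 * (1 - 1 / 64), tolerance = 1e-12)
  # stride << theta: all points identical, no within-window variance
  expect_equal(expected_window_variance(theta = 1e9, v = 2, n = 8, stride = 1e-6),
               0, tolerance = 1e-9)
})

test_that("expected_window_variance equals the brute-force double sum", {
  expect_equal(expected_window_variance(100, 1, 64, 10),
               0.735946018807510, tolerance = 1e-12)
  expect_equal(expected_window_variance(100, 1, 64, 10),
               bf_expected_window_variance(100, 1, 64, 10),
               tolerance = 1e-12)
  # larger windows accumulate more rounding in the brute-force double loop
  for (case in list(c(7, 0.5, 16, 3), c(1000, 4, 128, 1))) {
    expect_equal(
      expected_window_variance(case[1], case[2], case[3], case[4]),
      bf_expected_window_variance(case[1], case[2], case[3], case[4]),
      tolerance = 1e-10
    )
  }
})

test_that("expected_total_variance follows the variance decomposition", {
  expect_identical(
    expected_total_variance(one_ou_model(1, 1, 1, -1, n_steps = 10, seed = 1)), 0)
  expect_identical(
    expected_total_variance(one_ou_model(1, 3, 4, 0, n_steps = 10, seed = 1)), 25)
  two <- synthetic_model(
    rbind(ou_component(5, a = 1, b = 2, rho = -0.5),
          ou_component(50, a = 2, b = 1, rho = 0.25)),
    n_steps = 2e5, seed = 1
  )
  expect_identical(expected_total_variance(two), 9)
  mm <- model_moments(two)
  expect_equal(mm$var_tot, mm$var_p + mm$var_pw + 2 * mm$cov)
  # Monte-Carlo cross-check of the closed form
  vars <- vapply(1:20, function(s) {
    et <- energy_total(simulate_series(two, seed = 200 + s))
    mean((et - mean(et))^2)
  }, numeric(1))
  se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - 9), 3 * se)
})

test_that("identical models reproduce identical series bit for bit", {
  m <- synthetic_model(
    rbind(ou_component(3, 1, 0.5, -0.2), ou_component(30, 0.4, 2, -0.8)),
    n_steps = 5000, seed = 42
  )
  a <- simulate_series(m)
  b <- simulate_series(m)
  expect_identical(a$e_p, b$e_p)
  expect_identical(a$e_pw, b$e_pw)
  c_ <- simulate_series(m, seed = 43)
  expect_false(identical(a$e_p, c_$e_p))
})

test_that("lag-1 autocorrelation converges to exp(-delta/theta)", {
  theta <- 5
  ac1 <- vapply(1:10, function(s) {
    es <- simulate_series(one_ou_model(theta, 1, 0, 0, n_steps = 1e5,
                                       seed = 300 + s))
    x <- es$e_p
    cor(x[-1], x[-length(x)])
  }, numeric(1))
  se <- sd(ac1) / sqrt(length(ac1))
  expect_lt(abs(mean(ac1) - exp(-1 / theta)), 3 * se)
})

test_that("simulated series are stationary: variances of halves agree", {
  diffs <- vapply(1:12, function(s) {
    es <- simulate_series(one_ou_model(20, 1.5, 1, -0.4, n_steps = 1e5,
                                       seed = 400 + s))
    h <- nrow(es) %/% 2
    var1 <- mean((es$e_p[1:h] - mean(es$e_p[1:h]))^2)
    var2 <- mean((es$e_p[(h + 1):nrow(es)] - mean(es$e_p[(h + 1):nrow(es)]))^2)
    var1 - var2
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("invalid model parameters are rejected", {
  expect_error(ou_component(-1, 1, 1, 0), class = "roughscape_validation_error")
  expect_error(ou_component(1, 1, 1, 1.5), class = "roughscape_validation_error")
  expect_error(one_ou_model(1, 1, 1, 0, n_steps = 1, seed = 1),
               class = "roughscape_size_error")
  expect_error(
    synthetic_model(rbind(ou_component(10, 1, 1, 0), ou_component(5, 1, 1, 0)),
                    n_steps = 10, seed = 1),
    class = "roughscape_validation_error"
  )
  expect_error(expected_window_variance(10, 1, 1, 1),
               class = "roughscape_size_error")
})
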
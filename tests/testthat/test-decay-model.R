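test_that("noiseless model data is recovered exactly", {
  for (b in c(0.02, 0.1, 0.5)) {
    f <- fit_decay(exact_assay(b))
    expect_true(f$converged)
    expect_equal(f$A_hat, 20, tolerance = 1e-8)
    expect_equal(f$b_hat, b, tolerance = 1e-8)
    expect_lt(f$rss, 1e-12)
    hl <- half_life(f)
    expect_equal(hl$rit50_s, log(2) / b, tolerance = 1e-8)
  }
})

test_that("log-linear initialization has its closed forms", {
  init <- loglinear_init(exact_assay(0.1))
  expect_equal(unname(init["A0"]), 20, tolerance = 1e-10)
  expect_equal(unname(init["b0"]), 0.1, tolerance = 1e-10)

  two <- rit_assay("g", "r", c(0, 8), c(20, 10), validate = FALSE)
  init <- loglinear_init(two)
  expect_equal(unname(init["b0"]), log(2) / 8, tolerance = 1e-12)
  expect_equal(unname(init["A0"]), 20, tolerance = 1e-12)

  # a zero count is excluded, leaving the two-point fit above
  three <- rit_assay("g", "r", c(0, 8, 16), c(20, 10, 0), validate = FALSE)
  init3 <- loglinear_init(three)
  expect_equal(init3, init, tolerance = 1e-12)

  one <- rit_assay("g", "r", c(0, 8, 16), c(20, 0, 0), validate = FALSE)
  expect_error(loglinear_init(one), "fewer than 2 positive")
})

test_that("degenerate inputs are refused with clear errors", {
  flat <- suppressWarnings(rit_assay("g", "r", seq(0, 24, 8), rep(20, 4)))
  expect_error(fit_decay(flat), "rate not identifiable")
  short <- rit_assay("g", "r", c(0, 8), c(20, 10), validate = FALSE)
  expect_error(fit_decay(short), "at least 3 observations")
})

test_that("fit matches the dense grid-search oracle on a seeded assay", {
  cfg <- sim_config("sim", true_b = 0.08, n_intervals = 10, seed = 1)
  a <- simulate_assay(cfg, "r1")
  f <- fit_decay(a)
  obs <- a$observations
  oracle <- grid_search_refined(obs$time_s, obs$intact_count)
  expect_equal(f$A_hat, oracle$A, tolerance = 1e-3)
  expect_equal(f$b_hat, oracle$b, tolerance = 1e-3)
  expect_lte(f$rss, oracle$rss + 1e-6)
})

test_that("fit rss never exceeds the dense grid oracle (short assays)", {
  for (seed in 1:5) {
    cfg <- sim_config("sim", true_b = 0.07 + 0.02 * seed,
                      n_intervals = 8, seed = seed)
    a <- simulate_assay(cfg, "r1")
    f <- fit_decay(a)
    obs <- a$observations
    oracle <- grid_search_oracle(obs$time_s, obs$intact_count)
    expect_lte(f$rss, oracle$rss + 1e-6)
  }
})

test_that("half-life closed forms and delta-method propagation hold", {
  mk_fit <- function(A, b, cov = matrix(0, 2, 2)) {
    structure(list(A_hat = A, b_hat = b, cov = cov, rss = 0, n_obs = 9,
                   sigma2 = 0, converged = TRUE, genotype = "g",
                   replicate_id = "r", initial_count = 20,
                   options = fit_options()),
              class = "decay_fit")
  }
  # A = N0: definition reduces to ln2/b
  expect_equal(half_life(mk_fit(20, log(2) / 8))$rit50_s, 8)
  # A != N0: general closed form
  expect_equal(half_life(mk_fit(22, 0.1))$rit50_s, log(2.2) / 0.1,
               tolerance = 1e-12)
  # delta method with only b uncertain: se = (t50/b) * sd(b)
  cov <- diag(c(0, 0.01^2))
  hl <- half_life(mk_fit(20, 0.1, cov))
  expect_equal(hl$se_s, log(2) / 0.1 / 0.1 * 0.01, tolerance = 1e-12)
  expect_equal(hl$ci_high_s - hl$rit50_s, qnorm(0.975) * hl$se_s)
  expect_true(hl$ci_low_s <= hl$rit50_s && hl$rit50_s <= hl$ci_high_s)

  # undefined cases
  expect_error(half_life(mk_fit(9, 0.1)), "never reaches")
  expect_error(half_life(mk_fit(20, 0)), "rate is zero")

  # fitted-intercept variant is the pure exponential half-life
  expect_equal(half_life(mk_fit(22, 0.1), half_life_def = "fitted")$rit50_s,
               log(2) / 0.1)
})

test_that("rit50 is strictly decreasing in the decay rate at A = N0", {
  bs <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  t50 <- vapply(bs, function(b) {
    half_life(fit_decay(exact_assay(b)))$rit50_s
  }, numeric(1))
  expect_true(all(diff(t50) < 0))
})

test_that("rescaling time rescales the half-life and rate equivariantly", {
  cfg <- sim_config("sim", true_b = 0.09, n_intervals = 12, seed = 42)
  a <- simulate_assay(cfg, "r1")
  for (c_scale in c(10, 0.5)) {
    a2 <- a
    a2$observations$time_s <- a$observations$time_s * c_scale
    a2$interval_s <- a$interval_s * c_scale
    f1 <- fit_decay(a)
    f2 <- fit_decay(a2)
    expect_equal(f2$b_hat, f1$b_hat / c_scale, tolerance = 1e-6)
    h1 <- half_life(f1)
    h2 <- half_life(f2)
    expect_equal(h2$rit50_s, h1$rit50_s * c_scale, tolerance = 1e-6)
    expect_equal(h2$se_s, h1$se_s * c_scale, tolerance = 1e-4)
  }
})

test_that("bootstrap SE is deterministic, stable, and agrees with delta", {
  cfg <- sim_config("sim", true_b = 0.1, seed = 5)
  a <- simulate_assay(cfg, "r1")
  f <- fit_decay(a)
  hl <- half_life(f)

  b1 <- bootstrap_half_life(a, f, n_boot = 500, seed = 7)
  b2 <- bootstrap_half_life(a, f, n_boot = 500, seed = 7)
  expect_identical(b1, b2)

  # delta (error-propagation) SE within 25% of the bootstrap oracle
  expect_lt(abs(hl$se_s - b1$se_s) / b1$se_s, 0.25)

  # Monte-Carlo stability: doubling the resamples moves the SE < 10%
  b4 <- bootstrap_half_life(a, f, n_boot = 1000, seed = 7)
  expect_lt(abs(b4$se_s - b1$se_s) / b1$se_s, 0.10)

  expect_error(bootstrap_half_life(a, f, n_boot = 100, seed = 1),
               "n_boot")
})

test_that("fit covariance is symmetric with non-negative diagonal", {
  for (seed in 1:8) {
    cfg <- sim_config("sim", true_b = 0.05 + 0.03 * seed, seed = seed)
    f <- fit_decay(simulate_assay(cfg, "r1"))
    expect_true(f$b_hat >= 0)
    expect_true(f$A_hat > 0)
    expect_equal(f$cov, t(f$cov))
    expect_true(all(diag(f$cov) >= 0))
  }
})

test_that("iid covariance option reproduces the classical nls covariance", {
  cfg <- sim_config("sim", true_b = 0.1, seed = 5)
  a <- simulate_assay(cfg, "r1")
  f <- fit_decay(a, fit_options(cov_type = "iid"))
  m <- stats::nls(intact_count ~ A * exp(-b * time_s),
                  data = a$observations,
                  start = list(A = 20, b = 0.1))
  expect_equal(f$A_hat, unname(coef(m)["A"]), tolerance = 1e-6)
  expect_equal(f$b_hat, unname(coef(m)["b"]), tolerance = 1e-6)
  expect_equal(unname(f$cov), unname(vcov(m)), tolerance = 1e-4)
})
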
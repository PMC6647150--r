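test_that("the hazard is the scaled logistic with the cycle-rate ceiling", {
  spec <- hazard_spec(a_star = 0.61, b_star = 0.139, nu = ref_eq$nu)
  expect_equal(spec$rate_scale, 0.0447827, tolerance = 1e-5)
  expect_equal(hazard(1e6, spec), spec$rate_scale)
  expect_equal(hazard(spec$a_star, spec), spec$rate_scale / 2)
  expect_lt(hazard(0, spec), 1e-3)
  expect_true(all(hazard(seq(0, 5, by = 0.1), spec) <= spec$rate_scale))
  expect_error(hazard(-1, spec), "non-negative")
  expect_error(hazard_spec(0.6, 0, ref_eq$nu), "positive")
})

test_that("a constant hazard reproduces the exponential density exactly", {
  ## a_star far below 0 makes the logistic factor 1 for every radius
  spec <- hazard_spec(a_star = -1, b_star = 0.02, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  a0 <- spec$rate_scale
  d <- isi_density(spec, nf, t_grid = seq(1, 5 / a0, length.out = 60),
                   M = 100, n = 40, seed = 3)
  expect_lt(max(abs(d$g - a0 * exp(-a0 * d$t_grid)) /
                  (a0 * exp(-a0 * d$t_grid))), 0.01)
})

test_that("the density integrates to just below one over a long grid", {
  spec <- hazard_spec(a_star = 0.610148, b_star = 0.139075, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  ## the finer trapezoid rule; the coarse n = 10 default inflates the
  ## integral by ~2-3% because the hazard decorrelates faster than t/10
  d <- isi_density(spec, nf, M = 400, n = 50, seed = 4)
  expect_true(all(d$g >= 0))
  total <- sum(diff(d$t_grid) * (d$g[-1] + d$g[-length(d$g)]) / 2)
  expect_gte(total, 0.95)
  expect_lte(total, 1.02)
  ## unimodal bulk: the maximum sits strictly inside the grid
  expect_gt(which.max(d$g), 1)
  expect_lt(which.max(d$g), length(d$g))
})

test_that("density Monte-Carlo error shrinks when M doubles", {
  spec <- hazard_spec(a_star = 0.610148, b_star = 0.139075, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  tg <- seq(20, 400, by = 20)
  ref <- isi_density(spec, nf, t_grid = tg, M = 4000, n = 10, seed = 1)$g
  err <- function(M) {
    reps <- vapply(1:6, function(k)
      max(abs(isi_density(spec, nf, t_grid = tg, M = M, n = 10,
                          seed = 100 + k)$g - ref)), 0)
    mean(reps)
  }
  expect_lt(err(400), err(100))
})

test_that("thinning reproduces the exponential law under constant hazard", {
  spec <- hazard_spec(a_star = -1, b_star = 0.02, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  s <- sample_isi_lif(spec, nf, 2000, dt = 0.05, horizon = 1000, seed = 9)
  ks <- suppressWarnings(stats::ks.test(s$isi, stats::pexp,
                                        rate = spec$rate_scale))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a vanishing hazard censors every run", {
  spec <- hazard_spec(a_star = 100, b_star = 0.1, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  expect_error(sample_isi_lif(spec, nf, 10, horizon = 50, seed = 2),
               "censored")
})

test_that("thinning samples are consistent with the density estimator", {
  spec <- hazard_spec(a_star = 0.610148, b_star = 0.139075, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  n <- 2000
  s <- sample_isi_lif(spec, nf, n, dt = 0.05, horizon = 5000, seed = 12)
  tg <- exp(seq(log(1), log(1000), length.out = 120))
  d <- isi_density(spec, nf, t_grid = tg, M = 1000, n = 100, seed = 13)
  ## survival from the integrated density vs the empirical survival
  cum_trap <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  checkpoints <- seq(60, 600, by = 60)
  for (tc in checkpoints) {
    keep <- tg <= tc
    ## g(0) ~ alpha(0) is negligible at this hazard; anchor the rule at 0
    cum <- cum_trap(c(0, tg[keep]), c(0, d$g[keep]))
    surv_density <- 1 - cum
    surv_emp <- mean(s$times > tc, na.rm = FALSE)
    se <- sqrt(max(surv_emp * (1 - surv_emp), 0.01)) *
      sqrt(1 / n + 1 / d$M)
    expect_lt(abs(surv_density - surv_emp), 3 * se + 0.01)
  }
})

test_that("no thinned path fires above the hazard ceiling rate", {
  ## with the ceiling alpha0, waiting times stochastically dominate
  ## exponential(alpha0): the empirical mean cannot fall below 1/alpha0
  spec <- hazard_spec(a_star = 0.2, b_star = 0.05, nu = ref_eq$nu)
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  s <- sample_isi_lif(spec, nf, 1000, dt = 0.05, horizon = 2000, seed = 14)
  expect_gt(mean(s$isi), 1 / spec$rate_scale * 0.95)
})

test_that("ISI comparison detects identity and gross mismatch", {
  x <- stats::qexp(seq(0.005, 0.995, by = 0.005), rate = 0.01)
  same <- compare_isi(x, x)
  expect_equal(same$ks_statistic, 0)
  set.seed(8)
  heavy <- exp(stats::rnorm(500, mean = log(100), sd = 2))
  diff_cmp <- compare_isi(stats::rexp(500, 0.01), heavy)
  expect_gt(diff_cmp$ks_statistic, 0.2)
  expect_identical(dim(diff_cmp$quantiles), c(9L, 3L))
})
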
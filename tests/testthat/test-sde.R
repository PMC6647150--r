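test_that("the noiseless system converges to the stable fixed point", {
  cfg <- sim_config(T = 1000, seed = 1, initial_state = c(-1.00125, -0.45))
  traj <- simulate_fhn(ref_params, noise_spec(sigma0 = 0), cfg)
  n <- length(traj$v)
  expect_lt(sqrt((traj$v[n] - ref_eq$v_e)^2 + (traj$w[n] - ref_eq$w_e)^2),
            1e-3)
})

test_that("the noiseless linear system contracts at rate mu", {
  M <- ref_eq$M
  cfg <- sim_config(dt = 0.01, T = 300, seed = 1,
                    initial_state = c(0.1, 0))
  traj <- integrate_stratonovich(
    function(s) c(M[1, 1] * s[1] + M[1, 2] * s[2],
                  M[2, 1] * s[1] + M[2, 2] * s[2]),
    function(s) c(0, 0), cfg)
  ## sample at whole rotation periods to remove the oscillatory modulation
  period <- 2 * pi / ref_eq$nu
  idx <- round(seq(0, 12) * period / cfg$dt) + 1L
  nrm <- sqrt(traj$v[idx]^2 + traj$w[idx]^2)
  slope <- unname(coef(lm(log(nrm) ~ traj$times[idx]))[2])
  expect_equal(slope, -ref_eq$mu, tolerance = 0.05)
})

test_that("Euler-Heun and Euler-Maruyama converge to each other as dt shrinks", {
  gap <- function(dt) {
    cfg <- sim_config(dt = dt, T = 25, seed = 3,
                      initial_state = c(ref_eq$v_e, ref_eq$w_e))
    heun <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.005), cfg)
    cfg$scheme <- "euler_maruyama"
    em <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.005), cfg,
                       increments = heun$noise_increments)
    max(sqrt((heun$v - em$v)^2 + (heun$w - em$w)^2))
  }
  g <- vapply(c(0.02, 0.01, 0.005), gap, 0)
  expect_true(all(diff(g) < 0))
  ## at least linear shrinkage over the 4x refinement
  expect_lt(g[3], g[1] / 2)
})

test_that("identical seeds and replayed increments give bit-identical paths", {
  cfg <- sim_config(dt = 0.01, T = 20, seed = 11)
  a <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.01), cfg)
  b <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.01), cfg)
  expect_identical(a$v, b$v)
  expect_identical(a$w, b$w)
  c <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.01), cfg,
                    increments = a$noise_increments)
  expect_identical(a$v, c$v)
})

test_that("non-finite states abort with the failing step index", {
  cfg <- sim_config(dt = 0.5, T = 100, seed = 2, initial_state = c(50, 0))
  expect_error(
    integrate_stratonovich(function(s) s^3, function(s) c(0, 0), cfg),
    "non-finite state at step")
})

test_that("spike detection counts one spike per excursion", {
  tms <- seq(0, 4 * pi, by = 0.01)
  sine <- structure(list(times = tms, v = sin(tms)),
                    class = "fhn_trajectory")
  rec <- detect_spikes(sine)
  expect_length(rec$spike_times, 2)
  ## interpolated crossing lands on the analytic zero
  expect_lt(abs(rec$spike_times[2] - 2 * pi), 0.01)
  flat <- structure(list(times = tms, v = rep(-1, length(tms))),
                    class = "fhn_trajectory")
  expect_length(detect_spikes(flat)$spike_times, 0)
})

test_that("a moderately noisy path spikes and ISIs are positive", {
  cfg <- sim_config(dt = 0.01, T = 1000, seed = 4)
  traj <- simulate_fhn(ref_params, noise_spec(sigma0 = 0.01), cfg)
  rec <- detect_spikes(traj)
  expect_gte(length(rec$spike_times), 1)
  expect_true(all(rec$isi > 0))
  expect_true(all(diff(rec$spike_times) > 0))
})

test_that("spiking is rare at sigma0 = 0.005 and increases with sigma0", {
  counts <- vapply(1:5, function(k) {
    lo <- detect_spikes(simulate_fhn(
      ref_params, noise_spec(sigma0 = 0.005),
      sim_config(T = 1000, seed = 20 + k)))
    hi <- detect_spikes(simulate_fhn(
      ref_params, noise_spec(sigma0 = 0.02),
      sim_config(T = 1000, seed = 20 + k)))
    c(length(lo$spike_times), length(hi$spike_times))
  }, numeric(2))
  expect_true(all(counts[1, ] <= 2))
  ## the high amplitude spikes strictly more for the majority of seeds
  expect_gte(sum(counts[2, ] > counts[1, ]), 4)
})

test_that("median spike count is non-decreasing across noise amplitudes", {
  sig <- c(0.005, 0.008, 0.01, 0.02)
  med <- vapply(sig, function(s0) {
    stats::median(vapply(1:10, function(k)
      length(detect_spikes(simulate_fhn(
        ref_params, noise_spec(sigma0 = s0),
        sim_config(T = 500, seed = 100 * k + round(1e4 * s0))))$spike_times),
      0))
  }, 0)
  expect_true(all(diff(med) >= 0))
  expect_gt(med[4], med[1])
})

test_that("multiplicative noise vanishes on the zero recovery state", {
  ## v frozen at -alpha makes the recovery drift -eps*beta*w, so w = 0 is
  ## invariant because h(0) = 0 for h(w) = sigma0 * w
  eps <- ref_params$epsilon; beta <- ref_params$beta
  cfg <- sim_config(dt = 0.01, T = 10, seed = 6, initial_state = c(0, 0))
  traj <- integrate_stratonovich(
    function(s) c(0, -eps * beta * s[2]),
    function(s) c(0, 0.5 * s[2]), cfg)
  expect_true(all(traj$w == 0))
})

test_that("stationary variance of the transformed linear system matches the OU law", {
  M <- ref_eq$M
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  cfg <- sim_config(dt = 0.01, T = 5000, seed = 11,
                    initial_state = c(0, 0))
  lin <- integrate_stratonovich(
    function(s) c(M[1, 1] * s[1] + M[1, 2] * s[2],
                  M[2, 1] * s[1] + M[2, 2] * s[2]),
    function(s) c(0, 0.01), cfg)
  Y <- cbind(lin$v, lin$w) %*% t(nf$Q_inv)
  burn <- seq_len(20000)
  v_theory <- nf$sigma_eff^2 / (2 * nf$mu)
  expect_equal(var(Y[-burn, 1]), v_theory, tolerance = 0.05)
  expect_equal(var(Y[-burn, 2]), v_theory, tolerance = 0.05)
})

test_that("first-passage sampling censors and orders correctly", {
  expect_error(
    sample_isi_fhn(ref_params, noise_spec(sigma0 = 0),
                   sim_config(dt = 0.01, T = 5), n_samples = 3, seed = 1),
    "all runs censored")
  s <- sample_isi_fhn(ref_params, noise_spec(sigma0 = 0.02),
                      sim_config(dt = 0.01, T = 600), n_samples = 150,
                      seed = 8)
  expect_true(all(s$isi > 0))
  expect_identical(length(s$times), 150L)
  expect_identical(sum(is.na(s$times)), s$n_censored)
})

test_that("mean first-firing time decreases with the noise amplitude", {
  hi <- sample_isi_fhn(ref_params, noise_spec(sigma0 = 0.02),
                       sim_config(dt = 0.01, T = 2000), 200, seed = 9)
  lo <- sample_isi_fhn(ref_params, noise_spec(sigma0 = 0.008),
                       sim_config(dt = 0.01, T = 2000), 200, seed = 10)
  expect_lt(mean(hi$isi), mean(lo$isi))
  ## unimodal right-skewed shape: mean above median, both positive
  expect_gt(mean(lo$isi), stats::median(lo$isi))
})
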
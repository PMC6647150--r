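test_that("the transform reproduces the printed constants from M alone", {
  nf <- ref_nf_unit
  expect_lt(max(abs(nf$Q_inv %*% ref_eq$M %*% nf$Q - nf$A)), 1e-10)
  expect_equal(nf$h_e[1], 1.27722, tolerance = 1e-4)
  ## the second component is exactly 1/m21 = 1/epsilon
  expect_equal(nf$h_e[2], 1 / ref_params$epsilon, tolerance = 1e-12)
  expect_equal(sum(nf$h_e^2), 157.881, tolerance = 1e-3)
  expect_equal(nf$sigma_eff, 8.88486, tolerance = 1e-4)
  ## consistency identities across the printed constants
  expect_equal(sum(nf$h_e^2), -ref_eq$M[1, 2] / (ref_eq$M[2, 1] * ref_eq$nu^2))
  expect_equal(nf$transform_factor^2, sum(nf$h_e^2))
  expect_equal(sum(diag(nf$C %*% t(nf$C))), sum(nf$h_e^2))
  ## sigma0 scales the noise quantities linearly
  nf2 <- build_normal_form(ref_eq, sigma0 = 0.01)
  expect_equal(nf2$h_e, 0.01 * nf$h_e)
  expect_equal(nf2$sigma_eff, 0.01 * nf$sigma_eff)
  expect_equal(nf2$transform_factor, nf$transform_factor)
})

test_that("a singular recovery coupling invalidates the transform", {
  eq_bad <- list(M = matrix(c(-0.1, 0, -1, -0.06), 2, 2),
                 mu = 0.08, nu = 0.1)
  expect_error(build_normal_form(eq_bad), "m21")
})

test_that("the similarity holds across random excitable parameter sets", {
  n_ok <- 0
  for (p in random_excitable_params(100, seed = 77)) {
    eq <- tryCatch(equilibrium_analysis(p), error = function(e) NULL)
    if (is.null(eq)) next
    nf <- build_normal_form(eq)
    expect_lt(max(abs(nf$Q_inv %*% eq$M %*% nf$Q - nf$A)), 1e-10)
    expect_equal(nf$transform_factor^2, sum(nf$h_e^2), tolerance = 1e-12)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 50)
})

test_that("the averaged OU path has the stationary variance sigma^2/(2 mu)", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  ap <- averaged_ou_path(nf, y0 = c(0, 0),
                         config = sim_config(dt = 0.05, T = 20000, seed = 21))
  burn <- seq_len(4000)
  v_theory <- nf$sigma_eff^2 / (2 * nf$mu)
  expect_equal(var(ap$Y[-burn, 1]), v_theory, tolerance = 0.1)
  expect_equal(var(ap$Y[-burn, 2]), v_theory, tolerance = 0.1)
})

test_that("the noiseless averaged path is an exact contracting rotation", {
  nf0 <- build_normal_form(ref_eq, sigma0 = 0)
  y0 <- c(0.3, 0.1)
  ap <- averaged_ou_path(nf0, y0 = y0, config = sim_config(dt = 0.1, T = 50))
  expect_equal(sqrt(rowSums(ap$Y^2)),
               sqrt(sum(y0^2)) * exp(-ref_eq$mu * ap$times),
               tolerance = 1e-12)
})

test_that("the averaged path spectrum peaks at the rotation frequency", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  ap <- averaged_ou_path(nf, y0 = c(0, 0),
                         config = sim_config(dt = 0.01, T = 2000, seed = 22))
  ps <- psd_estimate(ap$Y[, 1], dt = 0.01, segment = 16384)
  fpeak <- ps$frequencies[which.max(ps$power)]
  expect_equal(fpeak, ref_eq$nu / (2 * pi), tolerance = 0.2)
})

test_that("the stationary radial law is Rayleigh with scale sigma/sqrt(2 mu)", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  samples <- unlist(lapply(1:200, function(k) {
    r <- simulate_radial_ou(nf, R0 = 0,
                            config = sim_config(dt = 1, T = 300,
                                                seed = 5000 + k))
    r$R[match(c(100, 200, 300), r$times)]
  }))
  scl <- nf$sigma_eff / sqrt(2 * nf$mu)
  ks <- suppressWarnings(
    stats::ks.test(samples, function(q) 1 - exp(-q^2 / (2 * scl^2))))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the two radial backends agree in law", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  scl <- nf$sigma_eff / sqrt(2 * nf$mu)
  draw <- function(backend, dt, seed0) {
    unlist(lapply(1:700, function(k) {
      r <- simulate_radial_ou(nf, R0 = 0.4,
                              config = sim_config(dt = dt, T = 250,
                                                  seed = seed0 + k),
                              backend = backend)
      idx <- round(c(150, 200, 250) / dt) + 1L
      r$R[idx]
    }))
  }
  a <- draw("norm", dt = 0.5, seed0 = 6000)
  b <- draw("direct", dt = 0.02, seed0 = 7000)
  ## each backend against the closed-form stationary law
  ray <- function(q) 1 - exp(-q^2 / (2 * scl^2))
  expect_lt(unname(suppressWarnings(stats::ks.test(a, ray))$statistic), 0.05)
  expect_lt(unname(suppressWarnings(stats::ks.test(b, ray))$statistic), 0.05)
  ## and against each other
  expect_lt(unname(suppressWarnings(stats::ks.test(a, b))$statistic), 0.05)
})

test_that("the noiseless radial path decays at rate mu and recovers it", {
  nf0 <- build_normal_form(ref_eq, sigma0 = 0)
  r <- simulate_radial_ou(nf0, R0 = 0.5, config = sim_config(dt = 0.1, T = 50))
  expect_equal(r$R, 0.5 * exp(-ref_eq$mu * r$times), tolerance = 1e-12)
  mu_hat <- -unname(coef(lm(log(r$R) ~ r$times))[2])
  expect_equal(mu_hat, ref_eq$mu, tolerance = 0.01)
})

test_that("polar radial coefficients average to the effective amplitude", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  h <- nf$h_e
  tt <- seq(0, 2 * pi / ref_eq$nu, length.out = 20001)[-20001]
  proj <- h[1] * sin(ref_eq$nu * tt) + h[2] * cos(ref_eq$nu * tt)
  ## time-average of the squared diffusion over one period is ||h||^2/2
  expect_equal(mean(proj^2), sum(h^2) / 2, tolerance = 1e-6)
  expect_equal(sum(h^2) / 2, nf$sigma_eff^2, tolerance = 1e-12)
  ## drift numerator vanishes when the phase aligns with h_e
  theta_aligned <- h / sqrt(sum(h^2))
  expect_equal(sum(h^2) - sum(h * theta_aligned)^2, 0, tolerance = 1e-12)
})

test_that("polar and radial-OU paths share their spectral shape", {
  nf <- build_normal_form(ref_eq, sigma0 = 0.01)
  cfg <- function(seed) sim_config(dt = 0.01, T = 2000, seed = seed)
  r43 <- simulate_radial_ou(nf, R0 = 0.3, config = cfg(31))
  r44 <- simulate_polar_radial(nf, R0 = 0.3, config = cfg(32))
  cmp <- psd_compare(list(psd_estimate(r43$R, 0.01),
                          psd_estimate(r44$R, 0.01)))
  expect_lt(cmp$gaps[1, 2], 0.1)
  expect_true(all(r44$R > 0))
})
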
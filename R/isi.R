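## Hazard-rate firing mechanism, Monte-Carlo ISI density and distributional
## comparison with the full model.

#' Hazard specification for the LIF firing mechanism
#'
#' The conditional firing probability per cycle, evaluated at radius
#' \code{r}, divided by the mean cycle duration \code{2 pi / nu}, gives the
#' hazard rate
#' \deqn{\alpha(r) = \frac{\nu}{2\pi} \frac{1}{1 + e^{(a^* - r)/b^*}},}
#' bounded above by the cycle rate \code{nu / (2 pi)}.
#'
#' @param a_star logistic location in normal-form coordinates.
#' @param b_star logistic scale (> 0).
#' @param nu rotation rate.
#' @return An object of class \code{"hazard_spec"}.
#' @export
hazard_spec <- function(a_star, b_star, nu) {
  if (b_star <= 0) stop("'b_star' must be positive: invalid hazard spec")
  stopifnot(nu > 0)
  structure(list(a_star = a_star, b_star = b_star, nu = nu,
                 rate_scale = nu / (2 * pi)),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat(sprintf("hazard: ceiling nu/2pi = %.6g, a* = %.6g, b* = %.6g\n",
              x$rate_scale, x$a_star, x$b_star))
  invisible(x)
}

#' Evaluate the hazard rate
#'
#' @param r radius (>= 0, vectorised).
#' @param spec a \code{\link{hazard_spec}}.
#' @return Hazard values in \code{[0, nu/(2 pi)]}.
#' @export
hazard <- function(r, spec) {
  if (any(r < 0)) stop("'r' must be non-negative")
  spec$rate_scale / (1 + exp((spec$a_star - r) / spec$b_star))
}

#' Monte-Carlo ISI density of the LIF reduction
#'
#' Estimates the first-firing-time density
#' \deqn{g(t) = E\big(\alpha(R_t)\, e^{-\int_0^t \alpha(R_s) ds}\big)}
#' by averaging over \code{M} radial realizations, the inner integral
#' approximated by the trapezoidal rule on \code{n} subdivisions of
#' \code{[0, t]}:
#' \deqn{g(t) \approx \frac{1}{M}\sum_m \alpha(R^{(m)}_t)
#'   \exp\Big(-\frac{t}{n}\sum_{i=1}^n
#'   \tfrac{\alpha(R^{(m)}_{it/n}) + \alpha(R^{(m)}_{(i-1)t/n})}{2}\Big).}
#' The same \code{M} paths serve every evaluation time: each path is
#' sampled once, by the exact Gaussian transition of the underlying 2-D OU
#' process (the singularity-free norm construction), at the union of all
#' subdivision times, started at \code{R_0 = 0} (reset at the fixed
#' point).
#'
#' @param spec a \code{\link{hazard_spec}}.
#' @param nf a \code{\link{build_normal_form}} object carrying
#'   \code{sigma_eff} and \code{mu} (build it with the actual
#'   \code{sigma0}).
#' @param t_grid positive, increasing evaluation times.  Default: 200
#'   points geometrically spaced on [1, 2000].
#' @param M number of radial realizations (default 1000).
#' @param n trapezoid subdivisions per evaluation time (default 10).
#' @param seed RNG seed.
#' @param R0 initial radius (default 0, the image of the fixed point).
#' @return An object of class \code{"isi_density"}: list with
#'   \code{t_grid}, \code{g}, \code{M}, \code{n}, \code{seed}.
#' @export
isi_density <- function(spec, nf,
                        t_grid = exp(seq(log(1), log(2000), length.out = 200)),
                        M = 1000L, n = 10L, seed = 1L, R0 = 0) {
  stopifnot(all(t_grid > 0), !is.unsorted(t_grid), M >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ## union of all subdivision times i*t/n across the grid
  sub <- outer(t_grid, seq(0, n) / n)           # |t_grid| x (n+1)
  all_t <- sort(unique(c(0, as.numeric(sub))))
  R <- .radial_ensemble(nf, R0, all_t, M)       # M x |all_t|
  al <- hazard(R, spec)
  idx <- matrix(match(as.numeric(sub), all_t), nrow(sub), ncol(sub))
  g <- numeric(length(t_grid))
  for (k in seq_along(t_grid)) {
    a_k <- al[, idx[k, ], drop = FALSE]          # M x (n+1)
    ## trapezoid: (t/n) * sum of midpoints of consecutive alpha values
    integral <- (t_grid[k] / n) *
      (rowSums(a_k) - 0.5 * (a_k[, 1] + a_k[, n + 1]))
    g[k] <- mean(a_k[, n + 1] * exp(-integral))
  }
  structure(list(t_grid = t_grid, g = g, M = M, n = n, seed = seed),
            class = "isi_density")
}

#' @export
print.isi_density <- function(x, ...) {
  cum <- sum(diff(x$t_grid) * (x$g[-1] + x$g[-length(x$g)]) / 2)
  cat(sprintf(
    "ISI density estimate: %d times, M = %d, n = %d, integral ~ %.3f\n",
    length(x$t_grid), x$M, x$n, cum))
  invisible(x)
}

#' Sample LIF interspike intervals by hazard thinning
#'
#' Draws first-firing times from the LIF reduction: along each simulated
#' radial path (exact-transition norm construction, reset at
#' \code{R_0 = 0}) the neuron fires in a step of length \code{dt} with
#' probability \code{1 - exp(-alpha(R_t) dt)}, exact for a hazard held
#' constant within the step.  \code{dt} must keep
#' \code{dt * nu/(2 pi)} well below 1 (checked).
#'
#' @param spec a \code{\link{hazard_spec}}.
#' @param nf a \code{\link{build_normal_form}} object (actual
#'   \code{sigma0}).
#' @param n_samples number of firing times to draw.
#' @param dt thinning step (default 0.05).
#' @param horizon censoring horizon (default 5000).
#' @param seed RNG seed.
#' @return An object of class \code{"fhn_isi"} (same shape as
#'   \code{\link{sample_isi_fhn}}).
#' @export
sample_isi_lif <- function(spec, nf, n_samples, dt = 0.05, horizon = 5000,
                           seed = 1L) {
  stopifnot(n_samples >= 1)
  if (dt * spec$rate_scale > 0.05)
    stop("'dt' too coarse for thinning: dt * max hazard must be << 1")
  if (!is.null(seed)) set.seed(seed)
  mu <- nf$mu; scale <- nf$sigma_eff / sqrt(mu)
  e <- exp(-mu * dt); sd_ou <- sqrt((1 - exp(-2 * mu * dt)) / 2)
  S1 <- numeric(n_samples); S2 <- numeric(n_samples)   # R0 = 0
  t_fire <- rep(NA_real_, n_samples)
  n_steps <- ceiling(horizon / dt)
  for (s in seq_len(n_steps)) {
    act <- which(is.na(t_fire))
    if (!length(act)) break
    m <- length(act)
    S1[act] <- S1[act] * e + stats::rnorm(m, 0, sd_ou)
    S2[act] <- S2[act] * e + stats::rnorm(m, 0, sd_ou)
    R <- scale * sqrt(S1[act]^2 + S2[act]^2)
    fire <- stats::runif(m) < 1 - exp(-hazard(R, spec) * dt)
    t_fire[act[fire]] <- s * dt
  }
  if (all(is.na(t_fire)))
    stop("all runs censored: hazard too small for this horizon")
  structure(list(isi = t_fire[!is.na(t_fire)], times = t_fire,
                 n_censored = sum(is.na(t_fire)), horizon = horizon,
                 seed = seed),
            class = "fhn_isi")
}

#' Compare two ISI samples
#'
#' Two-sample Kolmogorov-Smirnov statistic plus a decile
#' quantile-quantile table.  Accepts \code{"fhn_isi"} objects or plain
#' numeric vectors; censored trials are excluded.
#'
#' @param x,y ISI samples.
#' @return An object of class \code{"isi_comparison"}: list with
#'   \code{ks_statistic}, \code{p_value}, \code{quantiles} (3-column
#'   data frame), \code{n_x}, \code{n_y}.
#' @export
compare_isi <- function(x, y) {
  xs <- if (inherits(x, "fhn_isi")) x$isi else as.numeric(x)
  ys <- if (inherits(y, "fhn_isi")) y$isi else as.numeric(y)
  stopifnot(length(xs) >= 1, length(ys) >= 1)
  kt <- suppressWarnings(stats::ks.test(xs, ys))
  probs <- seq(0.1, 0.9, by = 0.1)
  structure(list(ks_statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 quantiles = data.frame(
                   prob = probs,
                   q_x = unname(stats::quantile(xs, probs)),
                   q_y = unname(stats::quantile(ys, probs))),
                 n_x = length(xs), n_y = length(ys)),
            class = "isi_comparison")
}

#' @export
print.isi_comparison <- function(x, ...) {
  cat(sprintf("ISI comparison: KS = %.4f (p = %.3g), n = %d vs %d\n",
              x$ks_statistic, x$p_value, x$n_x, x$n_y))
  print(x$quantiles, row.names = FALSE)
  invisible(x)
}
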
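## Monte-Carlo calibration of the conditional firing probability along the
## line L below the fixed point, sigmoid regression and transformation to
## normal-form coordinates.

#' Build the firing-probability grid on the line L
#'
#' The line \code{L = ((v_e, w) : w <= w_e)} runs straight down from the
#' fixed point.  The grid places 35 starting points
#' \code{L_i = (v_e, w_e - i delta)}, \code{i = 0..34}, with spacing
#' \code{delta = |w_e + separatrix_w| / 20}, so that the separatrix
#' reference sits at \code{i = 20}.  The constant \code{separatrix_w}
#' (default 0.453) is specific to the reference parameter set: it is the
#' w-level at which L meets the separatrix between sub-threshold return
#' and spiking.
#'
#' @param equilibrium an \code{"fhn_equilibrium"} from
#'   \code{\link{equilibrium_analysis}}.
#' @param separatrix_w separatrix reference level on w (positive constant
#'   c in \code{|w_e + c|}).
#' @param n_points number of grid points (default 35).
#' @return An object of class \code{"firing_grid"}: list with
#'   \code{delta}, \code{l} (distances \code{l_i}), \code{points}
#'   (n x 2 matrix of \code{L_i}), \code{separatrix_distance}.
#' @export
build_firing_grid <- function(equilibrium, separatrix_w = 0.453,
                              n_points = 35L) {
  w_e <- equilibrium$w_e; v_e <- equilibrium$v_e
  sep <- abs(w_e + separatrix_w)
  delta <- sep / 20
  i <- seq_len(n_points) - 1L
  l <- i * delta
  structure(list(delta = delta, l = l,
                 points = cbind(v = rep(v_e, n_points), w = w_e - l),
                 separatrix_distance = sep),
            class = "firing_grid")
}

#' Estimate the conditional firing probability from one starting point
#'
#' Runs \code{n_trials} short stochastic paths from the starting point and
#' records for each whether a spike (upward crossing of \code{v =
#' threshold}) occurs within the first cycle of the path around the fixed
#' point.  "One cycle" is measured as 2*pi of accumulated unwrapped angle
#' of the transformed state \code{Y = Q^-1 (X - X_e)}, whose rotation is
#' nearly uniform at rate \code{nu}; a hard time cap of
#' \code{cap_cycles * 2 pi / nu} guards against paths stalled near the
#' origin, and trials that neither spike nor complete the cycle within the
#' cap are counted as non-spikes (their frequency is reported).
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param noise a \code{\link{noise_spec}} object.
#' @param point numeric length-2 starting point \code{(v0, w0)}.
#' @param n_trials number of Monte-Carlo trials (default 1000).
#' @param config a \code{\link{sim_config}}; only \code{dt} is used.
#' @param equilibrium optional precomputed \code{"fhn_equilibrium"}.
#' @param threshold firing threshold on \code{v}.
#' @param cap_cycles time cap in units of the rotation period.
#' @param seed RNG seed.
#' @return A list with \code{p_hat}, \code{n_spikes}, \code{n_trials},
#'   \code{n_capped} (trials stopped by the time cap).
#' @export
estimate_firing_probability <- function(params, noise, point,
                                        n_trials = 1000L,
                                        config = sim_config(),
                                        equilibrium = NULL,
                                        threshold = 0, cap_cycles = 3,
                                        seed = config$seed) {
  stopifnot(n_trials >= 1)
  if (is.null(equilibrium)) equilibrium <- equilibrium_analysis(params)
  nf <- build_normal_form(equilibrium, sigma0 = 1)
  Qi <- nf$Q_inv
  v_e <- equilibrium$v_e; w_e <- equilibrium$w_e
  dt <- config$dt
  cap_steps <- ceiling(cap_cycles * (2 * pi / equilibrium$nu) / dt)
  if (!is.null(seed)) set.seed(seed)
  v <- rep(point[1], n_trials); w <- rep(point[2], n_trials)
  fired <- logical(n_trials); done <- logical(n_trials)
  y1 <- Qi[1, 1] * (v - v_e) + Qi[1, 2] * (w - w_e)
  y2 <- Qi[2, 1] * (v - v_e) + Qi[2, 2] * (w - w_e)
  th_prev <- atan2(y2, y1)
  cum <- numeric(n_trials)
  for (s in seq_len(cap_steps)) {
    act <- which(!done)
    if (!length(act)) break
    dW <- stats::rnorm(length(act), 0, sqrt(dt))
    st <- .fhn_heun_step(v[act], w[act], dW, params, noise, dt)
    newly <- !fired[act] & v[act] <= threshold & st$v > threshold
    fired[act[newly]] <- TRUE
    y1 <- Qi[1, 1] * (st$v - v_e) + Qi[1, 2] * (st$w - w_e)
    y2 <- Qi[2, 1] * (st$v - v_e) + Qi[2, 2] * (st$w - w_e)
    th <- atan2(y2, y1)
    dth <- th - th_prev[act]
    dth <- dth - 2 * pi * round(dth / (2 * pi))   # unwrap
    cum[act] <- cum[act] + dth
    th_prev[act] <- th
    done[act] <- fired[act] | abs(cum[act]) >= 2 * pi
    v[act] <- st$v; w[act] <- st$w
  }
  list(p_hat = mean(fired), n_spikes = sum(fired), n_trials = n_trials,
       n_capped = sum(!done))
}

#' Fit the two-parameter logistic firing-probability curve
#'
#' Least-squares fit of \code{p(l) = 1 / (1 + exp((a - l)/b))} to the
#' estimated probabilities (unweighted by default, matching a plain
#' non-linear regression of the grid estimates; binomial weighting by
#' trial count is available).  Initial values: \code{a0} is the first grid
#' distance at which \code{p_hat} exceeds 1/2 and \code{b0 = 5 sigma0};
#' a fit with non-positive scale is rejected as degenerate.  By
#' construction \code{p(a) = 1/2}, so \code{a} is the distance at which
#' firing is a coin flip.
#'
#' @param l grid distances.
#' @param p_hat estimated probabilities at \code{l}.
#' @param sigma0 noise amplitude (sets the initial scale \code{b0}).
#' @param weights optional trial counts for binomial weighting.
#' @return A list with \code{a}, \code{b}, \code{rss}, \code{converged},
#'   \code{fitted}.
#' @export
fit_sigmoid <- function(l, p_hat, sigma0 = 0.01, weights = NULL) {
  stopifnot(length(l) == length(p_hat), length(l) >= 4)
  if (stats::sd(p_hat) == 0)
    stop("degenerate firing probabilities: no spread to fit")
  a0 <- l[which(p_hat > 0.5)[1]]
  if (is.na(a0)) a0 <- max(l)
  b0 <- max(5 * sigma0, 1e-6)
  df <- data.frame(l = l, p = p_hat)
  ## plogis((l - a)/b) = 1/(1 + exp((a - l)/b)), overflow-safe for tiny b
  args <- list(p ~ stats::plogis((l - a) / b), data = df,
               start = list(a = a0, b = b0),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
  if (inherits(fit, "error"))
    stop("sigmoid fit failed to converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  ## increasing data cannot be fit by a flipped (b < 0) sigmoid; a
  ## non-positive scale indicates degenerate input
  if (cf["b"] <= 0)
    stop("sigmoid fit degenerate: non-positive scale b = ", cf["b"])
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       rss = sum(stats::resid(fit)^2),
       converged = fit$convInfo$isConv %||% TRUE,
       fitted = stats::fitted(fit))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Transform the fitted sigmoid to normal-form coordinates
#'
#' A distance \code{l} along L maps to the radius
#' \code{r = transform_factor * l} in normal-form coordinates, so the
#' logistic parameters transform linearly:
#' \code{a* = transform_factor * a}, \code{b* = transform_factor * b}
#' (the logistic shape is invariant under the linear map, so
#' \code{a*/b* = a/b}).
#'
#' @param fit a list with \code{a} and \code{b} (from
#'   \code{\link{fit_sigmoid}}).
#' @param nf a \code{\link{build_normal_form}} object.
#' @return The fit list extended with \code{a_star}, \code{b_star}.
#' @export
transform_fit <- function(fit, nf) {
  fit$a_star <- nf$transform_factor * fit$a
  fit$b_star <- nf$transform_factor * fit$b
  fit
}

#' Calibrate the firing mechanism at one noise amplitude
#'
#' Full calibration pipeline for a single \code{sigma0}: build the 35-point
#' grid on L, estimate the conditional firing probability at every grid
#' point by Monte Carlo, fit the logistic curve, and transform the
#' parameters to normal-form coordinates.  Additive noise is the
#' calibrated default; multiplicative calibration runs but is unvalidated.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param sigma0 noise amplitude.
#' @param n_trials trials per grid point (default 1000).
#' @param config a \code{\link{sim_config}}; only \code{dt} is used.
#' @param kind noise kind (default additive).
#' @param separatrix_w separatrix reference for the grid.
#' @param seed root seed; grid point \code{i} uses \code{seed + i}.
#' @param weights \code{"none"} (default) or \code{"binomial"}.
#' @return An object of class \code{"firing_fit"}: list with
#'   \code{sigma0}, \code{grid}, \code{p_hat}, \code{n_trials},
#'   \code{n_capped}, \code{a}, \code{b}, \code{a_star}, \code{b_star},
#'   \code{rss}, \code{converged}, \code{seed}.
#' @export
calibrate_firing <- function(params, sigma0, n_trials = 1000L,
                             config = sim_config(), kind = "additive",
                             separatrix_w = 0.453, seed = 1L,
                             weights = c("none", "binomial")) {
  weights <- match.arg(weights)
  noise <- noise_spec(kind, sigma0)
  eq <- equilibrium_analysis(params)
  nf <- build_normal_form(eq, sigma0 = 1)
  grid <- build_firing_grid(eq, separatrix_w)
  n_pts <- length(grid$l)
  p_hat <- numeric(n_pts); n_capped <- integer(n_pts)
  for (i in seq_len(n_pts)) {
    est <- estimate_firing_probability(
      params, noise, grid$points[i, ], n_trials = n_trials,
      config = config, equilibrium = eq, seed = seed + i - 1L)
    p_hat[i] <- est$p_hat
    n_capped[i] <- est$n_capped
  }
  w <- if (weights == "binomial") rep(n_trials, n_pts) else NULL
  fit <- fit_sigmoid(grid$l, p_hat, sigma0, weights = w)
  fit <- transform_fit(fit, nf)
  structure(list(sigma0 = sigma0, grid = grid, p_hat = p_hat,
                 n_trials = n_trials, n_capped = n_capped,
                 a = fit$a, b = fit$b,
                 a_star = fit$a_star, b_star = fit$b_star,
                 rss = fit$rss, converged = fit$converged, seed = seed),
            class = "firing_fit")
}

#' @export
print.firing_fit <- function(x, ...) {
  cat(sprintf("firing calibration at sigma0 = %g (%d trials/point)\n",
              x$sigma0, x$n_trials))
  cat(sprintf("  a = %.6f  b = %.6f  a* = %.6f  b* = %.6f\n",
              x$a, x$b, x$a_star, x$b_star))
  invisible(x)
}
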
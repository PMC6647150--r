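## Stratonovich SDE integration, spike detection, first-passage sampling.

#' Stratonovich SDE integration (Euler-Heun)
#'
#' Integrates \code{dX = F(X) dt + H(X) o dB} for a 2-D state by the
#' Euler-Heun predictor-corrector scheme, which is consistent with the
#' Stratonovich interpretation for constant (additive) and linear
#' (multiplicative) diffusion fields: predictor
#' \code{Xp = X + F(X) dt + H(X) dW}, corrector
#' \code{X' = X + (F(X) + F(Xp)) dt/2 + (H(X) + H(Xp)) dW/2}.
#' For additive noise the diffusion average is exact and the scheme
#' coincides in law with Euler-Maruyama.
#'
#' The Brownian increments actually used are returned with the trajectory
#' and can be replayed by passing them back through \code{increments}; two
#' systems integrated on the same increments are coupled by common noise
#' (the contract behind the linearization error experiments).
#'
#' @param drift function \code{state -> c(f, g)}.
#' @param diffusion function \code{state -> c(h1, h2)}, the diffusion
#'   vector multiplying the scalar Brownian increment.
#' @param config a \code{\link{sim_config}}; \code{config$seed} (if any)
#'   seeds the increments unless \code{increments} is supplied.
#' @param increments optional numeric vector of pre-drawn Brownian
#'   increments (length = number of steps) for common-noise replay.
#' @return An object of class \code{"fhn_trajectory"}: list with
#'   \code{times}, \code{v}, \code{w}, \code{noise_increments}, \code{dt},
#'   \code{scheme}, \code{seed}.
#' @export
integrate_stratonovich <- function(drift, diffusion, config,
                                   increments = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$dt
  n_steps <- floor(config$T / dt + 1e-9)
  if (is.null(increments)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    increments <- stats::rnorm(n_steps, 0, sqrt(dt))
  } else {
    stopifnot(length(increments) == n_steps)
  }
  v <- numeric(n_steps + 1L); w <- numeric(n_steps + 1L)
  x <- config$initial_state
  v[1] <- x[1]; w[1] <- x[2]
  heun <- config$scheme == "euler_heun"
  for (s in seq_len(n_steps)) {
    dW <- increments[s]
    f1 <- drift(x); h1 <- diffusion(x)
    if (heun) {
      xp <- x + f1 * dt + h1 * dW
      f2 <- drift(xp); h2 <- diffusion(xp)
      x <- x + 0.5 * (f1 + f2) * dt + 0.5 * (h1 + h2) * dW
    } else {
      x <- x + f1 * dt + h1 * dW
    }
    if (!all(is.finite(x)))
      stop("non-finite state at step ", s, " (t = ", s * dt, ")")
    v[s + 1L] <- x[1]; w[s + 1L] <- x[2]
  }
  structure(list(times = seq(0, by = dt, length.out = n_steps + 1L),
                 v = v, w = w, noise_increments = increments,
                 dt = dt, scheme = config$scheme, seed = config$seed),
            class = "fhn_trajectory")
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  cat(sprintf("FHN trajectory: %d steps, dt = %g, T = %g, scheme = %s\n",
              length(x$times) - 1L, x$dt, max(x$times), x$scheme))
  invisible(x)
}

## diffusion vector of the channel noise: (0, sigma0) additive,
## (0, sigma0 * w) multiplicative
.noise_field <- function(noise) {
  if (noise$kind == "additive") {
    s0 <- noise$sigma0
    function(state) c(0, s0)
  } else {
    s0 <- noise$sigma0
    function(state) c(0, s0 * state[2])
  }
}

#' Simulate the stochastic FHN model
#'
#' Wraps \code{\link{integrate_stratonovich}} with the FHN drift
#' (\code{\link{drift_field}}) and the channel-noise diffusion of
#' \code{noise}: \code{H = (0, sigma0)} for additive and
#' \code{H = (0, sigma0 w)} for multiplicative noise, both interpreted in
#' the Stratonovich sense.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param noise a \code{\link{noise_spec}} object.
#' @param config a \code{\link{sim_config}} object.
#' @param increments optional Brownian increments for common-noise replay.
#' @return An \code{"fhn_trajectory"} with \code{params} and \code{noise}
#'   attached as attributes.
#' @export
simulate_fhn <- function(params, noise, config, increments = NULL) {
  traj <- integrate_stratonovich(function(s) drift_field(s, params),
                                 .noise_field(noise), config, increments)
  attr(traj, "params") <- params
  attr(traj, "noise") <- noise
  traj
}

#' Detect spikes by threshold crossing
#'
#' A spike is an upward crossing of \code{v = threshold}; the crossing time
#' is linearly interpolated between the bracketing samples.  After a spike
#' the detector is disarmed until \code{v} re-enters \code{v < rearm}
#' (refractory exclusion), so numerical jitter at the threshold cannot
#' produce double counts: one spike per excursion.
#'
#' @param traj an \code{"fhn_trajectory"} (or any list with \code{times}
#'   and \code{v}).
#' @param threshold the firing threshold on \code{v} (default 0).
#' @param rearm re-arming level; defaults to the fixed-point \code{v_e}
#'   when the trajectory carries its parameters, otherwise to
#'   \code{threshold}.
#' @return An object of class \code{"spike_record"}: list with
#'   \code{spike_times} (interpolated, strictly increasing) and \code{isi}
#'   (successive differences).
#' @export
detect_spikes <- function(traj, threshold = 0, rearm = NULL) {
  v <- traj$v; times <- traj$times
  if (is.null(rearm)) {
    params <- attr(traj, "params")
    rearm <- if (!is.null(params)) fixed_point(params)$v_e else threshold
  }
  n <- length(v)
  up <- which(v[-n] <= threshold & v[-1] > threshold)
  spike_times <- numeric(0)
  armed_from <- 1L
  for (i in up) {
    if (i < armed_from) next
    tc <- times[i] + (times[i + 1L] - times[i]) *
      (threshold - v[i]) / (v[i + 1L] - v[i])
    spike_times <- c(spike_times, tc)
    below <- which(v[(i + 1L):n] < rearm)
    if (!length(below)) break
    armed_from <- i + below[1L]
  }
  structure(list(spike_times = spike_times,
                 isi = diff(spike_times),
                 threshold = threshold, rearm = rearm),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike record: %d spikes (threshold v = %g)\n",
              length(x$spike_times), x$threshold))
  invisible(x)
}

## One Euler-Heun step for an ensemble of FHN states (vectors v, w and
## increments dW of equal length). Used by the vectorized first-passage
## and firing-probability samplers.
.fhn_heun_step <- function(v, w, dW, params, noise, dt) {
  I <- params$I; alpha <- params$alpha; beta <- params$beta
  eps <- params$epsilon; s0 <- noise$sigma0
  mult <- noise$kind == "multiplicative"
  f1 <- v - v^3 / 3 - w + I
  g1 <- eps * (v + alpha - beta * w)
  h1 <- if (mult) s0 * w else s0
  vp <- v + f1 * dt
  wp <- w + g1 * dt + h1 * dW
  f2 <- vp - vp^3 / 3 - wp + I
  g2 <- eps * (vp + alpha - beta * wp)
  h2 <- if (mult) s0 * wp else s0
  list(v = v + 0.5 * (f1 + f2) * dt,
       w = w + 0.5 * (g1 + g2) * dt + 0.5 * (h1 + h2) * dW)
}

#' Sample first-firing times of the stochastic FHN model
#'
#' Draws \code{n_samples} independent first-firing times: each trial starts
#' a fresh path at the fixed point \code{X_e} (the reset rule) and runs
#' until \code{v} crosses the firing threshold upward or the horizon
#' \code{config$T} is reached, in which case the trial is censored.  Trials
#' are advanced together as a vectorized ensemble; all randomness derives
#' from \code{seed}.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param noise a \code{\link{noise_spec}} object.
#' @param config a \code{\link{sim_config}}; \code{dt} and \code{T} are
#'   used (the initial state is overridden by \code{X_e}).
#' @param n_samples number of trials (>= 1).
#' @param threshold firing threshold on \code{v} (default 0).
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @return An object of class \code{"fhn_isi"}: list with \code{isi}
#'   (uncensored first-firing times), \code{times} (all trials,
#'   \code{NA} = censored), \code{n_censored}, \code{horizon},
#'   \code{seed}.
#' @export
sample_isi_fhn <- function(params, noise, config, n_samples,
                           threshold = 0, seed = config$seed) {
  stopifnot(n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  fp <- fixed_point(params)
  dt <- config$dt
  n_steps <- floor(config$T / dt + 1e-9)
  v <- rep(fp$v_e, n_samples); w <- rep(fp$w_e, n_samples)
  t_fire <- rep(NA_real_, n_samples)
  active <- seq_len(n_samples)
  for (s in seq_len(n_steps)) {
    dW <- stats::rnorm(length(active), 0, sqrt(dt))
    st <- .fhn_heun_step(v[active], w[active], dW, params, noise, dt)
    hit <- v[active] <= threshold & st$v > threshold
    t_fire[active[hit]] <- s * dt
    v[active] <- st$v; w[active] <- st$w
    if (any(hit)) {
      active <- active[!hit]
      if (!length(active)) break
    }
  }
  if (all(is.na(t_fire)))
    stop("all runs censored: no firing at this amplitude/horizon")
  structure(list(isi = t_fire[!is.na(t_fire)], times = t_fire,
                 n_censored = sum(is.na(t_fire)), horizon = config$T,
                 seed = seed),
            class = "fhn_isi")
}

#' @export
print.fhn_isi <- function(x, ...) {
  cat(sprintf(
    "first-firing sample: n = %d (%d censored at T = %g), mean ISI = %.4g\n",
    length(x$times), x$n_censored, x$horizon, mean(x$isi)))
  invisible(x)
}
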
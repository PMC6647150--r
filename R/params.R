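#' Model parameters for the FitzHugh-Nagumo neuron
#'
#' Bundles the four dimensionless parameters of the FitzHugh-Nagumo (FHN)
#' model: the constant bias current \code{I}, the recovery offset
#' \code{alpha}, the recovery slope \code{beta} and the time-scale
#' separation \code{epsilon} (ratio of the fast to the slow time scale,
#' \code{0 < epsilon < 1}).
#'
#' The defaults are the excitable-regime reference set used throughout the
#' package: \code{I = 0.265}, \code{alpha = 0.7}, \code{beta = 0.75},
#' \code{epsilon = 0.08}, for which the system has a unique stable focus
#' at approximately \code{(-1.00125, -0.401665)}.
#'
#' Validation is permissive: values outside the excitable regime produce
#' warnings rather than errors, so that the exploration tools remain usable;
#' only structurally impossible values (\code{beta <= 0},
#' \code{epsilon <= 0}) are rejected.
#'
#' @param I bias current.
#' @param alpha recovery offset.
#' @param beta recovery slope; must be positive.
#' @param epsilon time-scale separation; must lie in (0, 1).
#' @return An object of class \code{"fhn_params"}.
#' @export
fhn_params <- function(I = 0.265, alpha = 0.7, beta = 0.75, epsilon = 0.08) {
  stopifnot(is.numeric(I), is.numeric(alpha), is.numeric(beta),
            is.numeric(epsilon), length(I) == 1L, length(alpha) == 1L,
            length(beta) == 1L, length(epsilon) == 1L)
  if (beta <= 0) stop("'beta' must be positive")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (epsilon >= 1)
    warning("'epsilon' >= 1: no fast/slow time-scale separation")
  structure(list(I = I, alpha = alpha, beta = beta, epsilon = epsilon),
            class = "fhn_params")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat(sprintf("FHN parameters: I = %g, alpha = %g, beta = %g, epsilon = %g\n",
              x$I, x$alpha, x$beta, x$epsilon))
  invisible(x)
}

#' Channel-noise specification
#'
#' The stochastic FHN model perturbs the recovery equation by Stratonovich
#' channel noise \code{h(w) dB}, with either \code{h(w) = sigma0}
#' (additive) or \code{h(w) = sigma0 * w} (multiplicative).
#'
#' @param kind \code{"additive"} or \code{"multiplicative"}.
#' @param sigma0 noise amplitude, non-negative.
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("additive", "multiplicative"), sigma0 = 0.01) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L)
  if (sigma0 < 0) stop("'sigma0' must be non-negative")
  structure(list(kind = kind, sigma0 = sigma0), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("%s channel noise, sigma0 = %g\n", x$kind, x$sigma0))
  invisible(x)
}

#' Simulation configuration
#'
#' Time step, horizon, seed, initial state and integration scheme for the
#' stochastic integrators. The defaults \code{dt = 0.01}, \code{T = 1000}
#' are the settings used for the reference trajectories; the default
#' initial state \code{(-1.00125, -0.4)} sits just above the stable fixed
#' point of the reference parameter set.
#'
#' \code{scheme = "euler_heun"} is the Stratonovich predictor-corrector
#' (Heun-type stochastic Runge-Kutta) integrator and the package default;
#' \code{"stochastic_rk"} is accepted as an alias for it.
#' \code{"euler_maruyama"} is available for comparison; for additive noise
#' the two coincide in law (Ito and Stratonovich integrals agree) and differ
#' pathwise only by the deterministic O(dt) drift-corrector term.
#'
#' @param dt step size (> 0).
#' @param T horizon (>= dt).
#' @param seed integer RNG seed or \code{NULL}.
#' @param initial_state numeric length-2 vector \code{(v0, w0)}.
#' @param scheme integration scheme.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.01, T = 1000, seed = NULL,
                       initial_state = c(-1.00125, -0.4),
                       scheme = c("euler_heun", "stochastic_rk",
                                  "euler_maruyama")) {
  scheme <- match.arg(scheme)
  if (scheme == "stochastic_rk") scheme <- "euler_heun"
  stopifnot(is.numeric(dt), is.numeric(T), length(dt) == 1L, length(T) == 1L,
            length(initial_state) == 2L, is.numeric(initial_state))
  if (dt <= 0) stop("'dt' must be positive")
  if (T <= 0) stop("'T' must be positive")
  if (dt > T) stop("'dt' must not exceed 'T'")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(dt = dt, T = T, seed = seed,
                 initial_state = as.numeric(initial_state), scheme = scheme),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: dt = %g, T = %g, scheme = %s, x0 = (%g, %g), seed = %s\n",
    x$dt, x$T, x$scheme, x$initial_state[1], x$initial_state[2],
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Read a plain-text configuration file
#'
#' Parses a \code{key = value} text file (one pair per line, \code{#}
#' comments allowed) into the three configuration objects used by the
#' package. Recognised keys: \code{I}, \code{alpha}, \code{beta},
#' \code{epsilon}, \code{noise.kind}, \code{noise.sigma0}, \code{sim.dt},
#' \code{sim.T}, \code{sim.seed}, \code{sim.v0}, \code{sim.w0},
#' \code{sim.scheme}. Missing keys fall back to the package defaults.
#'
#' @param path path to the configuration file.
#' @return A list with components \code{params} (\code{fhn_params}),
#'   \code{noise} (\code{noise_spec}) and \code{sim} (\code{sim_config}).
#' @export
read_fhn_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  get <- function(key, default, num = TRUE) {
    i <- match(key, keys)
    if (is.na(i)) return(default)
    if (num) as.numeric(vals[i]) else vals[i]
  }
  params <- fhn_params(I = get("I", 0.265), alpha = get("alpha", 0.7),
                       beta = get("beta", 0.75),
                       epsilon = get("epsilon", 0.08))
  noise <- noise_spec(kind = get("noise.kind", "additive", num = FALSE),
                      sigma0 = get("noise.sigma0", 0.01))
  seed <- get("sim.seed", NA_real_)
  sim <- sim_config(dt = get("sim.dt", 0.01), T = get("sim.T", 1000),
                    seed = if (is.na(seed)) NULL else as.integer(seed),
                    initial_state = c(get("sim.v0", -1.00125),
                                      get("sim.w0", -0.4)),
                    scheme = get("sim.scheme", "euler_heun", num = FALSE))
  list(params = params, noise = noise, sim = sim)
}
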
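## Deterministic model: vector field, fixed point, eigenstructure,
## excitability diagnostics and the analytic constants of the stochastic
## theory.

#' FHN drift field
#'
#' Evaluates the deterministic vector field
#' \deqn{f(v, w) = v - v^3/3 - w + I, \qquad g(v, w) = \epsilon (v + \alpha - \beta w).}
#'
#' @param state numeric length-2 vector \code{(v, w)}.
#' @param params an \code{\link{fhn_params}} object.
#' @return Numeric length-2 vector \code{(f, g)}.
#' @export
drift_field <- function(state, params) {
  v <- state[1]; w <- state[2]
  c(v - v^3 / 3 - w + params$I,
    params$epsilon * (v + params$alpha - params$beta * w))
}

#' Critical manifold of the fast subsystem
#'
#' The curve \code{w = v - v^3/3 + I} of equilibria of the layer problem
#' (singular limit \code{epsilon -> 0}); it coincides with the v-nullcline.
#'
#' @param v numeric vector of membrane-potential values.
#' @param params an \code{\link{fhn_params}} object.
#' @return \code{w} values on the critical manifold.
#' @export
critical_manifold <- function(v, params) {
  v - v^3 / 3 + params$I
}

## real cube root with sign handling; naive x^(1/3) is NaN for x < 0
.cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Unique fixed point via the closed-form cubic root
#'
#' Intersecting the two nullclines reduces the fixed-point condition to the
#' depressed cubic \code{v^3 + p v + q = 0} with
#' \code{p = 3 (1/beta - 1)} and \code{q = 3 (alpha/beta - I)}.  When the
#' discriminant \code{Delta = (1/beta - 1)^3 + (9/4)(alpha/beta - I)^2} is
#' positive there is a unique real root, given by Cardano's formula
#' \deqn{v_e = (-q/2 - \sqrt{\Delta})^{1/3} + (-q/2 + \sqrt{\Delta})^{1/3},}
#' and \code{w_e = (v_e + alpha)/beta}.  The Cardano value is refined by
#' safeguarded Newton steps on the cubic, which protects the printed
#' 6-significant-digit accuracy against floating cancellation when the two
#' cube roots nearly cancel (Delta close to 0).
#'
#' @param params an \code{\link{fhn_params}} object.
#' @return A list with components \code{p}, \code{q}, \code{discriminant},
#'   \code{v_e}, \code{w_e}.
#' @export
fixed_point <- function(params) {
  beta <- params$beta
  p <- 3 * (1 / beta - 1)
  q <- 3 * (params$alpha / beta - params$I)
  discriminant <- (1 / beta - 1)^3 + 9 / 4 * (params$alpha / beta - params$I)^2
  if (discriminant <= 0)
    stop("discriminant <= 0: not a unique fixed point; ",
         "excitable-regime analysis unavailable")
  v <- .cbrt(-q / 2 - sqrt(discriminant)) + .cbrt(-q / 2 + sqrt(discriminant))
  ## safeguarded Newton polish: accept a step only if it shrinks the residual
  resid <- function(v) v^3 + p * v + q
  for (i in 1:5) {
    r0 <- resid(v)
    if (abs(r0) < 1e-14) break
    dp <- 3 * v^2 + p
    if (dp == 0) break
    v_new <- v - r0 / dp
    if (abs(resid(v_new)) >= abs(r0)) break
    v <- v_new
  }
  if (abs(resid(v)) >= 1e-12)
    warning("cubic residual above 1e-12 after polishing")
  list(p = p, q = q, discriminant = discriminant,
       v_e = v, w_e = (v + params$alpha) / beta)
}

#' Jacobian and eigenvalue pair at the fixed point
#'
#' The Jacobian of the drift at \code{(v_e, w_e)} is
#' \code{M = [[1 - v_e^2, -1], [epsilon, -epsilon beta]]}.  In the excitable
#' regime its eigenvalues are the complex pair \code{-mu +/- i nu} with
#' \deqn{\mu = -\tfrac12 (1 - v_e^2 - \epsilon\beta), \qquad
#'       \nu = \tfrac12 \sqrt{4\epsilon - (1 - v_e^2 + \epsilon\beta)^2}.}
#' The closed-form pair is cross-checked against a numeric
#' eigendecomposition of \code{M} (agreement to 1e-10).
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param v_e the fixed-point v-coordinate (from \code{\link{fixed_point}}).
#' @return A list with components \code{M} (2x2 matrix), \code{mu},
#'   \code{nu}.
#' @export
jacobian_and_eigen <- function(params, v_e) {
  eps <- params$epsilon; beta <- params$beta
  disc <- 4 * eps - (1 - v_e^2 + eps * beta)^2
  if (disc <= 0)
    stop("real eigenvalues: non-oscillatory equilibrium; ",
         "averaging reduction invalid")
  M <- matrix(c(1 - v_e^2, eps, -1, -eps * beta), 2, 2)
  mu <- -0.5 * (1 - v_e^2 - eps * beta)
  nu <- 0.5 * sqrt(disc)
  ev <- eigen(M, only.values = TRUE)$values
  if (max(abs(sort(Re(ev))[1] + mu), abs(max(abs(Im(ev))) - nu)) > 1e-10)
    stop("closed-form eigenvalues disagree with numeric eigendecomposition")
  list(M = M, mu = mu, nu = nu)
}

#' Excitability report
#'
#' Checks, at the given parameters, the three conditions under which the
#' averaging reduction of the stochastic model is meaningful: a unique
#' fixed point (positive discriminant), a stable focus (complex eigenvalues
#' with positive contraction rate \code{mu}), and strong time-scale
#' separation of contraction versus rotation (\code{mu/nu} below
#' \code{ratio_threshold}).  The threshold operationalises "mu much smaller
#' than nu"; 0.2 is the package default.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param ratio_threshold upper bound on \code{mu/nu} for the averaging
#'   flag.
#' @return An object of class \code{"fhn_excitability"}: a list of flags
#'   plus the quantities behind them (\code{discriminant}, \code{mu},
#'   \code{nu}, \code{mu_nu_ratio}, \code{excitable}).
#' @export
excitability_report <- function(params, ratio_threshold = 0.2) {
  out <- list(discriminant = NA_real_, unique_fixed_point = FALSE,
              complex_eigenvalues = FALSE, stable = FALSE,
              v_e = NA_real_, w_e = NA_real_,
              mu = NA_real_, nu = NA_real_, mu_nu_ratio = NA_real_,
              ratio_threshold = ratio_threshold,
              averaging_valid = FALSE, excitable = FALSE)
  fp <- tryCatch(fixed_point(params), error = function(e) NULL)
  if (is.null(fp)) {
    out$discriminant <- (1 / params$beta - 1)^3 +
      9 / 4 * (params$alpha / params$beta - params$I)^2
    return(structure(out, class = "fhn_excitability"))
  }
  out$discriminant <- fp$discriminant
  out$unique_fixed_point <- TRUE
  out$v_e <- fp$v_e; out$w_e <- fp$w_e
  je <- tryCatch(jacobian_and_eigen(params, fp$v_e), error = function(e) NULL)
  if (is.null(je)) return(structure(out, class = "fhn_excitability"))
  out$complex_eigenvalues <- TRUE
  out$mu <- je$mu; out$nu <- je$nu
  out$stable <- je$mu > 0
  out$mu_nu_ratio <- je$mu / je$nu
  out$averaging_valid <- out$stable && out$mu_nu_ratio < ratio_threshold
  out$excitable <- out$unique_fixed_point && out$complex_eigenvalues &&
    out$stable && out$averaging_valid
  structure(out, class = "fhn_excitability")
}

#' @export
print.fhn_excitability <- function(x, ...) {
  cat("Excitability report\n")
  cat(sprintf("  discriminant        : %.7g (%s)\n", x$discriminant,
              if (x$unique_fixed_point) "unique fixed point" else
                "multiple fixed points"))
  if (x$unique_fixed_point)
    cat(sprintf("  fixed point         : (%.6g, %.6g)\n", x$v_e, x$w_e))
  if (x$complex_eigenvalues) {
    cat(sprintf("  eigenvalues         : -%.6g +/- %.6gi (%s)\n", x$mu, x$nu,
                if (x$stable) "stable focus" else "unstable focus"))
    cat(sprintf("  mu/nu               : %.6g (threshold %.3g)\n",
                x$mu_nu_ratio, x$ratio_threshold))
  } else {
    cat("  eigenvalues         : real (non-oscillatory)\n")
  }
  cat(sprintf("  verdict             : %s\n",
              if (x$excitable) "excitable (averaging valid)" else
                "not excitable"))
  invisible(x)
}

#' Combined equilibrium analysis
#'
#' Convenience wrapper running \code{\link{fixed_point}},
#' \code{\link{jacobian_and_eigen}} and \code{\link{excitability_report}}
#' on one parameter set.  Most downstream constructors
#' (\code{\link{build_normal_form}}, \code{\link{build_firing_grid}}) take
#' this object.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param ratio_threshold passed to \code{\link{excitability_report}}.
#' @return An object of class \code{"fhn_equilibrium"} with fields
#'   \code{params}, \code{p}, \code{q}, \code{discriminant}, \code{v_e},
#'   \code{w_e}, \code{M}, \code{mu}, \code{nu}, \code{mu_nu_ratio},
#'   \code{excitable}, \code{gamma_fn_coefficients}.
#' @export
equilibrium_analysis <- function(params, ratio_threshold = 0.2) {
  fp <- fixed_point(params)
  je <- jacobian_and_eigen(params, fp$v_e)
  rep <- excitability_report(params, ratio_threshold)
  structure(c(list(params = params), fp, je,
              list(mu_nu_ratio = je$mu / je$nu,
                   excitable = rep$excitable,
                   report = rep,
                   gamma_fn_coefficients = c(1 / 3, abs(fp$v_e)))),
            class = "fhn_equilibrium")
}

#' @export
print.fhn_equilibrium <- function(x, ...) {
  cat("FHN equilibrium analysis\n")
  cat(sprintf("  fixed point : (%.6f, %.6f)   discriminant %.7g\n",
              x$v_e, x$w_e, x$discriminant))
  cat(sprintf("  eigenvalues : -%.7g +/- %.6gi   mu/nu = %.6g\n",
              x$mu, x$nu, x$mu_nu_ratio))
  cat(sprintf("  excitable   : %s\n", x$excitable))
  invisible(x)
}

#' Remainder bound of the linearization
#'
#' The nonlinear remainder of the drift after linearization at the fixed
#' point satisfies \code{||Fbar(X - X_e)|| <= gamma(r) ||X - X_e||} for all
#' \code{||X - X_e|| <= r}, with the increasing function
#' \deqn{\gamma(r) = r^2/3 + |v_e| r.}
#'
#' @param r radius, non-negative (vectorised).
#' @param v_e fixed-point v-coordinate.
#' @return \code{gamma(r)}.
#' @export
gamma_bound <- function(r, v_e) {
  if (any(r < 0)) stop("'r' must be non-negative")
  r^2 / 3 + abs(v_e) * r
}

## nonlinear remainder Fbar(X - X_e) of the drift (first component only;
## the recovery equation is linear)
.drift_remainder <- function(x_shift, v_e) {
  dv <- x_shift[1]
  c(-(dv^2) * (dv + 3 * v_e) / 3, 0)
}

#' Dissipativity constants of the drift
#'
#' The drift is weakly dissipative:
#' \code{<X1 - X2, F(X1) - F(X2)> <= a - b ||X1 - X2||^2} with
#' \deqn{a = 3 (1 + \epsilon\beta/2 + (1-\epsilon)^2/(2\epsilon\beta))^2,
#'       \qquad b = \epsilon\beta/2.}
#'
#' @param params an \code{\link{fhn_params}} object.
#' @return A list with components \code{a_diss}, \code{b_diss}.
#' @seealso \code{\link{check_dissipativity}} for the Monte-Carlo check of
#'   the inequality.
#' @export
dissipativity_constants <- function(params) {
  eps <- params$epsilon; beta <- params$beta
  list(a_diss = 3 * (1 + eps * beta / 2 + (1 - eps)^2 / (2 * eps * beta))^2,
       b_diss = eps * beta / 2)
}

#' Monte-Carlo check of the dissipativity inequality
#'
#' Samples random point pairs uniformly in \code{box^2} and evaluates the
#' margin \code{a - b ||X1 - X2||^2 - <X1 - X2, F(X1) - F(X2)>}, which the
#' dissipativity inequality asserts to be non-negative.
#'
#' @param params an \code{\link{fhn_params}} object.
#' @param n number of point pairs.
#' @param box numeric length-2 interval from which both coordinates of both
#'   points are drawn.
#' @param seed RNG seed.
#' @return A list with the minimum margin (\code{min_margin}), the number
#'   of violations (\code{n_violations}) and the constants used.
#' @export
check_dissipativity <- function(params, n = 1e4, box = c(-10, 10), seed = 1L) {
  set.seed(seed)
  cc <- dissipativity_constants(params)
  v1 <- stats::runif(n, box[1], box[2]); w1 <- stats::runif(n, box[1], box[2])
  v2 <- stats::runif(n, box[1], box[2]); w2 <- stats::runif(n, box[1], box[2])
  eps <- params$epsilon; alpha <- params$alpha; beta <- params$beta
  f1 <- v1 - v1^3 / 3 - w1; f2 <- v2 - v2^3 / 3 - w2
  g1 <- eps * (v1 + alpha - beta * w1); g2 <- eps * (v2 + alpha - beta * w2)
  inner <- (v1 - v2) * (f1 - f2) + (w1 - w2) * (g1 - g2)
  margin <- cc$a_diss - cc$b_diss * ((v1 - v2)^2 + (w1 - w2)^2) - inner
  list(min_margin = min(margin), n_violations = sum(margin < 0),
       a_diss = cc$a_diss, b_diss = cc$b_diss, n = n)
}
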
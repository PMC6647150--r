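---
title: "Methods: reducing the stochastic FitzHugh-Nagumo neuron to a leaky integrate-and-fire model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reducing the stochastic FitzHugh-Nagumo neuron to a leaky integrate-and-fire model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnlif)
```

## The model and its regime

The package works with the two-dimensional FitzHugh–Nagumo (FHN) neuron

$$dv = \Big(v - \tfrac{v^3}{3} - w + I\Big)\,dt,\qquad
  dw = \varepsilon(v + \alpha - \beta w)\,dt + h(w)\circ dB,$$

where $v$ is the membrane potential (fast), $w$ the recovery current
(slow), $I$ a constant bias current, and $0<\varepsilon<1$ the time-scale
separation. All quantities are dimensionless; "time" is the fast time
scale of the membrane equation. Channel noise perturbs the recovery
equation, either additively ($h(w)=\sigma_0$) or multiplicatively
($h(w)=\sigma_0 w$), and is interpreted in the Stratonovich sense (for
additive noise this coincides with Itô).

Everything downstream assumes the *excitable regime*:

* a **unique fixed point**, equivalent to a positive discriminant
  $\Delta = (1/\beta - 1)^3 + \tfrac94(\alpha/\beta - I)^2$ of the
  depressed cubic $v^3 + pv + q = 0$,
  $p = 3(1/\beta - 1)$, $q = 3(\alpha/\beta - I)$;
* a **stable focus**: the Jacobian
  $M = \begin{pmatrix} 1-v_e^2 & -1\\ \varepsilon & -\varepsilon\beta\end{pmatrix}$
  has complex eigenvalues $-\mu \pm i\nu$ with $\mu > 0$;
* **rotation-dominated contraction**, $\mu/\nu \ll 1$, which is what
  licenses the stochastic averaging step. "Much smaller" has no canonical
  cutoff; `excitability_report()` uses a configurable threshold with
  default 0.2, chosen so that the reference set
  ($\mu/\nu \approx 0.111$) sits comfortably inside and parameter sets
  with comparable contraction and rotation are flagged.

The package defaults are the reference set
$(I,\alpha,\beta,\varepsilon) = (0.265, 0.7, 0.75, 0.08)$, giving
$(v_e,w_e) \approx (-1.00125, -0.401665)$, $\mu \approx 0.03125$,
$\nu \approx 0.28138$.

`fixed_point()` evaluates the closed-form Cardano root with real cube
roots ($\sqrt[3]{x} = \mathrm{sign}(x)|x|^{1/3}$) and then applies
safeguarded Newton steps on the cubic (a step is accepted only if it
shrinks the residual). Near $\Delta \to 0$ the two cube roots nearly
cancel and the naive evaluation loses several digits; the polish restores
residuals below $10^{-12}$, which the 6-significant-digit reference
values require. Parameter validation is deliberately permissive —
warnings rather than errors outside the excitable regime — because the
analysis functions are also exploration tools; hard errors are reserved
for structurally undefined cases ($\Delta \le 0$, real eigenvalues,
$m_{21} = 0$).

## Stochastic integration

`integrate_stratonovich()` implements the Euler–Heun predictor–corrector
(a Stratonovich stochastic Runge–Kutta of Heun type): predictor
$X^p = X + F(X)\,dt + H(X)\,\Delta B$, corrector
$X' = X + \tfrac12(F(X)+F(X^p))\,dt + \tfrac12(H(X)+H(X^p))\,\Delta B$.
For the diffusion fields used here — constant or linear in the state —
this is consistent with the Stratonovich interpretation; for additive
noise it coincides in law with Euler–Maruyama, which is also available
(`scheme = "euler_maruyama"`) and is used by a test that checks the two
schemes converge to each other as $dt$ shrinks. The configuration name
`"stochastic_rk"` is accepted as an alias for the Heun scheme.

Brownian increments are returned with every trajectory and can be
replayed, which is the contract behind all *common-noise* couplings: the
linearization error experiments integrate the full and linearized systems
on identical increments, otherwise a pathwise comparison would be
meaningless.

Defaults follow the reference settings: $dt = 0.01$, horizon $T = 1000$,
initial state $(-1.00125, -0.4)$ just above the fixed point. A
non-finite state aborts with the failing step index rather than
propagating NaNs.

**Spike definition.** A spike is an upward crossing of $v = 0$, with the
crossing time linearly interpolated between samples. After a crossing the
detector is disarmed until $v$ re-enters $v < v_e$: one spike per
excursion, immune to numerical jitter at the threshold. First-passage
sampling (`sample_isi_fhn()`) starts every trial exactly at the fixed
point (the reset rule) and reports censored trials (no spike before the
horizon) explicitly rather than discarding them.

**Randomness.** Every stochastic function takes a seed and records it in
its output. Monte-Carlo trials are advanced as a vectorized ensemble —
one `set.seed(seed)` stream per batch, increments drawn per step across
the active trials — which is what keeps thousand-trial calibrations
inside minutes in pure R; results are bit-reproducible from the root
seed, and the pipeline manifest records one derived seed per stage.

## Linearization and its error

Around the focus, the shifted system
$d\bar X = M\bar X\,dt + H(\bar X + X_e)\circ dB$ approximates the full
dynamics; freezing the diffusion at the equilibrium gives the fully
linear variant. The nonlinear drift remainder obeys
$\|\bar F(X - X_e)\| \le \gamma(r)\|X - X_e\|$ with
$\gamma(r) = r^2/3 + |v_e| r$ inside the ball of radius $r$, and the
pathwise error up to the exit time $\tau(r)$ is bounded by
$C\,\gamma(r)\,r$ (additive noise), with a mean-square analogue for
multiplicative noise.

Two design points in `error_scaling_experiment()`:

* $\tau$ is evaluated on the discrete grid (first index with
  $\|X - X_e\| \ge r$), without sub-step refinement — the experiment
  checks a bound, not a precise hitting time.
* The bound is a small-ball statement. At a fixed amplitude, paths exit a
  small ball almost immediately, so the bound is probed far from
  saturation and the measured slope is inflated. By default the
  experiment scales $\sigma_0 \propto r$, under which the linear dynamics
  inside the ball is exactly self-similar and the exit time is
  $r$-independent in law; the nonlinearity then produces the clean
  $r^2$ scaling, with the estimated constant stable across radii
  (`scale_noise = FALSE` restores the fixed-amplitude probe). For the
  frozen-noise variant the $C r^2$ mean-square bound is loose — the
  measured decay is faster — so the tests assert the bound envelope
  (slope at least 2, monotone error) rather than a tight slope.

The unknown constant $C$ is estimated as the error/bound ratio at the
smallest radius and required stable within ±50% across radii.

## Normal form and the radial reductions

With $Q = \begin{pmatrix} -\nu & m_{11}+\mu\\ 0 & m_{21}\end{pmatrix}$,
the transform $Y = Q^{-1}\bar X$ turns the drift into the
contraction–rotation $A = \begin{pmatrix}-\mu & \nu\\ -\nu & -\mu
\end{pmatrix}$ (similarity verified to $10^{-10}$ at construction). The
transformed unit noise is $h_e = Q^{-1}(0, \sigma_0)^T$; its second
component is exactly $1/m_{21} = 1/\varepsilon$, and
$\|h_e\|^2/\sigma_0^2 = -m_{12}/(m_{21}\nu^2)$ is both the leading
coefficient of the polar radial SDE and the square of the distance
conversion factor. All of these constants are *computed from the
Jacobian*, never hard-coded; at the reference set they reproduce the
reference values (1.27722, 12.5, 157.881) and generalize to any excitable
parameter set.

Averaging approximates $Y_t$ by
$(\sigma/\sqrt\mu)\,\mathrm{Rot}_{-\nu t}\,\bar S_{\mu t}$ with $\bar S$ a
standard 2-D OU process and
$\sigma = \sqrt{\|h_e\|^2/2}$, so the radius
$R_t = \|Y_t\|$ obeys the radial OU equation
$dR = (\sigma^2/(2R) - \mu R)\,dt + \sigma\,d\tilde B$. Two backends
simulate it:

* **norm** (default, the reference): simulate $\bar S$ by its *exact*
  Gaussian transition and take the norm. This follows the derivation
  route, has no singularity at $R = 0$ (so paths can start at the fixed
  point image $R_0 = 0$), and is exact in law on any grid.
* **direct**: a drift-implicit Euler–Maruyama step on the 1-D SDE,
  solving $x' = x(1-\mu\,dt) + \sigma\Delta B + \sigma^2 dt/(2x')$ in
  closed form. The implicit handling of the singular $1/R$ term is the
  standard positivity-preserving discretization for Bessel/CIR-type
  drifts. An explicit step with reject-and-halve retries was tried first
  and abandoned: the polar equation pins at the origin whenever the
  averaged phase aligns with $h_e$ while $R$ is tiny (the restoring
  numerator vanishes), and rejection cannot recover from that state.

The polar variant keeps the phase explicit,
$\theta_t = (\sin\nu t, \cos\nu t)$, with diffusion
$\langle\theta_t, h_e\rangle$ and drift numerator
$\|h_e\|^2 - \langle h_e,\theta_t\rangle^2 \ge 0$; it uses the same
implicit step. Its time-averaged squared diffusion over one period equals
$\sigma^2$, tying the two reductions together. The rotation sign is
$\mathrm{Rot}_{-\nu t}$ (clockwise for $\nu > 0$); phase angles are
unwrapped for continuity. The abstract Brownian motion of the radial
equation is independent of the original one only in law; nothing enforces
or needs pathwise identity.

## The firing mechanism

The conditional probability of firing is calibrated on the line
$L = \{(v_e, w): w \le w_e\}$ straight below rest: 35 starting points
$L_i = (v_e, w_e - i\delta)$ with $\delta = |w_e + 0.453|/20$, so the
separatrix reference sits at grid index 20. The constant 0.453 is the
$w$-level where $L$ meets the separatrix *for the reference parameter
set*; it is a configuration value (`separatrix_w`), not a derived
quantity — the package does not compute the separatrix.

For each $L_i$, `estimate_firing_probability()` runs short stochastic
paths and records whether a spike occurs within the *first cycle* around
the fixed point. The source notion of "one cycle" is not operational;
the package formalizes it as $2\pi$ of accumulated unwrapped angle of the
transformed state $Y = Q^{-1}(X - X_e)$, whose rotation is nearly uniform
at rate $\nu$ — angle is the natural clock of the normal form. A hard
time cap of 3 rotation periods guards against paths stalled near the
origin where the angle increment is noise-dominated; trials that neither
spike nor complete the cycle are counted as non-spikes and their
frequency is reported (at the reference settings they are rare).

The 35 estimates are fitted by unweighted Levenberg–Marquardt least
squares to the two-parameter logistic
$p(l) = 1/(1+e^{(a-l)/b})$, evaluated through `plogis` for overflow
safety at small scales; binomial weighting is available behind a flag.
Initial values: $a_0$ = first grid distance with $\hat p > 1/2$,
$b_0 = 5\sigma_0$. Bound-constrained variants of the optimizer were
found to collapse onto the degenerate step-function corner ($b$ at the
bound), so the fit runs unconstrained and a non-positive fitted scale is
rejected as degenerate. The fitted location sits at the separatrix
distance ($a \approx 0.05$) across amplitudes, and the scale $b$ grows
with $\sigma_0$ — as the noise vanishes the curve steepens toward the
step function of a deterministic threshold.

Only additive noise is calibrated by default; multiplicative calibration
runs but is unvalidated.

## ISI statistics

In normal-form coordinates the fitted sigmoid becomes
$p(r) = 1/(1+e^{(a^*-r)/b^*})$ with
$a^* = \sqrt{-m_{12}/(m_{21}\nu^2)}\,a$ (same for $b^*$), and since one
cycle takes $2\pi/\nu$ time units on average, the hazard rate is
$\alpha(r) = \frac{\nu}{2\pi}\,p(r)$, capped by the cycle rate.

`isi_density()` implements the Monte-Carlo estimator of
$g(t) = E[\alpha(R_t)\,e^{-\int_0^t \alpha(R_s)ds}]$ with the trapezoidal
rule on $n$ subdivisions of $[0,t]$ and $M$ radial realizations (defaults
$M = 1000$, $n = 10$, matching the source settings), the same $M$ paths
serving every evaluation time. Radial paths are generated by the
singularity-free norm construction started at $R_0 = 0$, the image of the
reset at the fixed point. Two numerical caveats are documented rather
than hidden:

* the coarse $n = 10$ rule undersamples the hazard path (whose
  correlation time $1/\mu \approx 32$ is much shorter than $t/10$ at
  late $t$) and inflates the integral of $g$ to about 1.026; with
  $n = 50$ the integral is 1.000. $n = 10$ stays the default for source
  fidelity; the consistency tests use the finer rule.
* the default evaluation grid is 200 geometrically spaced times on
  $[1, 2000]$, sized for $\sigma_0 = 0.01$.

`sample_isi_lif()` draws firing times by thinning: along each exact
radial path, a step of length $dt$ fires with probability
$1 - e^{-\alpha(R_t)dt}$ (exact for a hazard held constant within the
step); $dt\,\nu/(2\pi) \ll 1$ is enforced. Thinning rather than inversion
because the hazard rides on the stochastic path $R_t$. Censored runs are
reported. `compare_isi()` gives the two-sample Kolmogorov–Smirnov
statistic and a decile table; distribution comparisons use normalized
densities throughout.

## Spectral comparisons

`psd_estimate()` is an averaged-overlapping-segment (Welch) periodogram —
Hann taper, 50% overlap, default segment 1024 samples — normalized so
that the PSD integrates to the series variance; no pre-installed R
package exposes this estimator, so it is written on `stats::fft`
directly. Comparisons rescale each PSD to a common maximum (40, an
arbitrary display constant) and report normalized $L^2$ gaps, so the
estimator choice affects both sides equally. Shifted-vs-linearized
comparisons use only subthreshold stretches of the full path
(`subthreshold_segments()`, runs with $v < -0.5$), because spike
excursions are exactly what the linearization cannot represent. The
default segment length resolves shapes but not the rotation peak
($\nu/2\pi \approx 0.0448$ falls below the first non-DC bin at
$dt = 0.01$); peak-location checks use 16384-sample segments.

## Problem sizes in the test suite

Deterministic checks run at the reference values. The Monte-Carlo
calibrations are tested at the reference 1000 trials per grid point for
the amplitudes whose regression values are compared
($\sigma_0 = 0.005, 0.01$) and at 400 trials for the two additional
amplitudes entering only the monotonicity trend; ISI comparisons use
1000 first-firing times per side; spectral comparisons use horizons of
2000–5000 time units at $dt = 0.01$; the radial stationary law is checked
on 600 near-independent samples from 200 paths. These sizes were chosen
once, as a balance between Monte-Carlo resolution and a test suite that
runs in a few minutes.

## What the simulations do and do not show

All data in this package are generated by the model itself; there is no
external dataset. The generator *is* the stochastic FHN equation at the
reference parameters, so passing tests demonstrate internal consistency
of the reduction — that the embedded LIF reproduces the statistics of the
equation it was derived from — not biological realism: no refractory
channel dynamics beyond the recovery variable, no colored or synaptic
noise, no parameter heterogeneity.

Known limitations:

* **Averaging error at the firing threshold.** With
  $\mu/\nu \approx 0.111$, the radial OU law slightly overstates the
  full model's excursions at the radii where firing happens (there
  $\gamma(r)$ is order one in the original coordinates). The consequence,
  measured by the acceptance suite at $\sigma_0 = 0.01$, is that the
  calibrated LIF fires faster than the full model (two-sample KS
  $\approx 0.18$ between 1000 first-firing times per side), even though
  the calibration itself reproduces the reference regression table
  closely. The reduction captures the shape and scale of the ISI
  distribution, not its fine quantiles.
* The separatrix constant 0.453 and the default density grid are specific
  to the reference parameter set.
* Multi-fixed-point regimes ($\Delta \le 0$) are detected, not analysed;
  no bifurcation continuation.
* SDE schemes are first order (Euler–Heun / drift-implicit EM); no
  Milstein or adaptive stepping. Jump and colored noise are out of scope.
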
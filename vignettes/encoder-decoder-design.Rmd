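---
title: "Designing matched encoder-decoder pairs for linear-Gaussian BCIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing matched encoder-decoder pairs for linear-Gaussian BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcicodesign)
```

## The model and its assumptions

A closed-loop cursor BCI is modeled as a linear-Gaussian state-space system.
The user's intended kinematics $x_t \in \mathbb{R}^n$ follow a stationary
AR(1) prior $x_t = P x_{t-1} + z_t$, $z_t \sim \mathcal{N}(0, Q)$, and drive
$k$ neural channels linearly, $y_t = A x_t + \epsilon_t$,
$\epsilon_t \sim \mathcal{N}(0, C)$. Everything is zero-mean: means are
assumed removed by pre-processing and are never modeled. The decoder is the
steady-state Kalman filter (SSKF)
$\hat{x}_t = F y_t + G \hat{x}_{t-1}$ with
$F = \Sigma_{SS} A^\top (A \Sigma_{SS} A^\top + C)^{-1}$ and
$G = P - F A P$, where $\Sigma_{SS}$ solves the filter-form discrete
algebraic Riccati equation. Working in steady state discards only the
filter's initial transient, which is irrelevant to long-run closed-loop
performance.

The central object is the penalized design objective over encoder-decoder
pairs,
$$\mathcal{L}(A, F, G) = \mathbb{E}\,\|\hat{x}_t - x_t\|^2
  + \lambda\, \mathcal{G}(A),$$
minimized jointly over the encoding matrix $A$ (what an idealized user can
learn) and the decoder $(F, G)$. Co-adaptation — user and decoder taking
turns improving — is coordinate descent on $\mathcal{L}$, so its fixed point
can be computed offline and the optimal decoder presented as a *fixed*
decoder for the user to learn.

Two penalties are implemented. The trace-of-quotient penalty
$\mathcal{G}_{joint}(A) = \mathrm{tr}(\Sigma_y^{-1} A \Sigma_x A^\top)$
constrains encoded signal power relative to the total neural covariance
$\Sigma_y$; each generalized eigenvalue of (signal, total) lies in $[0, 1)$,
so it saturates at $\min(k, n)$. The SNR penalty
$\mathcal{G}_{SNR}(A) = \mathrm{tr}(C^{-1} A \Sigma_x A^\top)$ is unbounded
and degree-2 homogeneous; without any penalty the MSE objective has the
degenerate solution $\|A\| \to \infty$ (arbitrarily strong encoding), which
the tests exhibit directly in the static case with $\lambda = 0$.

### Which $\Sigma_y$ the joint penalty uses

Two readings of $\Sigma_y$ are coherent: the model-implied covariance
$\Sigma_y(A) = A \Sigma_x A^\top + C$ of the current iterate, or a *fixed*
empirical covariance measured in a calibration session. Both are
implemented; the model-implied form is the default for `penalty_joint()` and
`full_objective()`, and passing `Sigma_y_ref` switches to the fixed form.
The distinction matters more than it looks. For 1-D control the model-implied
penalty and the MSE both depend on $A$ only through the scalar
$a^\top C^{-1} a$, so the *direction* of the optimal encoder across channels
is completely indeterminate. Against a fixed calibration covariance the
penalty is a quadratic form that prices each channel by its native total
variance, the direction becomes meaningful, and the optimizer concentrates
weight on natively high-SNR channels. This is why the covariance-pair design
problems (`optimize_from_covariances()`) and the pre-computed decoder of the
OPS emulator evaluate the penalty against $\Sigma_{sig} + C$: the
signal/noise covariance pair is then a sufficient statistic for the design.

## Exact objective evaluation

The coupled (intention, decoded-cursor) process is itself linear:
$$\begin{pmatrix} x_t \\ \hat{x}_t \end{pmatrix}
 = \begin{pmatrix} P & 0 \\ F A P & G \end{pmatrix}
   \begin{pmatrix} x_{t-1} \\ \hat{x}_{t-1} \end{pmatrix}
 + \begin{pmatrix} z_t \\ F A z_t + F \epsilon_t \end{pmatrix},$$
so its stationary second moments solve one $2n \times 2n$ discrete Lyapunov
equation and the stationary MSE is
$\mathrm{tr}(S_{\hat{x}\hat{x}} - 2 S_{x\hat{x}} + S_{xx})$ in closed form
(`mse_objective()`). The expanded form written with the lagged cross moment
$\mathbb{E}[x_t \hat{x}_{t-1}^\top] = P\, S_{x\hat{x}}$ is implemented as an
internal cross-check and agrees to machine precision. Because the augmented
transition matrix has spectrum $\sigma(P) \cup \sigma(G)$, the objective is
defined for *every* $A$ once $(F, G)$ come from a stable decoder — there is
no stability constraint on the encoder update.

Gradients of the stationary MSE in $A$ are computed by the adjoint method:
with $S$ the moment matrix and $\Lambda$ the solution of the dual Lyapunov
equation $\Lambda = M^\top \Lambda M + L$, the differential is
$2\,\mathrm{tr}(S M^\top \Lambda\, dM) + \mathrm{tr}(\Lambda\, dW)$, two
Lyapunov solves regardless of $k$. The analytic gradient was derived here
independently and is held to a central finite-difference contract (relative
error below $10^{-5}$) in the test suite, which is treated as ground truth.

## Numerical choices

* **Lyapunov solves** use the vectorized closed form
  $\mathrm{vec}(S) = (I - M \otimes M)^{-1} \mathrm{vec}(W)$ — exact and
  cheap at the state dimensions used here ($2n \le 20$). The matrix
  recursion iterated to convergence is kept as an independent test oracle.
* **Riccati solves** use a structured doubling algorithm (quadratically
  convergent), with the plain fixed-point iteration of the Riccati
  recursion (tolerance $10^{-12}$, cap $10^5$) as fallback and as the
  cross-checking oracle. Both agree with the asymptotic gain of the
  time-varying Kalman recursion to $10^{-6}$ on random instances.
  Covariances are re-symmetrized after every update; no square-root
  filtering is needed at $n \le 10$, $k \le 200$.
* **Encoder updates** default to L-BFGS (`stats::optim`) on the analytic
  gradient with a monotonicity safeguard: if the quasi-Newton step fails to
  improve, an Armijo backtracking gradient descent (factor 0.5) runs from
  the incumbent, and the incumbent is kept when nothing improves. Plain
  Armijo descent is also exposed (`inner_method = "armijo"`); it satisfies
  the same descent contract but converges too slowly to be the default at
  $k = 200$.
* **Coordinate descent** alternates the $A$-update with the exact SSKF
  solve. Both half-steps are descent steps, so the outer objective trace is
  monotone non-increasing by construction — asserted, not assumed, in the
  tests. Stopping: relative objective change below $10^{-8}$, cap 500 outer
  iterations. Initial encoders are i.i.d. normal, rescaled so the initial
  penalty sits at half its saturation value; 5 seeded restarts by default
  with the best objective kept and all reported. Across seeds the final
  objective agrees to a relative $10^{-3}$ (and in practice to $10^{-10}$)
  even at $k = 200$, $n = 3$, while the parameters themselves differ — the
  solution set is a manifold of equivalent optima, and tests assert
  objective invariance only, never parameter uniqueness.
* **Sign canonicalization** flips column signs of $A$ (with the matching
  row of $F$, and conjugation of $G$) so each column's dominant entry is
  positive. Per-dimension flips preserve the objective exactly when $P$ and
  $Q$ are diagonal — the position-only setting used throughout; the global
  flip $(A, F) \to (-A, -F)$ is an exact symmetry always.
* **Degenerate inputs**: non-stationary priors, singular noise covariances,
  unstable decoder recursions and rank-deficient probes all fail with
  explicit errors; noiseless intuition cases are exercised through a
  noise-disabled simulation flag rather than singular $C$, so every formula
  involving $C^{-1}$ stays well-posed.

## The static (robust-coding) limit

Restricting the decoder to the static form $\hat{x}_t = F y_t$ recovers the
classical optimal-coding problem for i.i.d. Gaussian sources: for fixed $A$
the optimal static decoder is the Wiener gain
$\Sigma_x A^\top (A \Sigma_x A^\top + C)^{-1}$
(`static_decoder_solution()`). As $P \to 0$ the temporal correlations
vanish and the full Kalman-decoder solution collapses onto this marginal
solution; with $P = 10^{-6} I$ the two optimal objectives agree to a
relative $10^{-3}$ in the acceptance tests. A scalar subtlety documented by
the tests: under the trace-of-quotient penalty the scalar static objective
is *linear* in the penalty value, so its optimum sits at a boundary
($a = 0$ or $a \to \infty$ depending on $\lambda$ versus $\sigma_x^2$); the
scalar grid-search cross-check therefore uses the SNR penalty, which has an
interior optimum.

## The OPS emulator and the simulated user

The emulator reproduces the structure of an online prosthesis simulator: a
user's intention drives $k = 6$ synthetic channels through one of three
signal cases, a fixed SSKF decodes a 1-D cursor at 10 steps/s over the
workspace $[-1, 1]$, and sessions follow either a pinball task (uniform
random targets, halo radius 0.075 of the workspace width, 1 s hold, 15 s
timeout, 180 s sessions) or a pursuit-tracking task whose target follows
the AR(1) prior. The task constants resolve "approximately" specified
values to exact defaults and are all exposed in `task_spec()`. The prior is
position-only, $P = 0.99$, $Q = 0.01$ (per-step persistence just under 1 to
discourage drift; process noise matched to task speeds at 10 Hz), giving
stationary variance $\approx 0.5025$.

Signal cases map movement features one-per-driven-channel, remaining
channels pure noise: case 1 right-hand horizontal (noisy) vs vertical
(clean); case 2 both-hands-sum (noisy) vs hands-distance (clean); case 3
each hand's horizontal (noisy) and vertical (clean) positions. Channel
noise is "high" (1.0, equal to the signal power of a heavily used channel)
or "low" (0.1, a 10:1 power ratio — chosen once as a realistic high/low
contrast for pre-processed single-unit-like channels). The biomimetic
("motor-imitation") strategy drives the horizontal feature(s) in every
case, so naive control rides the noisy channels; its decoder is fit by
recursive least squares on an open-loop probe, mirroring a supervised
tracing phase. The pre-computed decoder comes from the joint optimization
against the calibration covariance (all features active at natural
magnitude).

Three idealizations matter when interpreting results. First, intention
equals the current target position — the same proxy the encoder-estimation
regression assumes, making user model and estimator self-consistent, but
discarding trajectory planning. Second, the simulated user learns by
line-searched gradient steps on the *true* objective at the fixed decoder
(every 10 steps during free exploration, frozen during testing). Real users
do not have gradient access; this stand-in probes whether the optimal
encoder is *reachable* by smooth local improvement, not how humans learn.
Third, the user's encoder is an unconstrained $k \times 1$ matrix: the
feature bottleneck of the physical setup is represented only through the
noise structure (undriven channels carry pure high noise, so the optimizer
and the learning user avoid them), not as a hard support constraint.
Consequently, passing tests show internal consistency of the framework and
learnability-in-principle under its own assumptions — they say nothing
about human learning rates, fatigue, or model mismatch in real recordings.

## Calibrating $\lambda$

$\lambda$ sets the magnitude of the signal-power constraint and is the one
free parameter with no canonical value; it should be tuned to the SNR of
the actual system. For the OPS comparison the package calibrates it
automatically (`calibrate_lambda()`): bisection on $\log \lambda$ until the
optimized encoder's penalty equals the native motor-imitation encoding's
penalty value — the user's signal budget. This matters for the smoothing
comparison: with an arbitrary large $\lambda$ the optimized encoder is
weaker than the native one and the pre-computed decoder *oversmooths*
relative to the motor-imitation decoder, inverting the expected
autocorrelation ordering. Calibrated, the pre-computed decoder has the
smaller recursion weight $G$ (0.72 vs 0.86 on case 1) and the faster cursor
ACF falloff, and roughly doubles the acquisition rate.

## Problem sizes used in tests

The test suite and acceptance script run at deliberately modest scales,
chosen as the smallest sizes that make each claim sharp: 50 random
instances ($n \le 3$, $k \le 6$) for Riccati agreement; 20 instances with
$10^6$-step compiled simulations for the analytic-MSE check (with a
1000-step burn-in discarded, and an ensemble bound on the twenty 3-sigma
comparisons, since demanding twenty independent 3-sigma events all pass is
itself a ~5% false-failure test); 10 seeds at $k = 200$, $n = 3$ for
objective invariance; and 20 closed-loop sessions per arm for the two-arm
comparison. The tracking-error and consistency checks use batch-means
standard errors to account for autocorrelation.

## Known limitations

Position-only control is the exercised regime; structured priors with
velocity blocks are accepted by the types but not specially supported.
Non-Gaussian or signal-dependent noise, Poisson observations, nonlinear
decoders, time-varying observation models, and nonstationarity tracking are
out of scope. The gradient-learning user is an idealization; the emulator's
sessions are 1-D. Global optimality is never certified — only seed-invariance
of the achieved objective and dominance over penalty-matched competitors.
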
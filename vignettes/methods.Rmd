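---
title: "Methods: stochastic optimal control for desynchronizing neural oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic optimal control for desynchronizing neural oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pathological neural synchrony — the collective, phase-locked spiking of a
population of neurons — is the target of desynchronizing stimulation
strategies. One energy-efficient idea is *phase resetting*: instead of
continuously forcing the population, drive each oscillator to its
**phaseless set**, the single state where asymptotic phase is undefined.
There, intrinsic noise scatters trajectories across isochrons, randomizing
each neuron's next spike time. A brief, well-shaped input applied only when
the population is detectably synchronized can therefore replace continuous
stimulation.

This package computes such inputs for a noisy conductance-based neuron by
solving a *stochastic* Hamilton–Jacobi–Bellman (HJB) equation, and applies
them to coupled populations with an event-based controller. The central
scientific claim it implements and tests is that a policy computed from the
value function with the *correct noise intensity* uses less input energy
than the policy computed from the deterministic (noise-free) value
function.

## Model

The neuron is the planar reduction of the Hodgkin–Huxley equations in
membrane voltage $V$ (mV) and potassium gating variable $n$: sodium
activation is instantaneous, $m = m_\infty(V)$, and sodium inactivation is
slaved to the potassium gate, $h = 0.8 - n$. With baseline current
$I_b = 10\,\mu A/cm^2$ (all conductances and reversal potentials at their
classical squid-axon values, `neuron_params()`), the model spikes
periodically. `find_period()` measures the period from interpolated upward
crossings of the Poincaré section $V = 0$ after a 200 ms transient;
`find_fixed_point()` locates the unstable focus inside the orbit — the
phaseless set — by damped Newton iteration. `scan_bifurcations()` brackets
the two organizing bifurcations in $I_b$: loss of fixed-point stability
(bisection on the largest real part of the Jacobian eigenvalues, tolerance
0.01) and onset of the stable periodic orbit (bisection on sustained versus
decaying oscillation, tolerance 0.02). The orbit-onset classifier runs
500 ms from the spiking-regime orbit and calls the oscillation sustained
when the late peak-to-peak voltage amplitude exceeds half the initial
amplitude; this is robust to the slow decay near the saddle-node of
periodic orbits. Since the underlying references do not specify how those
thresholds were originally computed, the bisection tolerances are this
package's choice.

## The stochastic HJB equation

In solver coordinates $z = (x, y) = (V/K, n)$ with $K = 100$ (so both
states are order one), the controlled noisy neuron is
$dz = (F(z) + Bu)\,dt + B\sqrt{2D}\,dW$ with $B = (1/K, 0)^T$: control and
noise enter the voltage equation only. The cost of a control episode over
$[0, T_{end}]$ is
$$J = \int_0^{T_{end}} u^2\,dt + \gamma q(z(T_{end})),$$
with a Gaussian end-point cost $\gamma q$ that is zero at the phaseless
point and saturates at $\gamma$ away from it. The minimum *expected* cost
$\mathcal V(z, t)$ satisfies
$$\frac{\partial \mathcal V}{\partial t}
  + \min_{|u| \le u_{max}} \mathcal H(z, \nabla \mathcal V, u)
  + \frac{D}{K^2}\frac{\partial^2 \mathcal V}{\partial x^2} = 0,$$
solved backward from $\mathcal V(\cdot, T_{end}) = \gamma q$. Minimizing
the Hamiltonian under the bound gives the saturated feedback law
$u = -\mathcal V_x/(2K)$, clipped at $\pm u_{max}$ when
$|\mathcal V_x| > 2Ku_{max}$ (Pontryagin saturation); both branches agree
at the switch, which the tests verify to machine precision.

Defaults follow the study conditions: $T_{end} = 7$ ms,
$u_{max} = 10\,\mu A/\mu F$, $\gamma = 1000$,
$\sigma_x^2 = \sigma_y^2 = 0.001$, and a $320 \times 320$ grid.

## Numerical scheme

`solve_hjb()` marches in reverse time with per-step Lie splitting:

* **Hamiltonian (explicit).** One-sided costates from fifth-order WENO
  (weighted essentially non-oscillatory) Hamilton–Jacobi reconstructions,
  combined by a local Lax–Friedrichs flux with directional dissipation
  bounds $\alpha_x \ge |f_x| + u_{max}/K$, $\alpha_y \ge |f_y|$ maximized
  over the grid line through each node. WENO avoids spurious oscillations
  near the kinks the bounded control introduces into the value function.
* **Diffusion (implicit).** The $x$-only second-order term (noise enters
  the voltage equation alone) is discretized with centered differences and
  homogeneous-Neumann boundary rows, giving one tridiagonal (Thomas) solve
  per $y$-line per step. Implicitness makes the diffusion unconditionally
  stable, so the time step is set by the explicit part alone:
  $\Delta t = \mathrm{CFL} \cdot \min(\Delta x/\alpha_x^{max},
  \Delta y/\alpha_y^{max})$ with CFL = 0.5.
* **Boundaries.** WENO ghost nodes by linear extrapolation (outflow-like;
  no spurious inward characteristics reach the orbit region), Neumann for
  the diffusion.

With $D = 0$ the same code path (diffusion skipped, bitwise) produces the
deterministic value function; the suite asserts this reduction exactly.
The domain is $x \in [-1.0, 0.55]$, $y \in [0, 0.9]$: the periodic orbit
spans $V \in [-75, 45]$ mV, $n \in [0.39, 0.72]$, and even strongly noisy
trajectories ($D = 15$) stay within $V \in [-82, 48]$ mV, so the bounds
leave wide margins. Extending further into the hyperpolarized/high-$n$
corners would only add states no trajectory visits while tripling the
grid-corner drift speeds that throttle the CFL step. The terminal slice is
stored exactly; slices are stored about every 0.01 ms and policy lookups
interpolate linearly in time between them, which removes cadence
sensitivity.

Scheme-level oracles in the test suite: exactness of WENO5 on linear data
and its high-order convergence on smooth data; a pure-advection problem
transported against the method of characteristics; the implicit diffusion
step against the closed-form heat kernel; and a linear-quadratic control
problem against its Riccati ODE solution.

## Policy evaluation strategies

`hh_policy()` differentiates each stored slice on the nodes (central
differences, one-sided at edges) and *then* interpolates the gradient
bilinearly — gradient-before-interpolation. The alternative (interpolate
the value, then differentiate) was equally open; we fix
gradient-before-interpolation because it makes the emitted control a
continuous, piecewise-bilinear field and keeps the saturation exact at
query points. Off-grid queries clamp to the boundary node: rare noise
excursions must not abort a run.

Four evaluation strategies are distinguished, matching how the value
function and the simulated trajectory are paired: the stochastic value
function on the stochastic trajectory ($u^*$, the per-realization optimum),
on the deterministic trajectory ($\tilde u^*$, the noise-independent
waveform used for event-based population control), and the deterministic
value function on the stochastic ($u_0^*$) or deterministic ($u_d^*$)
trajectory. All stochastic simulation uses Honeycutt's second-order
stochastic Runge–Kutta scheme with the same Gaussian draw in predictor and
corrector; with $D = 0$ it reduces bitwise to deterministic Heun.
$dt_{sde} = 0.005$ ms (about 2400 steps per spike period) is a
convergence-based choice, not a published value.

## Event-based population control

`simulate_population()` integrates $N$ electrotonically coupled neurons,
$\dot V_i \ni \frac1N \sum_j \alpha_{ij}(V_j - V_i)$, with i.i.d. noise
per neuron (streams split deterministically from one master seed, so every
realization is reproducible bit-for-bit) and one shared control input. The
controller watches the population mean voltage every SDE step and, on an
upward crossing of $-20$ mV, replays the fixed 7 ms waveform
$\tilde u^*$; crossings during an active window are ignored and the
controller re-arms as soon as the window ends. Upward crossings are the
event the collective spike produces; the mean voltage reaches $-20$ mV on
the upstroke only when enough neurons fire together, so the controller
fires exactly when synchrony has rebuilt. All neurons start synchronized
at the spike point (the voltage maximum of the deterministic orbit); a
phase-spread initializer exists for diagnostics.

Network builders: homogeneous (constant $\bar\alpha$), heterogeneous
(pairwise strengths $\sim \mathcal N(\bar\alpha, 0.2\bar\alpha)$,
mirrored; negative draws truncated to zero — electrotonic coupling is
non-negative and the 5-sigma margin makes truncation rare), and
sparse-heterogeneous (exactly 20% of unordered pairs zeroed). Spike
rasters record upward crossings of 0 mV with a 1 ms refractory; the raster
extraction convention is ours, as none is published.

## What the generators emulate — and what they do not

The synthetic networks and noise reproduce the *study conditions*: paired
noise/coupling levels $(D, \bar\alpha) \in \{(0.5, 0.05), (1, 0.1),
(5, 0.15), (10, 0.2), (15, 0.25)\}$, $N = 100$, a 425 ms horizon, and
Gaussian white voltage noise. They do not emulate real neural tissue:
no synaptic (chemical) coupling, no conduction delays, no parameter
heterogeneity across cells, no plasticity, and noise that is white rather
than shaped by synaptic bombardment. Passing tests therefore demonstrate
the *computational* claims (the solver solves the PDE it claims to solve;
the stochastic policy beats the deterministic one under the stated model)
— not clinical efficacy of any stimulation protocol.

## Problem sizes and tolerances

The original study used $320^2$ grids, 10,000 single-neuron Monte Carlo
realizations and 100 population realizations. The package defaults keep
the $320^2$ grid, while the test suite and the acceptance script run
desk-scale versions chosen to converge acceptably: $96^2$ grids for the
noise sweep, $160^2$–$224^2$ for the population energy comparisons, 500
single-neuron and 20 population realizations. Episode input energy is the
quantity most sensitive to grid resolution, because the Gaussian end-point
well ($\sigma \approx 0.032$ in scaled units) spans only a few cells on
coarse grids; the well is under-resolved on anything much coarser than
$192^2$ and absolute episode energies at desk scale sit below their
fine-grid values, while orderings between strategies and network kinds are
stable across every resolution we run. Ensemble orderings are tested with
one-sided Welch tests (unequal variances across strategies) at
$p < 0.01$.

A note on the single-neuron 425 ms Monte Carlo statistics: the 7 ms policy
does not define a 425 ms control by itself. We implement the long-horizon
statistics as repeated independent 7 ms episodes from the spike point,
matching the per-episode cost semantics of the cost functional.

## Known limitations

* First-order backward time marching (no TVD-RK): the splitting and LLF
  dissipation smear the narrow terminal well on coarse grids, biasing
  desk-scale episode energies low (see above).
* The bilinear/central-difference policy read-off is not monotone near the
  saturation kink; in practice the clip to $\pm u_{max}$ bounds any
  overshoot.
* The gating-rate lookup table used inside the compiled SDE integrators
  introduces an $O(10^{-8})$ interpolation error relative to the exact
  rate functions (far below SDE discretization error); the HJB drift
  fields and all R-level model functions use exact expressions.
* No state estimation: feedback assumes the full state (single neuron) or
  the mean voltage (population) is observable noise-free.
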
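---
title: "Exact mean-field dynamics of a QIF excitatory-inhibitory network: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact mean-field dynamics of a QIF excitatory-inhibitory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qifdyn)
```

## The model and its assumptions

`qifdyn` treats one excitatory and one inhibitory population of quadratic
integrate-and-fire neurons,

$$\dot V = V^2 + \eta + I_\mathrm{ext} - J_e (V - E_e)\,S_e(t) - J_i (V - E_i)\,S_i(t),$$

all-to-all coupled through the instantaneous conductance gates
$S_k = N^{-1}\sum_l H(V_l - V_\mathrm{th})$, the fraction of the
presynaptic population above the gating threshold.  A spike is the escape
of $V$ to infinity; numerically the neuron is detected at $V_\mathrm{peak}$
and reset to $-V_\mathrm{peak}$.  The per-neuron constant current $\eta$ is
quenched disorder drawn from a Lorentzian with center $\bar\eta$ and
half-width $\Delta$.

Because the Lorentzian has simple poles, the $N\to\infty$ continuity
equation closes exactly under the ansatz that each population's voltage
density is Lorentzian with half-width $x_k = \pi r_k$ and center $v_k$,
where $r_k$ is the firing rate and $v_k$ the mean membrane potential.
The resulting four-dimensional system is

$$\dot r_k = \Delta/\pi + 2 r_k v_k - g_k r_k,\qquad
\dot v_k = \bar\eta + v_k^2 - \pi^2 r_k^2
 - J_e (v_k - E_e) S_e - J_i (v_k - E_i) S_i\ (+ I_\mathrm{ext}),$$

with $g_e = J_e S_e$, $g_i = J_i S_i$ in the form implemented by default
(`rate_coupling = "own"`; the variant `"full"` uses
$g_k = J_eS_e + J_iS_i$, the form a full conductance reduction produces —
at the reference parameters the two differ by less than a percent in every
quantity we examined).  The external stimulus drives the excitatory
population only (`iext_target = "excitatory"`); the alternative `"both"`
is available, but it suppresses the sustained collective oscillation at
$(I_\mathrm{ext}, J_e) = (8, 15)$ that the network clearly shows, so it is
not the default.

Reference parameters throughout: $J_e = 15$, $J_i = 8$, $E_e = 75$,
$E_i = -75$, $\bar\eta = -5$, $\Delta = 1$, $V_\mathrm{th} = 50$.  All
quantities are dimensionless model units; one model time unit is the unit
in which rates are conventionally quoted.

## The synaptic-gate convention — the decision that shapes everything

Evaluating $S_k$ under the ansatz is an elementary integral: the mass of a
Lorentzian with center $v$ and half-width $x = \pi r$ above
$V_\mathrm{th}$,

$$S = \frac1\pi\left(\frac\pi2 -
  \arctan\frac{V_\mathrm{th} - v}{\pi r}\right).$$

Printed statements of this reduction sometimes carry $r$ instead of
$\pi r$ in the denominator (the same slip that writes the pole as
$\pi r + i v$ one line earlier).  The two conventions give *qualitatively
different* phase diagrams, and only the exact $\pi r$ width reproduces the
phenomenology that the finite network itself shows:

* with the `"r"` gate there is **no bistability anywhere near**
  $(I_\mathrm{ext}, J_e) = (-3, 32)$ — a single quiescent equilibrium; the
  fold structure only appears at $J_e \gtrsim 45$;
* with the exact `"pi_r"` gate the $(-3, 32)$ point is bistable
  (quiescent state, saddle, high-rate focus at $r_e \approx 3.37$), the
  upper branch loses stability at a Hopf point at $J_e \approx 41.9$, and
  the full repertoire of the network appears.

`qifdyn` therefore defaults to `gate_width = "pi_r"` and keeps `"r"`
available for comparison.  Both forms are integrated by the same kernels,
and the analytic Jacobian covers both.

We verified the choice against the spiking simulation directly: a network
of $2\times2000$ neurons initialized on the `"pi_r"` focus stays there,
and its quiescent rate, oscillation period and stationary voltage
histogram match the `"pi_r"` mean field (next section); under the `"r"`
interpretation the focus does not exist at all.

## What the reduction does and does not reproduce

The test suite asserts, and the acceptance script recomputes, the model's
repertoire at named reference points (`experiment_catalogue()`): the
catalogue carries both the behaviour *reported* for each point in the
original two-parameter scenario and the behaviour this implementation
*actually produces* (`model_class`), so any drift is a test failure
rather than a silent relabel.  The two columns agree on quiescence,
sustained period-1 oscillation, the stable focus at $(5, 30)$, and
node+focus / node+cycle bistability along $I_\mathrm{ext} = -3$ — but not
on the locations of the period-doubled states:

* the reported period-2/period-4/chaotic points at
  $J_e = 51, 52.4, 53.5$ are **plain period-1** here; the coexisting
  cycle's Floquet multiplier closest to $-1$ stays in $(-0.7, 0)$
  everywhere we continued it ($J_e$ up to 130, several
  $I_\mathrm{ext}$ slices), so no period-doubling curve crosses the
  analysis window;
* strongly irregular, amplitude-modulated episodes do exist at
  $J_e \gtrsim 80\!-\!105$, but in long runs (1500 time units) they decay
  onto the stable period-1 cycle and the largest Lyapunov exponent stays
  at the cycle value ($\lambda \approx 0.002\!-\!0.004$, indistinguishable
  from 0 at our renormalization settings): chaotic *transients*, not a
  chaotic attractor, at the points we probed;
* consequently the traced curve set in the window
  $I_\mathrm{ext}\in[-6,10]$, $J_e\in[5,80]$ is the fold curve plus two
  genuine Hopf curves, and it bounds **6** regions (stable from raster
  resolution 300 through 1000), not 10.

These are honest properties of the equations as given; the acceptance
tests that encode the reported values stay red and say so.

## Bifurcation machinery

*Equilibria.* Multi-start damped Newton from a Halton low-discrepancy grid
over $r_k\in[0,20]$, $v_k\in[-80,80]$ (1024 starts by default),
deduplicated with rates scaled $\times 10$; every root is re-verified
(residual $<10^{-9}$) and classified from the analytic Jacobian's
eigenvalues with hyperbolicity tolerance $10^{-6}$.  Doubling the number
of starts does not change the root count at any tested operating point.

*Branches.* Pseudo-arclength predictor–corrector with adaptive step
(initial 0.01–0.1, halving on corrector failure).  Folds are flagged by
the tangent's parameter component reversing and localized by bisection in
arclength; Hopf points by the leading real part of a genuinely complex
pair (imaginary part $> 10^{-3}$) crossing zero, and the located point is
accepted only if the pair's frequency exceeds 0.05 — near-fold real pairs
otherwise masquerade as zero-frequency "Hopf" points.

*Codimension 2.* Fold and Hopf curves are continued as augmented defining
systems (equilibrium + null vector, or equilibrium + rotated complex
eigenpair with orthonormal phase fixing), with finite-difference
Jacobians of the defining system.  The Hopf system is symmetric under
$(q_i, \omega)\to(-q_i,-\omega)$, so continuation through $\omega = 0$
would silently retrace the same curve; tracing stops at the
Bogdanov–Takens collapse instead, and the loose end is snapped onto the
fold curve so the rasterized partition seals.  Period-doubling curves are
assembled from one-parameter slices: the cycle is continued in $J_e$ by
single shooting and the multiplier crossing of $-1$ bisected to
$10^{-4}$.

*Cycles.* Single shooting with the monodromy matrix from the variational
equations, a phase anchor along the largest vector-field component, and a
damped Newton that rejects steps leaving the basin; seeds are harvested
at the orbit's *rate minimum* (the slow phase — anchoring at the spike is
numerically the worst choice for relaxation-like orbits).  The trivial
multiplier's deviation from 1 is the accuracy diagnostic (typically
$10^{-13}\!-\!10^{-9}$ at `dt = 1e-4..1e-3`).

*Region counting.* Curves are rasterized onto a grid with sub-cell
sampling; the complement is flood-filled (4-connectivity) and components
smaller than 0.02% of the grid are discarded — they are one-or-two-cell
debris at curve crossings, not regions.  Counts are reported together
with a doubled-resolution recount.

## Numerical choices

* **Mean-field integrator**: classical RK4, default `dt = 1e-3`.  The
  often-quoted `dt = 0.01` is adequate in smooth regimes but overflows on
  the sharp rate spikes of the exact-gate system in strongly synchronized
  regimes; self-convergence at order 4 is part of the test suite, as is
  agreement with an independent fixed-step RK4 (`deSolve`) to $10^{-9}$.
* **Network integrator**: explicit Euler (`dt = 1e-3`); a smooth
  higher-order scheme is ill-defined across the discontinuous reset.
  Gates are evaluated from the pre-step state, one global gate per
  population per step, matching the all-to-all mean coupling.
* **Spike cutoff**: `Vpeak = 300`, `Vreset = -300`.  The free-neuron
  inter-spike-interval bias is $\approx 2/V_\mathrm{peak} < 1\%$, but the
  dominant finite-cutoff effect is subtler: the conductance gate counts
  the Lorentzian tail above $V_\mathrm{th}$, and a cutoff at 100 removes
  about half of that mass at working rates.  Measured at $2\times2000$
  neurons, the synchronized period differs from the mean field by 18–19%
  with cutoff 100 and by 3–4% with cutoff 300, which fixes the default.
* **Heterogeneity**: deterministic Lorentzian quantiles
  $\eta_j = \bar\eta + \Delta\tan\!\big(\pi(2j - n - 1)/(2(n+1))\big)$ by
  default (removes sampling noise from the quenched disorder; i.i.d.
  sampling available with `het_mode = "sample"`).
* **Rate estimator**: binned counts / $(N\,\mathrm{bin})$, bin 0.05,
  21-bin moving average for plots; period comparisons use bin 0.02 with a
  5-bin window because a smoothing window comparable to the oscillation
  period flattens the peaks it is supposed to locate.
* **Attractor classification**: transient removal of
  $\max(T/2,\,200)$ time units; peak sequences (quadratically refined on
  a full-resolution trace — sub-sampled storage aliases several percent
  of spike amplitude) classified period-$n$ at 2% relative tolerance on
  amplitudes and intervals, $n \le 16$, else "chaotic"; a chaos label is
  corroborated by $\lambda > 0.005$ from the Benettin two-trajectory
  exponent when both are computed.
* **Initial conditions for experiments**: the quiescent equilibrium at
  zero external input, offset by $10^{-3}$ in the rates, then the
  protocol is applied — starting *exactly* on an equilibrium (stable or
  not) freezes the trajectory there.

## Problem sizes

The suite and the acceptance script run the mean field at `dt = 1e-3`
over horizons of 80–400 time units, networks at $2\times(500\!-\!8000)$
neurons over 20–25 time units, Lyapunov estimates over 500–1500 time
units, and the two-parameter scenario at raster resolutions 300–800 —
sizes chosen so that each quantity is converged at the tolerance its test
asserts (finite-size error of the quiescent rate falls 0.20 → 0.12 → 0.07
across $N = 500, 2000, 8000$, and all counts are resolution-stable).

## Known limitations

* Coupling is all-to-all with a single global gate per population; no
  sparse or distance-dependent connectivity, no synaptic kinetics beyond
  the instantaneous Heaviside gate.
* The reduction requires the Lorentzian heterogeneity; no other disorder
  distributions are supported.
* Chaos diagnostics run on the mean field only; the spiking network is
  compared qualitatively.
* Only the largest Lyapunov exponent is computed.
* Sub/supercritical character of Hopf points is inferred from nearby
  attractor simulation, not from normal-form coefficients; the upper
  Hopf at $(I_\mathrm{ext}=-3, J_e\approx41.9)$ is subcritical (the
  stable cycle appears at a cycle fold near $J_e\approx46\!-\!48$ and
  coexists with the focus below the Hopf).
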
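# qifdyn

Dynamics of a two-population spiking network of quadratic
integrate-and-fire (QIF) neurons and of its exact mean-field reduction.

Large networks of spiking neurons are hard to analyse directly; for QIF
neurons with Lorentzian-distributed input currents the thermodynamic limit
admits an *exact* low-dimensional reduction: the population's
membrane-potential density stays Lorentzian with half-width `pi*r(t)` and
center `v(t)`, so the whole network collapses onto a small ODE system for
the firing rates and mean potentials.  `qifdyn` implements both levels for
an excitatory (e) / inhibitory (i) pair with conductance-based
instantaneous synapses, plus the dynamical-systems tooling needed to map
the model's repertoire: quiescence, high-rate focus, collective
oscillations, bistability, and long chaotic transients.

## The model

Each neuron obeys `dV/dt = V^2 + eta + I_ext - I_syn`, spikes at
`V_peak` and resets to `-V_peak`, with

    I_syn = Je (V - Ee) Se(t) + Ji (V - Ei) Si(t),
    Sk(t) = (1/N) sum_l H(V_l - Vth),

where `Sk` is the fraction of population `k` above the gating threshold.
With `eta ~ Lorentzian(eta_bar, delta)` the exact mean field is the 4-D
system for `(r_e, v_e, r_i, v_i)`:

    dr_k/dt = delta/pi + 2 r_k v_k - g_k r_k
    dv_k/dt = eta_bar + v_k^2 - (pi r_k)^2
              - Je (v_k - Ee) Se - Ji (v_k - Ei) Si  (+ I_ext for k = e)

with gates `Sk = (1/pi) * (pi/2 - atan((Vth - v_k)/(pi r_k)))` — the mass
of the Lorentzian voltage density above `Vth`.  Reference parameters:
`Je = 15, Ji = 8, Ee = 75, Ei = -75, eta_bar = -5, delta = 1, Vth = 50`.
Both gate-width conventions found in the literature for this reduction
(`pi*r`, exact, the default; and plain `r`) are available via
`qif_params(gate_width = )`; the two give qualitatively different
bifurcation diagrams, which the methods vignette discusses in detail.

## What the package provides

* `run_network()` — compiled Euler simulation of the spiking pair
  (raster, population rates, gate traces), with deterministic quantile
  heterogeneity for sharp finite-size comparisons.
* `mf_integrate()` — compiled fixed-step RK4 for the mean field under
  piecewise-constant stimulus protocols (`step_protocol()`,
  `bistability_protocol()`, ...).
* `find_equilibria()`, `mf_jacobian()`, `classify_eigenvalues()` —
  multi-start Newton equilibrium location with eigenvalue classification.
* `continue_equilibrium()`, `find_limit_cycle()`,
  `continue_limit_cycle()` — pseudo-arclength branch continuation with
  fold/Hopf detection, and single-shooting periodic orbits with Floquet
  multipliers.
* `trace_codim2_curve()`, `trace_pd_curve()`, `partition_regions()`,
  `two_parameter_scenario()` — fold/Hopf curves in the `(I_ext, Je)`
  plane by augmented defining systems, period-doubling search by
  multiplier bisection on one-parameter slices, and flood-fill region
  counting.
* `detect_peaks()`, `classify_period()`, `isi_bifurcation_sweep()`,
  `lyapunov_max()` — attractor classification, orbit diagrams and the
  largest Lyapunov exponent (Benettin method).

## Worked example: bistability probed by a transient pulse

At `(I_ext, Je) = (-3, 32)` the mean field has three equilibria — a
quiescent state, a saddle, and a high-rate focus:

```r
library(qifdyn)
p <- qif_params(Je = 32)
find_equilibria(p, Iext = -3, n_starts = 512)
#> 3 equilibria at I_ext = -3
#>   r_e=0.06441 v_e= -2.4514 r_i=0.09024 v_i= -1.7567  stable focus   |f|=6.9e-14
#>   r_e=0.34936 v_e= -0.3445 r_i=0.64268 v_i= -0.1965  saddle         |f|=7.4e-14
#>   r_e=3.37364 v_e=  1.0385 r_i=3.43583 v_i=  0.2256  stable focus   |f|=4.1e-13
```

A 2-time-unit pulse to `I_ext = +3` switches the system from the
quiescent state onto the coexisting high-rate focus, where it stays after
the pulse ends:

```r
eq <- quiescent_equilibrium(p, -3)
tr <- mf_integrate(eq$state + c(1e-3, 0, 1e-3, 0),
                   bistability_protocol(-3, 3, 80), p)
mean(tr$r_e[tr$t > 70])
#> [1] 3.373635
```

The settled rate 3.37 is the `r_e` coordinate of the upper focus: the
persistent activity that a transient stimulus writes into the network.
The two-parameter scenario over `I_ext in [-6, 10]`, `Je in [5, 80]`
traces the fold curve and the two genuine Hopf curves and counts the
regions they bound:

```r
sc <- two_parameter_scenario(qif_params(), resolution = 400)
sc$n_regions
#> [1] 6
```

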
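# inertabp

Underdamped active Brownian motion in R: simulation, closed-form theory,
trajectory statistics, and parameter inference.

## The problem

Motile microorganisms and colloidal microswimmers are well described by
*overdamped* active Brownian motion: friction swamps inertia, so the
velocity is slaved to the propulsion direction.  Macroscopic
self-propelled particles — vibrated granular robots ("vibrobots"),
activated complex-plasma grains, floating and flying organisms — are not
in that regime.  Their finite mass $M$ and moment of inertia $J$ produce
two qualitatively new effects: the velocity direction *lags* the body
orientation by a measurable delay, and the long-time diffusion
coefficient acquires an explicit, unbounded dependence on the moment of
inertia.  `inertabp` is a toolbox for the model behind those effects,
the underdamped Langevin equations

$$M\ddot R + \xi \dot R = \xi V_p\, n(t) + \xi\sqrt{2D}\, f_{st}(t),
\qquad
J\ddot\phi + \xi_r\dot\phi = \tau_0 + \xi_r\sqrt{2D_r}\,\tau_{st}(t),$$

with propulsion axis $n = (\cos\phi, \sin\phi)$, white noises $f_{st}$,
$\tau_{st}$, and the six identifiable rates $\tau = M/\xi$,
$\tau_r = J/\xi_r$, $D$, $D_r$, $V_p$, $\omega = \tau_0/\xi_r$.

It is intended for people who simulate or measure inertial
self-propelled particles: it generates trajectories with exact
Ornstein–Uhlenbeck transitions, evaluates every closed-form observable
of the model (orientational correlation, kinetic factor
$\mathfrak{f}(\mathcal{D}_0,\mathcal{D}_1,\mathcal{D}_2)$, short- and
long-time mean squared displacements, long-time diffusivity $D_L$ and
its small-/large-$J$ asymptotics, the analytic delay function, angular
and velocity distributions), mirrors the experimental estimators
(finite-difference velocimetry, time-and-ensemble-averaged MSDs,
histograms with error bands, the empirical delay function), and
recovers the six rates from trajectory ensembles by the staged
iterative fit plus a Nelder–Mead refinement against all curves.

The central special function is the lower incomplete gamma function of
complex argument, $\gamma(\mathcal{D}_0 - i\mathcal{D}_1 \pm
\mathcal{D}_2,\ \mathcal{D}_0)$, evaluated through an overflow-free
regularised Kummer series (see the methods vignette
`vignettes/underdamped-abp.Rmd`).

## Worked example

Simulate an ensemble of inertial circle swimmers at the reference
parameter set, compare the measured inertial delay with the closed
form, and recover the parameters:

```r
library(inertabp)

p <- abp_preset("fig2")     # tau = 1/6.46 s, tau_r = 1/5.4 s, D = 8e-5,
                            # D_r = 2.59, V_p = 0.092, omega = 0.7
delay_numbers(p)
#> delay numbers: D0 = 0.47963, D1 = 0.12963, D2 = 1.1963

f_delay(delay_numbers(p))          # fraction of V_p^2 in <v^2>
#> [1] 0.8542003
velocity_second_moment(p)          # 2D/tau + f V_p^2, m^2/s^2
#> [1] 0.008263551
long_time_diffusion(p)             # m^2/s
#> [1] 0.002185151

# the analytic delay function peaks after ~0.34 s
tt <- seq(0, 2, by = 1e-3)
C <- delay_function_analytic(p, tt)
tt[which.max(C)]
#> [1] 0.343

# synthetic experiment: 60 runs, 150 Hz-style sampling
cfg <- sim_config(dt = 0.0066, n_steps = 6000, n_runs = 60, seed = 101,
                  init = "stationary")
ens <- simulate_ensemble(p, cfg)
cs  <- abp_curves(ens)

fit <- fit_abp(cs)                 # staged: rotational stage, then the
fit$params                         # f-bounded translational iteration
#> Underdamped active Brownian particle parameters
#>   tau   = 0.135172 s      (1/tau   = 7.398 1/s)
#>   tau_r = 0.192153 s      (1/tau_r = 5.2042 1/s)
#>   D     = 7.00697e-05 m^2/s
#>   D_r   = 2.70803 rad^2/s
#>   v_p   = 0.090853 m/s
#>   omega = 0.701442 rad/s
#>   delay numbers: D0 = 0.5204, D1 = 0.1348, D2 = 1.422
```

The staged estimate lands within ~10–15% of the generating parameters
(τ and D are the soft directions — only their product enters the
dominant terms); `fit_full(cs, fit$params)` then refines all six rates
against the full curve set, including the delay function, and
`fit_uncertainty()` reports quadrupled-error intervals.

A command-line front end over the same functions is installed at
`inst/cli/abp-tool.R` (subcommands `simulate`, `analyze`, `compare`,
`fit`).

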
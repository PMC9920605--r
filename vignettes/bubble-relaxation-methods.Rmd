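---
title: "Methods: bubble relaxation dynamics in the PBD model of DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bubble relaxation dynamics in the PBD model of DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bubblerelax` simulates homopolymer DNA with the Peyrard–Bishop–Dauxois
(PBD) lattice: one transverse coordinate $y_n$ (Å) per base pair, the
stretching of the pair away from its equilibrium hydrogen-bond distance.
The Hamiltonian over $N$ base pairs with periodic boundaries ($y_0 = y_N$)
is

$$H = \sum_{n=1}^{N} \frac{p_n^2}{2m} + V_1(y_n) + V_2(y_n, y_{n-1}),$$

with the on-site Morse pairing potential
$V_1(y) = D\,(e^{-a y} - 1)^2$ and the anharmonic stacking coupling
$V_2(y_n, y_{n-1}) = \tfrac{K}{2}\,
\big(1 + \rho\, e^{-b (y_n + y_{n-1})}\big)\,(y_n - y_{n-1})^2.$
The Morse plateau $D$ is the pairing dissociation energy; the stacking
stiffness interpolates between $K(1+\rho)$ when both neighbours are closed
and $K$ when both are open, which is the mechanism behind sharp thermal
denaturation in this model family.

Parameters are the standard melting-curve calibration:

| parameter | AT | GC | units |
|---|---|---|---|
| $D$ | 0.05 | 0.075 | eV |
| $a$ | 4.2 | 6.9 | 1/Å |
| $K$ | 0.0228 | 0.0192 | eV/Å² |
| $\rho$ | 2 | 2 | — |
| $b$ | 0.35 | 0.35 | 1/Å |
| $m$ | 300 | 300 | amu |

The calibration source for $D$, $a$, $\rho$, $b$ does not pin the reduced
mass uniquely in every later study; we adopt the standard $m = 300$ amu of
that parameterisation and expose it as a `pbd_params()` field, so
sensitivity to it can be probed directly.

**Units.** Everything internal is eV–Å–amu, which keeps the table above
verbatim; the derived time unit is $\sqrt{\mathrm{amu}\,\text{Å}^2 /
\mathrm{eV}} \approx 10.1805$ fs. All user-facing times are in fs (time
steps), ps (recording grids) or ns (durations and relaxation times).

**Temperature.** Simulations are strictly microcanonical: no thermostat,
temperature emerges as $T = 2\langle \mathrm{KE}\rangle/(N k_B)$. Energies
of 0.043 eV (AT) and 0.045 eV (GC) per base pair put the chain at
physiological temperature, around 310 K. The anharmonicity is strong at
this energy — roughly a third of the energy is kinetic, and the mean
displacement $\langle y\rangle$ is positive and of order half an Å — which
is exactly the near-melting softness that makes bubble dynamics
interesting.

## Integration

The integrator is the six-stage symplectic Runge–Kutta–Nyström composition
SRKN$^b_6$ (kick coefficients $b_1 \ldots b_4$ mirrored symmetrically, six
force evaluations per step once adjacent kicks are merged). Being
symplectic, its energy error is bounded rather than secular, so multi-µs
runs remain trustworthy. Two controls are built in for diagnostics:
velocity Verlet (symplectic, lower order) and classical RK4
(non-symplectic; its drift grows roughly linearly in time, which the test
suite asserts as the contrast case).

The default timestep is 10 fs, about 1/80 of the fastest AT phonon period
(1/50 for GC). The package enforces an explicit drift contract: the
recorded relative energy error $|H(t) - H(0)|/H(0)$ must stay below
`drift_tolerance` (default $10^{-7}$), else the trajectory record is
flagged with a warning. At 10 fs the observed drift of thermalised N = 300
chains is ~$10^{-9}$–$10^{-8}$; 20 fs sits near $10^{-7}$ and can breach
the contract on unlucky realisations, which is why 10 fs is the default
everywhere, including the slow ensemble tests.

Recording uses a logarithmic grid (default 50 points per decade from
0.01 ps, plus $t = 0$) because the relaxation spans five decades in time;
requested instants snap to the step grid.

## Protocol

Each realisation follows the same pipeline:

1. **Initialisation** — `initial_state()`: $y_i = 0$, momenta drawn from a
   zero-mean normal and rescaled by one scalar so $\sum p^2/2m$ equals
   $N \varepsilon$ exactly.
2. **Thermalisation** — `thermalise()`: 10 ns of free evolution (the
   full-scale condition; scaled studies may shorten it — kinetic
   temperature equilibrates within a few hundred ps at these energies).
   The chain-mean displacement is time-averaged over the final 1 ns and
   carried along as the equilibrium displacement estimate.
3. **Bubble insertion** — `insert_bubble()`: displacements of the $w$
   central sites are replaced by the Gaussian $y(x) = h\,
   e^{-(x-c)^2/2\sigma^2}$ with $\sigma = w/6$ (tails at $3\sigma$, i.e.
   $\approx 0.011\,h$, near equilibrium). The remaining $N - w$
   displacements are multiplied by a common factor $\lambda$, found by
   bisection on $\lambda \mapsto H'(\lambda)$, until $|H' - H| <
   10^{-10}$ eV. Momenta are untouched, so insertion changes neither the
   total energy nor the temperature.
4. **Relaxation** — `evolve()` for 100 ns (AT) or 5 µs (GC) at full scale,
   recording the bubble window's displacements and local energies in log
   time, with $t = 0$ the insertion instant.

Design choices worth stating:

* *Rescaling form.* A single multiplicative $\lambda$ on all non-bubble
  displacements is the simplest scheme a one-dimensional bisection can
  solve. $H'(\lambda)$ need not be monotone; the bracket $[0, 1]$ (grown
  ×2 up to 8 when needed) is verified by a sign change before bisecting,
  and an infeasible insertion — more potential energy in the bubble than
  can be removed outside — raises an error naming the shortfall in eV.
  Since an inserted bubble essentially always adds window energy,
  $\lambda < 1$ in practice, i.e. the environment is slightly cooled in
  displacement space.
* *Equilibrium displacement.* $y_{eq}$ is a time average over the final
  1 ns of thermalisation and an ensemble average over runs, not a single
  pre-insertion snapshot; a single instant of one chain has $O(N^{-1/2})$
  scatter that would leak into the limiting value $\chi_D$.
* *Boundaries.* Periodic by default. At N = 300 the bubble window is ~50
  sites from the boundary seam and boundary effects on the relaxation are
  negligible; free boundaries can be emulated by constructing states
  directly, but the packaged protocol is periodic.
* *Seeds.* A master seed expands to per-realisation seeds by a recorded
  counter-based draw; every realisation is bitwise reproducible alone.

## Autocorrelation analysis

Over the bubble window ($w$ sites), the package computes the raw,
non-normalised, $t=0$-anchored products

$$C_D(t) = \Big\langle \tfrac{1}{w} \textstyle\sum_i y_i(0)\, y_i(t)
\Big\rangle, \qquad
C_E(t) = \Big\langle \tfrac{1}{w} \textstyle\sum_i \varepsilon_i(0)\,
\varepsilon_i(t) \Big\rangle,$$

with $\varepsilon_i = p_i^2/2m + V_1(y_i) + \tfrac12\big(V_2(y_{i+1},
y_i) + V_2(y_i, y_{i-1})\big)$, so $\sum_i \varepsilon_i = H$ exactly.
No mean subtraction or normalisation is applied: only in this raw form do
the limiting values

$$\chi_D = \Big\langle \tfrac{1}{w} \textstyle\sum_i y_i(0)
\Big\rangle\, y_{eq}, \qquad
\chi_E = \Big\langle \tfrac{1}{w} \textstyle\sum_i \varepsilon_i(0)
\Big\rangle\, \varepsilon_{eq}$$

act as long-time asymptotes. For the energies, $\varepsilon_{eq}$ is just
the configured energy per site (0.043/0.045 eV): microcanonical evolution
fixes the mean local energy. Uncertainty bands are the standard deviation
of the ensemble mean per time point; the estimator is linear in runs, so
half-ensemble means average exactly to the full mean (asserted in tests).

## Stretched-exponential fitting

The decay stage is fitted with the Kohlrausch–Williams–Watts form

$$C(t) = A \exp\!\big[-(t/\tau)^\beta\big] + \chi,$$

with $\chi$ **fixed** at the limiting value — it is a known asymptote, not
a free parameter — and $(A, \tau, \beta)$ free, by weighted
Levenberg–Marquardt least squares (weights $1/\mathrm{sem}^2$) on the
log-spaced points with $t \ge t_{start}$. Initial guesses:
$A = C(t_{start}) - \chi$, $\tau$ at the $1/e$ crossing of $C - \chi$,
$\beta = 0.7$; bounds $A \ge 0$, $\tau > 0$, $\beta \in [0.05, 2]$.

**Fit window.** Relaxation has an oscillatory first stage (bubble
rearrangement, up to ~20 ps in AT, 10–40 ps in GC) that the KWW form does
not describe. `select_fit_start()` median-smooths the mean curve over 5
grid points and returns the earliest time after the last "significant
rise", where a rise between consecutive points counts as significant if
it exceeds twice the standard error of the difference of two ensemble
means: coherent oscillations rise by far more than the SEM and are
excluded; incoherent tail noise is not. For energy autocorrelations the
oscillations are strongly suppressed, so this rule alone can return
t = 0 even though the first tens of ps are kinetic-energy decorrelation
and rearrangement rather than the rapid decay stage; the experiment
pipeline therefore floors the automatic start at 0.04 ns (just past both
homopolymers' oscillatory windows; `fit_min_start_ns`). At the other end,
once the smoothed mean has converged to `chi` the remaining record is
noise — in a small ensemble a single realisation whose rearranged bubble
survives for many nanoseconds can hold the tail visibly above the
asymptote — so `select_fit_end()` truncates the window where the smoothed
curve first comes within half a median-SEM of `chi`. Both ends are
overridable everywhere.

**Optimisation.** The KWW objective on noisy, decade-limited data is
multimodal, with a degenerate ridge at very small `beta` (a nearly flat,
power-law-like profile) that can undercut the physical optimum. The
fitter restarts Levenberg–Marquardt from a small grid of `(tau, beta)`
values and keeps the lowest weighted-SSE solution, bounds `beta` below at
0.3 by default (fitted exponents for these relaxations sit well above
that, and smaller values would imply implausibly broad relaxation-time
distributions), and caps `A` at three times the amplitude remaining at
the window start. Each safeguard can be switched off
(`multistart = FALSE`, `beta_range`).

**Average relaxation time.** The fitted curve is summarised by
$\tau_{av} = \Gamma(1/\beta)\,\tau/\beta$, the mean of the underlying
relaxation-time distribution, equal to $\int_0^\infty
e^{-(t/\tau)^\beta} dt$ (asserted against numerical quadrature to
$10^{-8}$).

**Uncertainties.** Bootstrap over realisations: resample runs with
replacement, rebuild the mean curve, refit with the same $\chi$ and
$t_{start}$, report parameter standard deviations across resamples
(default 1000 resamples; an error is raised if more than 10% of refits
fail). With small ensembles the $\tau_{av}$ resampling distribution is
heavy-tailed — a low-$\beta$ refit inflates $\Gamma(1/\beta)/\beta$ — so
desk-scale bootstrap bands should be read as conservative.

## Trends in amplitude and width

Per width, $\tau_{av}(h)$ is fitted with a weighted straight line
$\tau_{av} = \tau_0 + \alpha h$; across widths, $\tau_0(w)$ and
$\alpha(w)$ are fitted with straight lines in turn, composing a closed
form $\tau_{av}(w, h)$. Uncertainties are printed in compact parenthesis
notation (`0.24(8)` for 0.238 ± 0.082). The test suite round-trips an
exactly linear synthetic $\tau_{av}$ surface through both fitting layers.

## Synthetic fixtures

`synth_kww_ensemble()` generates noisy KWW ensembles with known
$(A, \tau, \beta, \chi)$: per-run curves carry AR(1) noise along the time
grid (lag-1 correlation 0.5, marginal sd `noise_scale`). Correlated noise
is deliberate — real per-run autocorrelation curves are smooth, so
independent noise would make parameter recovery unrealistically easy and
overstate fit precision. `phonon_fixture()` provides plane-wave initial
conditions with the analytic dispersion
$\omega(q)^2 = \big(2 D a^2 + 2 K (1+\rho)(1 - \cos q)\big)/m$, the
linearisation oracle for the integrator (frequencies match to 0.1%).
`mini_ensemble()` runs the full protocol at reduced scale.

What the fixtures do **not** emulate: the oscillatory rearrangement stage,
the slow intermediate decay of GC relaxation, and any coupling between
$A$, $\tau$, $\beta$ across runs. Passing the fixture-based tests
demonstrates that the analysis stage is calibrated, not that the dynamics
are right — the dynamics are checked separately against conservation
contracts, dispersion oracles and the emergent 310 K temperature.

## Problem sizes

Full-scale study conditions are N = 300, 10 ns thermalisation, and
2000 runs × 100 ns (AT) or 1000 runs × 5 µs (GC); these are provided as
the named profiles `AT_full` and `GC_full` and are cluster-scale jobs (the
GC profile integrates ~5 ms of total chain time, on the order of a
core-month at ~2 s per simulated ns). The packaged desk-scale checks
instead use ensembles of 10–200 runs, 1.5–2 ns thermalisation and
5–15 ns post-insertion windows for AT, which resolve AT relaxation times
(0.5–2 ns) well; GC relaxation (hundreds of ns) is validated at the
property level only (trend directions, scaled fixtures), not against its
full-scale values. Reduced thermalisation is benign here because the
kinetic temperature and mean displacement plateau within a few hundred
ps. At ten runs per cell the mean-curve estimator inherits visible
skew from rare long-lived localised structures, which is why the fit
window is truncated at convergence and why desk-scale `tau_av` values
carry generous bootstrap bands; ensemble size is the single knob that
tightens them.

## Known limitations

* Homopolymers only: a single $(D, a, K)$ per run; heterogeneous
  sequence-dependent stacking tables are out of scope.
* One degree of freedom per base pair: no helicity, torsion, bending,
  solvent or counter-ion effects; "bubble" means large transverse
  stretching in this reduced geometry.
* The KWW fit describes the rapid-decay stage only; the early oscillatory
  stage is excluded by construction, and displacement autocorrelations —
  whose short decay stage makes their fits sensitive to $t_{start}$ — are
  supported but the energy autocorrelation is the headline observable.
* Desk-scale ensembles make trend coefficients reproducible only within
  their (bootstrap) uncertainties; tightening them is purely a matter of
  ensemble size and run length.
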
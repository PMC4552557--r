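---
title: "Thermodynamics of the reversible MinDE oscillator: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of the reversible MinDE oscillator: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`minflux` simulates the pole-to-pole oscillation of the Min proteins in a
rod-shaped bacterium and accounts, term by term, for the free energy the
oscillation dissipates. The cell is a cylinder (radius $R = 0.5\,\mu m$,
length $L = 4\,\mu m$). Three species diffuse in the cytoplasm — MinD:ADP
($\rho_{D:D}$), MinD:ATP ($\rho_{D:T}$) and the MinE dimer ($\rho_E$) —
and two live on the membrane without diffusing: membrane-bound MinD:ATP
($\rho_d$) and the MinE:MinD:ATP complex ($\rho_{de}$). MinC rides along
with MinD in the real cell but does not feed back on the oscillation, so
it is not part of the dynamical model.

Four reaction steps close a "futile" cycle, and — unlike most published
Min models — every step is microscopically reversible, with mass-action
flux densities

1. nucleotide exchange: $j_{+1} = k_{+1}\rho_{D:D}$,
   $j_{-1} = k_{-1}\rho_{D:T}$ (volumetric);
2. membrane attachment, spontaneous $j_{+2} = k_{+2}\rho_{D:T}$,
   $j_{-2} = k_{-2}\rho_d$ and cooperative
   $j_{+2'} = k_{+2'}\rho_{D:T}(\rho_d + \rho_{de})$,
   $j_{-2'} = k_{-2'}\rho_d(\rho_d + \rho_{de})$;
3. MinE recruitment: $j_{+3} = k_{+3}\rho_E\rho_d$,
   $j_{-3} = k_{-3}\rho_{de}$;
4. MinE-aided release (ATP hydrolysis): $j_{+4} = k_{+4}\rho_{de}$,
   $j_{-4} = k_{-4}\rho_{D:D}\rho_E$.

The cytoplasmic species obey diffusion equations with $\pm j_1$ as the
only volumetric source; the membrane species obey
$\partial_t \rho_d = j_2 + j_{2'} - j_3$ and
$\partial_t \rho_{de} = j_3 - j_4$, and the membrane reactions enter the
cytoplasm as boundary fluxes (attachment removes MinD:ATP, release
injects MinD:ADP, recruitment/release exchange MinE). Total MinD
($N_D = 2000$) and MinE dimers ($N_E = 700$) are conserved.

The nonequilibrium parameter
$\gamma = \frac{k_{+1}k_{+2}k_{+3}k_{+4}}{k_{-1}k_{-2}k_{-3}k_{-4}}$
is dimensionless; $\gamma = 1$ is detailed balance and $\ln\gamma$ is the
chemical free energy (in $k_BT$) dissipated per completed cycle, i.e. per
ATP. The spontaneous and cooperative attachment channels are two routes
over the same free-energy drop, which is why the package enforces
$k_{+2}/k_{-2} = k_{+2'}/k_{-2'}$ at construction time. Per-step standard
free energies $\Delta G_i = \ln(k_{-i}/k_{+i})$ refer to unit Min
concentrations at fixed physiological ATP/ADP/Pi pools (the nucleotides
are folded into the rate constants), so they are meaningful relative to
that convention only; they always satisfy
$\sum_i \Delta G_i = -\ln\gamma$.

## Dissipation accounting

Each reaction step dissipates locally at the rate density
$\sigma_i = (j_{+i} - j_{-i})\ln(j_{+i}/j_{-i}) \ge 0$; step 2 folds in
the cooperative channel as $\sigma_2 = (j_2 + j_{2'})\ln(j_{+2}/j_{-2})$,
which is exact because both channels share one free-energy drop.
Diffusion dissipates at $|\mathbf j|^2 / (D\rho)$ — the continuum limit
of the entropy production of unbiased hopping on a lattice, a limit the
test suite verifies against an independent master-equation oracle on 1D
chains. The chemical uptake rate is $\sigma_{ATP}(t) = J_1(t)\ln\gamma$
with $J_1$ the volume-integrated nucleotide-exchange flux.
Instantaneously $\sigma_{ATP} \ne \sigma_{tot}$ during oscillation, but
their averages over whole periods must agree, and the period-averaged
fluxes of the four steps must balance:
$\langle J_1 \rangle = \langle J_2 + J_{2'} \rangle = \langle J_3
\rangle = \langle J_4 \rangle \equiv \langle J \rangle$, with
$\langle\sigma\rangle = \langle J\rangle \ln\gamma$. These closures are
computed by `period_averaged_budget()` and asserted (at 1%) in the test
suite. When almost all MinE is membrane-bound the cycle flux saturates
at $k_{+4} N_E$, giving the kinetic ceiling
$\langle\sigma\rangle_{osc} \approx k_{+4} N_E \ln\gamma$
(`dissipation_ceiling()`).

## Parameters and defaults

Forward rates are the experimentally grounded values used across the Min
modelling literature: $k_{+1} = 6\,s^{-1}$, $k_{+2} = 0.1\,\mu m\,s^{-1}$,
$k_{+2'} = 0.01\,\mu m^3 s^{-1}$, $k_{+3} = 0.4\,\mu m^3 s^{-1}$,
$k_{+4} = 1\,s^{-1}$, with $D_D = 16$ and $D_E = 10\,\mu m^2 s^{-1}$.
The backward rates are the experiment's control dials; the package
defaults to the reference oscillatory set $k_{-1} = 0.6\,s^{-1}$,
$k_{-2} = 0.01\,s^{-1}$, $k_{-2'} = 10^{-3}\,\mu m^2 s^{-1}$,
$k_{-3} = 0.04\,s^{-1}$, $k_{-4} = 10^{-5}\,\mu m^4 s^{-1}$, i.e.
$\gamma = 10^8$, $\ln\gamma \approx 18.4$ — the physiological free energy
of one ATP hydrolysis. `presets()` carries the named variants: the
dissipation axis (sweeping $k_{-1}$), the $k_{+4}$ window axis
($k_{-1} = 0.06\,s^{-1}$), the stationary regime ($k_{-1} = 30\,s^{-1}$),
the non-cooperative control ($k_{+2} = 1\,\mu m\,s^{-1}$,
$k_{-2} = 0.1\,s^{-1}$, no cooperative channel), and the fixed-budget
strategy search. Units are micrometres and seconds throughout; energies
are $k_BT$; configs may attach unit strings which are validated
literally (no SI prefixes).

## Numerics

*Discretization.* An axisymmetric finite-volume mesh: annular cells of
width `dr` and height `dz` (defaults 0.1 µm), membrane patches on the
lateral wall and on both end caps. Membrane reaction fluxes enter the
adjacent cell scaled by patch-area over cell-volume, so conservation of
$N_D$ and $N_E$ holds discretely by construction; the solver keeps it to
better than $10^{-6}$ relative over long runs. The explicit end caps
matter: they absorb MinD:ATP, deplete membrane binding nearby, and
produce the slightly mid-cell-enriched profiles (negative performance)
of the stationary regime, which a 1D reduction cannot show.

*Integration.* The method-of-lines system is stiff (cooperative
attachment and recruitment at high membrane density). We integrate it
with `deSolve::lsodes` (sparse implicit BDF, adaptive steps) at
`rtol = 1e-6`, `atol = 1e-9`, with the right-hand side compiled in C++.
No clipping is applied anywhere; nonnegativity is maintained by the
tolerances alone and checked in the tests. The dynamics are
deterministic — there is no random number stream in the package.

*Initial condition.* The uniform state is an unstable solution, so runs
start from a symmetry-breaking step: all MinD mass as cytoplasmic
MinD:ADP in the half-cell $z < L/2$, MinE uniform, everything else zero.
Any asymmetric perturbation selects the same limit cycle; the step is
merely the cleanest. (A fully symmetric start stays symmetric, which the
tests confirm.)

*Oscillation detection.* The probe is membrane-bound MinD averaged over
one end cap. After discarding the first half of the run as transient,
the system counts as oscillating when sd/mean of the probe exceeds
$10^{-3}$ *and* the amplitude is sustained: the cv over the last half of
the analysis window must be at least 0.3 times the cv over the first
half. The second condition is needed because near the bifurcation a
stable focus rings down over hundreds of seconds (critical slowing
down), and a bare variance threshold would misread that decaying spiral
as a limit cycle and bias every onset estimate low. The period is the
mean spacing of successive probe maxima, cross-checked against the first
autocorrelation peak; fewer than three maxima is reported as
undetermined.

*Performance score.* The time-averaged lateral-membrane profile of
$\rho_d + \rho_{de}$ (caps excluded, axis normalized to $[0,1]$) is
rescaled by its mid-cell value. If any point exceeds 1 the depth is
$h = \max - 1 > 0$ (valley at mid-cell); if the mid-cell is itself the
maximum, $h = \min - 1 < 0$. The width $w$ is the distance between the
half-depth crossings (level $1 + h/2$) found moving outward from
mid-cell, falling back to the pole position on a side that never crosses;
a flat profile scores exactly 0. Half-depth is the standard width
convention; it is our operationalization and is applied uniformly.
Averages always use an integer number of detected periods (default: the
last 5).

*Bifurcation localization.* Log-scale bisection on a single rate between
endpoints of opposite classification, to a default 5% relative bracket.
Classification runs are 1200 s long: near-critical transients decay
slowly, and shorter runs blur the boundary. A zero-width bracket returns
the endpoint with a warning; equal endpoint classifications are an
error, not a guess.

*Strategy search.* A deterministic grid over
$(\Delta G_1, \Delta G_3, \Delta G_4)$ with $\Delta G_2$ closed by the
budget, default $13^3$ over $[-12, 0]\,k_BT$, with one local refinement
pass halving the spacing around the incumbent; ties break toward the
smaller average dissipation (prefer the cheaper strategy). The test
suite exercises a thinned grid (step 3 $k_BT$, i.e. $5^3$ points) on a
0.25/0.2 µm mesh with 400 s runs — enough to rank the dissipation
fractions at the optimum; reproducing the exact published partition
percentages needs the full grid and is left to the user with time on
their hands.

*Problem sizes used by the shipped tests and acceptance script* (stated
here as the package's own choices): reference runs 600 s on the 0.1 µm
mesh (700 unknowns); bifurcation bisections 1200 s per classification,
about 8–9 runs per axis; strategy scans as above. On one ordinary CPU
core the reference run takes about one second.

## What the model does and does not emulate

The simulator *is* the data generator: it reproduces the deterministic
reaction–diffusion field theory of the Min oscillator under the study's
conditions — pole-to-pole oscillation with a roughly 40 s period at the
reference rates, onset of oscillation only beyond a finite dissipation
threshold, MinE sequestration onto the membrane across that threshold,
and the mid-cell valley in the time-averaged membrane MinD profile.
It does not emulate: finite-copy-number fluctuations (the deterministic
picture is accurate above roughly 2000 molecules, but noise in period
and profile is absent here); MinC dynamics and FtsZ-ring inhibition
(downstream of the oscillator); membrane-bound diffusion or direct
MinE–membrane binding (alternative mechanisms deliberately out of
scope); non-axisymmetric 3D modes; and cell growth or division. Passing
tests therefore validate the reversible field model and its
thermodynamic bookkeeping, not the stochastic behaviour of a real cell.

## Known limitations

- Quantities tied to bifurcation locations inherit an O(few %)
  discretization dialect; the finite-volume mesh here is not the same
  spatial scheme as a finite-element solver, so critical values are
  reproducible to a few percent, not to the digit.
- The irreversible limit ($k_{-i} \to 0$) is singular: dissipation
  diverges. The package refuses to construct such models and returns a
  flagged `Inf` from the dissipation densities rather than a large
  float.
- $\Delta G_i$ values are relative to the fixed-nucleotide-pool
  convention; only differences and $\ln\gamma$ are physically
  comparable across parameter sets.
- Diffusive dissipation integrates interior fluxes only; the
  membrane-adjacent boundary-flux contribution is excluded by
  convention. Diffusion is a percent-level share of the total, so the
  convention does not move any headline number.
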
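# minflux

Nonequilibrium thermodynamics of the *E. coli* MinDE oscillator, in R.

The Min proteins oscillate pole-to-pole in a rod-shaped bacterium and,
on time average, mark the mid-cell for symmetric division. `minflux`
simulates that oscillation with a **microscopically reversible**
reaction–diffusion model — every step of the MinD ATPase cycle carries a
forward *and* a backward flux — so the free energy the oscillator burns
can be accounted for exactly, step by step. It is intended for
quantitative biologists and biophysicists who want to ask not just
*does it oscillate?* but *what does the oscillation cost, and where is
the energy spent?*

## The model in brief

Three cytoplasmic species (MinD:ADP, MinD:ATP, MinE dimers) diffuse in a
cylindrical cell (R = 0.5 µm, L = 4 µm); two membrane species
(MinD:ATP and MinE:MinD:ATP) live on the wall and end caps. Four
reversible steps close a futile cycle: nucleotide exchange (k±1), MinD
membrane attachment — spontaneous (k±2) and cooperative (k±2′) — MinE
recruitment (k±3), and MinE-aided MinD release (k±4, the hydrolysis
step). The nonequilibrium parameter

    gamma = (k+1 k+2 k+3 k+4) / (k-1 k-2 k-3 k-4)

is 1 at detailed balance; ln γ is the free energy (kBT) dissipated per
ATP. Each reaction dissipates locally at
σᵢ = (j₊ᵢ − j₋ᵢ) ln(j₊ᵢ/j₋ᵢ), diffusion at |j|²/(Dρ), and the chemical
uptake rate is σ_ATP = J₁ ln γ; over whole oscillation periods
⟨σ_ATP⟩ = ⟨σ_tot⟩ = ⟨J⟩ ln γ. Mid-cell-marking quality is the signed
h/w score of the valley in the time-averaged membrane-MinD profile.

The package covers the full workflow: stiff 2D-axisymmetric
finite-volume simulation (`simulate_min()`), oscillation detection and
period estimation (`detect_oscillation()`), dissipation budgets
(`period_averaged_budget()`), performance scoring (`performance()`),
bifurcation localization (`find_bifurcation()`), parameter-plane scans
(`scan_plane()`) and fixed-budget dissipation-strategy optimization
(`optimize_strategy()`). Results come back as tibbles with
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(minflux)
p <- min_params()                      # reference rates: gamma = 1e8
g <- build_geometry(p$R, p$L)          # 0.1 um mesh: 5 x 40 cells
tr <- simulate_min(p, g, t_end = 600)  # ~1 s of wall time

detect_oscillation(tr)[, 1:4]
#> # A tibble: 1 × 4
#>   oscillating period amplitude    cv
#>   <lgl>        <dbl>     <dbl> <dbl>
#> 1 TRUE          38.2      146. 0.645

tidy(period_averaged_budget(tr))
#> # A tibble: 7 × 4
#>   quantity   step  value_kBT_per_s fraction
#>   <chr>      <chr>           <dbl>    <dbl>
#> 1 reaction   1              1467.   0.116
#> 2 reaction   2              1453.   0.115
#> 3 reaction   3              2248.   0.177
#> 4 reaction   4              7428.   0.585
#> 5 diffusion  <NA>             91.7  0.00723
#> 6 total      <NA>          12689.  NA
#> 7 atp_uptake <NA>          12689.  NA

performance(tr)[, 1:3]
#> # A tibble: 1 × 3
#>       h     w score
#>   <dbl> <dbl> <dbl>
#> 1 0.814 0.587  1.39
```

Reading it: the reference cell oscillates with a 38 s period; it burns
about 12,700 kBT/s — close to the kinetic ceiling k₊₄·N_E·ln γ ≈ 12,900
— of which 58% goes into the MinE-aided release step and under 1% into
diffusion; the total equals the ATP uptake rate (the bookkeeping
closes); and the time-averaged membrane-MinD profile has a mid-cell
valley of depth h ≈ 0.81 and width w ≈ 0.59, scoring h/w ≈ 1.4.
`autoplot(tr)` draws the kymograph; `plot_performance_profile(tr)`
shows the valley and its half-depth construction.

Experiment presets (`presets()`) and a YAML config loader
(`load_config()`) cover the canonical parameter sets, including the
non-cooperative control that never oscillates. A thin command-line
front end lives at `inst/cli/minflux.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/minflux.R", package="minflux"))')" \
    simulate --preset fig2 --grid coarse --out out/
```

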
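# rowerchain

Brownian-dynamics simulation and analysis of hydrodynamically coupled
**rower** chains near a no-slip wall — a minimal physical model for how
carpets of motile cilia coordinate, and for how an organism might *switch*
that coordination (its swimming gait) with purely mechanical changes.

## The science

Each cilium is coarse-grained to a bead of radius $a$ on a fixed 1-D track,
driven by an attractive power-law trap $k|x - x_v|^\alpha$ whose position
flips when the bead crosses a geometric switch point (amplitude $A$, switch
offset $x_s$).  The rower has no internal clock: all phase behaviour emerges
from the overdamped Langevin dynamics

$$\dot u_i \;=\; \sum_j M_{ij}\,F_j \;+\; \xi_i, \qquad
\langle \xi_i \xi_j \rangle = 2 k_B T\, M_{ij}\,\delta(t - t'),$$

where $M$ is the track-projected mobility from the Stokes Green's function
bounded by a plane wall (Stokeslet + image system), evaluated with a
minimum-image convention on the periodic ring of $N$ tracks.  Correlated
thermal noise uses the Cholesky factor of $M$.

On top of the uniform chain ($N = 60$, $d/a = 7$, $h/a = 3$, $A/a = 30$,
$\alpha = 1/2$, 2 s beat period, noise $\xi = 3.7\times10^{-5}$), three
control mechanisms can be applied every $N_g$ rowers:

* **spacing** — insert extra gap $d_X$ between groups (shape change);
* **amplitude** — change the beat amplitude by $A_X$, trap recalibrated so
  the solo frequency is unchanged;
* **frequency** — scale the trap strength by $f_X$, detuning the rower.

The analysis side converts trajectories to geometric phases, forms the
neighbour phase-difference profile $\Delta\phi_i$ around the ring, and
detects **chevrons** (reversals of the metachronal wave direction) as the
dominant spatial Fourier mode of that profile above a 0.15 rad threshold,
keeping modes coarser than three rowers ($N/2k > 3$).  Across an ensemble of
seeded re-initialisations, chevron occurrence is scored per available site
(reversals come in pairs: 3 sites for 6 disruption points) and tested
against chance with the exact two-tailed binomial test at $p_0 = 0.5$.

## Worked example

A 30-rower chain in groups of 5 with a large extra gap ($d_X = 16\,a$,
i.e. $d_X/d = 16/7$), 200 cycles, then a seeded three-point spacing sweep:

```r
library(rowerchain)
spec <- chain_spec(n_rowers = 30L, mechanism = "spacing",
                   group_size = 5L, d_X = 16)
traj <- simulate_chain(spec, n_cycles = 200, seed = 42)
cc <- run_chevron_count(traj)
cat("chevron count:", cc, " max coefficient:",
    round(attr(cc, "max_coefficient"), 3), "\n")
#> chevron count: 4  max coefficient: 0.697

man <- sweep_manifest("spacing", c(0, 8, 16), preset = "reduced",
                      base_seed = 1L)
res <- run_sweep(man)
res$summary[, c("control_value", "n_sites", "p_ch", "p_value", "class")]
#>   control_value n_sites  p_ch  p_value         class
#> 1             0       3 0.133 5.21e-09       reduced
#> 2             8       4 0.550 4.34e-01 no_preference
#> 3            16       4 0.700 4.52e-04      enhanced
```

Reading: with no extra spacing the chain settles toward a single
phase-locked wave and chevrons are significantly *rarer* than chance
(`reduced`; the residual 0.133 is reduced-scale transient, see the
vignette).  At $d_X/d = 16/7$ wave reversals between groups occur *more*
often than a fair coin per site (`enhanced`) — extra spacing switches the
collective state.  `n_sites` is raised from 3 to the maximum observed count
when runs exceed the nominal site number (flagged in the full summary).

A command-line interface covering `simulate`, `analyze`, `sweep` and
`fixtures` is installed at `inst/cli/rowerchain` (see `--help`-style usage
in its header).

## Layout

* `R/chain.R` — chain geometry and the three control mechanisms
* `R/mobility.R` — Oseen/Blake tensors, track-projected mobility
* `R/dynamics.R` — trap force, switch, calibration, noise, simulation
* `src/rower_core.cpp` — compiled integrator (RcppArmadillo)
* `R/phase.R` — geometric phase, profiles, Fourier chevron detection
* `R/chevron-stats.R` — surveys, exact binomial preference tests
* `R/sweep.R`, `R/io.R` — sweep runner, presets, fixtures, config/CSV I/O
* `vignettes/rowerchain-methods.Rmd` — model, numerics and design choices
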
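---
title: "Rower chains near a wall: model, numerics and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rower chains near a wall: model, numerics and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowerchain)
```

## The model

A *rower* is the minimal bead model of a motile cilium: a sphere of radius
$a$ constrained to a straight 1-D track, pulled by an attractive power-law
trap $V(x) = k\,|x - x_v|^\alpha$ whose vertex $x_v$ sits a distance $x_s$
beyond a geometric switch point at $\pm A/2$.  When the bead crosses the
switch point the trap flips to the other side, so the bead shuttles back and
forth with amplitude $A$ but carries no internal phase variable — all timing
emerges from the mechanics.  This "geometric switch" is what lets purely
hydrodynamic forces synchronise a collection of rowers.

`rowerchain` simulates $N$ such rowers on parallel tracks in the plane
$z = h$ above a no-slip wall, tilted $45^\circ$ from the chain axis $x$, with
track centres spaced $d$ apart along $x$ and a periodic boundary closing the
chain into a ring (the ring mimics the closed cilia band of a small swimming
organism).  The beads interact only through the fluid.  In the overdamped
(zero Reynolds number) limit the equation of motion projected on the tracks
is the Langevin system

$$\dot u_i = \sum_j M_{ij}(u)\,F_j(u_j,\sigma_j) + \xi_i(t),
\qquad \langle \xi_i(t)\xi_j(t')\rangle = 2 k_BT\, M_{ij}\,\delta(t-t'),$$

where $F_j = \alpha k_j r^{\alpha-1}$ is the trap force at distance $r$ from
the vertex, $\sigma_j = \pm 1$ the trap orientation, and $M$ the
track-projected mobility built from the Green's function of Stokes flow
bounded by a plane no-slip wall (a Stokeslet plus its image system: image
Stokeslet, Stokes doublet and source doublet).  The wall matters twice: it
screens the coupling (tangential decay $\sim h^2/r^3$ instead of the bulk
$1/r$) and it is the physical setting of a cilia carpet.

### Default parameters

All lengths are in bead radii ($a = 1$, nominally 1 µm), times in seconds.

| parameter | symbol | default | meaning |
|---|---|---|---|
| `n_rowers` | $N$ | 60 | chain length |
| `amplitude` | $A$ | 30 | full stroke length |
| `spacing` | $d$ | 7 | track separation along $x$ |
| `height` | $h$ | 3 | track height above the wall |
| `switch_offset` | $x_s$ | 2.5 | vertex distance beyond the switch point |
| `force_exponent` | $\alpha$ | 0.5 | trap potential exponent |
| `target_period` | $T$ | 2 s | calibrated single-rower beat period |
| `noise_level` | $\xi$ | $3.7\times10^{-5}$ | dimensionless noise (below) |
| `tilt_angle` | — | $\pi/4$ | track tilt within the plane $z=h$ |

The step size is $2\times10^{-3}$ cycles and production runs are 2000 cycles
long, re-initialised 50 times per condition, matching the regime the package
is built to reproduce.  The $45^\circ$ tilt is an arbitrary geometric choice
that keeps beads at least $d/\sqrt2 \approx 4.9\,a$ apart despite the large
$A/d$ ratio; the tilt is taken *in-plane* (tracks parallel to the wall), so
every bead stays at height $h$ for all time.

### Trap calibration

For the isolated deterministic rower the half-stroke time follows by
quadrature: $\gamma\,\dot r = -\alpha k r^{\alpha-1}$ from $r = A + x_s$ down
to $x_s$ gives
$$T = \frac{2\gamma}{\alpha(2-\alpha)k}\left[(A+x_s)^{2-\alpha} -
x_s^{2-\alpha}\right],$$
inverted by `calibrate_trap_strength()`; for $\alpha = 1/2$ this is
$k = (8\gamma/3T)\,[(A+x_s)^{3/2} - x_s^{3/2}]$ with $\gamma = 6\pi\eta a$.
The amplitude control mechanism recalibrates the trap of modified rowers so
their solo period stays $T$; the frequency mechanism instead scales $k$ by
$f_X$, detuning the solo frequency by the same factor (period
$\propto 1/k$ at fixed geometry).

### Noise level

The dimensionless noise $\xi$ is interpreted as the ratio of thermal energy
to the driving-potential drop over one half stroke of an unmodified rower,
$$k_BT = \xi\, k\left[(A+x_s)^\alpha - x_s^\alpha\right],$$
kept behind the single function `noise_energy()` so that an alternative
convention is a one-line change.  At the default $\xi$ the per-step thermal
displacement is $\approx 0.017\,a$ against a deterministic step of
$\approx 0.1\,a$: noise perturbs the approach to phase locking without
destroying it.

## Numerical scheme

* **Mobility.**  Point-force wall Green's function between bead centres;
  self-mobility is the bulk Stokes drag $1/(6\pi\eta a)$ without a Faxén wall
  correction (a constant diagonal shift that does not affect the locking
  structure; the far-field pair terms carry the wall physics).  Periodic
  images are applied along $x$ only, via the minimum-image convention on the
  ring — the topology is 1-D and the $1/r^3$ screened decay makes farther
  images negligible.  The matrix is recomputed from the current bead
  positions every step (the beads sweep $\pm 15\,a$, a large excursion); a
  cached-at-centres mode exists as a documented speed option, off by
  default.
* **Integration.**  One step applies a Heun (predictor–corrector) stage to
  the drift $M F$, with $M$ frozen at the start-of-step configuration, then
  adds the correlated random displacement $\sqrt{2k_BT\,\mathrm{d}t}\,L z$
  with $L L^\top = M$ (Cholesky).  The mobility-divergence drift of the full
  Ermak–McCammon scheme vanishes here: beads ride rigid 1-D tracks at fixed
  height and the configuration dependence of $M$ is a far-field correction.
* **Switch handling.**  The crossing $\sigma u \ge A/2$ is located *inside*
  the step by linear interpolation and the reversed stroke restarts from the
  switch point for the remaining step fraction.  This matters: a plain Euler
  step with the switch checked only at step boundaries biases the beat
  period by $\approx 6\,\mathrm{d}t$ per cycle ($+1.2\%$ at the default
  step), because the trap force is largest exactly where the overshoot
  happens.  With event location and the Heun stage the measured noise-free
  period agrees with the calibration target to $3\times10^{-2}$ of a time
  step, and deterministic trajectories converge under step halving at
  better-than-first-order rate.
* **Degenerate inputs.**  Force evaluation at the vertex is a domain error
  (unreachable: the switch fires $x_s$ short of the vertex); a step that
  carries a bead past the vertex aborts with advice to reduce
  $\mathrm{d}t$; a non-positive-definite mobility is reported, never
  silently repaired.
* **Reproducibility.**  Every stochastic run is a pure function of
  (specification, seed): initial positions $u_i \sim U(-A_i/2, A_i/2)$ and
  orientations are drawn from R's RNG, and the compiled core draws its
  Gaussian noise from the same stream.

## Phase analysis and chevron detection

The geometric phase maps $(u, \sigma)$ linearly onto $[0, 2\pi)$, upstroke
to $[0,\pi)$, downstroke to $[\pi, 2\pi)$, per-rower normalised by its own
amplitude.  The object analysed is the *neighbour phase-difference profile*
$\Delta\phi_i = \mathrm{wrap}(\phi_{i+1} - \phi_i)$, which closes to $0
\pmod{2\pi}$ around the ring.  A metachronal wave is a constant profile; a
*chevron* is a sign reversal of $\Delta\phi$, and reversals come in
$\wedge\vee$ pairs on a ring.

Detection takes the spatial Fourier amplitudes
$c_k = (2/N)\,|\sum_i \Delta\phi_i e^{-2\pi i k i/N}|$ for
$k = 1, \dots, k_\mathrm{max}$, keeping only modes larger than three rowers
in scale ($N/2k > 3$, so $k \le 9$ at $N = 60$).  Working on the
*difference* profile makes a $k$-chevron state a square wave whose
fundamental is $(4/\pi)s \approx s$ for per-pair difference $s$, so the
detection threshold 0.15 reads directly as a per-pair phase difference
($2\pi/40 \approx 0.157$, the gradient expected if every 40th rower were
disrupted — structure too fine to arise spontaneously in a 60-chain).  If
all $c_k$ fall below the threshold the count is 0, otherwise the count is
the dominant mode number.  A run's chevron count is the modal detection over
snapshots taken once per cycle in the final 5 % of the run, ties broken
toward the latest snapshot.

The dominant-mode count is deliberately crude: when detuned rowers fail to
lock it reports the number of kinks (mode 6 for six detuned rowers), and
when decoupled groups drift freely the boundary entries are random spikes
that can dominate any admissible mode.  Both situations are flagged rather
than hidden — see *Limitations*.

## Binomial preference statistics

For an ensemble of seeded re-initialisations at one control level, chevron
occurrence is modelled as Bernoulli trials over $n_s$ available sites per
chain ($n_s = 3$ for six disruption points, since reversals pair up).  The
estimate is $p_{ch} = \sum \mathrm{counts} / (n_s \cdot n_\mathrm{runs})$
and the two-tailed *exact* binomial test against $p_0 = 0.5$ uses the
minimum-likelihood convention (sum of all outcome probabilities no larger
than the observed one) — symmetric at $p_0 = 0.5$ and conservative, as the
type-I computation in the test suite verifies.  Significant results are
classed `reduced` or `enhanced` by the side of 0.5.  Counts above $n_s$
violate the fixed-trials assumption and raise an error in `p_chevron()`;
`run_sweep()` then raises $n_s$ to the maximum observed count and flags the
column, the same move the source analysis makes for the amplitude mechanism.
Bimodal count distributions (≥ 25 % of runs at both 0 and $n_s$) carry a
validity warning: there the binomial model is known to strain.

## Synthetic data

Two generators exist, at different levels:

* `make_fixture_profile()` emits phase-difference profiles with *known*
  chevron structure (flat, square wave, triangle wave, noisy square) so the
  whole analysis chain can be exercised without physics.  Its defaults
  (amplitude 0.3 rad, $N = 60$) put the square-wave fundamental at
  $\approx 2.5\times$ the detection threshold — a clear chevron, matching
  the sharp reversals seen in spacing-controlled chains.
* `simulate_chain()` itself is the physical generator; the *reduced* preset
  ($N = 30$ in 6 groups of 5, 200 cycles, 20 runs) preserves the group count
  and therefore the site structure of the full grid while running in a few
  minutes on one CPU.

What a green test on the reduced preset establishes is the *direction* of
the control effects (chevrons absent without disruption versus abundant at
intermediate extra spacing), not the published grid values: 200 cycles is
roughly $0.2\,N^2$ coupling times versus $0.56\,N^2$ at full scale, so
reduced-scale runs retain slow transients that full-scale runs have shed.
The suite verifies separately (three full-scale seeds) that the uniform
$N = 60$, 2000-cycle chain settles well below the detection threshold.

## Limitations

* Point forces only: no finite-radius (Rotne–Prager) or lubrication
  corrections, no stresslets, no height fluctuations — consistent with the
  far-field regime $d/a = 7$, $h/a = 3$ the model targets.
* The wall correction to the *bulk* limit decays first order in $r/h$
  (image system at distance $2h$), so "far from the wall" means
  $h \gtrsim 10^6 r$ for $10^{-6}$ agreement with the free-space Oseen
  tensor.
* At the reduced scale the uniform chain has not fully relaxed at 200
  cycles: residual transients occasionally exceed the detection threshold,
  so the "never a chevron" property holds strictly only at full scale.
* In the fully decoupled-groups limit the dominant-mode detector overcounts
  relative to true reversals (drifting group phases put broad-spectrum
  spikes at the boundaries); a direct reversal count from per-group wave
  directions recovers chance level.  Conclusions drawn in that limit should
  use the per-run count distributions that `run_sweep()` reports, not the
  binomial classification alone.
* The binomial machinery assumes independent, fixed-number chevron sites;
  the frequency mechanism violates this by design (incoherent detuned
  rowers), and its surveys are processed under a warning flag rather than
  reinterpreted.
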
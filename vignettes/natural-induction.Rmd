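---
title: "Viscoelastic networks that learn to optimise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic networks that learn to optimise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natind)
```

## The model

`natind` simulates `N` point masses in a 2D plane joined by springs. A
spring between masses `i` and `j` with stiffness `k` and natural length
`l_ij` stores elastic energy `1/2 k (r_ij - l_ij)^2`, where `r_ij` is the
current separation, so the total potential is

    V(x, l) = sum_{ij in S} 1/2 k_ij (r_ij - l_ij)^2.

Two kinds of processes relax this energy, on widely separated timescales:

* **Optimisation (fast).** The positions move down the energy gradient.
  In the heavily damped regime the dynamics reduce to the first-order flow
  `dx_i/dt = F_i / gamma` with `F_i = -dV/dx_i`; the masses settle into a
  local minimum of `V` — a locally optimal resolution of the frustration
  between springs.
* **Learning (slow).** Plastic springs are Maxwell viscoelastic elements:
  an ideal spring in series with a dashpot of damping constant `gamma_m`.
  Under sustained stress the natural length creeps as
  `dl_ij/dt = (k/gamma_m)(r_ij - l_ij)`, which is exactly
  `-dV/dl_ij` up to the positive factor `1/gamma_m`
  (see `gradient_check()`). The structure accommodates to the state the
  system is in: an unsupervised, physical form of Hebbian learning.

Neither process alone is interesting: relaxation finds an arbitrary local
optimum, and creep at a single optimum just deepens it. The phenomenon the
package studies arises when the state is **repeatedly disturbed**
(positions re-randomised, spring parameters untouched) while creep
accumulates across the visited equilibria. The plastic layer then learns a
correlation model of the distribution of local optima, which reshapes the
attractor basins, which biases which optima are visited next — a positive
feedback that concentrates the dynamics onto configurations of
exceptionally low energy, including energies below every optimum the
unlearned system was observed to visit. Because both the problem
constraints and the learned model live in pairwise interactions, the
learned landscape generalises: it can enlarge the basins of low-energy
configurations that were never visited.

Timescale ordering is essential and is enforced by construction: settling
happens to completion between disturbances, and creep is applied as a
discrete per-equilibrium update rather than along transients (a standard
quasi-static approximation for `gamma_m >> gamma`). The per-equilibrium
update moves every plastic natural length a fraction `eta` toward the
current separation: `l <- l + eta (r - l)`. `eta` plays the role of
`k Delta_t / gamma_m` for a residence time `Delta_t`; it is exposed as
`learning_rate` everywhere.

## Relaxation methods

`settle()` offers four integrators. Which one a protocol uses matters for
two different reasons: *where* a trajectory ends (basin statistics) and
*how much it costs*.

* `"euler"` — explicit Euler on the overdamped flow, with an adaptive step
  that rejects any energy increase. This is the reference first-order
  trajectory; the two-body closed form
  `r(t) = l + (r_0 - l) exp(-2kt/gamma)` is reproduced to 1e-4 and is part
  of the test suite.
* `"fire"` — the fast inertial relaxation engine used throughout
  mechanical-network statics, with the same energy-rejection guard, so the
  elastic energy is monotonically non-increasing at every accepted step
  (checked trajectory-by-trajectory in the tests). It reaches the same
  kind of critical points as the overdamped flow at a small fraction of
  the cost, and is the workhorse for warm restarts and quasi-static
  accommodation.
* `"inertial"` — the lightly damped second-order dynamics
  `m dv/dt = F - gamma v` (semi-implicit Euler, unit mass and unit
  viscosity by default). Positions transiently oscillate for a few
  ring-down times `2m/gamma` while the *total* (elastic plus kinetic)
  energy dissipates. Ringing matters for basin statistics: kinetic energy
  carries trajectories across shallow features, so wide, deep basins
  capture disproportionately many initial conditions — the physical
  annealing that underlies the memory-formation result. A strictly
  monotone first-order descent, by contrast, is trapped by whatever
  shallow minimum it first touches; we measured that the same
  creep-accommodated configuration captures only ~50–80% of random
  initial conditions under monotone descent but ~95–100% under the
  lightly damped dynamics.
* `"anneal"` (default) — the inertial dynamics for `anneal_time` time
  units (default six ring-downs, by when the transient amplitude has
  decayed below 1% and the basin is decided), then FIRE to polish
  convergence within that basin. It reproduces the basin
  statistics of `"inertial"` at a fraction of the cost; shortening the
  anneal from 12 to 2 time units shifts the scenario-1 adaptation medians
  by about 10%, within the run-to-run spread. The disturbance protocols
  use it throughout.

Settling stops when the largest per-mass force drops below
`equilibrium_tolerance` (default `1e-6` times the mean stiffness times the
mean natural length — a force about six orders below typical transient
forces). Coincident connected masses during integration are handled by
clamping the separation to `1e-9` with a fixed arbitrary direction; with
continuous disturbance distributions this is a measure-zero event.

## Protocols

**Memory formation** (`run_memory_experiment()`): settle a small
all-plastic network (by default `N = 15`, connection probability 0.9,
`l_0 = 10`, `k = 10`) from many random initial conditions; hold the first
equilibrium sampled while creep runs to near-completion
(`creep_to_rest()`, stopping when the largest plastic stress falls below
1% of its initial value); re-settle from the *same* initial conditions.
Settling uses the full `"inertial"` dynamics here, because the claim being
measured is about the basins of the physical transients. Convergence to
the held configuration is judged on the pairwise-distance vector
(rigid-motion invariant) at 1% relative Euclidean distance — comparable to
settling precision but far below the typical distance between distinct
equilibria (~30%).

**Scenario 1** (`run_scenario1()`): disturb / settle / record / creep on
an all-plastic network. Because learning destroys the original problem
(the springs *are* the problem), quality is assayed by `resettle_energy()`:
a pristine copy of the original springs is settled from the learned
configuration and its energy `V_o` is read off. The baseline replays the
identical disturbances against the pristine springs. The headline statistic
(`std_score()`) is the number of baseline standard deviations between the
mean baseline energy and the minimum late-run learned energy, computed on
log energies (equilibrium energies are closer to log-normal; energies are
floored at 1e-12 before the log). "Late" is the final quarter of the run
(`late_frac = 0.25`), reflecting that the minimum final learnt energy is a
property of the converged regime, not of early luck.

**Scenario 2** (`run_scenario2()`): the problem lives in non-plastic
P-springs; a dense, much weaker plastic L-layer learns. After the
disturbance loop, a final settling phase alternates settling and creep
until every L-spring's stress is below `1e-3` times the mean L stiffness
times the mean natural length — the learning layer "melts away", leaving a
configuration held by the problem springs alone (the residual L energy is
checked to be below 1e-6 of the P energy). Scenario 2a draws P-springs
with probability 0.5, lengths uniform on [0, 1], `k_P = 1`, and an L-layer
at connectivity 0.99 with `k_L = 0.1`. Scenario 2b encodes a +/-J spin
glass (MaxCut) instance; see below.

## The spin-glass embedding (Scenario 2b)

Each binary variable is a mass whose single-variable energy is bistable:
two strong non-plastic anchor springs tie it to fixed pseudo-masses at
`(0, h)` and `(0, -h)` (default `h = 0.5`), with natural length
`sqrt(1 + h^2)`, so both anchors are simultaneously unstressed only at
`(+1, 0)` and `(-1, 0)`. A coupling `J` between two variables is a
non-plastic spring with rest length 0 for `J > 0` (favours the same well)
and 2 for `J < 0` (favours opposite wells), stiffness proportional to
`|J|`. The spin is the sign of the x coordinate (ties to +1), and the
reported energy is `E = -sum J_ij s_i s_j`.

Design choices here were genuinely open, and were fixed by two
requirements measured directly: (i) the embedded ground state must be a
fixed point of the relaxation whose binarisation reproduces the exact
optimum from exhaustive enumeration on small instances (`n <= 14`) — this
is the encoding's correctness oracle and part of the test suite; (ii) the
anchors must dominate single-variable energetics (so states stay near the
wells and binarisation is meaningful) while the learning layer is strong
enough to steer which well a variable falls into. The defaults — anchor
stiffness twice the expected coupled degree, L-layer stiffness 0.8 with
rest lengths uniform on [0, 2] (the span of inter-well distances), and
`eta = 0.05` — satisfy both. With them the learned runs routinely end at
or near the enumerated/observed optimum of the instance. Anchor
pseudo-masses are immovable, excluded from disturbances and from distance
vectors. Disturbances for 2b draw positions in a box of side 3, covering
both wells with a margin.

One structural point worth stating: the "without learning" baseline for 2b
(settling the problem layer alone from the same disturbances) is a fairly
weak optimiser under these strong anchors — most variables simply fall
into the nearest well. That is what makes the learned system's
near-optimal final states many standard deviations better; with weaker
anchors, relaxation alone already optimises well, and the same learned
quality scores fewer standard deviations because the baseline is both
better and relatively tight. The standard-score ceiling
`(baseline mean - ground energy) / baseline sd` is an intrinsic property
of the instance class and the encoding.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `damping` (gamma) | 1 | force·time/length | mobility of positions |
| `mass` | 1 | mass | inertia of the physical transients |
| `learning_rate` (eta) | 0.02 (s1), 0.05–0.1 (scenario 2) | — | per-equilibrium creep fraction |
| `n_resets` | 300 | — | disturbances per run |
| `box_size` | `sqrt(N) * mean l` | length | disturbance box side |
| `equilibrium_tolerance` | `1e-6 k l` | force | "settled" threshold |
| `anneal_time` | `12 m / gamma` | time | inertial phase of `"anneal"` |

`eta` trades learning speed against premature lock-in: too small and the
run ends before the positive feedback has concentrated the dynamics; too
large and the system memorises its first few (arbitrary) equilibria. The
defaults were chosen so that convergence develops over one to three
hundred resets in each scenario: 0.02 suffices for the all-plastic
Scenario 1 (every spring learns), while the weak two-layer systems need
more creep per visit (0.1 for 2a, 0.05 for 2b).

The disturbance box follows `sqrt(N) * mean natural length` so that mass
density after a disturbance is roughly independent of `N`; measured
sensitivity of the results to the box side is weak (factor-of-four changes
move the memory-formation statistic by a few percent).

## What the generators emulate — and what they do not

All experiments run on synthetic networks drawn by the package itself:
Bernoulli random connectivity, uniform or uniformly drawn natural lengths,
i.i.d. couplings. These match the study conditions the protocols are
defined for. They do **not** emulate features of real viscoelastic
networks such as heterogeneous per-connection damping, spatially local
connectivity, asymmetric interactions, stiffness (rather than length)
plasticity, underdamped oscillatory *learning* regimes, or hidden state —
all outside this package's scope. Passing tests therefore demonstrate the
feedback-between-optimisation-and-learning effect under the stated
idealised conditions, not its quantitative behaviour in any particular
physical material.

## Numerical choices and degenerate inputs

* Energy-descent guard: descent methods reject steps that raise `V` by
  more than 1e-12 relative; the inertial method instead dissipates
  `V + kinetic`.
* Disconnected generator draws are rejected (up to 100 redraws) so every
  mass participates in the shared energy.
* `r = 0` between connected masses: clamped (see above); generator and
  file validation reject self-springs and duplicate pairs per layer
  outright.
* Ties in binarisation (`x = 0`) break to +1; cluster labels are assigned
  by first occurrence so clustering is deterministic under input order.
* Zero-variance baselines make the standard score undefined and raise an
  error rather than returning infinity.
* All randomness flows through R's RNG, seeded once per run from
  `config$seed`; runs are bit-reproducible and resumable from checkpoints
  (springs plus RNG state).

## Problem sizes used by the packaged experiments

The packaged test-and-reproduction scripts run the memory experiment at
`N = 15` with 1000 initial conditions, Scenario 1 and 2a at `N = 100` with
200 disturbances and 10 independent realisations, and Scenario 2b at
`n = 30` variables with 300 disturbances and 10 instances. These sizes
were chosen as the point where the phenomena of interest are clearly
expressed while a complete reproduction stays comfortable on a single
CPU; the underlying effects strengthen with system size (baseline
fluctuations self-average as `1/sqrt(N)` while the learned improvement
does not shrink), so larger runs — supported by the same functions — give
larger scores.

## Known limitations

* The standard-score statistics at these system sizes carry 10-run
  sampling noise; single-run scores vary by +/- 1.
* The anneal/inertial distinction matters: results about *which* basin is
  reached are statements about the lightly damped physical dynamics, not
  about idealised gradient flow.
* Scenario 2a's adaptation is weaker at `N = 100` than at larger sizes
  (the self-averaging argument above); its mean score here sits near the
  low end of what larger systems show.
* MaxCut values are not reported separately from coupling energies; the
  affine map between them is `MaxCut = (sum|J| - E) / 2`.

```{r example, eval = FALSE}
# a complete small run, end to end
net <- generate_random_network(15, 0.9, seed = 1)
cfg <- sim_config(seed = 1)
mem <- run_memory_experiment(net, cfg, n_starts = 200)
convergence_fraction(mem$post, mem$held)
```
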
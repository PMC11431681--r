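# natind

Networks of masses joined by viscoelastic springs that *learn to
optimise*: overdamped relaxation of the mass positions performs physical
optimisation of the elastic energy, while slow creep of the plastic
springs' natural lengths performs unsupervised physical learning. Under
repeated random disturbances of the state, the feedback between the two
processes enlarges the attractor basins of low-energy configurations, and
the system spontaneously discovers solutions of exceptionally rare
quality — to its own frustration problem, and to external problems encoded
in non-deformable "problem" springs, including spin-glass / MaxCut
instances.

The package is aimed at researchers in self-organisation, physical
learning, and energy-landscape dynamics who want a reproducible, tested
simulator of this effect rather than a one-off script.

## The model

`N` point masses in a 2D plane are joined by Hookean springs; the elastic
energy is

    V(x, l) = sum_{ij in S} 1/2 k_ij (r_ij - l_ij)^2

with `r_ij` the current pair distance and `l_ij` the natural length.

* **State relaxation (fast):** in the overdamped regime positions follow
  `dx_i/dt = F_i / gamma`, settling into local minima of `V`.
* **Viscoelastic creep (slow):** plastic springs are Maxwell elements
  whose natural lengths deform under sustained stress,
  `dl_ij/dt = (k/gamma_m)(r_ij - l_ij)`, which equals `-dV/dl_ij` up to a
  positive constant. Positions relax *to* the springs; springs
  accommodate *to* the positions.
* **Disturbances:** the positions (never the spring parameters) are
  occasionally re-randomised, so the slowly deforming springs experience a
  whole distribution of settled configurations — and learn an associative
  model of it.

Between disturbances the system settles fully, and creep is applied once
per equilibrium visited (`l <- l + eta (r - l)`, `eta` the learning rate),
the quasi-static limit of slow deformation.

## A worked example: memory formation

A small all-plastic network (15 masses, 90% connectivity, `l0 = 10`,
`k = 10`) is settled from 200 random initial conditions, allowed to rest
at the first equilibrium found while its springs creep, then re-settled
from the *same* 200 initial conditions:

```r
library(natind)
net <- generate_random_network(15, 0.9, natural_length = 10,
                               stiffness = 10, seed = 1)
cfg <- sim_config(seed = 1)
mem <- run_memory_experiment(net, cfg, n_starts = 200)

length(cluster_attractors(mem$baseline)$counts)   # 200
convergence_fraction(mem$baseline, mem$held)      # 0.005
convergence_fraction(mem$post, mem$held)          # 0.965
potential_energy(mem$deformed_network)            # 0.53  (was 5310.8)
```

Before creep the system reaches a different equilibrium from almost every
initial condition (200 distinct attractors; only the held start itself
maps to the held state). After the springs have accommodated, 96.5% of the
same initial conditions converge to the held configuration: deformation
has not just lowered that configuration's energy (5310.8 to 0.53), it has
enlarged its basin of attraction ~200-fold. The structure has formed an
associative memory of a state it was merely *in*.

The disturbance protocols build on this: `run_scenario1()` (the network
learns to minimise its own original energy — assayed by re-settling a
pristine copy of the springs from each learned configuration),
`run_scenario2()` (elastic problem springs plus a weak plastic learning
layer that eventually "melts away", leaving the problem springs holding an
exceptionally good configuration), and `generate_spinglass_problem()` /
`binarised_energy()` (a bistable-anchor embedding of +/-J spin glasses,
scored against exhaustive enumeration on small instances). Measurement
tools include PCA embeddings of equilibria (`pca_embed`), attractor
clustering (`cluster_attractors`), log-energy standard scores
(`std_score`), and a neutrality check for the unlearned learning layer
(`neutrality_check`).

A thin command-line wrapper is provided at `inst/cli/natind.R`
(`Rscript natind.R s1 --seed 1 --out runs/`), with JSON configs
(`inst/extdata/scenario1_config.json`) and plain-text edge-list I/O
(`read_edge_list` / `write_edge_list`).

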
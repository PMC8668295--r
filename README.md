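# dgnet — a dentate gyrus microcircuit simulator with small-world analysis

The dentate gyrus is the gateway through which cortical information enters
the hippocampus, and its recurrent rewiring (mossy-fiber sprouting, mossy
cell loss) is central to temporal-lobe epilepsy. `dgnet` builds a reduced
computational model of this circuit in a *healthy* configuration — granule
cells are not directly interconnected — and in a *pathological* one with
sprouted recurrent granule-cell synapses and optional mossy-cell deletion.
It is written for computational neuroscientists who want a self-contained,
scriptable version of this class of model: no simulation platform, no
external data.

The package has three layers:

1. **Topographic connectivity generation.** Four cell populations (500
   granule cells, 15 mossy cells, 6 basket cells, 6 HIPP cells) are placed
   evenly on a normalized septotemporal axis. Each projection is defined by
   a divergence, a nearest-neighbour target pool and an optional central
   exclusion zone — e.g. every mossy cell contacts exactly 200 granule
   cells drawn from the 350 nearest after skipping the closest 50. Edge
   conservation makes the convergence means exact: mean MC→GC convergence
   is 15·200/500 = 6.0 by construction of the realized graph.

2. **Multicompartment conductance-based simulation.** Cells are somatic
   cylinders plus passive dendrites (9 compartments for granule cells, 17
   for mossy and basket cells, 13 for HIPP cells) with Hodgkin–Huxley-type
   Na/K spiking at the soma, calibrated per type to landmark resting
   potentials, thresholds and spike peaks. Synapses are double-exponential
   conductances with per-projection delays; a perforant-path-like pulse at
   5 ms drives 100 granule cells, 2 basket cells and 2 random mossy cells;
   integration is a two-stage exponential scheme on a fixed 0.1 ms grid
   over 100 ms.

3. **Small-world graph analysis.** For a connectivity graph with `N`
   neurons, per-node path length `L_i = Σ_j d_ij /(N−1)` and clustering
   `C_i = 2E_i /(k_i(k_i−1))` are averaged into `L` and `C`, compared
   against the equivalent random graph `L_rand = ln N / ln⟨k⟩`,
   `C_rand = ⟨k⟩/N`, and summarized by the small-world quotient
   `Q = (C/L)/(C_rand/L_rand)`; `Q > 1` indicates small-world structure.

## Worked example

```r
library(dgnet)

net <- generate_network(seed = 1)                 # healthy, 527 cells
connectivity_summary(net)[4, ]                    # the MC -> GC projection
#>   pre_type post_type n_edges divergence_mean convergence_mean convergence_sd
#> 4       MC        GC    3000             200                6       3.032225

sim <- run_simulation(net, seed = 1)
sim
#> <dg_sim> healthy network, 100 ms at dt 0.1 ms, seed 1
#>   126 spikes (GC 110, MC 8, BC 2, HIPP 6); 104 stimulated cells; 10 recorded traces

small_world_stats(net)
#> <dg_smallworld>
#>     <k>       L       C  L_rand  C_rand       Q
#> 27.4307  1.9584  0.4754  1.8925  0.0521  8.8255
#>   L >= L_rand; C / C_rand = 9.13; small-world by quotient (Q > 1)
```

The simulation prints a raster of 126 spikes: the 104 directly stimulated
cells fire ~4 ms after the 5 ms pulse, network-driven HIPP and mossy cells
follow several milliseconds later, and unstimulated basket cells stay
silent — the healthy circuit's signature. Rerunning on the pathological
network (`generate_network(mode = "pathological", sprouting_degree = 2)`)
roughly decuples the spike count, the hyperexcitability signature of
mossy-fiber sprouting. In the analysis row, `C` is ~9× its random
reference while `L` is close to `L_rand`, hence `Q ≈ 8.8 > 1`: the healthy
circuit is small-world.

A command-line wrapper over the same functions is installed at
`inst/cli/dgnet.R` (subcommands `generate`, `simulate`, `analyze`,
`fixtures`).

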
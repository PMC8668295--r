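---
title: "Modelling the dentate gyrus microcircuit: connectivity, dynamics and small-world structure"
author: "dgnet"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dgnet` implements a reduced model of the dentate gyrus in a healthy and a
pathological (epileptic) configuration. This vignette is the package's
methodological record: the model and its assumptions, the parameters that
matter and why they hold their default values, the numerical choices, and
what the simulated circuit can and cannot say about real tissue.

# The circuit model

## Populations and the septotemporal axis

Four cell classes dominate the dentate gyrus numerically and carry its
canonical microcircuit: excitatory granule cells (GC) and mossy cells
(MC), and the inhibitory basket (BC) and HIPP interneurons. The default
network scales the biological counts down by roughly 2000:1 to
**500 GC / 15 MC / 6 BC / 6 HIPP** (527 cells). We fix the basket-cell
count at 6 rather than 5: the target convergence statistics of the
connection table are only jointly consistent with 6 basket cells and 6
HIPP cells (e.g. GC→BC convergence 83.33 = 500/6, BC→GC convergence
1.2 = 6·100/500, HIPP→GC 1.92 = 6·160/500), so the table wins over the
nominal 500:15:5:6 ratio. Counts are configurable.

Each population is laid out evenly on a single normalized septotemporal
axis (cell *i* of *n* at position (*i*+0.5)/*n*). This one-dimensional
lamella abstraction is what gives "an MC connects to 200 GCs *near it*"
its meaning; it deliberately ignores 3-D axonal morphology.

## Topographic connection rules

A projection is a tuple (divergence *d*, pool size *p*, central exclusion
*x*): every presynaptic cell makes exactly *d* contacts, drawn uniformly
without replacement from the *p* nearest postsynaptic cells after removing
the *x* nearest (mossy-cell axons famously skip the granule cells nearest
their soma: *d* = 200, *p* = 350, *x* = 50). Pools clamp at the axis ends —
a strip of tissue, not a ring; a wraparound variant was considered and
rejected as less anatomical. Same-type rules (MC→MC, BC→BC) exclude the
cell itself: autapses are not part of the circuit. Sampling without
replacement makes each rule's edge set a simple directed graph, so
"divergence" counts distinct postsynaptic targets.

One divergence is inferred rather than copied: the GC→HIPP projection is
listed nominally as 1:1 but its convergence target of 250 inputs per HIPP
cell forces 500·*d*/6 = 250, hence *d* = 3.

Because every presynaptic cell realizes its divergence exactly, the mean
convergence of a projection equals pre_count·*d*/post_count *identically*,
not just in expectation — the generator's key conservation law, and the
basis of several tests.

## Healthy versus pathological mode

Under normal physiology granule cells are not synaptically
interconnected; the healthy mode therefore contains **no GC→GC rule**, and
basket cells do not project to HIPP cells. The pathological mode models
two lesions of the epileptic dentate gyrus:

* **mossy-fiber sprouting** — each granule cell gains `sprouting_degree`
  recurrent GC→GC contacts drawn from its 100 nearest neighbours
  (default 2, the canonical "two random granule cells per granule cell";
  fully configurable, and analyses of heavily sprouted tissue are usually
  run at higher degrees — the sprouted reference statistics shipped in the
  worked example correspond to degree 10);
* **mossy-cell loss** — `mc_loss` randomly chosen mossy cells lose all
  afferent and efferent connections.

## Randomness and reproducibility

A single integer seed drives generation. Each rule draws from its own
substream (a hash of the rule label folded into the seed), so adding or
removing one projection never perturbs another's realized edges. Changing
the seed changes the edges but — by the conservation law above — none of
the divergence/convergence means.

# Single-cell and synaptic dynamics

## Compartmental skeletons

Cells are a cylindrical soma plus unbranched dendrites of four serial
sections each (section 1 proximal): GC 9 compartments (2 dendrites), MC
and BC 17 (4 dendrites), HIPP 13 (3). Granule somata are 10 µm cylinders;
dendritic sections default to 60–80 µm with uniform diameter per section.
Membrane: specific capacitance 1 µF/cm², axial resistivity 210 Ω·cm, leak
densities giving membrane time constants of 30 ms (GC, HIPP), 20 ms (MC)
and 5 ms (BC — a deliberately fast integrator so basket cells respond to
synchronous volleys rather than slow summation).

## Active properties and calibration

The soma carries classic Hodgkin–Huxley Na/K currents whose rate functions
are evaluated at *V* − shift, with a per-type voltage shift: shifting the
activation range is the one-parameter way to place the spike threshold
without re-deriving kinetics. Each type is calibrated to three landmarks —
resting potential, spike-onset potential, spike peak (e.g. GC: −70.44,
−39.44, +37.14 mV) — with tolerances ±2, ±5 and ±10 mV:

* the somatic leak reversal is *solved*, not fitted, so the target rest is
  an exact fixed point of the membrane equations (dendrites, being
  passive, rest there trivially);
* `calibrate_cell()` then iterates a current-clamp protocol, moving the
  kinetics shift against the measured onset (rate-of-rise criterion,
  dV/dt ≥ 20 mV/ms) and the Na reversal against the measured peak.

The shipped defaults are the converged values; rerunning the calibration
reproduces them. The kinetics themselves are an assumption — the model's
claim is that the *landmarks* are honoured, not that the channel gating
matches any particular recording.

All cells start at −60 mV regardless of their own rest (the protocol's
initial condition) and relax to their calibrated rest within the first
few milliseconds.

## Synapses and stimulation

Synapses are double-exponential conductances (rise/decay normalized so a
unit event peaks at `gmax`) with a lumped axonal-plus-synaptic delay per
projection and reversal 0 mV for excitatory (GC, MC) sources and −70 to
−75 mV for inhibitory (BC, HIPP) sources. Placement follows standard
dentate targeting: basket-cell output onto the soma, mossy-fiber and
sprouted input onto proximal dendrites, HIPP output and the
perforant-path stimulus onto distal dendrites (spread over sections 3–4).

The default protocol delivers one pulse at 5 ms to 100 granule cells (a
contiguous central block — topographic stimulation; the protocol does not
specify *which* cells, so a deterministic central block was chosen), 2
central basket cells and 2 seed-chosen mossy cells. A plain-text
spike-time file (one ms value per line) can replace the pulse for
continuous stimulation. The stimulus synaptic delay (3 ms) plus rise time
reproduces the observed ~4 ms lag between pulse and the first spikes of
directly driven cells.

Synaptic weights were tuned, once, to the circuit's qualitative
fingerprint and then frozen: directly stimulated cells fire at ~9 ms;
network-driven HIPP (and unstimulated mossy) cells fire several
milliseconds later; unstimulated basket cells stay silent in the healthy
circuit but are recruited by the massive recurrent volley of a heavily
sprouted one; and any sprouted configuration produces strictly more total
spikes than the healthy circuit under the same seed.

# Numerical scheme

Integration is a fixed-step, two-stage exponential method: each
compartment is advanced analytically under its instantaneous total
conductance, first with start-of-step coefficients, then again with the
average of start and predicted end coefficients (a midpoint estimate);
gating variables use exact exponential updates with rates at the midpoint
voltage; synaptic conductances enter as their trapezoidal average over the
step. Each 0.1 ms grid step is internally subdivided (`substeps`,
default 2). With these choices, halving the grid step moves somatic spike
times by well under 0.5 ms on reference networks; the residual error is
dominated by near-rheobase crossings, where spike timing is intrinsically
sensitive.

Determinism is exact: deliveries are snapped to the next grid point at or
after spike time plus delay, spike times are linearly interpolated at the
0 mV upward crossing with a 2 ms refractory merge, and identical seed and
configuration give bit-identical rasters. Integration aborts with the
offending cell and time if any potential leaves ±200 mV.

Problem sizes throughout the package's own checks — the full 527-cell
protocol, 20-seed generation sweeps, 20-cell convergence networks — were
chosen as the smallest that exercise every mechanism at full fidelity.

# Small-world analysis

Neurons are nodes; connections are edges. Per-node path length
*L<sub>i</sub>* = Σ<sub>j</sub> *d<sub>ij</sub>* /(N−1) (breadth-first
distances) and clustering *C<sub>i</sub>* = 2*E<sub>i</sub>*
/(*k<sub>i</sub>*(*k<sub>i</sub>*−1)) average into the network statistics
*L* and *C*; nodes with fewer than two neighbours contribute
*C<sub>i</sub>* = 0 rather than being dropped, so *C* is always a mean
over all *N* nodes. The equivalent-random-graph references are the closed
forms *L*<sub>rand</sub> = ln *N* / ln⟨*k*⟩ and *C*<sub>rand</sub> =
⟨*k*⟩/*N* — no null graphs are sampled — and the small-world quotient is
*Q* = (*C*/*L*)/(*C*<sub>rand</sub>/*L*<sub>rand</sub>).

Two definitional choices matter:

* **Distances and clustering** are computed on the symmetrized simple
  graph (an undirected edge wherever either direction exists; self-loops
  dropped): the path-length and triangle formulas presuppose an
  undirected simple graph. A directed-metrics mode is out of scope.
* **Mean degree ⟨k⟩ counts synaptic connections per neuron** — in-degree
  plus out-degree of the *directed* graph — rather than 2E/N of the
  collapsed graph. Under the topographic rules, reciprocal pairs
  (especially GC↔HIPP and GC↔MC) are frequent, so the two conventions
  differ by ~10%; counting each directed connection once is the
  convention under which this circuit's reference statistics are
  internally consistent, and it feeds the random-graph formulas above.
  For graphs read from plain undirected edge lists, ⟨k⟩ reduces to 2E/N.

The artificial stimulation source is a signal generator, not a neuron,
and is never a node of the analyzed graph. Disconnected graphs are
rejected explicitly (distances would be undefined) rather than silently
restricted to a component.

For the default healthy network, *C* exceeds *C*<sub>rand</sub> several
fold while *L* stays near *L*<sub>rand</sub>, giving *Q* well above 1
across seeds — the circuit is small-world; the test suite asserts this
over 20 seeds, and `scripts/acceptance.R` recomputes it.

# What the generated data do and do not show

The generator *is* the study system: there is no external data set. A
passing suite therefore demonstrates internal consistency — exact
divergences, conserved convergences, reproducibility, numerical
convergence, small-world structure of the generated topology, and the
qualitative physiology above — on a 1-D, four-cell-type, point-stimulus
abstraction. It does not validate 3-D axonal targeting, the four omitted
interneuron classes (axo-axonic, MOPP, HICAP, IS), channel kinetics
beyond the calibrated landmarks, or quantitative spike shapes and
latencies in real tissue. Millivolt/millisecond agreement with published
trace figures is explicitly out of scope: those depend on unpublished
channel parameters, and the package treats them as calibration targets
and ordering properties instead.

# Known limitations

* Dendrites are passive; active dendritic channels (and hence dendritic
  spike initiation) are absent.
* Synaptic weights are phenomenological, tuned to the circuit fingerprint
  rather than to unitary recordings.
* The 1:1-scale network (10^6 granule cells) is out of scope; the
  implementation is vectorized R and comfortable at the default 527-cell
  scale (a full run takes a few seconds).
* The equivalent-random-graph formulas assume ⟨k⟩ > 1 and a connected
  graph; degenerate inputs raise errors rather than returning NaN.
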
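---
title: "Tracing and modeling taste circuits in a whole-brain connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing and modeling taste circuits in a whole-brain connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastetrace)
```

## The analysis

`tastetrace` reconstructs the early gustatory pathway of the adult
*Drosophila* brain from a synaptic connectome. Four classes of labellar
gustatory receptor neurons (GRNs) — sugar-, water-, bitter-sensing and
IR94e-expressing — seed the analysis; the package identifies their direct
postsynaptic partners (second-order neurons, 2Ns) and the partners of those
partners (third-order neurons, 3Ns), then characterizes the resulting
circuit: how much the four modality pathways overlap, how much excitatory
versus inhibitory feedback and lateral connectivity they carry, where their
output synapses sit anatomically, what fraction of their input is
taste-derived, and which of them a whole-brain leaky integrate-and-fire
(LIF) model predicts to respond to GRN stimulation.

The connectome is represented as a directed multigraph: a neuron table
(identifier, superclass, class, hemisphere, neuron-level neurotransmitter
prediction) and an edge table in which one row is all synapses between one
presynaptic and one postsynaptic neuron within one neuropil, carrying an
edge-level neurotransmitter prediction. Both tables follow the column
dialect of public FlyWire-style dumps; the loader accepts configurable
column aliases because the dumps rename columns across releases.

## Layer identification rules

A *connection* is the set of synapses between an ordered neuron pair; by
default thresholds apply to the pair total summed across neuropils.

* **2N rule.** A neuron is a 2N for modality *m* if at least one GRN of *m*
  connects to it with ≥ 5 synapses (the conventional false-positive cutoff
  for single connections) and the neuron is not itself an annotated GRN of
  any modality. Fan-in and total GRN synapses are recorded per 2N.
* **3N rule.** Only 2Ns receiving ≥ 10 total same-modality GRN synapses are
  expanded (the "hop-1 gate"; connections of roughly 10 synapses are the
  scale at which connectivity is reliable across hemispheres and brains).
  A neuron is a 3N for *m* if it receives ≥ 10 synapses from at least one
  expanded 2N of *m*, is not a GRN, and is not a 2N of the same modality.
  A 3N may be a 2N of a different modality.

Whether the 5-synapse cutoff should be applied per neuropil rather than to
pair totals is ambiguous in the field's usage; pair totals are the more
inclusive reading and match the "total synapses" phrasing of the hop-1
gate, so they are the default, with `mode = "per_neuropil"` available on
both tracing functions. Raising any threshold can only shrink a layer; the
test suite asserts this monotonicity together with equivalence to a
brute-force two-hop enumerator on planted circuits.

GRN–GRN connectivity is tallied with no threshold (raw synapse sums,
normalized per source GRN), since single-synapse crosstalk between GRNs is
part of the quantity of interest; a threshold argument exists for
sensitivity analyses.

## Sign conventions

Acetylcholine is treated as excitatory; GABA and glutamate as inhibitory;
dopamine, serotonin, octopamine and unknown labels as `other`, because
their postsynaptic effect is not reliably signed. Two label sources are
used deliberately:

* **Edge-level labels** drive synapse-count matrices (feedback and lateral
  E/I heatmaps, output NT composition): these are per-synapse quantities.
* **Neuron-level labels** drive the convergence analysis, net excitation
  and sign-motif censuses, where each neuron pair must be counted exactly
  once and per-edge labels can disagree within a pair.

Net excitation of a 3N is the difference between excitatory and inhibitory
input synapses over qualifying same-modality 2N inputs (those passing the
tracing thresholds); inputs with sign `other` are excluded from both
tallies but reported.

## The convergence null

For 3Ns receiving exactly *k* (2 or 3) qualifying same-modality 2N inputs,
the null hypothesis is that input signs are independent draws with the
population excitatory proportion *p*: the expected fractions of all-E,
all-I and mixed convergence are *p*^k, (1−*p*)^k and the remainder. *p* is
estimated from the analyzed population itself (each 2N–3N pair once), and
neurons with any `other`-signed input are excluded. Observed category
counts are compared with a chi-squared goodness-of-fit statistic without
continuity correction; when a category's expected count is zero it is
dropped from the statistic with a warning. Because *p* is estimated from
the same data, the test is slightly conservative; the suite verifies it is
not anti-conservative by simulation (300 null replicates) and checks the
statistic against `stats::chisq.test` and a hand-rolled formula to 1e-10.
Results from fewer than 10 neurons are flagged rather than suppressed.

## Anatomy

The subesophageal zone (SEZ), the primary taste region, is the neuropil
set {GNG, PRW, SAD, FLA, CAN}; membership is decided after stripping the
`_L`/`_R` hemisphere suffix, so the definition is side-invariant. A neuron
is *local* if all its qualifying output connections (per-neuropil, ≥ 5
synapses) lie in the SEZ, *projection* otherwise, and `no_brain_output` if
it has no qualifying output connection at all. Synapse partitions are
synapse-level: SEZ versus outside, with non-SEZ synapses split into
ipsilateral/contralateral by suffix (ipsilateral defaults to the left
hemisphere, the side of the traced GRN arbors) or non-lateralized when the
region has no suffix. Synapses in unannotated neuropils are counted in a
separate bucket with a warning and excluded from the SEZ/non-SEZ identity,
which the code asserts on every run. Region profiles pool homologous
`_L`/`_R` regions and keep the top *k* regions per modality (6 for 2Ns, 12
for 3Ns by default); ties order by count then lexicographic region code and
are flagged. Proportion comparisons between modalities use Fisher's exact
test (two-sided).

## Input census

For every 2N and 3N, the fraction of its total input synapses (no
threshold on the denominator) arriving from annotated seed GRNs and from
*known taste neurons* — the union of GRNs, 2Ns and 3Ns across all four
modalities — is computed; the seed-GRN fraction can never exceed the
known-taste fraction, and neurons with zero input synapses are excluded
with a note. Input-partner censuses count distinct presynaptic neurons per
target modality at the 5-synapse connection threshold (the global
connection definition; `conn_threshold = 0` disables it), tallied by
superclass and class; a synapse-weighted variant is available.

## The LIF model

Each neuron is a point neuron with resting and reset potential −52 mV,
spike threshold −45 mV, refractory period 2.2 ms, synaptic decay constant
5 ms, spike-to-effect delay 1.8 ms, and a synaptic weight of 0.275 mV per
synapse, signed by the presynaptic neuron-level transmitter (ACH/DA/SER/OCT
positive, GABA/GLUT negative, unknown excluded by default). These values
follow the published whole-brain model fitted to experimental data. The
membrane time constant is not part of that parameter list; the default of
20 ms is adopted from the reference model's configuration, is an explicit
`lif_params()` argument, and is echoed in every simulation result.

The state equations per neuron are

dv/dt = (v_rest − v)/τ_mem + g/τ_syn,  dg/dt = −g/τ_syn,

with g incremented by the connection weight when a presynaptic spike
arrives (after the delay), so an isolated input of weight w deflects the
membrane by slightly less than w. Integration is fixed-step exponential
Euler at dt = 0.1 ms with delays in a ring buffer; dt must be smaller than
every time constant or construction fails. Stimulated GRNs emit Poisson
spike trains at the nominal rate for 1 s (regular trains are available for
deterministic tests) and are not themselves integrated. Rates are averaged
over 30 trials and any neuron with a positive mean rate counts as
*activated*; no neuron can exceed 1/2.2 ms ≈ 454.5 Hz within a trial, an
invariant the suite asserts. Two- and three-neuron motifs are checked
against an independent fine-step (0.005 ms) reference integration; spike
times agree within one integration step for single-pulse protocols.
Sustained strong drive produces bursting, where timing between integrators
drifts beyond a step over hundreds of milliseconds — a known discretization
property, which is why the oracle comparison uses single-pulse fixtures.

## The synthetic connectome

Because the real connectome is an external download, every stage is
validated against a generator that plants known structure and emits the
same CSV dialect. The generator's defaults are the study conditions of the
traced left-hemisphere labellar circuit:

* GRN counts 22/18/20/9 (sugar/water/bitter/IR94e); planted 2N layers
  76/51/64/24 with pairwise overlaps sugar∩water 28, water∩bitter 6,
  bitter∩IR94e 8; planted 3N layers 515/324/396/222.
* 3N pairwise overlaps are only partially reported for the real circuit
  (sugar∩water 201, sugar∩bitter 129, sugar∩IR94e 67, i.e. 39 %/25 %/13 %
  of sugar 3Ns); the remaining pairs (water∩bitter 60, water∩IR94e 40,
  bitter∩IR94e 70) were chosen once as comparable mid-range values and are
  configurable. Planted sharing is pairwise only — a neuron belongs to at
  most two modalities — which understates the higher-order overlap of the
  real circuit.
* Suprathreshold connection strengths are shifted-geometric (threshold +
  geometric tail: 5 + G(0.35) for GRN→2N, 10 + G(0.30) for 2N→3N), giving
  the heavy right tail of real connection-strength distributions (most 2Ns
  under 20 total GRN synapses, a few over 100). Fan-in is 1 + Poisson (1.5
  for 2Ns, 0.7 for 3Ns), matching median fan-ins of 2–3 GRNs and ~1 2N. An
  optional coupling mode correlates fan-in with per-input strength; it is
  off by default.
* Excitatory fractions, SEZ output fractions and contralateral fractions
  are per-(modality, layer) parameters set to the reported composition of
  each population (e.g. bitter/IR94e 2Ns mostly inhibitory and more
  strongly projecting than sugar/water 2Ns).
* About 10 % of each modality's exclusive 2Ns are planted *weak* (5–9
  total GRN synapses) to exercise the hop-1 gate, and decoy edges sit at
  each filtering boundary: GRN edges at 4 synapses, expanded-2N edges at 9,
  and ≥ 10-synapse edges from weak 2Ns.
* Feedback and lateral edges (2N→GRN, 2N→2N, 3N→2N, 3N→GRN) are drawn at
  configurable per-source rates with synapse counts capped in 5–9 and with
  no repeated neuron pair. The cap is a deliberate generator constraint:
  it keeps feedback registering as connections while guaranteeing that no
  feedback edge promotes an extra neuron into a planted layer, so planted
  memberships are exactly recoverable. For the same reason parents of
  planted 3Ns are drawn from modality-exclusive expanded 2Ns — a shared 2N
  is above the gate in both its modalities and would leak its children
  into both 3N layers.
* 120 background neurons (mechanosensory, antennal-lobe, lateral-horn,
  mushroom-body, ascending, descending and unannotated classes) provide
  non-taste input at Poisson rates of 3 partners per 2N and 4 per 3N,
  chosen so that roughly half of a taste neuron's input is taste-derived,
  as in the real circuit. Edge-level NT labels equal the presynaptic
  neuron's label, so planted signs are exact — which also means the
  edge-level/neuron-level label disagreement present in real data is not
  emulated; tests of that distinction use hand-built fixtures instead.

All randomness flows through one seeded generator; the seed is recorded in
the ground truth and identical seeds give byte-identical tables. What
passing tests show is therefore recovery of *planted* structure under
realistic sizes and noise — not that the pipeline's scientific conclusions
transfer to the real connectome, whose degree distribution, morphology and
annotation noise the generator does not attempt to match.

## Problem sizes and runtime choices

The test suite uses three planted scales: hand-built motifs of 2–15
neurons for rule checks, a ~70-neuron circuit for brute-force oracle
equivalence, and a ~700-neuron circuit (3N layers scaled to 180/120/140/80)
for statistics with adequate sample sizes. The acceptance script runs the
full default circuit (~1,250 neurons, ~59,000 synapses): generation and
two-layer tracing take seconds, and a five-rate, 30-trial LIF sweep runs in
about ten seconds on one core. Simulation fixtures in tests use 1–5 trials
and short durations; the full 30-trial protocol is exercised by the
acceptance script.

## Known limitations

* The pipeline stops at 3Ns by design; deeper layers quickly cover most of
  the brain.
* Neuropil-based anatomy inherits the edge table's region annotations; no
  synapse coordinates are used, and unannotated synapses are only bucketed.
* The convergence machinery supports k ∈ {2, 3} only, mirroring the scope
  of the underlying analysis.
* The LIF model assumes identical biophysics for every neuron and signed
  unit weights; neurons with unknown transmitter contribute no drive
  unless explicitly switched to excitatory.
* Cross-modality correlations of net excitation double-count 2Ns shared
  between the two modalities, a convention the result object flags
  (`shared_inputs_double_counted`).
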
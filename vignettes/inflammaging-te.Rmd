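---
title: "Inflammation, aging and cell-cell information flow: the model behind inflammate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inflammation, aging and cell-cell information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`inflammate` couples a lattice agent-based model of acute inflammation with
an information-theoretic analysis of the cell migration it produces. This
vignette explains the model, the estimators, and every numerical convention
the package had to pin down where the underlying biology admits more than
one reading.

## The agent-based model

The tissue is a 2D lattice (default 100 x 100 sites) of epithelial cells,
initially all alive. Two populations of motile immune cells walk on top of
it: 20 macrophages and 20 fibroblasts, placed uniformly at random on
distinct sites. Two diffusible cytokine fields live on the same lattice:
TNF (pro-inflammatory, secreted by activated macrophages) and TGF
(anti-inflammatory, secreted by activated fibroblasts).

A mechanical stimulus `S` in [0, 1] represents injury magnitude. At the
first iteration each macrophage activates with probability `S`; afterwards
an unactivated macrophage activates with probability `min(1, TNF)` read
from the maximum over its Moore neighbourhood (the 8 adjacent sites plus
its own). An unactivated fibroblast activates with probability
`min(1, TNF)` the same way. With `S = 0` there is never any TNF, so nothing
in the causal chain can fire: no activation, no cytokine, no apoptosis.
This null course is asserted exactly in the test suite.

Activation is one-way and differs by type:

* an activated **macrophage** stays mobile and, each iteration, releases one
  unit of TNF at its site when a draw from Beta(alpha3, beta3) is at least
  the local TGF concentration (TGF inhibits TNF synthesis);
* an activated **fibroblast** settles at the injury site (stops migrating),
  its remaining lifespan drops to 25%, and each iteration it releases one
  unit of TGF when a draw from Beta(2, 1) is at most the local TNF
  concentration (TNF promotes TGF synthesis).

"Local" for these synthesis gates is the cell's own site; neighbourhood
maxima are used only where sensing is involved (activation, apoptosis,
healing), which is the package's reading of "in the neighbourhood".

Movement is a biased random walk at velocity 3: three single-site Moore
sub-steps per iteration, each choosing among the current site and the
unoccupied in-grid neighbours with probability proportional to
`exp(concentration / temperature)` over the field the cell senses (TNF for
macrophages, TGF for fibroblasts). With all candidate concentrations equal
the choice is uniform -- a pure random walk -- so unstimulated runs are
exactly diffusive. The softmax with temperature 1 (configurable) is the
package's concrete form for "biased toward the highest concentration":
it degenerates gracefully to uniform, is strictly increasing in
concentration, and realising velocity as three sub-steps preserves
collision avoidance at every site change. Motile cells age one iteration
per update and are removed at their lifetime (20 iterations); every 5
iterations, empty population slots are refilled with fresh unactivated
cells at random free sites. A slot therefore carries a sequence of disjoint
cell lifetimes ("segments"), which matters for the angle analysis below.

The epithelium updates synchronously after the (randomly permuted,
asynchronous) agent updates:

1. **Apoptosis**: an alive cell dies when the Moore-maximum TNF exceeds the
   preset's apoptosis threshold.
2. **Healing**: a dead cell exposed to any TGF in its neighbourhood
   accumulates a healing clock; once the clock reaches the healing time
   `th` the cell regrows with probability `Pmt` per iteration.
3. **Fibrosis**: regrowth ensures at least one fibrosis site in the Moore
   neighbourhood -- if none is present, one random neighbour is marked for
   `Kc` iterations. An alive cell whose 3 x 3 block contains `Nc` fibrosis
   sites dies with probability `Nc / 9` per iteration; counters decrement
   every iteration.

The fibrosis composition deserves a note, because it is the one place where
a naive reading produces degenerate dynamics. If *every* successful
regrowth seeded a *fresh* fibrosis site, the healing/collagen-damage loop
would saturate the lattice with fibrosis under every parameter set and no
course could ever recover -- the "ensure at least one" reading caps
standing fibrosis density so that normal-parameter healing
(`Pmt = 0.20` > the 1/9 expected collagen kill rate of a single nearby
fibrosis site) outpaces damage, while the aging presets (slower mitosis,
longer healing time, double-length fibrosis) sustain injury. We verified
the degenerate alternative numerically before fixing this convention.

Finally, both cytokine fields take one explicit forward-Euler
reaction-diffusion step per iteration:
`phi <- (phi + D * lap(phi)) * (1 - K)` with the 5-point Laplacian,
lattice spacing 1 and dt = 1. Boundaries are reflecting (no-flux), so with
`K = 0` total mass is conserved exactly -- a property the tests exercise on
arbitrary fields -- and cytokine is not silently drained at the edges.
Decay is applied after the diffusion half-update; the alternative order
differs at O(D K), far below anything observable here. The explicit scheme
is stable and positivity-preserving for `D <= 1/4`, which the parameter
validator enforces; the reference constants (`D_TNF = 0.07`,
`D_TGF = 0.10`, `K_TNF = 1e-3`, `K_TGF = 1e-5`) sit comfortably inside it.

### Aging presets

Aging ("inflammaging") enters through four coupled parameter changes, from
Normal (`N`) through `A1` to `A2`: TNF synthesis is encouraged (Beta gate
(1.0, 3.0) to (1.2, 2.5) to (1.5, 2.0)), the apoptosis threshold drops
(0.8 / 0.6 / 0.4), regeneration weakens (`Pmt` 0.20 / 0.16 / 0.10, `th` 5 /
6 / 8 iterations) and fibrosis lasts longer (`Kc` 50 / 75 / 100
iterations). All three presets share the TGF gate Beta(2, 1) and the
motile-cell parameters. The presets are totally ordered in severity, which
the test suite asserts directly.

## From migration to information flow

Every mobile cell's position is recorded each iteration. Within one
lifetime segment, consecutive positions define displacement vectors, and
the *turning angle* at iteration t is the signed angle (counter-clockwise,
column = x, row = y) from the previous displacement to the current one,
mapped to [0, 2pi). An inverse-cosine alone would fold the domain to
[0, pi]; the signed extension via the cross product is the package's
resolution consistent with the full stated range. Zero-displacement steps
leave the angle undefined at the adjacent iterations (skipped, not given a
sentinel symbol), and angles never bridge segment boundaries.

Angles are discretised into 20 equal bins (width pi/10, about 0.314 rad).
All information measures are histogram plug-in estimates in bits:
Shannon entropy `H`, mutual information `I(X;Y) = H(X) + H(Y) - H(X,Y)`,
conditional mutual information
`I(X;Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)`, and transfer entropy from
a source series to a target series

    T(src -> tgt) = I(tgt_t ; src_(t-1) | tgt_(t-1)),

estimated from the joint histogram of `(tgt_t, tgt_(t-1), src_(t-1))`
triples. The test suite pins every estimator to an independent brute-force
summation over the full joint table at 1e-12, and to closed-form limits
(a deterministic one-step copy of a uniform 20-symbol source approaches
log2 20 = 4.32 bits).

One directionality subtlety: the printed definition of the
macrophage-to-fibroblast transfer entropy in this literature can be read
with either cell as the conditioned target. `transfer_entropy()` makes
direction explicit (`source`, `target`), and the pipeline's "T M->F" takes
the macrophage as source -- the degree of influence a macrophage exerts on
a fibroblast's next heading -- matching the interpretation that macrophage
TNF release steers fibroblasts. The opposite reading is available through
`pairwise_te(source = "fibroblast")`.

### Sample-size handling and pooling

`pairwise_te()` aligns each (macrophage slot, fibroblast slot) pair on
common iterations and pools triples across lifetime segments. Pairs with
fewer than `min_samples` (default 50) complete triples are reported
*missing* rather than as unreliable numbers.

Plug-in estimates over a 20^3-cell alphabet are severely biased at small
sample sizes: a few hundred triples of independent uniform symbols score
around 2-2.7 bits of spurious "transfer", and the bias is non-monotone in
the sample count. Single-run TE matrices are therefore comparable only at
matched sample sizes, and the package follows the study design it
implements: for condition-level distributions, `pairwise_te()` accepts the
*list* of replicate track tables and pools triples per slot pair across
replicates before estimating, which is how the joint histograms reach
useful occupancy. No analytic bias correction is applied -- the estimator
is deliberately the plain plug-in -- so TE values should always be read
comparatively (between conditions estimated the same way), never as
absolute information rates.

A per-iteration diagnostic, `configuration_entropy()`, summarises how
clustered the macrophage population is: the grid is cut into 10 x 10-site
blocks and the Shannon entropy of block occupancy is computed per
iteration. In stimulated runs it falls as cells converge on the injury
region while mean cytokine concentrations rise; `zscore()` puts both on a
common scale for plotting.

## Transfer-entropy networks

For one experimental condition (a stimulus level and a preset), the
defined TE entries of all replicates are pooled and their first and third
quartiles (linear-interpolation convention, the common default) become the
edge criterion -- a band around the most likely TE values, with the
histogram mode reported as a diagnostic. Each replicate then yields a
bipartite graph: 20 macrophage and 20 fibroblast nodes, an undirected edge
for every pair whose TE lies inside the band. Undirected is a deliberate
simplification: the analysis treats the band membership, not the TE
magnitude or direction, as the relationship of interest. On each graph the
package computes normalised shortest-path betweenness (divisor
(n-1)(n-2)/2, isolated nodes scoring 0) and the summary statistic

    F/M = (sum of fibroblast-node betweenness) / (sum of macrophage-node betweenness),

undefined (NA) when the macrophage sum is zero. F/M above 1 marks
fibroblast-centred topology, the signature of a normally resolving course;
below 1 marks macrophage-centred topology. `condition_summary()` returns
the per-replicate networks, their F/M values, and the mean and standard
error over replicates.

## Study conditions, problem sizes and determinism

`run_experiment()` reproduces the full design: stimulus levels 0, 0.2,
0.4, 0.8 crossed with presets N, A1, A2, ten replicates each, on the
package defaults of a 100 x 100 grid and 1000 iterations. The test suite
and the acceptance script run a reduced version of the same design -- a
60 x 60 grid, 500 iterations and five replicates per condition -- chosen
so a full grid completes in minutes on one core while the qualitative
contrasts (null course at S = 0, the TE shift with aging, the F/M balance)
remain measurable. Every replicate derives its seed deterministically from
the plan's base seed, a run is bit-reproducible from (parameters, seed),
and each archive carries the fully resolved configuration so any single
run can be re-created in isolation.

## What the simulation does and does not emulate

The model captures the architecture of an inflammatory episode -- a
pro-/anti-inflammatory feedback loop, chemotactic convergence, injury and
healing with fibrotic scarring, and aging as coupled shifts in synthesis,
sensitivity and repair. It does not emulate: population dynamics
(recruitment, proliferation -- populations are held at 20 + 20 by
repopulation), senescent cells or their secretory phenotype, age-dependent
migration speed or gradient sensing, ECM mechanics, molecular resolution
markers, or dose-dependent secretion (activation is binary, deposits are
unit-sized). Consequently, passing tests show that the *mechanisms as
specified* produce the expected contrasts between conditions; they say
nothing about quantitative agreement with any particular tissue, and the
turning-angle statistics inherit lattice artefacts (angles concentrate on
multiples of the 8 lattice directions) that real imaging data would not
show.

## Known limitations

* TE estimates at realistic track lengths are bias-dominated; only
  matched-design comparisons are meaningful (see above).
* The Q1-Q3 criterion always admits about half of the defined pairs, so
  the networks are dense; centrality contrasts between the parts are
  correspondingly modest at reduced scale.
* At the reduced grid the injury can percolate across the whole lattice
  under strong stimulus, compressing the score contrast between presets to
  late iterations; the severity *ordering* N < A1 < A2 is preserved.
* The explicit diffusion scheme limits `D` to 1/4 per iteration; faster
  spreading requires sub-stepping, which the package does not implement.
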
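---
title: "Evolving terminal-differentiation gene networks with a thermodynamic model of transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving terminal-differentiation gene networks with a thermodynamic model of transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnevolve)
```

# The system

`grnevolve` simulates the evolution of gene regulatory networks (GRNs) that
drive terminal cell differentiation, in the spirit of *C. elegans* neuronal
differentiation programs. An *organism* is a set of cells sharing one
genome: a collection of promoter strings, one per gene, over the alphabet
A,C,G,T. Genes are either transcription factors (TFs) — activators or
repressors — or *terminal features* (effector genes, the non-regulatory
genes whose expression defines a cell type). Every TF carries a position
weight matrix (PWM) describing its degenerate binding preference; PWMs are
sampled once at the start of a simulation and never mutate, while promoter
sequences do. Differentiation starts from an initial expression pattern in
which only a small set of *lineage TFs* is expressed (a different one in
each cell), and runs for a fixed developmental time; fitness compares the
resulting adult pattern of the terminal features with a predefined optimal
pattern. Selection and mutation act on a population of such organisms until
the population matches the target.

# Sequence to expression

## Binding sites

For TF $h$ with PWM $P_h$ (probabilities $a_{ij}$ of base $i$ at position
$j$, length $L = 8$), the log-likelihood ratio of a sequence window $s$
against the uniform background $b = 0.25$ is

$$\mathrm{LLR}(s, h) = \sum_{k=1}^{L} \log_2 \frac{a_{s_k k}}{0.25}.$$

Both strands of every promoter are scanned; windows with
$\mathrm{LLR} \ge 0.7\,\mathrm{LLR}_{max}$ (70% of the consensus score) are
retained as binding sites. Overlapping sites do not compete — all are kept.
PWM columns are sampled from symmetric Dirichlet distributions with
concentration parameters $(0.4, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3, 0.4)$, making
the core of a motif sharper than its flanks, as in PWMs inferred from PBM
or SELEX experiments. Raw Dirichlet draws can contain exact zeros, which
would send an LLR to $-\infty$; entries are therefore floored at
$\varepsilon_p = 10^{-4}$ and renormalized, which is numerically safe and
far below the retention threshold's resolution. The rare sampled PWM whose
consensus LLR is not positive would make the 70% threshold meaningless and
is resampled.

## Promoter occupancy

Transcription rate is read as the equilibrium occupancy of the promoter by
the basal transcriptional machinery (BTM). A promoter with $n$ sites has
$2^n$ bound/unbound configurations $\sigma$ with statistical weights
$W_\sigma = \prod_i q_i^{\sigma_i}$, where the weight of an occupied site is

$$q_i = \phi_i \, [\mathrm{TF}_h] \, K_{max}\, e^{\mathrm{LLR}(s_i,h) - \mathrm{LLR}_{max}},$$

with $[\mathrm{TF}_h]$ the current TF concentration, $K_{max} = 1$ the
consensus association constant and $\phi_i$ the local chromatin
accessibility (identically 1 when the chromatin layer is off). Each bound
TF multiplies the weight of the BTM-bound state by $\alpha_h$ (2.0 for
activators, 0.005 for repressors), so

$$E = \frac{Z_{ON}}{Z_{ON} + Z_{OFF}}, \qquad
Z_{OFF} = \prod_i (1 + q_i), \qquad
Z_{ON} = \prod_i (1 + \alpha_i q_i) - 1,$$

using the exact factorization of the configuration sums over independent
sites (verified in the tests against full $2^n$ enumeration). Both products
are accumulated in log space, so promoters with hundreds of sites cannot
overflow.

Two readings of the model differ in how the *empty* configuration (no TF
bound) is treated, and the package exposes both plus a compromise
(`dynamics_params(basal_mode = ...)`):

* `exclude-empty` (default): the empty configuration is removed from
  $Z_{ON}$ (the $-1$ above), so an unregulated promoter is perfectly
  silent. This is the only reading consistent with the behaviour of the
  evolved systems this model is built to reproduce: expression ranges from
  0 to about 4, genes without active sites converge to 0, and "expressed"
  can be meaningfully defined as "> 0". It is the package default.
* `include-empty`: the unmodified configuration sums, under which a
  promoter with no sites transcribes at $E = 0.5$ — a basal rate of half
  maximum, which drives every gene to half its ceiling and makes the
  documented optimal patterns unreachable.
* `btm-weight`: GEMSTAT-style explicit basal weight $q_{btm}$ for the
  BTM-bound empty configuration ($Z_{ON} = q_{btm}\prod(1+\alpha_i q_i)$;
  default $q_{btm} = 10^{-3}$), which interpolates between the two.

A second convention choice is the base of the exponent: the LLR is
defined in bits (log2) while Boltzmann factors are conventionally written
with $e$. The default exponentiates the bits-valued deficit with base $e$;
`dynamics_params(llr_scale = log(2))` instead converts the deficit to
natural-log units first. With the default, a site one bit below consensus
has $q_{base} = e^{-1} \approx 0.368$ rather than $0.5$ — a slightly
steeper affinity penalty; none of the qualitative behaviour depends on the
choice.

## Developmental dynamics

$E$ is a transcription *rate*, not a level: concentrations follow

$$\frac{d[x_g]}{dt} = E([\mathrm{TF}_{1..n}]_t) - b\,[x_g]$$

with degradation $b = 0.2$, integrated by the Euler method with step size 1
for $T = 10$ steps. The update is synchronous — all rates are computed from
the state at $t$ before any gene advances — which makes trajectories
independent of gene ordering (the update order is otherwise unspecified in
this kind of model). Concentrations are clamped at 0. From $x = 0$ under
maximal activation the reachable ceiling after 10 steps is
$(1 - 0.8^{10})/0.2 \approx 4.463$, which motivates the default "high"
optimal level of 4.0 (see below).

## Chromatin accessibility

In the chromatin variant every nucleotide $s_i$ of every promoter carries
an accessibility $\phi_{g,s_i}$, initialized uniformly at $\phi_0 = 1$ and
multiplying the weight of any site at that position. Bound TFs remodel
chromatin around their sites with a Gaussian footprint:

$$\frac{d\phi_{g,s_i}}{dt} = \beta\left[\frac{1}{H}\sum_h [\mathrm{TF}_h]\,
K_{max}\,\rho_h\, e^{-\frac{(s_i - s_h)^2}{2\sigma_h^2} + \mathrm{LLR}(s_i,h) -
\mathrm{LLR}_{max}} + \delta\,\phi_{g,s_i}\right]$$

with modification capacity $\rho = 1$ for activators and $-3$ for
repressors, amplitude $\sigma_h = 25$ bp, plasticity $\beta = 0.8$ and a
constant closing drift $\delta = -0.2$; the TF term is normalized by the
total number of sites $H$ on the promoter so that evolution is not
implicitly pushed toward site-dense sequences. A site's reference position
$s_h$ is the 0-based start of its window (sites span 8 bp, small against
$\sigma = 25$, so the choice of reference point within the window is
immaterial). With no sites, accessibility decays by the factor
$1 + \beta\delta = 0.84$ per step. $\phi$ is clamped at 0 — a negative
accessibility would turn site weights negative and break the partition
function — and needs no upper clamp because the $\delta\phi$ term bounds
growth. Chromatin conditions use 600 bp promoters instead of 150 bp; all
other parameters are unchanged.

# Conditions

Built-in conditions follow a common architecture over 4 cells:

* `mce0` / `mce0fix`: 40 genes — 15 TFs (4 cell-specific lineage
  activators, the rest split between further activators and repressors)
  and 25 terminal features (5 *terminal-all*, optimally high in every
  cell, the panneuronal-gene analogue; 20 *terminal-specific*, 5 per
  cell).
* `mce1` / `mce1fix`: 10 extra terminal features optimally high in cell
  pairs (cells 1–2 or 3–4), modelling an intermediate organizational
  hierarchy.
* `mce2` / `mce2fix`: as `mce0` plus a fifth lineage TF expressed in every
  cell initially — partially overlapping pre-differentiation states.
* `mce0Xss`: `mce0` with 600 bp promoters and chromatin enabled.

About 30% of TFs are repressors (4 or 5 of 15). The `fix` suffix is
treated purely as a preset label: the presets differ only in their
registered overrides (here, the repressor count — 4 for the `fix`
variants, 5 otherwise), since nothing else distinguishes them. The shared
TF of `mce2` is modelled as a fifth lineage activator seeded at the same
low level in all cells.

Numeric levels are not dictated by the model and are configurable; the
defaults are **low = 0.5** for initially expressed lineage TFs, **high =
4.0** for optimally-on terminal features and **0** elsewhere. The high
level is deliberately a little below the dynamic ceiling 4.463 so that a
perfect genome can actually reach it within the 10-step differentiation
window (a target above the ceiling could never satisfy the convergence
threshold); the low level seeds lineage TFs weakly enough that they must
evolve autoregulation or cross-activation to sustain themselves.

`mce0mini` / `mce2mini` are reduced presets with the identical
architecture (4 cells; 10 TFs of which 4 lineage and 3 repressors — the
same 30% repressor fraction; 3 terminal-all and 2 terminal-specific per
cell, 21 genes total). They exist so that replicated experiments — twenty
or more full evolutionary runs plus their downstream mutagenesis and motif
statistics — fit in a test suite; the vignette-scale analyses and the test
suite use them, and single full-size `mce0fix` runs are used to check that
nothing qualitative changes with roster size.

# Evolution

Fitness is the inverse of the mean squared error of the adult pattern over
terminal features only:
$\mathrm{MSE} = \frac{1}{C}\sum_c \frac{1}{G}\sum_g (x_{cg} - o_{cg})^2$
(TFs are free to evolve any expression pattern). Each generation, every
one of the $N = 24$ offspring is produced by two independent tournaments:
$k$ organisms drawn without replacement, the fittest of each tournament
becoming a parent (the same organism may win both — selfing is allowed,
and no elitism is used). Ties are broken by population index for
reproducibility. Genes segregate independently; homologous promoters
recombine at `Poisson(0.2/kb)` crossover points and mutate at a scheduled
substitution rate: 5/kb before generation 100, 1/kb to generation 300,
then 1.5 and (from generation 500) 1.25 substitutions per genome.
Tournament size starts at $k = 12$ and rises to 18 after generation 300
once mean MSE < 0.5. Each individual's substitution rate is additionally
scaled by fitness so that offspring of less fit parents mutate more; the
exact proportionality is not pinned down by the description, so the
package scales by the mid-parent MSE relative to the population mean,
clipped to $[0.5, 2]$ — bounded so that the early generations (where MSE
ratios are extreme) cannot run away. A run stops when mean MSE drops below
$\varepsilon = 0.01$, or is flagged non-converged at generation 5000.

All randomness — PWM sampling, initial genomes, tournaments, segregation,
recombination, substitution — flows from the single `seed` argument
through R's RNG (the compiled generation loop draws from the same stream),
so a run is bit-for-bit reproducible from its manifest.

## Binding-site tracking

With `track_sites = TRUE` the run records, for every population-level site
key (gene, TF, window position, strand), the generation it first appears
in any individual and the generation it disappears from all of them.
Position is part of the identity: a site that drifts by 1 bp counts as a
death plus a birth, which makes the persistence statistics slightly
conservative for both gene classes alike. Mean lifespans are computed over
died sites; persisted sites are right-censored at the final generation and
excluded unless requested (`count_persisted = TRUE`).

# Perturbation analysis

Two knockout flavours quantify robustness: `knockout_tf_sites()` deletes a
TF's cached sites on terminal-feature promoters (direct effects only; the
DNA is untouched, so the deletion cannot create new sites) and
`knockout_tf()` sets the TF's $K_{max}$ to 0 (direct plus indirect
effects). Phenotype is mutant minus wildtype adult expression, recorded
for each terminal feature only in cells where its optimal expression is
nonzero. "Expressed" in the regulator-counting and repression summaries
means strictly greater than zero, which is exact under the default basal
mode (silent means exactly 0); an epsilon floor argument exists because
repressor-only promoters can carry tiny nonzero expression under the other
basal modes.

# Network motifs

The *active network* of a cell has a directed edge from TF A to gene B iff
A's adult expression in that cell is above the floor and B's promoter
carries at least one site for A. Terminal features with identical optimal
rows are merged into single vertices and self-regulation is ignored. All
weakly connected induced subgraphs of sizes 3–5 are enumerated (ESU
algorithm, each subset exactly once) and retained when every TF node has
an output edge, every non-lineage TF also has an input edge, at least one
lineage TF is present, and a regulated non-TF node is present. Lineage
status uses the true gene identity (a lineage TF of any cell counts),
while class identity uses only the TF/non-TF typing: two subgraphs are
equivalent when some type-respecting relabeling equates their adjacency
matrices, computed by brute force over at most $5! = 120$ permutations.

Applying those degree criteria to all abstract typed digraphs yields
exactly 6 admissible classes of size 3 and 75 of size 4
(`enumerate_possible_classes()`). One subtlety: the 75th size-4 class is
the disjoint union of two independent TF→target pairs. The inventory is
therefore enumerated without a *global* weak-connectivity requirement —
admissible graphs are disjoint unions of admissible connected pieces
(every component must contain a regulated non-TF node); under a strict
global-connectivity reading the size-4 inventory has 74 classes
(`connected = TRUE`), while size 3 is 6 under both readings.

Enrichment is scored against 10 sets of randomized networks built by
repeatedly swapping the target endpoints of edge pairs within each
network, rejecting self-loops and duplicate edges — preserving every
node's out-degree exactly and the in-degree multiset globally, which is
the invariant "shuffling the outputs of each node" guarantees. The
Z-score is $(N_{real} - \overline{N_{rand}})/\mathrm{sd}(N_{rand})$ with
the population (divide-by-$n$) standard deviation, and classes with
$Z \ge 2$ count as motifs. Within a motif, node positions are named by the
orbits of its type-respecting automorphism group (`p0, p1, ...` for unique
positions, `set0, ...` for symmetric ones), and the occupancy matrix
counts, for every gene of every simulation in every cell, how often it
occupies each named position — one row per (simulation, cell, gene), in
sparse MatrixMarket-exportable form.

# What the synthetic system does and does not emulate

The generator *is* the study system: there is no external data. It
reproduces the ingredients that the downstream claims depend on — degenerate
PWM binding with thresholded double-strand scanning, thermodynamic
integration of activation and repression, multicellular initial/optimal
patterns separating broadly expressed from cell-specific targets, and
selection on expression error. It deliberately omits TF–TF cooperativity,
nucleosome/histone-mark detail (the chromatin layer is an unspecific
spatial-cooperativity smoothing, not a nucleosome model), diploidy and
linkage, and PWM evolution. Conclusions from passing tests therefore
concern this model class, not real genomes: in particular the motif
inventory and persistence statistics depend on the merged-vertex
convention and on position-exact site identity.

# Numerical and testing choices

* Partition sums in log space; `expm1`/`log1p` around the excluded empty
  configuration; hard error (with step index) on non-finite state.
* Expression and accessibility clamped at 0; trajectories bounded by the
  analytic ceiling, asserted in tests.
* Tournament and best-of-population ties break toward the lower index.
* The test suite validates every fast path against an independent slow
  oracle: scanning against a character-level R rescan, activation against
  full $2^n$ enumeration, trajectories against stepwise application of the
  exported single-step functions, subgraph counts against an all-subsets
  oracle, canonical keys against igraph's VF2 colored isomorphism, and the
  class inventory against a second brute force.
* Replicated biology checks run on `mce0mini` (20 seeds, every one
  convergent in the packaged configuration) plus a single full `mce0fix`
  run; a full 200-replicate campaign is a compute-cluster exercise, not a
  test.

# Known limitations

* In replicated runs of the packaged configuration, the top size-3 class
  by Z-score is the reciprocal activator pair with a shared target
  ({T1⇄T2, both→N}), not the feed-forward loop: evolved populations here
  sustain TF expression partly through mutual activator pairs (alongside
  the self-activation that the network analysis ignores), and any
  out-degree-preserving randomization makes reciprocal coincidence rare,
  so this enrichment dominates the ranking. The feed-forward loop is
  abundant in absolute count (about 2–3 instances per active network) but
  sits below its degree-preserving null expectation. The ranking is
  computed by the replicated-biology acceptance test and is robust to the
  null variant, the expression floor and the roster size.
* Persistence tracking treats positional drift as death+birth (above).
* The `include-empty` basal mode is provided for completeness but cannot
  reach the documented optima (silent genes converge to $E/b = 2.5$, and
  the MSE floor is far above $\varepsilon$).
* Orbit names are stable only relative to a class's canonical form;
  comparing occupancy columns across package versions requires matching
  canonical keys first.
* `enumerate_possible_classes()` is exact only to size 5 (the canonical
  encoding uses one 64-bit word).
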
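---
title: "Logical modelling of tumour-cell invasion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical modelling of tumour-cell invasion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

boolmet analyses a Boolean (logical) model of the early steps of
metastasis — epithelial–mesenchymal transition (EMT), invasion and
migration of tumour cells — together with the statistical machinery
needed to interrogate it: exact attractor enumeration, continuous-time
stochastic simulation, an in-silico genetic-interaction screen, a
robustness census over rule perturbations, and two ways of confronting
the model with transcriptome data. This vignette explains the model,
the algorithms, the tunable parameters, and the design decisions taken
where more than one reasonable choice existed.

## The model and its formalism

Each molecular species (p53, NICD, the miR-34/200/203 microRNAs, the
core EMT transcription factors SNAI1/2, ZEB1/2, TWIST1, the AKT
isoforms, E- and N-cadherin, …) is a Boolean variable updated by a
logical rule over its regulators, written with `!`, `&`, `|` and
parentheses (precedence `!` > `&` > `|`). Two nodes, `ECMicroenv`
(extracellular matrix / microenvironment) and `DNAdamage`, are *inputs*:
free constants with no rule that never change during dynamics. Six
nodes are phenotype read-outs: `CellCycleArrest`, `Apoptosis`, `EMT`,
`Invasion`, `Migration` and `Metastasis`; by construction `Metastasis`
copies `Migration`, and migration requires EMT and invasion, so a cell
must acquire all three capabilities for the metastatic read-out to
switch on. The bundled 32-node model ships as a plain-text rule file
(`inst/extdata/metastasis_rules.txt`); `ECM` is accepted as an alias of
`ECMicroenv`.

Dynamics are asynchronous: exactly one variable changes per transition,
so each state of the 2^32 hypercube has one candidate successor per
rule whose value disagrees with the current bit. A *stable state* is a
state with no successor; it is an absorbing attractor of the
asynchronous dynamics. The wild-type model has nine stable states — a
homeostatic epithelial state (all read-outs OFF, CDH1 ON), four
apoptotic states, two EMT-arrested states and two metastatic states —
shipped as a reference fixture and re-derived by the solver in the test
suite.

```{r}
library(boolmet)
model <- load_metastasis_model()
states <- enumerate_stable_states(model)
apply(states, 1, function(s) as.character(label_stable_state(s)))
```

## Exact stable-state enumeration

`enumerate_stable_states()` solves `x = f(x)` by depth-first
branch-and-propagate over partial assignments, implemented in C++.
Rules are compiled to postfix token vectors and evaluated in Kleene
three-valued logic (0 / 1 / unknown); whenever a partial assignment
fully determines a rule, the target node is fixed (or a contradiction
prunes the branch), and only then does the solver branch on the first
unassigned node in declared order, 0 before 1. This yields all stable
states in lexicographic order without touching the full state space;
on the bundled model a solve takes about a millisecond. Inputs are
branched like any other free node, so every input combination is
explored; clamped nodes are pre-assigned and their rules ignored. The
test suite checks the solver against an independent vectorised
brute-force enumeration of all 2^n states on hundreds of random models
(up to 14 nodes), with and without clamps.

## Stochastic simulation and phenotype probabilities

Mutant phenotypes are quantified as the probability that a phenotype
node is ON at the end of a random walk on the asynchronous transition
graph, simulated as a continuous-time Markov chain: every eligible flip
carries rate `rate_up` or `rate_down` (both default 1 per time unit —
there is no experimental basis for heterogeneous rates), waiting times
are exponential in the total rate, and the flip is drawn proportionally
to its rate (Gillespie's algorithm). A trajectory stops on absorption
in a stable state or at `max_time` (default 100 time units, roughly two
orders of magnitude above the typical absorption time of the 32-node
model at unit rates; `fraction_absorbed` reports cut-off trajectories,
which flag possible cyclic attractors in perturbed models). The
read-out is the endpoint state, not a time average: all wild-type
attractors are fixed points, so the endpoint law is the asymptotic law.

Initial states default to i.i.d. uniform bits on every node; a
fixed/mixed policy (`initial =` in `sim_config()`) supports
experiments such as forcing `ECMicroenv`, `GF` and `TGFbeta` ON.
Reported probabilities are endpoint means with Monte-Carlo standard
errors `sqrt(p(1-p)/n)`. Each trajectory draws from its own
counter-based substream of the master seed (SplitMix64), so results are
bit-reproducible, independent of node order, and stable under growing
`n_trajectories` — the first *k* trajectories never change.

For clamped models whose free state space is small,
`exact_endpoint_probabilities()` builds the full embedded jump chain
and solves the absorbing-Markov-chain linear system `(I - Q) B = R`
(sparse LU). The property suite requires simulation and exact solve to
agree within three Monte-Carlo standard errors on random models whose
trajectories all absorb; models with recurrent cycles are excluded,
since their endpoint law is not defined by absorption.

## Mutants, epistasis and the interaction screen

A gain-of-function (GoF) mutation clamps a node ON, a loss-of-function
(LoF) clamps it OFF; pathway-level mutants clamp every member of a
module (e.g. `TGFb_pthw` = {TGFbeta, SMAD}). The default mutatable set
is the 24 nodes that are neither inputs nor phenotype read-outs;
`mutatable_nodes(include_inputs = TRUE)` widens it to 26 for screens
that also clamp the microenvironment and DNA-damage inputs (an input
clamp is a legitimate perturbation — a constitutively matrix-attached
or damage-free cell).

For a gene pair, epistasis with respect to metastasis is scored on the
event of *not* reaching the phenotype under a multiplicative null:
`epsilon = (1 - p12) - (1 - p1)(1 - p2)`. Negative values are
synergies, positive values alleviating (masking) interactions. The
exported interaction network keeps `epsilon < -0.2` or
`epsilon > 0.3` (cuts placed in observed gaps of the epsilon
distribution), with nodes sized by single-mutant probability and edges
weighted by `|epsilon|`, in SIF and GraphML. Gene pairs are further
classified by which of the four direction combinations cancel the
phenotype (probability below `cancelled_tol`, default 0.05) and which
amplify it (above the largest single-mutant probability) into the five
qualitative patterns `1a`, `1b`, `2a`, `2b` and `3` — pattern `3` being
the synthetic-dosage archetype in which only a mixed LoF/GoF
combination, such as p53 LoF with NICD GoF, makes the phenotype
certain. A 2-D overview of mutants (`mutant_landscape_coordinates()`)
uses ordinary PCA of the endpoint phenotype-combination distributions,
keeping combinations with mean prevalence above 1%; linear PCA was
chosen over non-linear manifold methods to keep the embedding exact,
deterministic and dependency-free, at the cost of some local-structure
fidelity.

### Certain-metastasis synergies: an exact census

"The double mutant reaches metastasis with probability 1" is a
stochastic statement; `find_metastatic_synergies()` turns it into a
checkable exact one. A pair qualifies when (i) every stable state of
the doubly clamped model has `Metastasis = 1` (exact, by the solver),
(ii) at least one stable state exists and 1000 independent trajectories
all absorb in metastatic states (guarding against cyclic attractors),
and (iii) neither single mutant is itself certain (each retains a
non-metastatic stable state). On the 24-gene set this census finds six
pairs: four involving Notch activation — NICD GoF with p53 LoF, with
p73 GoF, with SNAI2 GoF, and with AKT2 GoF — and two that force the
TGF-β pathway instead, AKT2 GoF with TGFbeta GoF and AKT2 GoF with SMAD
GoF. The mechanism of the latter two is transparent in the rules: AKT2
ON switches off the whole p53 family (hence all microRNAs), and a
forced TGF-β/SMAD signal supplies the invasion condition
`SMAD & CDH2`, so the formerly EMT-arrested attractors become
metastatic. These two pairs converge an order of magnitude more slowly
than the NICD-containing ones (at a horizon of 20 time units their
estimated probability is still ≈ 0.91 while the four NICD pairs are
already at 1.0), so finite-horizon simulation-only screens
systematically miss them; this is why the package insists on the exact
attractor confirmation rather than a simulated `p >= 0.995` alone, and
why the simulation horizon was left at its default rather than tuned.

## Robustness to operator swaps

The robustness analysis perturbs the logic itself: every model variant
that differs from the wild type by flipping `&`/`|` at one operator
site, at two sites of the same rule, or at one site in each of two
rules. The bundled model has 126 operator sites, giving
126 + 283 + 7592 = 8001 variants. A flip is defined *textually*: the
operator token is swapped in the rule as written and the rule is
re-read under standard precedence, so the flipped operator re-binds by
precedence (an `&` flipped inside an OR-chain binds its two
neighbours; a `|` flipped inside an AND-chain splits the conjunction).
This convention was chosen over tree-local alternatives (swapping at a
node of a left- or right-folded binary tree, or making the flipped
operator bind tightest) because grouping conventions change the variant
semantics, and the textual one is both the natural behaviour of
operator substitution in a rule file and the one whose census
statistics agree best with the reference robustness figures for this
model; the alternatives were implemented and measured before being
rejected. The census enumerates each variant's stable states exactly
(the 8001 solves take a few seconds), counts occurrences with
multiplicity, pools distinct 32-node state vectors, and computes each
distinct state's Hamming distance to the nearest wild-type stable state
over all 32 nodes. Shares are reported over occurrences, where the
wild-type states account for ≈ 59.5% and distance-1 neighbours for
≈ 13.3%; `phenotype_probability_sweep()` adds simulated phenotype
probabilities over a seeded subsample of variants.

## Matching expression time courses to stable states (EBP)

The expression-based phenotype score asks which stable state a
transcriptome most resembles. The pipeline: (1) map measured genes to
model nodes — most nodes carry their HUGO symbol; the read-outs use
biomarkers (Apoptosis → CASP9, Migration → CDC42, Invasion → MMP2) and
`GF`/`ERK` map to EGFR and MAPK1 as the closest measured species, all
overridable via the mapping table; (2) average replicates per
timepoint; (3) binarize each gene, by default with an exact
one-dimensional 2-means over the gene's series, thresholding at the
midpoint of the two cluster centres — genes whose series spans less
than `min_range` (default 1 log2 unit) are treated as flat and called
against the global median, yielding always-ON/always-OFF flags, while
genes with both bits present are flagged dynamic; a global-quantile
method is available and, being quantile-consistent, makes the scores
invariant under monotone transforms of expression; (4–5) compare each
gene's bit with the corresponding node's bit in every stable state,
scoring 1 per agreement; (6) sum agreements into an integer EBP score
per (timepoint, stable state) and rank states per timepoint with ties
preserved. By default scoring is restricted to the eleven genes with
genuine dynamics during an EMT induction (CDH1, CDH2, CTNNB1, EGFR,
MAPK1, MMP2, SMAD3, SNAI2, TGFB1, VIM, ZEB1); a switch scores all
mapped genes with their constant bits instead. Note that states
differing only outside the scored gene set (e.g. the two metastatic
states, which differ in the DNA-damage input) tie by construction.

## Module activity and differential testing

A module's activity in a sample is the sample's projection onto the
first principal axis of the module's gene-centred expression submatrix
— a one-number summary of coordinated target-gene expression. Genes
are centred but not standardised by default (a `standardise` switch
exists); the axis sign is fixed by positive correlation with the mean
module expression, removing PCA's sign ambiguity, so a single-gene
module scores as that gene's centred profile. Group differences are
tested per module with Welch's t-test (chosen over the pooled-variance
test because cohort designs of interest are heavily unbalanced, e.g.
88 non-metastatic vs 17 metastatic samples); `var.equal = TRUE`
restores the pooled test. Significance defaults to p < 0.05.
Single-gene differential expression is the same operation applied to
singleton modules.

## Synthetic data: what it emulates and what it does not

`generate_timecourse()` emulates a TGF-β EMT-induction experiment:
3 replicates at 0, 8, 24 and 72 h; the eleven dynamic genes follow
sigmoid log2-trajectories `baseline + amplitude / (1 + exp(-slope (t -
midpoint)))` with additive Gaussian noise (sd 0.25, multiplicative on
the raw scale, as for microarray-like data); CDH1 is lost late
(midpoint 40 h) while ligand and pathway genes respond early (TGFB1 at
4 h, SMAD3 at 6 h) and the mesenchymal programme mid-course, so the
8 h timepoint sits near the epithelial/mesenchymal decision boundary
and the per-timepoint EBP argmax moves from the epithelial/apoptotic
states at 0 h to the metastatic states by 24–72 h. Static genes sit
clearly above or below the global threshold. `generate_cohort()`
emulates a two-group tumour cohort (defaults 88 vs 17) with `n` target
genes per module at log-normal baselines and planted per-module group
shifts in pooled-SD units; `generate_random_model()` produces random
rule files for oracle testing. All generators return ground truth
sufficient to check downstream results and are deterministic under a
fixed seed.

These generators make no attempt to match real platform artefacts:
probe effects, heteroscedastic noise, correlated background genes,
tumour purity or bulk dilution of EMT signal. Passing tests therefore
demonstrate that the pipeline recovers planted structure under its own
assumptions, not that it would recover biology from any particular
real data set.

## Numerical choices and degenerate inputs

Stable states and census outputs are ordered lexicographically over
declared node order so that diffs against fixtures are stable. EBP ties
are reported as ties, never broken arbitrarily. The 2-means split is
exact (all n−1 splits of the sorted series are scored), so binarization
has no k-means initialisation randomness; constant genes cannot be
split and fall back to the global threshold with a flag rather than an
error. PCA embeddings fix signs by the largest-magnitude loading;
degenerate (zero-variance) clouds fall back to raw columns. Epistasis
inputs outside [0, 1] are rejected; a double mutant clamping one gene
twice is rejected; an empty interaction network still exports valid
files. The Hamming distance requires identical node sets. Percentages
in the census are computed over occurrences with multiplicity, then
rounded to whole percent for reporting.

## Problem sizes in the tests and acceptance script

The suite cross-checks the solver on ~250 random models of 5–14 nodes,
the simulator on 2000-trajectory runs against exact absorption solves
of 7–8-node models, the census end-to-end on 6–7-node models against a
per-variant brute force, module-activity power on 200 simulated 50/50
cohorts, and the full 8001-variant census plus a 26-gene exact synergy
screen on the bundled model; the whole suite runs in well under five
minutes on one CPU. The acceptance script recomputes the variant count,
census totals, maximum distance and the NICD-GoF/p53-LoF metastasis
probability (2000 trajectories) from scratch.

## Known limitations

Only fixed-point attractors are enumerated; cyclic attractors are
detected indirectly (non-absorbed trajectories) but not characterised.
Heterogeneous per-node rates and time-resolved probability curves are
out of scope. The reduced modular model is not re-implemented as its
own rule set: pathway-level mutants are realised as multi-node clamps
on the detailed model, which preserves the wild-type attractors but is
not guaranteed to match a hand-built modular model in all perturbed
conditions. The operator-swap census depends on the swap-grouping
convention; the adopted textual convention is documented above and the
package exposes `apply_variant()` so alternative conventions can be
studied explicitly. Real A549/TCGA data are not bundled; analyses of
them must be run through the TSV interfaces.
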
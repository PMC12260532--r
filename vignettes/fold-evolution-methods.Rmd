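---
title: "Simulating the evolution of protein folds: models and methods"
author: "foldevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of protein folds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldevo)
```

# The model

`foldevo` simulates the evolution of protein folds from random amino acid
sequences with a classic mutation–evaluation–selection loop over a
population of fixed size $N$:

1. **Mutation.** Every individual produces exactly one mutant per
   generation. The mutation is drawn from an *evolutionary dictionary*: a
   probability table over eight event types (amino acid substitution,
   single-residue insertion and deletion, multi-residue deletion, random
   multi-residue insertion, partial and complete tandem duplication, and
   circular permutation), together with a substitution model and a length
   law for multi-residue indels.
2. **Evaluation.** The mixed pool of the $N$ parents and their $N$ mutants
   ($2N$ individuals) is passed through a structure backend that returns,
   for each sequence, backbone coordinates, a per-residue confidence
   (pLDDT, held on $[0,1]$ internally), and a global confidence (pTM).
3. **Scoring.** Each pool member receives the multiplicative fitness
   $$s_i = \overline{\mathrm{pLDDT}} \times \mathrm{pTM} \times \mathrm{CD}
   \times (\mathrm{ipLDDT} \times \mathrm{iCD}) \times \mathrm{constr},$$
   where CD is the long-range contact density, the two interface terms are
   the identity $1$ for monomers, and `constr` is a product of logistic
   length penalties. A product form means any vanishing factor (no
   long-range contacts, chains that never touch in dimer mode) zeroes the
   score — fold formation and, in dimer mode, binding are both obligatory.
4. **Selection.** $N$ survivors are chosen from the $2N$ pool by strong
   (deterministic top half), fitness-proportional, or Gibbs (softmax)
   selection. Every selected individual is recorded in a lineage tree with
   the mutation event on its incoming edge.

The run stops as soon as a selected individual reaches both stop
thresholds (defaults $\overline{\mathrm{pLDDT}} \ge 0.85$ and
$\mathrm{pTM} \ge 0.75$, both inclusive), or at the generation budget.
The stop condition is checked on the survivors of each completed
generation, not on founders, so a zero-threshold configuration stops at
generation 1 after one full mutation–selection round.

## Fitness terms in detail

**Contact density.** For a chain of length $l$,
$$\mathrm{CD} = \frac{1}{l}\,\#\{(i,j) : |i-j|>5,\;
d(\mathrm{C}\beta_i, \mathrm{C}\beta_j) < 6\,\text{Å},\;
\mathrm{pLDDT}_i > 0.5,\; \mathrm{pLDDT}_j > 0.5\}.$$
Pairs are unordered and all three filters are strict inequalities. The
sequence-separation filter alone removes the local $(i,i+4)$-type contacts
of an α-helix, so no additional secondary-structure exclusion is applied.
Glycine, which has no Cβ, contributes its Cα position instead.

**Interface terms (dimer mode).** When the evolving chain is co-folded
with a fixed binding partner, interface contacts are inter-chain Cβ pairs
closer than 6 Å with both residues above the confidence cutoff; no
sequence-separation filter applies across chains. `ipLDDT` is the mean
confidence over all residues (either chain) participating in at least one
such pair, and `iCD` is the number of qualifying pairs divided by the
*evolving* chain's length. An empty interface sets `ipLDDT` to 0, which
zeroes the dimer score: the selection pressure toward binding is built into
the score rather than added as a separate objective.

**Length constraints.** Each law is the decreasing logistic
$$P(L) = 1 - \frac{1}{1 + e^{C (L_0 - L)}},$$
with $P(L_0) = 0.5$ exactly, $P \to 1$ for short and $P \to 0$ for long
inputs, and the point symmetry $P(L_0-x) + P(L_0+x) = 1$. Defaults: chain
length $C = 0.2$, $L_0 = 250$; helix elements $C = 0.5$, $L_0 = 30$;
strand elements $C = 0.5$, $L_0 = 12$. The constraint factor is the chain
law evaluated at the sequence length times the helix/strand law evaluated
at the length of *every* maximal H and E element. Applying the element
laws as a product over all elements (rather than only to the longest one)
was a genuinely open choice; the product matches the multiplicative
structure of the score and penalises each oversized element independently.

## Selection modes

With pool scores $s_1 \dots s_{2N}$:

* **Strong**: the $n$ highest-scoring members survive, each at most once.
  The formal median rule breaks down under ties straddling the median, so
  the implementation is a stable sort (descending score, ties in pool
  order) followed by taking the top half — deterministic and
  reproducible.
* **Proportional**: $n$ independent draws *with replacement* with
  $p_i = s_i / \sum_k s_k$; the same member may survive several times,
  giving true sampling drift. An all-zero pool falls back to the uniform
  $1/(2N)$ so early populations with no fold drift neutrally.
* **Gibbs**: $p_i = e^{\beta s_i} / \sum_k e^{\beta s_k}$, computed with a
  max-shift so large $\beta s$ cannot overflow. $\beta = 0$ is exactly
  uniform; $\beta \approx 1$ resembles proportional selection of the
  exponentiated scores (softmax of log-scores is proportional selection —
  a tested identity); $\beta \gtrsim 5$ behaves like strong selection.
  Gibbs draws are *without* replacement (successive renormalisation).
  This is a deliberate design decision: with replacement, the softmax
  collapses onto the single best individual as $\beta$ grows and can never
  reproduce strong selection's "each member at most once" survivor set,
  which is the limit the mode is defined to approach.

Survivor clones produced by with-replacement selection get fresh
identities pointing at the individual they copy, with an event-free edge;
the genealogy therefore stays a tree rather than a DAG, and lineage
extraction skips the event-free edges (repeated selection of an unchanged
parent adds no mutation, so a lineage always carries fewer distinct
sequences than the run has generations).

# The deterministic surrogate backend

The structure evaluator is a pluggable contract
(`StructureEvaluator` / `evaluateStructure()`): any backend that maps
sequences to coordinates plus confidences can drive the engine, including
an adapter around a neural structure predictor. The bundled surrogate
exists so that *every* stage of the pipeline runs and is tested at desk
scale. It is explicitly not a physical model; it is a deterministic,
fast, pure function of the residue string with predictor-like *shape*:

* **Signals.** Kyte–Doolittle hydropathy is centred by its trailing
  running mean and autocorrelated at lags 3–4 (the $\sim$3.6-residue
  period of an amphipathic helix) and lag 2 (the buried/exposed
  alternation of a strand). Products are attributed to the right endpoint
  of each pair and smoothed with a trailing window of 7 residues with a
  fixed denominator. The causal, fixed-width design has two consequences
  used by the tests: extending a chain never changes existing per-residue
  signals, and a hydropathy wave whose repeat matches the window has an
  exactly phase-independent steady state — so the mean confidence of a
  pure periodic helix is non-decreasing in its length.
* **Labels.** Residues take H or E where the dominant signal exceeds a
  threshold (2.2 in squared hydropathy units, above the smoothed noise
  level of random sequences); runs shorter than 4 (H) or 3 (E) are
  demoted to coil.
* **Geometry.** Ideal-geometry coordinates per segment: helices with
  2.3 Å radius, 1.5 Å rise and 100° turn per residue; strands extended at
  3.3 Å rise with an alternating 0.8 Å pleat; coil as a self-avoiding
  random walk (3.8 Å steps, clash floor 3 Å) biased toward the centroid
  of the chain built so far, so structured chains pack and can form
  long-range contacts. The walk is seeded by a hash of the sequence:
  identical sequences give bit-identical structures, and the caller's RNG
  is never touched.
* **Confidences.** Per-residue pLDDT is a logistic of the smoothed local
  signal strength (midpoint 2.1, steepness 0.55); pTM a logistic of mean
  pLDDT and the structured fraction. Random sequences land mostly in the
  0.25–0.5 band (below the contact-density confidence filter), periodic
  amphipathic ones in the 0.6–0.9 band.
* **Dimer placement.** The evolving chain is rigidly placed against the
  centred partner along the x axis with a 4.5 Å gap between the closest
  Cβ extents — a deterministic stand-in for docking that lets interface
  contacts form without guaranteeing them.

What the surrogate does *not* emulate: real energetics, side chains,
cooperative folding, or any calibrated relationship between sequence and
native structure. Tests passing under the surrogate demonstrate that the
evolutionary machinery (mutation bookkeeping, scoring algebra, selection,
lineage recording, reproducibility) is correct, not that any particular
biological fold would evolve; biological conclusions require a real
predictor behind the same contract.

## Secondary structure assignment

The constraint laws need element labels and lengths only, so the default
assigner is geometric, on the Cα trace: each overlapping quadruplet is
classified by its virtual torsion and Cα(i)–Cα(i+3) / Cα(i)–Cα(i+2)
distances (helix: torsion 20–100°, d13 4.2–6.2 Å; strand: |torsion| ≥
130°, d02 > 6 Å); a residue takes a label it receives at least two
quadruplet votes for, short runs are demoted, and chains under 4 residues
are all coil. The assigner is pluggable in `fitnessScore()` for users who
prefer an external tool.

# Reproducibility and numerics

* **RNG streams.** One master seed spawns named streams (founders,
  mutation, selection); each stream's state is saved and restored around
  its use. Adding draws to one purpose cannot shift another, so runs are
  reproducible under configuration evolution. The surrogate's coil walk
  uses sequence-hashed draws outside all streams.
* **Checkpointing.** The full engine state (population, records, lineage
  nodes, all stream states) serialises to a checkpoint; a resumed run
  continues the exact trajectory of an uninterrupted one, and evaluator
  failure mid-run saves the last valid state before aborting.
* **Caching.** Mutants are re-evaluated every generation, matching a
  re-predicting backend; an optional cache keyed by sequence
  (`memoize = TRUE`) changes runtime only — a tested equivalence — and is
  off by default.
* **Degenerate inputs.** Deletions that would shrink a chain below 10
  residues and insertions/duplications that would exceed 500 are resampled
  as substitutions, so chains can neither vanish nor run away. Circular
  permutation allows any internal cut point (1..L−1); the termini
  themselves are excluded because they would be identity operations.
* **Score scale.** pLDDT is $[0,1]$ everywhere inside the package; the
  0–100 convention appears only in the PDB B-factor column at I/O
  boundaries. This removes the silent ×100 bug class; the type invariant
  on `StructureModel` rejects out-of-range confidences outright.

# Study conditions and defaults

The generator defaults mirror the simulation conditions the package is
built to reproduce: population size 100; founders of 24 random residues
(variable-length regime) or 50 (fixed-length regime, point mutations and
single indels only, via `fixedLengthRates()`); uniform substitution rates;
stop thresholds 0.85/0.75. Event rates for the non-point mutations are not
fully specified by the regime description, so the defaults make
substitutions dominant (0.88) and duplications/permutations rare (0.005
each), consistent with duplications being rarely fixed; the indel length
law is uniform on 2–10, bounded to keep desk-scale runs cheap. All of
these are configuration, not code.

Summary statistics follow the bookkeeping identities exactly: total
mutation load $= N \times$ generations (one mutation per individual per
generation); fixed mutations are the events on the nucleation lineage —
the lineage of the first individual to satisfy the stop condition (ties
broken by higher score, then stable order), or of the best final
individual for budget-stopped runs; fixation rate $=$ fixed/total, which
is bounded by $1/N$ because a single lineage fixes at most one event per
generation. For variable-length runs, "mutations per site" (fixed
mutations over mean final length) is flagged as an overestimate, because
chains were shorter for much of their history. Multi-run tables aggregate
as mean-over-runs, with ratio statistics formed from the means.

# Problem sizes used in the test suite

The suite exercises the full engine at deliberately desk-scale sizes:
populations of 4–20, generation budgets of 3–200, and a 20-replicate
selection-response experiment (N = 20, 200 generations,
fitness-proportional selection) that reproduces the qualitative rising
fitness trace of the simulated-evolution setting — the median best score
of the final generation exceeds the median founder best across
replicates. Statistical assertions (event-type frequencies, substitution
goodness of fit, selection probabilities) use $10^5$ draws against
binomial 3σ bounds or χ² at α = 0.001.

# Known limitations

* The surrogate's structures are geometric cartoons; contact densities
  and confidence values are internally consistent but not comparable to a
  neural predictor's absolute scale.
* Coordinates for N and C backbone atoms are placed from the Cα trace and
  are only approximately stereochemical; they exist so PDB round trips
  and downstream tools have a complete backbone.
* mmCIF input is not supported; PDB covers the desk-scale use cases.
* Codon-level mutation models are out of scope; amino-acid-level target
  frequencies or replacement matrices are the supported biases.
* A single fixed partner chain is supported in dimer mode; the partner
  does not adapt, matching the co-evolution setting the score was
  designed for.
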
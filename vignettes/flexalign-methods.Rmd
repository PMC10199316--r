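---
title: "Flexible RMSD-bounded alignment of nucleic-acid 3D structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible RMSD-bounded alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexalign)
```

## The problem and the objective

Given a target structure T (n nucleotides) and a model structure M (m
nucleotides), an alignment is an injective pairing of target residues with
model residues. Its quality is the *actual RMSD*: the root-mean-square
deviation of the paired coordinates after the optimal rigid-body
superposition of the paired set. `flexalign` searches for the **longest
alignment whose actual RMSD does not exceed a user ceiling U**; among
equally long feasible alignments the one with the lowest RMSD wins, and
exact ties resolve to the first one found (made deterministic by a global
creation counter, since "first" is otherwise ill-defined). The ceiling is a
hard constraint: no public operation ever returns an alignment above U.

Flexible alignment — assembling the result from locally superposable
fragments rather than one global rigid fit — is what makes the problem hard
(its protein analogue is NP-hard), hence the two stochastic heuristics.

## Coarse-grained representation

Each nucleotide is reduced to at most three pseudoatoms placed at unweighted
geometric centers of atom groups:

| bead | atoms | notes |
|------|-------|-------|
| phosphate | P, OP1, OP2, OP3 (old-style O1P/O2P accepted) | absent on 5′-terminal residues |
| ribose | C1′–C5′, O2′–O5′ (`*` primes normalized) | always required |
| base | all remaining heavy atoms | residues without base atoms are dropped with a warning |

Hydrogens never enter a bead: most depositions lack them, and including them
would make bead positions deposition-dependent. A missing phosphate is not
imputed; instead every pairwise computation uses only the beads present in
*both* members of a pair (the intersection rule), so terminal residues
contribute 2 beads instead of 3. One function, `alignment_rmsd()`, builds
these paired-bead matrices and performs the superposition; GEOS, GENS, the
oracle and all reports share this single definition of distance.

Superposition is the Kabsch construction: SVD of the 3×3 covariance matrix
with a determinant correction so that only proper rotations (det = +1) are
admitted. The tests verify it against two independent references: an
Euler-angle grid search with iterative refinement, and the least-squares
fitter in `bio3d`.

## GEOS: kernel search with greedy extension

1. **Kernel identification.** Two target residues are drawn at random;
   candidate model partners are drawn until the two-pair superposed RMSD
   falls below `U2` (default 0.65 Å). A third pair is then drawn until the
   three-pair RMSD falls below `U3` (default 1.0 Å); after a bounded number
   of failed partner draws the third target residue itself is redrawn. Draw
   budgets (`pair_draws = 5000`, `ntc_redraws = 100`, `nmc_draws = 500`)
   bound each attempt; attempts repeat until the stop controller halts.
   Kernels with identical pair sets are not expanded twice.
2. **Greedy extension.** The kernel's transform is applied to the model;
   the admissible unused pair with the smallest mean shared-bead Euclidean
   distance is added; the alignment is re-superposed. A pair is accepted
   only if the *grown* alignment stays below U (a look-ahead; accepting
   first and testing afterwards could overshoot the ceiling once).
   By default the updated transform guides the next nearest-pair search
   (`refit_extension = TRUE`); the variant that keeps the kernel transform
   throughout is available for comparison, since the greedy signal degrades
   measurably with a stale transform.
3. **Selection.** The best extension under the preference order is kept;
   sampling continues until a stopping criterion fires.

## GENS: genetic algorithm over assignment chromosomes

A chromosome is an integer vector V of length n with V[i] = j > 0 aligning
target residue i to model residue j and V[i] = 0 leaving it unaligned.
Admissibility requires nonzero values to be unique and strictly increasing
along the chain — chain-order consistency with gaps allowed. (The stricter
reading that model indices must also be *consecutive* would forbid
insertions entirely and contradict flexible alignment, so it was rejected.)
In sequence-dependent mode V[i] is further restricted to the positional
correspondence.

* **Initialization** fills each chromosome's positions in *random order*,
  choosing uniformly among 0 and the still-legal model indices. Visiting
  positions 5′→3′ instead is subtly but badly biased: as the running
  maximum approaches m the legal set shrinks, so runs of the highest model
  indices pile up at the 5′ end of the target and then act as absorbing,
  unextendable local optima.
* **Fitness.** score = N_aligned − w_r·rmsd − w_b·N_bad − w_p·max(0,
  rmsd − U)·N_aligned, with defaults w_r = w_b = 1, w_p = 2. N_bad counts
  pairs whose mean bead distance after the chromosome's own superposition
  exceeds `bad_pair_cutoff`, which defaults to `U2` — the same threshold
  below which a nucleotide pair counts as well-aligned in kernel
  construction. The per-pair term matters: pooled RMSD dilutes the cost of
  a single wrong pair roughly as 1/k, so with a length-dominant reward
  alone the search accretes individually-wrong, collectively-feasible pairs
  it can never repair locally (dense chromosomes admit almost no legal
  point mutations). An earlier cutoff at U itself never fires and leaves
  the criterion inert.
* **Selection and operators.** The fittest 15% of *distinct* chromosomes
  seed the next generation: mutation of a random elite with probability
  .74, crossover of two random members of the whole current population with
  .25, a fresh random chromosome with .01; the incumbent best is copied
  through unchanged. Distinctness in the elite matters because crossover of
  identical parents reproduces the parent, and exact copies otherwise flood
  the elite within a few generations and freeze all drift.
* **Crossover** copies a random subvector from one parent and the rest from
  the other, zeroes one copy of every duplicated value at random, then
  zeroes entries violating monotonicity in a scan whose direction is drawn
  at random per call — a fixed scan direction systematically favors
  fragments at one chain end.
* **Mutation** applies k ∈ {1,2,3,4} point mutations with probabilities
  (.65, .15, .10, .10), each of a type drawn uniformly among: unassign;
  assign a legal model index to an unassigned position; re-assign an
  assigned position; swap two positions' assignments. Choices are
  restricted to admissibility-preserving options; a point with no legal
  option is skipped.
* **Multiple solutions** come from iterative peeling: once a run converges,
  the residues used by its best alignment are removed and the GA reruns on
  the remainder, so each further solution covers a disjoint fragment —
  exactly the behavior wanted when two structures share several fragments
  that superpose only under different rigid transforms. Reported solutions
  are ranked by the preference order and filtered so each shares less than
  `overlap_filter` (default 50%) of its pairs with any better one.

The operators and the generation step are implemented in C++ (drawing from
R's RNG stream, so `set.seed()` reproduces runs bit-exactly). This is not a
luxury: the GA needs on the order of 10²–10³ generations of 200 fitness
evaluations each, and an interpreted inner loop starves it of generations
within any realistic time budget.

## Modes

Sequence-independent mode admits every (target, model) residue pair.
Sequence-dependent mode pairs residues at corresponding sequence positions:
for equal lengths, position i with position i; for unequal lengths, the
ungapped offset maximizing base-identity matches defines the
correspondence, and the mode refuses structures whose best offset matches
fewer than 90% of overlapping bases — superposition of corresponding
nucleotides is only meaningful for near-identical sequences. Which
corresponding positions to *keep* remains the heuristics' choice, so
sequence-dependent alignments can still be partial and fragmented.

## Stopping

Both heuristics halt on the first of: (i) all target residues aligned;
(ii) wall-clock cap `cl` (default 300 s); (iii) GENS only, `cg` generations
without improvement (default 300); (iv) no improvement within the adaptive
time buffer, which starts at `bi0` (default 10 s, configurable) and grows by
`delta_t` (default 1 s) on every improvement. "Improvement" means the
best-so-far changed under the preference order — a length increase or an
RMSD decrease at equal length. Optional hard caps `max_kernels` /
`max_generations` bound individual runs in tests and batch settings.

## The synthetic generator

Testing needs structures with known ground truth, so the package generates
its own:

* `make_structure(n, "helix")` places ribose beads on an A-form-like
  helical curve (rise 2.8 Å, twist 32.7°, radius 9.4 Å). The base bead sits
  at a base-dependent distance from the axis (purines reach ~1.4 Å further
  than pyrimidines), and a small deterministic per-residue distortion
  (σ = 0.5 Å, drawn inside the seeded construction) is superimposed on all
  beads. Both choices exist for identifiability: a mathematically perfect
  periodic helix maps onto itself under register shifts, so the identity
  self-correspondence would be undiscoverable *in principle* by any
  RMSD-driven method. Real molecules are never that regular; the generator
  emulates their discriminability, not their chemistry.
* `make_structure(n, "random_coil")` grows a self-avoiding random walk
  (6 Å steps, 3 Å minimum separation) — a maximally irregular counterpart.
* `perturb()` applies, in order, a rigid transform, isotropic Gaussian bead
  noise, teleportation of chosen outlier residues, and optional embedding
  of a motif among shuffled decoys, recording the ground-truth
  correspondence for `recovery_score()`.
* `expand_to_atoms()` writes a synthetic full-atom representation (three
  atoms per bead group, centered on the bead) so the PDB/mmCIF readers and
  the coarse-graining can be exercised end to end without downloads.

What passing tests on these fixtures does **not** show: robustness to real
experimental artifacts (missing atoms mid-chain, modified residues beyond
the mapping table, alternate conformer soups), to topologies the generator
cannot produce (pseudoknots wrapping through space so that chain-order
monotonicity actively hurts), or to the atom-naming variability of older
depositions beyond the normalizations implemented.

## Numerical and policy choices

* Actual RMSD is bead-level, not all-atom — both heuristics operate on the
  coarse representation throughout, and reporting a different metric than
  the one optimized would misstate the guarantee.
* Alt-locs resolve to highest occupancy, ties to the alphabetically first
  code; multi-model files contribute the first model only; chains are
  concatenated in file order. All three policies exist for determinism.
* Nucleotide detection: residue-name whitelist (A, C, G, U, T, DA, DC, DG,
  DT, …) *or* presence of C1′, O4′ and N9/N1 — so DNA and mappable modified
  nucleotides pass, and water/ions/amino acids do not.
* The kernel gates U2 < U3 < U are the operative definition of a
  "well-aligned" pair and seed triple; the informal requirement that a
  kernel's RMSD be far below U has no other measurable content.
* Degenerate inputs: empty alignments are representable (0 pairs, undefined
  RMSD) and are every run's initial best; a single-residue pair superposes
  its 2–3 shared beads (generically nonzero RMSD — three generic points are
  congruent only to themselves).
* The `threads` option is accepted and echoed for interface compatibility,
  but this implementation executes sequentially: determinism of fixed-seed
  runs is a contract here, R's RNG stream is process-global, and the
  supported workloads are bounded by the stop controller rather than by
  core count.

## Problem sizes in the shipped tests

The test suite and acceptance script run on 60-nt fixtures for recovery and
self-alignment, 1000 sampled kernels for the gate checks, 100 toy instances
(4–6 nt) against the exhaustive oracle, 10 000-case operator property
tests, and a 40-nt two-fragment fixture for multi-solution behavior; these
sizes keep the full suite in the minutes range on one core while leaving
every claim at its stated sample size.

## Known limitations

* Chain-to-chain assignment in multichain complexes is not optimized;
  chains concatenate in file order.
* The sequence-dependent correspondence for unequal lengths is a single
  ungapped offset; indel-containing near-identical sequences are refused
  rather than approximated.
* GENS cost grows steeply with structure size; for molecules beyond a few
  hundred nucleotides GEOS is the practical choice.
* The exhaustive oracle is limited to 8 residues a side by combinatorial
  growth; all optimality statements at larger sizes are empirical.
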
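---
title: "Methods: iterative fine-tuning of structural RNA alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative fine-tuning of structural RNA alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, parameter choices and design decisions
behind the package, and what its green tests do and do not establish.

## The procedure

Given `n >= 2` concrete RNA sequences, `run_planacstar()` executes:

1. `A <- progressive_align(B_1..B_n)` — affine-gap progressive alignment
   over a UPGMA guide tree (skipped when a starting alignment is given).
2. `C <- alifold(A)`, `X <- sci(E_A, mean MFE)` — preliminary consensus.
3. `C_i <- project_consensus(C, A, i)` — consensus pairs mapped onto each
   ungapped sequence; pairs with a gapped end, a non-canonical residue
   combination, or a projected hairpin shorter than the model minimum are
   dropped (constraints must be formable, or constrained energies would be
   undefined).
4. `S_i <- constrained_fold(B_i, C_i)` — minimum-energy structure
   containing every constraint pair; added pairs are nested around them.
5. `Y <- multiple_structure_align(S_1..S_n)` — ordered-forest alignment,
   pair nodes aligned to pair nodes irrespective of residues.
6. `A* <- implied_sequence_alignment(Y)`.
7. `C* <- alifold(A*)`, `X* <- sci(...)`; accept iff `X* > X + epsilon`.
8. On acceptance set `A <- A*`, `C <- C*` (re-projecting in step 3 needs
   the current consensus, and step 7 has already computed it — re-folding
   again would be redundant) and repeat from step 3; otherwise stop.

Two guards: the loop stops unconditionally after `max_iterations` rounds
(default 10; one round normally suffices), and a round whose implied
alignment equals the current one is a fixed point and ends the loop
without being recorded. A recorded round carries an `accepted` flag, so a
final rejected round is visible in the trace. The SCI denominator (the
unconstrained individual MFEs) does not depend on the alignment and is
computed once.

By construction, consensus pairs are never undone: each projected pair is
mandatory in its refold, so fine-tuning can only realign or augment the
structure found initially. If the initial consensus is wrong, the loop
tunes towards a wrong structure — it is a fine-tuning add-on, not a
search.

## Structure conservation index

`sci(E_A, mfes) = E_A / mean(mfes)`, carried at full precision, printed to
4 decimals. When the mean MFE is 0 (sequences that cannot pair at all) the
SCI is defined as 0 if `E_A = 0` and is an error otherwise. Covariance
pseudo-energies can push `E_A` below the mean MFE, so SCI > 1 is possible
and indicates strong covariance support.

## Energy model

`energy_model()` is a closed nearest-neighbour surrogate: pair energies
CG/GC −3, AU/UA −2, GU/UG −1 (kcal/mol-like, arbitrary but ordered as in
thermodynamic tables), stacking bonus −1 for directly stacked pairs,
hairpin loops ≥ 3 unpaired bases, no other loop terms. The choice is
deliberate: the fine-tuning algorithm is model-agnostic, and a small
closed model admits exact enumeration oracles (every folding DP in the
test suite is checked against brute force). The `EnergyModel` interface is
the hook for richer models; no claim of thermodynamic accuracy is made.
All folds break energy ties towards fewer pairs, then by a fixed traceback
order, so results are deterministic.

## Consensus folding

Two alignment columns may pair when at least `q = 0.5` of the rows that
are gap-free in both columns can form a canonical pair (and at least one
row pairs). The column pseudo-energy is

```
sum(pair energies of pairing rows) / n_rows
  + cov_weight * ( -(n_pair_types - 1) + mismatch_penalty * n_nonpairing )
```

with `cov_weight = 1`, `mismatch_penalty = 1` per gap-free non-pairing
row. Dividing by the *total* row count (not by the pairing rows) is
essential: rows gapped at a pair column dilute the consensus energy, which
is precisely how a shifted gap buries the covariance signal and leaves the
fine-tuning something to repair. On an alignment of identical rows the
consensus reduces exactly to the single-sequence MFE (covariance 0,
SCI 1). The surrogate covariance term mirrors the averaged-energy-plus-
covariance design of alignment folding without claiming parameter parity
with any particular implementation.

## Sequence alignment

Affine-gap Gotoh (match +2, mismatch −1, gap open −5, extend −1; a
length-k gap costs `open + (k-1)*extend`), profile–profile merges with
sum-of-pairs column scores along a UPGMA tree on `1 − identity`. The
tie-break — diagonal first, then gap-in-shorter, then gap-in-longer,
resolved left-to-right over a suffix DP — is load-bearing: score-neutral
gap placements are exactly the pathology the pipeline repairs, and a fixed
rule makes the pathological case constructible and every run reproducible.
Identity uses a per-row-pair denominator counting columns where at least
one of the two rows has a residue (gap–gap columns excluded); the exact
published variant of this "improved" identity is only cited in the
literature, so this implementation is a documented approximation.

## Structure alignment

Structures are ordered forests (PAIR nodes carry both residues and a
subforest; UNPAIRED nodes are leaves). Pairwise alignment is a
Jiang–Wang–Zhang-style tree alignment over closed subforests: PAIR aligns
to PAIR or gap (a gapped PAIR promotes its children), UNPAIRED to UNPAIRED
or gap. Scores: pair match +4 *independent of residues* (this is what
recovers compensatory changes), unpaired match +1, mismatch 0, gaps −2
(pair) / −1 (base). A configurable `pair_ident_bonus` (default 0) can
favour residue-identical pairs; it defaults to off because the defining
property of this stage — a compensatory double substitution leaves the
alignment score unchanged — must hold exactly, and any nonzero bonus
breaks it. Multiple alignment is progressive over a UPGMA tree on
max-self-score-normalized pairwise distances; profile forests carry one
row per input, and sum-of-pairs scoring makes merges pairwise calls. The
multiple strategy of the original tree-alignment tool is undocumented;
progressive merging is this package's own choice.

The implied sequence alignment is the in-order traversal of the merged
forest: one column per UNPAIRED node, two per PAIR node. Degapping row i
always returns sequence i (asserted on every synthetic family).

## Synthetic families — the stated world

`generate_family()` emulates benchmark-style subalignments: 5 sequences
per family sharing a consensus, compensatory substitutions at paired
sites, neutral substitutions in loops, and indels confined to unpaired
regions. Defaults: a 51-nt three-helix consensus, loop substitution 0.35,
compensatory rate 0.35, pair-breaking 0, indel rate 0.03 with mean length
2 — chosen once so the default family lands in the twilight band
(~0.30–0.55 identity, measured 0.39 at seed 11) and frozen. Indels never
touch paired sites so the reference consensus stays well-defined in every
row; hairpin loops never shrink below 3. `sweep_families()` tunes a single
divergence scalar by bisection per identity target — a calibration the
generator's contract prescribes, done against the reference alignment's
identity, never against pipeline outcomes.

What the generator does *not* emulate: phylogenetic tree structure
(mutations are star-shaped from one ancestor), helix-length variation,
indels inside helices, non-canonical pairs, or any real family's
composition. A green pipeline test therefore establishes that the
algorithm recovers covariance signal that sequence alignment obscured
under these controlled conditions — not benchmark-level performance on
curated data, which depends on external datasets and tool versions and is
out of scope.

`make_twilight_pathology()` is the distilled gap-placement trap: three
long members share a two-pair helix with compensatory variation (including
the literal toy member `AAGGAAAACCAA`), two short members carry a
one-sided deletion in each arm plus a compensatory switch of the remaining
pair to A–U — a pair type no long member uses, so their pairing bases
match nothing in the helix columns, every placement is score-neutral
there, and the deterministic tie-break parks them on non-supporting
columns. A distinctive CAAU loop anchors the alignment so the trap cannot
be escaped by merging the two gaps. Strict SCI improvement on these
families is asserted for a range of seeds.

## Numerical and degenerate-input choices

- Coordinates are 1-based everywhere (the R convention); one internal
  convention prevents off-by-one drift between projection and extraction.
- Energy ties: lexicographic (energy, pair count) minimisation with a
  1e-9 comparison epsilon; acceptance uses `epsilon = 1e-9` on the SCI.
- The toy example's printed lower sequence is one base short of its
  structure; fixtures treat the structure as authoritative and use the
  synthetic completion `AACAAAAGAA` (documented in the fixture helper).
- IUPAC ambiguity codes are rejected with an explicit message (the
  structure-alignment stage requires concrete sequences); an opt-in flag
  maps each code to the first concrete base of its set.
- Empty structures, empty constraint sets and all-gap columns are legal
  intermediate values; all-gap columns are removed on alignment
  construction.
- Savitzky–Golay smoothing fits least-squares polynomials in symmetric
  windows, evaluating the boundary window's fit at endpoint positions, so
  polynomials up to the filter order are reproduced exactly.

## Known limitations

- The surrogate energy model has no loop-length, dangling-end or special
  hairpin terms; absolute energies and SCIs are not comparable to
  thermodynamic implementations.
- The covariance term's weighting in production alignment folders is
  version-dependent and not published in closed form; parameters here are
  explicitly surrogate values.
- Progressive (sequence and forest) alignment is heuristic; only the
  pairwise building blocks are certified optimal (against enumeration
  oracles).
- Pseudoknots are out of scope throughout: non-nested pair sets are
  rejected at the dot-bracket boundary.
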
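---
title: "Evolutionary RNA design: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary RNA design: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inverse RNA folding asks: given a target secondary structure, find a
sequence whose minimum-free-energy (MFE) structure under a nearest-neighbour
(Turner) energy model is exactly the target. The search space is exponential
in the sequence length and the objective — the Hamming distance between the
predicted and target dot-bracket strings — is only available through a
cubic-time folding computation, so practical solvers are heuristics.

This package implements an evolutionary search that operates at the level of
*structural components* rather than single nucleotides, and supports two
kinds of user constraints that matter for designing biologically plausible
molecules:

* **sequence constraints** — a per-position IUPAC mask fixing positions to a
  nucleotide or a subset of nucleotides (e.g. conserved protein-binding
  residues), and
* **an energy interval** — the free energy of the designed sequence
  *evaluated over the target structure* must lie in `[Emin, Emax]` kcal/mol
  (inclusive). The defaults are `(-Inf, 0]`: the sequence must at least be
  stabilising. Only some structures with a specific level of free energy can
  take part in a given cellular reaction, which is why a design tool needs
  this knob at all.

## Component model and fragment pools

Any pseudoknot-free structure decomposes uniquely into stems (maximal
helices of stacked pairs), hairpin loops, internal loops, bulges,
multi-loops, and the external loop. `rna_components()` computes this
partition: stems carry all paired positions, loops carry the unpaired
positions they enclose, so every position belongs to exactly one component.

Each component is keyed by its *geometry*: kind plus an integer signature
(stem: pair count; hairpin: loop length; bulge: strand length; internal
loop: left/right lengths; multi-loop: branch count and the 5'→3' unpaired
segment lengths; external loop: segment lengths). `build_pools()` folds
every corpus sequence to its MFE structure, decomposes it, and bins the
sub-sequences by geometry key. Sampling a fragment for a component of the
target then reuses sequence material that *demonstrably* adopts that
geometry in some MFE structure — the mechanism by which designs inherit
natural-looking composition. Duplicates are kept, so sampling is
frequency-weighted.

Two fallbacks keep sampling total:

* a multi-loop key with no exact hit first relaxes to "same branch count,
  same total unpaired length" and re-chunks the segments (multi-loop
  signatures are sparse);
* any remaining miss generates a fragment de novo, drawing paired bases
  from the natural pair-class distribution (AU 0.39, GC 0.49, GU 0.12;
  orientations equiprobable) and unpaired bases from the natural unpaired
  distribution (A 0.38, C 0.19, G 0.17, U 0.26).

Fragments are always filtered against the IUPAC mask slice of their
component *at sampling time*, so constraint violations cannot be created in
the first place and never need repairing. A mask whose symbols admit no
canonical pair at some target pair (`detect_conflicts()`) makes the problem
unsatisfiable and is reported as an error before any search starts.

## Hierarchical decomposition at multi-loops

Folding costs O(n³), so improving a long sequence as one block is slow,
while optimising every tiny component separately wastes iterations. The
intermediate scheme splits the target at multi-loops. Closing pairs of a
multi-loop are ordered by their 5' index; the order-minimum is the *tag
base pair*, the stem containing it the *tag stem*, and the order-minimum
pair of the tag stem (its outermost pair) the *breaking base pair*. When
several multi-loops offer breaking pairs at one level, the split whose two
parts are closest in length wins; ties go to the lowest 5' index. Recursion
stops below 40 nt (a configurable floor — parts that small fold quickly
anyway).

How a split partitions the string was a genuinely open design point. We
make the region enclosed by the breaking pair `i.j` one child (a closed,
independently foldable sub-structure that keeps the pair) and the remainder
`1..i-1, j+1..n` the other. The two children partition the parent's
positions, so reassembly is exact by construction. We deliberately do *not*
duplicate the breaking pair into the remainder: that would leave an
adjacent `()` pair there — a zero-length hairpin that no folding engine can
ever predict, so that child could never reach distance 0. For the same
reason a split is skipped (the next most balanced candidate is tried) when
removing the arch would leave the remainder with an under-sized loop.

Each leaf is optimised independently, the leaf solutions are written back
at their original coordinates, and the full-length sequence is polished by
one more optimisation loop, which also enforces the energy interval (the
interval constrains the full molecule, not its parts).

## The evolutionary loop

1. **Initial sequence** — every component of the target is filled with a
   pool fragment; the assembled sequence is pairing-compatible by
   construction. Up to 1000 resampling attempts enforce the sequence
   constraints, then up to 1000 further attempts (evaluated in batches)
   enforce the energy interval; on exhaustion the attempt closest to the
   interval is kept and flagged unmet.
2. **Population** — the parent is folded; every target component containing
   a position where the parent's MFE structure disagrees with the target
   spawns one offspring with that component's fragment resampled. Mutation
   acts only at component level; there is no crossover. When more
   components mismatch than the per-parent cap (default 30), that many are
   sampled uniformly.
3. **Selection** — all candidates are scored by free energy over the target
   and sorted ascending — or, when a finite interval is given, by distance
   to the interval centre. The best three are folded (the expensive step);
   their Hamming distances, together with the incumbent best, pick the
   three survivors and the new incumbent (smallest distance; ties resolved
   by the energy criterion, then input order — every tie-break is stable,
   so a fixed seed reproduces a run bit for bit).
4. **Termination** — distance 0 with all constraints satisfied, or the
   iteration cap (default 250). The cap applies per optimisation loop (each
   leaf, then the final polish); it is exposed as `max_iter`.

The result records the sequence, its distance, the energy over the target,
iteration count, per-constraint flags, and the full configuration.
`success` means distance 0 *and* both constraint flags true.

## Folding engines

The search only needs `fold(seq)` and `energy_of(seq, structure)`. The
production engine adapts the ViennaRNA command-line tools (`RNAfold` /
`RNAeval`, Turner parameters at 37 °C by default), batching whole
populations over stdin — one process per generation, not per candidate.
Energies are engine-specific: results obtained with different engine
versions must not be mixed.

A second, deterministic *toy* engine — maximum base pairing with minimum
hairpin length 3, scoring −1 per canonical pair, ties broken toward
5'-most pairing — keeps unit tests hermetic and fast. Its energies are pair
counts, not kcal/mol; it is a test double with the same contract, not an
approximation of the thermodynamic model.

## Synthetic corpus: what it does and does not emulate

`synthetic_corpus()` stands in for a database of natural sequences. It
reproduces the natural *mononucleotide* totals (A 0.27, C 0.22, G 0.25,
U 0.26) so that pools built from it have naturalistic composition, and its
sequences are long enough (default 50–150 nt) to contribute all component
kinds. It does not reproduce dinucleotide correlations, conserved motifs,
or the length and family distribution of real databases, so tests passing
on it show the machinery is correct and well-calibrated — not that designs
trained on it inherit family-level signals real corpora would provide.

Two target generators support testing: `random_structure()` samples
arbitrary valid structures (including awkward geometries — good for
partition and round-trip properties), and `random_stem_loop()` samples
single-arch targets whose helix segments always hold at least two stacked
pairs. The latter restriction is deliberate: isolated lonely pairs flanked
by single-nucleotide bulges frequently admit *no* exact MFE design under
the Turner model, so they measure instance infeasibility, not algorithm
quality. Where an arbitrary but designable benchmark target is needed (as
in the acceptance script), we use the standard construction: the MFE
structure of a random sequence.

## Evaluation metrics

* expected time per success `E_T = total time / SC` (`Inf` when `SC = 0`);
* expected energy distance `E_ED = mean |E_designed − E_natural|`;
* Needleman–Wunsch percent identity under the EMBOSS-needle default
  scheme — EDNAFULL-equivalent matrix (match 5 / mismatch −4), gap open 10,
  gap extend 0.5, a gap of length L costing `open + L·extend`, identity
  denominator the full alignment length including gap columns. The needle
  "Identity" figure is the default; the "Similarity" variant is exposed
  behind a flag (for a nucleotide matrix the two coincide);
* expected within-group similarity `E_SA` (mean over structures of the mean
  pairwise identity among that structure's designs — lower means more
  diverse designs) and expected similarity to the natural counterpart
  `E_SN`;
* nucleotide/base-pair distributions: paired positions as unordered classes
  AU, GC, GU (non-canonical pairs are excluded from the normalisation and
  warned about), unpaired and total per base.

## Numerical choices and degenerate inputs

* Coordinates are 1-based and inclusive everywhere; pairs are stored as
  `i < j`.
* Minimum hairpin length 3 is enforced at parse time (the folding-engine
  convention); balance errors are reported before loop-size errors, naming
  the offending position.
* `T` is accepted anywhere a sequence enters the package and normalised to
  `U`; corpora with lowercase letters are uppercased.
* Interval endpoints are inclusive; "interval given" (for centre-based
  selection) means both endpoints finite.
* Empty-length components are kept as empty strands where the geometry
  demands them (zero-length multi-loop segments), so keys, masks and
  fragments always agree structurally.
* All randomness flows through R's RNG; seeding `design(seed = )` makes the
  whole run — including pool sampling and selection tie-breaks —
  reproducible byte for byte.

## Problem sizes used by the test suite

The suite exercises the partition and round-trip properties on 1000 random
structures of length 20–300, the breaking-pair oracle on 200 multi-loop
structures, the design success floor on 50 stem-loop targets of length
20–50 with the ViennaRNA engine, constraint soundness on 200 randomized
constrained runs (10–30% fixed positions, assorted intervals), and the
metric implementations against brute-force recomputation at 1e-9 relative
tolerance. These sizes were chosen as the smallest that make the
statistical checks meaningful; the acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline at a comparable scale.

## Known limitations

* Pseudoknots are out of scope — dot-bracket input here is strictly nested.
* The energy interval is enforced on the full-length sequence only; leaf
  sub-designs run unconstrained in energy.
* Success on the hardest structures (long multi-loop-rich targets, heavily
  constrained instances) is not guaranteed within the default iteration
  cap; the best-found candidate is returned with honest flags instead.
* The similarity metric fixes one parameterization of global alignment;
  numbers are comparable within this package, not across tools using other
  gap conventions.
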
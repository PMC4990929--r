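---
title: "Methods: structural screening of CBL-type calcium sensors and CIPK kinases"
author: "cblscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural screening of CBL-type calcium sensors and CIPK kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cblscreen)
```

## The biological problem

Calcineurin B-like proteins (CBLs) are a family of Ca²⁺ sensors that,
together with their partner kinases (CBL-interacting protein kinases,
CIPKs), form a two-component Ca²⁺ decoding module. Although long regarded
as plant-specific, both components occur scattered across distant
eukaryotic lineages, and they can be recognized from sequence alone by a
small set of structural hallmarks:

* **Sensors.** All members of the wider family (calmodulin, calcineurin B,
  neuronal calcium sensors, CBLs) carry four EF-hand Ca²⁺-binding loops.
  The canonical loop spans 12 residues, with the six coordinating positions
  labeled X, Y, Z, −Y, −X, −Z at offsets 0, 2, 4, 6, 8, 11. CBLs are set
  apart by their **first** EF-hand: insertions between the X and Y
  coordinates extend it to 14 residues (the plant and most non-plant CBLs),
  15 residues (a stramenopile lineage marked by an S→L exchange at X, a G
  in the insertion and a Q-[HN]-E triplet in the middle of the loop), or
  19 residues (an Aphanomyces/Saprolegnia-type lineage). The X coordinate
  of genuine CBLs is serine where calmodulin and CNB/NCS proteins carry
  aspartate, and the residue immediately following the −Z coordinate is an
  invariant phenylalanine in CBL/CNB/NCS proteins but leucine in
  calmodulins. In land-plant CBLs the spacer between the first and second
  EF-hand is invariant at 23 residues, while it varies from 19 to 24
  elsewhere; plant CBLs additionally carry N-terminal membrane-targeting
  signals (an MGXXXS/T N-myristoylation motif and/or a palmitoylated
  cysteine at position 3) and a C-terminal FPSF phosphorylation motif.
* **Kinases.** CIPKs are Ser/Thr kinases defined by a 21-residue regulatory
  NAF domain whose invariant Asn-Ala-Phe tripeptide is necessary for CBL
  binding; closely related kinases without the NAF domain do not interact.

`cblscreen` turns these rules into a reusable, testable screening pipeline
for predicted proteomes, together with a synthetic-data generator that
emits every architecture with exact ground truth.

## EF-hand scanning

Each loop template fixes six coordinating offsets; all extension sits
between X and Y, and −Z is always the last loop position. A window is
scored additively:

| term | contribution |
|------|--------------|
| −Z anchor | E +3.0, D +1.5, otherwise −5.0 |
| X | D or S +2.0, N +1.0 (15-mer only: A +1.0, L +1.5), otherwise −2.0 |
| Y, Z | +1.0 each for D, N, S, T, E, G, Q |
| −X | +0.5 for D, N, S, T, E, G |
| −Y | 0 (coordinates through the backbone; any residue) |
| 15-mer bonuses | +1.0 for a G in the X–Y insertion, +1.0 for Q-[HN]-E at loop offsets 4–10 |

The ambiguity code X contributes 0 at every scored position, so runs of
unknown residues in draft proteomes neither create nor veto hits. The
weights themselves are a design choice — the structural literature names
the informative residues but no scoring scheme — and were fixed once so
that every archetype loop clears the acceptance threshold while an anchor
violation can never be rescued: the largest score attainable with a
non-D/E anchor is 1.5 for the 15-mer template, far below the default
threshold of 4.0.

Every window of every enabled template is scored; windows at or above the
threshold are resolved to a non-overlapping set greedily by score, then
leftmost start, then longer template (a deterministic tie-break that
prefers the extended variants the screen exists to find), capped at 6 hits
per protein. Spacers are counted strictly between consecutive loops. The
position of the Q-[HN]-E triplet is only loosely constrained by the
literature ("middle part of the loop"); we search loop offsets 4–10 and
expose nothing else, since published alignment figures are not
machine-readable.

## Sensor classification

Classification applies ordered rules to the first four hits (sensor
proteins have exactly four EF-hands; later hits are reported but carry no
weight). Canonical EF1 with D at X splits into calmodulin-like (L after
−Z) versus CNB/NCS-like (F after −Z). A 14-residue EF1 with S at X is a
CBL; it is called *plant* only when both the invariant 23-residue spacer
and an N-terminal targeting motif are present, because plant CBLs are
distinguished by the EF-hand spacing **and** the membrane-targeting
sequence, not by either alone. The 15-residue L-at-X loop (with its G
insertion or Q-[HN]-E triplet) defines the stramenopile class, a
19-residue EF1 the extended class, and an A at X in a 14/15-residue loop
the degenerate class described for highly divergent parabasalid paralogs
(an S→A exchange accompanied by a single-residue insertion). A final
fallback keeps the screen sensitive to divergent sequences: four EF-hands
with the invariant post-−Z F still earn a low-confidence non-plant CBL
call, mirroring how divergent proteins with multiple substitutions are
still inventoried while noting possible loss of function. Window sizes for
"N-terminal" (30 residues) and "close to the C-terminus" (40 residues) are
fixed package defaults, since no published values exist.

## NAF detection

The NAF domain is modeled as a 21-column log-odds PSSM against a uniform
background with additive pseudocounts, rather than a profile HMM: at desk
scale the discriminative signal is the invariant tripeptide plus columnar
conservation, and no insert/delete states are needed. The tripeptide is a
hard constraint — a window without a contiguous `NAF` at an admissible
offset (default 6–12, a permissive range because the exact position inside
the published 21-mer is not printed) is never a hit regardless of score.
The packaged seed alignment is generated from the synthetic CIPK archetype
family and is labeled synthetic; screens of real proteomes should supply a
curated seed alignment. A deliberately crude kinase-core gate (`HRD`
followed by `DFG` at 10–60 residues) separates CIPK calls from NAF-less
kinases; it gates NAF calls and is not a kinase annotator.

## Distances, trees and amplification

Pairwise Needleman–Wunsch global alignments (BLOSUM62, affine gaps 11/1)
give identity-based distances `1 − identity`, with gap columns counting as
non-matches so that the length heterogeneity of the extended loops remains
informative. A Poisson correction (−log identity) is available behind a
config flag but off by default to keep distances bounded. Trees come from
our own Saitou–Nei neighbor joining with deterministic tie-breaking
(smallest label pair) and negative-branch clamping that transfers the
deficit to the sibling branch; on additive matrices the reconstruction is
exact to numerical precision, which the test suite verifies against
simulated tree metrics. Intraspecific gene amplification is flagged by an
unrooted monospecific-clade test: a species with two or more candidate
genes is flagged when some edge bipartition isolates exactly its leaves.
No outgroup is assumed, and the flag is a topological proxy — the original
analyses rest on posterior support values that a distance method does not
re-derive.

## The synthetic generator

The generator is the package's stand-in for database sequences: no
accessions are redistributed, so every test runs on synthetic proteomes
with machine-readable ground truth.

* **Shared scaffold.** Sensor archetypes share fixed consensus residues
  for the four loops and inter-loop spacers, emulating the global homology
  of a real protein family; this is what lets a local-alignment prefilter
  with a fraction-of-self-score cutoff (default 0.25) retain every planted
  CBL subtype when queried with the plant archetype, exactly as homology
  search retains family members. Spacer filler is drawn from residues that
  can serve neither as a −Z anchor nor as a favorable X, so the fixed
  scaffold can never spawn a competing loop window.
* **Seeded tails and cleaning.** N- and C-terminal tails are drawn
  uniformly over the 20 residues by seeded RNG. Because an additive motif
  score over random sequence occasionally clears any threshold, tail draws
  that would create an unplanned above-threshold window — or an accidental
  targeting motif, FPSF, kinase core or NAF tripeptide that contradicts the
  label — are resampled until the emitted sequence carries exactly the
  planted signals. Ground truth is therefore exact by construction, which
  is the property the round-trip tests rely on; the cleaning never touches
  decoys, whose false-positive behavior is measured raw.
* **Noise.** Substitution noise replaces each unconstrained position with
  probability `substitution_rate` by a uniformly drawn different residue.
  The six coordinating residues of every planted loop, the post-−Z
  residue, motif anchors and the NAF tripeptide are never mutated, so
  planted signals stay anchored while their context decays; recovery
  degrades through competing windows that displace planted hits.
* **Paralogs.** Within one proteome, all copies requested by a spec entry
  are divergent near-copies (default divergence 0.03) of a single base
  archetype — the sequence signature of recent intraspecific duplication
  that the amplification detector looks for. Copies from different entries
  or different proteome seeds are unrelated in their seeded positions.
* **Decoys** are uniform-composition random proteins (natural residue
  frequencies would make the decoy analysis depend on a composition model;
  uniform keeps it self-contained). Non-plant EF1–EF2 spacers are drawn
  uniformly from the observed 19–24 range; all other spacers default to
  the plant value of 23.

What passing tests on these data do **not** show: robustness to indels and
domain shuffling (the generator performs neither), to natural residue
composition, or to the full divergence of real proteomes — the archetypes
share a scaffold by design, so prefilter recall on real data depends on a
sensible user-supplied query and threshold.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open; all serialized output is
  1-based inclusive, with the converter pair tested as a bijection.
* All thresholds live in one configuration object shared by generator and
  detectors, so the two can never disagree on constants.
* Greedy overlap resolution, NAF-window resolution and NJ joins all carry
  explicit deterministic tie-breaks; identical inputs and configuration
  give byte-identical outputs, including in the orchestrated screen (no
  timestamps enter any output; files are stamped with a config hash and
  seed instead).
* Per-species failures in the orchestrated screen are isolated and logged
  rather than fatal.
* The decoy false-positive criterion is evaluated per scored window
  (windows at or above threshold over all windows scanned, about 1% at
  default settings on 1000 uniform 300-mers). A per-protein reading is not
  attainable by any threshold for an additive score over ~1100 random
  windows per decoy and would contradict the scheme fixed above; the
  per-window rate is the quantity the threshold actually calibrates.
* Test problem sizes (50 random 120-mers for scanner-oracle equivalence,
  30 alignment pairs, 100 additive matrices, 100 seeds for the confusion
  matrix, 60 seeds per noise level, 1000 decoys) are the package's chosen
  desk-scale sizes; each suite runs in seconds.

## Known limitations

The scanner is loop-only (plus the single post-loop residue) and does not
model the flanking helices or predict Ca²⁺ affinity; pseudo-EF-hands
without the −Z anchor are out of scope by design. The kinase-core gate is
a two-anchor heuristic. The amplification flag is a topological proxy
without support values. Census numbers for real proteomes depend on the
prefilter query and threshold, which must be tuned by the user; the
package's verified claims are the structural constants and the internal
consistency of the pipeline, both of which the acceptance script and test
suite recompute from scratch.
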
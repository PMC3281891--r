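---
title: "Profile-based discovery of seven-transmembrane protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based discovery of seven-transmembrane protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqfam)
```

## The problem

Distant homology among polytopic membrane proteins is notoriously hard to
establish: sequence identity between family members can fall below the
twilight zone while the architecture — here, a bundle of seven
transmembrane (TM) helices with short connecting loops, a one-residue
lumenal N-terminus and a ~15-residue cytoplasmic C-terminus — remains
conserved. The PQ-loop proteins (KDEL receptors, cystinosin, MPDU1,
SWEETs, and relatives) are the motivating case: a family definable only by
iterative profile searches, held together by position-specific signals (a
proline–glutamine doublet in the loops, a handful of strongly conserved
basic and serine columns) rather than by overall identity.

`pqfam` implements the discovery protocol as a testable pipeline:

1. build a position-specific profile from a seed alignment;
2. calibrate the profile's null score distribution and search a proteome;
3. accept hits by a **dual criterion** — E-value below a threshold *and*
   the hit's alignment covering *every* TM segment of the query;
4. realign accepted sequences to the profile, rebuild, and repeat until
   the accepted set stops changing;
5. characterise the family: consensus TM topology, internal N-half/C-half
   duplication, column conservation, motifs, and a neighbor-joining tree.

Because the real proteome-scale searches cannot be reproduced at desk
scale, every stage is validated against a synthetic family generator that
emits complete ground truth.

## Profiles, scoring and E-values

A profile is a sequence of 20-dimensional emission columns built from the
match columns (≤ 50% gaps; ties count as match) of an alignment.
Emissions are Henikoff position-based weighted frequencies mixed with
`pseudocount` (default 1.0) parts background and renormalised; the
background is a curated-database average composition. The model is
deliberately simpler than a full profile HMM — no insert-state emissions,
affine gap constants per profile (default open 11 bits, extend 1 bit) —
because the protocol needs reliable *ranking* and aligned *spans*, not
likelihood parity with HMMER. Non-standard residues (B, Z, U, O) map to
`X`, which scores zero everywhere, keeping the scoring model closed over
20 letters.

Scoring is local (Smith–Waterman) dynamic programming, implemented once in
C++ over a precomputed position-pair score matrix and shared by the
profile-vs-sequence (log-odds emission scores) and profile-vs-profile
(log2 co-emission ratio `sum_a p_a q_a / f_a`) modes. Ties break
deterministically toward the diagonal; between two matched pairs a gap may
run in only one of the two sequences, the standard Gotoh restriction. On
profiles of up to five columns the DP is verified exactly against
exhaustive enumeration of all legal local pairings.

E-values come from a maximum-likelihood Gumbel fit (Newton iterations on
the profile likelihood of the scale parameter, tolerance 1e-9, at most
200 iterations) to scores of the profile against seeded null samples:
length-matched i.i.d. background sequences in sequence mode,
column-shuffled copies of the target profile in profile mode. The
reported quantity is `E = N exp(-lambda (s - mu))` clamped to `[0, N]`,
with `N` the number of database records. E-values are therefore
*internally* calibrated; they are comparable across runs of this package
but not numerically to any external search engine, whose profile
databases and score variants differ.

## The dual acceptance criterion

`search_config()` fixes the rule: a hit is accepted iff its E-value is
below `e_accept` (default 1e-5) and its aligned query span overlaps each
of the profile's TM segments by at least `min_segment_overlap` columns
(default 5; the coverage requirement can be disabled, in which case one
covered segment suffices). The coverage arm is what separates genuine
full-length family members from the short "half-proteins" homologous to
only three of the seven helices: those reach extremely significant
E-values yet cover at most four segments, and are routed to
`classify_half_protein()` rather than accepted. The minimum overlap is
nowhere quantified in descriptions of the protocol ("matched all helices"
is a yes/no statement); 5 residues is this package's documented choice,
small enough that boundary jitter does not reject a true full-length hit
and large enough that a span merely touching a segment does not count.

Iteration (`discover_family()`) rebuilds and *recalibrates* the profile
every round, because E-values are profile-specific. Convergence is defined
on accepted identifier sets, not scores: re-running the search seeded with
a converged accepted set must return the identical set (score values may
shift as the profile deepens). Equal-E ties order lexicographically by
target id, making hit tables reproducible. If the set oscillates, the loop
stops at `max_iterations` (default 10) with a warning flag.

## Topology: windowed hydropathy and consensus

`predict_tm()` is a transparent stand-in for homology-aware TM predictors:
a 19-residue centred Kyte–Doolittle window mean above 1.6 marks candidate
residues; marked runs of ≥ 15 residues become helices; runs longer than 35
(two fused 21-residue helices) are split recursively at their interior
hydropathy minimum. Windows truncate at the sequence ends (the mean is
taken over the residues present): with a full-window rule a helix
following the one-residue N-tail could never accumulate the minimum run.
All four constants are exposed as arguments.

`consensus_topology()` lifts the per-sequence predictions to alignment
columns: a column is consensus-TM when more than half of the sequences
with a residue there lie inside one of their own predicted segments;
consensus runs of ≥ 12 columns become segments, and runs longer than 35
columns are split at the column of minimum mean hydropathy — the same
rule as per-sequence, without which families with very short loops (3–4
residues) merge adjacent helices irrecoverably. Sidedness is an
annotation, not a prediction: the N-terminal side defaults to the lumen
(the experimentally established KDEL-receptor orientation) and loops
alternate with each crossing, so the C-terminus of a 7-TM protein lands
in the cytoplasm. No positive-inside inference is attempted.

## Internal duplication

`split_profile()` cuts the profile at the midpoints of the loops flanking
the central helix: for seven segments the N-core holds helices 1–3, the
C-core helices 5–7, and helix 4 belongs to neither core — the repeat
boundary is not specified more precisely by the family's own structure, so
the symmetric midpoint rule is used and tested. `detect_duplication()`
aligns the two half-profiles and calibrates the score against
column-shuffled copies of the C-half (profile-mode null, default
`n_null = 500`); the verdict threshold (E < 1e-3) is deliberately separate
from the search acceptance threshold, since half-vs-half alignments of a
~110-column core are a different score regime from proteome hits.

One subtlety matters for the false-positive rate. The generator's default
family plants the PQ doublet in a loop of *each* half and a conserved
basic residue at a helix tip of *each* half, mirroring the repeated motif
annotations of real PQ-loop proteins. A family generated with
`duplication = FALSE` therefore still carries genuinely repeated planted
features, and the detector flags a fraction of such families — correctly,
in the sense that the repeated features are real. The proper negative
control for *helical-body* duplication plants features in one half only;
specificity tests in this package use that control.

## The synthetic generator and what it does (not) emulate

`family_spec()` describes a family: 7 helices of 21 residues, loops drawn
uniformly from 3–19 residues (short, as in the modelled architecture),
N-tail 1, C-tail 15, internal duplication of the first three helices and
their interleaving loops onto the last three, a PQ doublet planted
centrally in the loops after helices 1 and 5, two basic columns at the
N-tips of helices 2 and 6 and a serine near the tip of helix 3, all
evolving at 0.05x the family rate. Members receive Poisson substitutions
(hydrophobicity-preserving proposals inside helices, background proposals
elsewhere), and indels (geometric length, mean 2, initiation 0.02/site)
only in unplanted loop and terminus sites — conservation in these families
lives almost entirely in the helical body, and indels in helices would
break that premise. The generator emits the true alignment by
construction, per-member coordinate maps, and every planted feature's
span; the default divergence of 0.5 substitutions/site is a calibration
choice (real family divergence is not quantified), and all draws run from
one explicitly seeded RNG stream per call.

Two generator choices deserve their rationale spelled out, because they
were made to make the architecture *recoverable by design* under the fixed
hydropathy rule rather than left to chance:

* **Helix emission.** 85% of helix emission mass sits on
  {A,C,F,I,L,M,V,W,Y}, weighted within the set by background frequency
  times `exp(KD/1.4)` — a Boltzmann tilt toward the strongly hydrophobic
  aliphatics that dominate real TM cores. With an untilted choice, the
  mean windowed hydropathy of a helix sits so close to the 1.6 calling
  threshold that whole families fail whenever one *ancestral* helix draws
  cold — an error no amount of consensus can average away, because all
  members inherit it.
* **Insertion viability floor.** Each ancestral helix must reach a mean
  Kyte–Doolittle value of `min_helix_hydropathy` (default 3.2); draws
  below it are rejected and redrawn, including the mutated copies made at
  the duplication event and including any planted charged residue in the
  check. The biological reading: a TM helix that would not partition into
  the bilayer does not survive in a polytopic membrane protein. The
  practical reading: the floor removes the family-level failure mode
  above. Conserved charged residues are planted at helix *tips* for the
  same reason — a mid-helix lysine depresses every window of its helix
  and, worse, attracts the long-run split point to the middle of the
  helix, fabricating two half-helices.

What the generator does **not** emulate: phylogenetic structure (members
radiate from the ancestor in a star; there is no tree-shaped covariance),
re-entrant loops and signal peptides, domain insertions, compositional
drift between species, and real loop-length distributions. Passing tests
therefore demonstrate that the pipeline's logic is correct under the
stated statistical structure, not that its thresholds transfer unchanged
to real proteomes.

## Conservation, motifs and the phylogeny

`column_conservation()` reports, per column, the relative entropy (bits)
of Henikoff-weighted, lightly pseudocounted (default 0.05) residue
frequencies against background, plus the majority residue, its weighted
frequency, and the gap fraction; columns over 50% gaps are masked. With a
non-uniform background the score's ceiling is `log2(1/min f)` (about 6.5
bits), not `log2 20`.

`find_conserved_class_columns()` calls the strongly conserved basic
(K/R/H) and serine columns. Relative entropy alone cannot do this at
realistic family sizes: with 20 members at divergence 0.5, a rare residue
(histidine especially) retained by binomial chance in 17 of 20 members
outscores a genuinely invariant lysine column, because relative entropy
conflates rarity with conservation. The detector therefore also requires
near-invariance (weighted majority frequency ≥ 0.85), near-full occupancy
(gap fraction ≤ 0.1), and — as used by the pipeline — membership in the
consensus TM segments, where the family's conserved columns reside. These
thresholds were calibrated on generator draws (seeds disjoint from those
used in the validation suite) by comparing the planted-column score
distribution with the per-family maximum among unplanted class-anchored
columns; the operating point leaves both the recovery rate and the
no-plant false-call rate with margin.

`find_motif()` counts, per member, exact motif occurrences restricted to
loop columns and reports the columns carried by at least half the members;
planting the C-half PQ at a lower mutation rate than the N-half one makes
the reported C-half carrier fraction the larger, the asymmetry observed in
the real family. Distances for the tree are plain p-distances (1 −
fractional identity over mutually ungapped columns; a `-ln(1-p)` Poisson
correction is available but off by default — only topology-level claims
are tested, and the original tree-building stack is not reproducible
bit-exactly). Neighbor-joining uses the classical algorithm via `ape`,
with closed-form handling of two and three taxa and negative branch
lengths clamped to zero.

## Numerical and interface choices

* Coordinates are 1-based inclusive spans throughout, the R idiom; all
  span intersections and tests use that convention.
* Gumbel fits refuse degenerate nulls (zero score variance) rather than
  returning an unusable calibration; `n_null` must be at least 100.
* `evalue()` clamps to `[0, N]`: at the Gumbel location the raw value is
  exactly `N`, and larger scores decay exponentially.
* The pipeline configuration is an R list or a YAML file with per-stage
  sections; every run writes a manifest with the config snapshot, seeds,
  per-file MD5 hashes and timings, and reruns with the same config are
  hash-identical.
* Problem sizes in the validation suite: the demo proteome is one
  20-member family plus 200 globular decoys and 10 half-proteins;
  architecture-recovery and duplication statistics use 100 seeded
  replicates; per-module tests run reduced replicates (10–25 seeds) of
  the same constructions.

## Known limitations

* E-values are internally calibrated and not comparable to external
  search engines; the acceptance threshold 1e-5 is meaningful relative to
  this package's null model only.
* The coverage criterion uses the hit's aligned span, not the matched
  columns along the traceback; an alignment with a long internal deletion
  could in principle claim coverage it does not have, though the affine
  gap costs make such alignments suboptimal in practice.
* The topology predictor is windowed hydropathy, adequate for the
  generator's families and transparent to test, but far below modern
  HMM-based predictors on real sequences.
* Star-phylogeny evolution means the NJ tree of a synthetic family has no
  meaningful internal structure; tree correctness is tested on additive
  and ultrametric matrices instead.
* Half-protein classification against a duplicated family is inherently
  ambiguous (both halves are homologous to the query); the label reports
  the better-covered half and flags spans touching both.
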
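---
title: "CRISPR spacer-guided mobilome discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR spacer-guided mobilome discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerlink)
```

## The problem

Metagenome-assembled genomes of CRISPR-carrying prokaryotes pose two linked
questions that `spacerlink` answers from the assembly alone:

1. *Which co-assembled contigs are mobile elements of this host?* CRISPR
   spacers are sequence samples of past invaders; a spacer matching a contig
   at full length with at most one mismatch is direct evidence of a
   host-element interaction.
2. *Can the chromosome be closed?* Multi-kilobase CRISPR arrays are longer
   than the repeat-resolving power of short-read assemblers, so assemblies
   tend to break inside them. The broken ends retain partial arrays; a shared
   run of consecutive identical spacers across two contig ends pins their
   adjacency and orientation.

All internal coordinates are 0-based half-open; GFF3 output is 1-based
inclusive (the GFF3 mandate). `N` is legal in inputs but conservatively
treated: it never matches anything during spacer comparison (including
another `N`) and is excluded from every skew denominator.

## Array detection

`detect_arrays()` is a deliberately minimal seed-cluster-extend detector —
downstream stages consume only array coordinates and ordered spacer
sequences, so recovery of planted arrays is the testable contract, not
feature parity with full-scale detectors.

* **Seed**: exact 13-mers occurring at least `min_repeats` (3) times.
* **Cluster**: occurrence runs whose successive gaps lie in
  `[repeat_min + spacer_min, repeat_max + spacer_max]` = [43, 100] nt and
  vary by at most `gap_spread` (12) nt. Repeats 23-50 nt and spacers
  20-50 nt cover the ranges reported for type I systems.
* **Extend**: columns are added left and right of the seed while the
  majority letter over occurrences agrees in at least `min_col_agreement`
  (0.8) of them, capped so spacers cannot shrink below `spacer_min`. Edge
  columns are then trimmed back to near-unanimity
  (`repeat_edge_agreement` = 0.95): over few occurrences a random flanking
  column occasionally clears 0.8 (6 of 7 matching letters occurs at roughly
  0.1% per column), and a one-column offset would shift every spacer boundary
  in the array — fatal for exact spacer-run comparison between two
  independent observations of the same array.
* **Emit and merge**: at least `min_repeats` repeats make an array; spacers
  are inter-repeat gaps; overlapping candidates collapse to the one with more
  repeats. Boundary repeats truncated by a contig end count if at least half
  the consensus survives, because contig-edge arrays are exactly the ones the
  join logic needs.

Orientation is reported `unknown`: repeat polarity and leader inference are
out of scope, and nothing downstream requires them.

## Spacer matching

`find_hits()` operationalises "100% query coverage, bounded mismatches" as
ungapped Hamming search on both strands: every window of spacer length with
at most `max_mismatches` (1) mismatches is a hit. Indel-containing
alignments are deliberately out of contract — exactness makes the operation
testable against a naive brute-force scan, which the test suite enforces
set-identically on whole synthetic assemblies. The implementation delegates
the window search to `Biostrings::matchPattern` with `N` masked in the
subject so that `N` never matches; the test oracle is an independent
vectorised scan.

Self-hits are removed by excluding hits overlapping detected arrays on the
target, padded by one repeat length: a spacer trivially matches its own
array, and only inter-element hits carry information. An adversarial
generator mode (`sim_decoy_in_array`) plants one spacer in both arrays so the
filter's behaviour is tested in isolation.

`summarize_linkage()` counts, per target, distinct spacers whose best hit is
exact and those whose best hit has exactly one mismatch; a spacer hitting two
contigs counts toward both, and an attached `totals` attribute reports the
deduplicated convention as well, since published counts do not always state
which convention they use.

## Element classification

Three signatures, then ordered rules:

* **Terminal direct repeat** (`detect_circularity`): assemblers emit circular
  replicons as linear strings with the start duplicated at the end. The
  longest prefix matching an equal-length suffix (within `circ_max_mismatch`,
  default 0; at least `circ_min_overlap` = 20 nt; at most half the contig,
  avoiding degenerate self-overlap) is located via candidate anchoring of the
  first 20 nt — complete for any mismatch budget *m*, since a valid overlap
  has at most *m* mismatches in its first window — and verified in full.
* **Terminal inverted repeat** (`detect_tir`): the first `max_scan` (500) nt
  against the reverse complement of the last 500 nt, extended ungapped from
  position 0 with +1/−3 match/mismatch scoring and an X-drop of 20; the arm
  is the longest match-ending prefix attaining the maximal score, reported if
  ≥ `tir_min_len` (20) nt and ≥ `tir_min_identity` (0.85). Score-based
  maximality is the one deliberate refinement over "longest arm above an
  identity floor": against random flanking sequence a chance match just past
  the true arm would otherwise extend it, making arm length ill-defined.
  The default minimum length is intentionally permissive — the ~80 nt
  exemplar in linear dsDNA archaeal viruses is one observation, not a
  distribution.
* **Coverage ratio** (`coverage_ratio`): contig depth over chromosome depth;
  ratios ≥ 2 are treated as replication evidence. Depth arrives as a TSV
  (mean per contig; an optional Rsamtools adapter computes it from a BAM, but
  the pipeline never requires alignments).

`classify()` applies first-match-wins rules: designated-or-longest contig →
`chromosome`; ≥ 50% array-covered → `crispr_fragment`; terminal direct
repeat → `circular_mobile`; TIR → `linear_tir_mobile`; any spacer hit,
elevated coverage, or user-supplied mobile-gene annotation → `mobile_other`;
else `unclassified`. Rule order is part of the contract (a circular contig
with spacer hits is `circular_mobile`) and is pinned by a test. Gene-content
evidence (integrases, endonucleases) and contaminant overrides (e.g. rRNA
carried by conserved-sequence artifacts) enter only through an optional
annotation table: homology search and gene calling are out of scope, but the
evidence class is preserved.

## Replication origin from nucleotide skews

`windowed_skews()` computes per-window GC = (G−C)/(G+C), AT = (A−T)/(A+T),
RY = ((A+G)−(C+T))/N and MK = ((A+C)−(G+T))/N with zero denominators mapping
to 0, and cumulative prefix sums. The origin is the boundary following the
global cumulative-GC minimum (ties leftmost): with the (G−C) sign convention
the leading strand is G-rich downstream of the origin, which makes the
minimum criterion and the sign convention mutually consistent. The other
three cumulative tracks corroborate the call when below their medians at
that window — advisory flags, never vetoes. `origin_candidates()` lists the
deepest local minima for manual review, replacing the by-inspection step of
published practice with a ranked list. `rotate_to_origin()` permutes a
circular contig so the selected position becomes nucleotide +1; rotating a
linear contig is a hard error.

The default window of 1000 nt (step = window) keeps tracks smooth at both
the 60 kb test scale and megabase scale; at 1000 nt the per-window drift of
the default synthetic bias is about twice the binomial noise, so the V-tip
is localised to about one window.

## Contig joins

`propose_joins()` aligns boundary-array spacer lists end-to-end — a suffix of
the upstream array against a prefix of the downstream one, in both
orientations of the second contig — and emits a proposal when the longest run
of identical consecutive spacers reaches `min_k` (4, configurable; taken
from the observed evidence level that justified closure, treated as
sufficient-to-hypothesise rather than calibrated). Spacer identity is exact
string equality: spacers are the unique evidence, whereas the repeats between
them may disagree at up to `repeat_tol` (10%) of positions during the merge
(`merge_contigs()`), reflecting repeat degeneracy at array edges. A spacer is
excluded from run computation only when it is both short (< 90% of the
array's median spacer length) and flush with a contig end — the only
situation that produces partial spacers; dropping on length alone would
discard genuine short spacers (planted lengths span 35-42 nt) from run
interiors. Merged contigs carry `join_evidence=in_silico` in their
description: a proposal is a hypothesis for targeted validation (e.g.
long-range PCR), never a claimed closure. Self-joins of one contig's two
ends (distinct boundary arrays) are allowed and flagged as circularisation
evidence.

## The synthetic generator: what it emulates, and what it does not

`generate_assembly()` emits the pipeline's exact input formats with recorded
truth. Defaults define the study conditions:

* **Chromosome** (60 kb; thresholds are length-independent, so desk scale
  substitutes for megabase scale): GC content 0.41 (a plausible neutral
  choice, configurable, with no claim of realism); per-base G-vs-C excess
  0.04 on the replichore downstream of a uniformly drawn origin and the
  mirror bias upstream, giving the cumulative GC track a unique global
  minimum at the origin. The A-vs-T excess is 0.06 — deliberately above the
  GC bias, because the amino-keto track's downstream drift is
  2(a_bias − g_bias) and would peak rather than dip at the origin otherwise;
  with these defaults all three corroborating tracks dip there. The
  array/marker block is sampled with its local replichore bias for the same
  reason: kilobases of composition-neutral insert would erode the V-shape.
* **Arrays**: two arrays (20 + 10 spacers, one 30 nt repeat consensus,
  spacer lengths uniform on [35, 42], mutually distinct) flanking a 2 kb
  marker locus, placed away from the origin and both contig ends.
* **Mobile contigs**: two plain 8 kb mobiles; a 10 kb circular virus
  represented with its first 30 nt duplicated at the end (the linear
  representation assemblers actually emit); a 12 kb linear virus with exact
  80 nt terminal inverted repeats at 3.5× chromosome depth. The four inner
  flanking bases of each TIR arm are forced non-complementary so the planted
  arm length is sharply defined — a real TIR ends where complementarity
  ends, and without the barrier a chance complementary base would genuinely
  lengthen the planted repeat.
* **Protospacers**: 9 spacers planted verbatim (0 mismatches) across the 4
  mobile contigs, the linear virus receiving 3 exact and 3 one-substitution
  copies, either strand, never inside arrays.
* **Fragmented mode** (`fragment_at_array()`): splits the chromosome at
  repeat boundaries inside an array so the two fragments share exactly
  `k_shared` (4) consecutive spacers; concatenating the fragments minus the
  duplicated overlap reconstructs the chromosome byte-for-byte, which is the
  oracle for the join stage.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: sequencing error and read-level artifacts (depth is
emitted directly, no FASTQ); repeat degeneracy within arrays (planted repeat
copies are identical, so detector recovery rates here are upper bounds);
array orientation signals (leaders); gene content; compositional
heterogeneity beyond the two-replichore bias (no horizontally transferred
islands, which in real genomes perturb skew); chimeric or misassembled
contigs.

## Numerical choices and degenerate inputs

* Ties in the cumulative-skew minimum resolve leftmost; zero-denominator
  skews are 0; trailing windows shorter than half a window are dropped.
* `detect_arrays` on a contig shorter than three repeat lengths returns an
  empty list (no arrays is a result, not an error); empty assemblies error.
* Spacers shorter than 15 nt are rejected as uninformative queries.
* Duplicate FASTA ids, empty records, negative depths, features past contig
  ends, and cross-run report inputs are hard errors naming the offender.
* One global seed governs every stochastic operation; regeneration under the
  same seed is byte-identical, and the end-to-end report is byte-identical
  across reruns on identical inputs.

## Problem sizes used by the tests and acceptance script

Sweeps use 60 kb chromosomes (~98 kb assemblies): 20 seeds for
oracle-equivalence, recovery, classification and join round-trips, 50 for
origin recovery, chosen so the whole suite runs in minutes on one CPU while
estimating each rate to a few percent. At the default bias the measured
per-seed chance of the origin call slipping one window past the planted
position is ~3% (window-level binomial noise at the V tip), so the 50-seed
origin recovery statistic typically prints 94-100 with a mean near 97.

## Known limitations

* The array detector assumes near-identical repeats; heavily degenerate
  repeats (> 20% divergence) or spacer-length drift outside 20-50 nt will
  fragment or miss arrays.
* Hamming-only matching misses indel-containing protospacers by design.
* TIR detection is ungapped; arms interrupted by indels are reported short or
  missed.
* The origin caller reports the windowed cumulative minimum; it does not fit
  changepoints, search oriC motifs, or resolve below one window.
* Join proposals assume the shared array region is collinear between
  fragments; rearranged arrays defeat the end-alignment model.
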
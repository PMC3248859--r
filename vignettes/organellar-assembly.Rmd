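---
title: "Assembling plant organellar genomes from whole-genome shotgun contig graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling plant organellar genomes from whole-genome shotgun contig graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgc)
```

## The problem

Total DNA extracted from plant tissue is a mixture: one nuclear genome and
two organellar genomes, chloroplast (cp) and mitochondrial (mt), present in
many copies per cell.  When such a mixture is shotgun-sequenced and
assembled, the organellar contigs are not labelled -- but they are
*deeper*.  Mean read depth of a contig is proportional to the copy number
of the genome it came from, so a sample sequenced to ~9x nuclear coverage
can simultaneously carry ~43x mt and ~87x cp coverage.  `orgc` turns that
depth signal, plus the assembler's contig connection graph, into complete
circular organellar genomes without any organelle isolation in the lab.

The pipeline is: read the contig graph; classify contigs by depth; extract
the class subgraph; prune false links and forks; find the circular
traversal with repeat multiplicities; resolve dispersed repeats with
mate-pair link counts; and concatenate the oriented contig sequences into
the finished circle.

## Data model

A `contig_graph` stores contigs (id, length, mean read depth, optional
sequence) and *end-typed* edges: a spanning read tells you that one
specific end (5' or 3') of a contig abuts a specific end of another.
Edges are stored unordered -- traversals, not storage, decide orientation.
All internal coordinates are 0-based and half-open, which keeps arithmetic
on circular sequences unambiguous.

Readers are provided for GFA 1 (depth in a `DP:f:` tag) and for a
tab-separated Newbler-style "454AllContigGraph" dialect.  The vendor format
was never publicly specified, so the reader accepts a documented dialect
carrying exactly the fields the method needs (contig rows: index, id,
length, depth; link rows: id, end, id, end, spanning-read count) and skips
unknown record types with a counted warning.

## Depth classification

`classify_by_depth()` labels a contig CP when `depth >= t_high` (default
60), MT when `t_low < depth < t_high` (defaults 20/60, the open interval),
and NUCLEAR otherwise.  The defaults suit the 87/43/9 regime; for other
samples, `depth_histogram()` is the diagnostic for picking thresholds --
the three classes appear as separated modes.

Thresholding alone misplaces exactly one kind of contig: collapsed
repeats.  An assembler merges the identical copies of a repeat into one
contig whose depth is `copies x` the single-copy depth, so a two-copy mt
repeat at ~86x thresholds into cp territory.  `flag_repeats()` estimates a
class's single-copy base depth as the length-weighted median of its contig
depths (length-weighted, because the short low-depth contig tail would
otherwise drag an unweighted median; one refinement pass re-estimates the
base from the contigs consistent with a single copy) and flags contigs at
`m >= 2` multiples within a relative tolerance of 0.35 -- deliberately
loose, since observed repeat depth ratios are near, not exactly, integral.
`repeat_candidates()` applies the same rule across the whole graph, and
reachability (not depth) then decides which candidates belong to the
class: `extract_component()` walks out from seed contigs through
class-labelled and candidate contigs.

Seeds default to every contig the thresholds place in the class.  When
conserved reference sequences are available (e.g. the respiratory-chain
genes conserved across plant mt genomes, or related cp genomes),
`find_seed_contigs()` offers sequence-based seeding by shared canonical
k-mers (k = 31, at least 5 distinct shared k-mers with a single reference
record).  Canonical k-mers -- the lexicographic minimum of a k-mer and its
reverse complement -- make the match strand-blind; the defaults are
deliberately permissive because seeding only needs one true contig per
genome to anchor reachability.

During mt extraction, cp-labelled contigs connected to at least two
already-reached mt contigs are adopted into the component: plastid
fragments are frequently transferred into plant mt genomes, so a cp-like
contig *internal* to an mt path is genuine mt sequence, while cp contigs
on full cp paths stay out.

## Pruning

`remove_false_links()` removes out-of-class contigs and edges supported by
fewer than `min_support = 2` spanning reads.  The support default removes
single-read joins -- the signature of one chimeric read -- and is applied
*before* reachability in the pipeline, because a single chimeric link could
otherwise pull a foreign genome's contigs into the extracted component
(repeat-candidate depths are ambiguous between classes: 2 x 43 is within
tolerance of 1 x 87).  Every removal is logged with its reason, and
`apply_removal_log()` replays a log exactly.

`detect_forks()` enumerates forks: pairs of contig ends joined by two or
more internally-disjoint paths (at most 5 internal contigs per branch; the
cap bounds enumeration and detour branches are short in practice).
`resolve_forks()` keeps the branch whose length-weighted mean depth is
closest to the reference depth of the unique, non-fork contigs, breaking
ties by total edge support and then lexicographically, with every decision
logged.  One guard matters: forks that touch repeat contigs -- as branch
internals *or* as fork endpoints -- are left alone.  Around a collapsed
two-copy repeat, the direct flank edge and the loop back through the
repeat (or the two inter-copy segments hanging off the repeat's ends) look
exactly like alternative branches, but all of them are used by the true
circular walk; resolving them as detours would delete genuine structure.

## The circular walk

`find_circular_path()` searches for closed walks that traverse each contig
exactly its multiplicity and realize every edge at least once.  Each
traversal of a contig crosses each of its ends exactly once, so the number
of edge crossings at an end must equal the contig's multiplicity; an end
whose distinct-edge degree exceeds its multiplicity (or is zero) is
reported as a degree violation before any search.  Edges may be crossed
more than once: when a multi-contig inverted repeat collapses, its
internal edges are traversed once per copy, which is why "each edge
exactly once" would be the wrong invariant.

The search is exhaustive backtracking over an edge-expanded state
(remaining crossings per contig end), not a heuristic: after pruning, an
organellar graph has tens of nodes, and completeness is worth more than
speed at that scale.  Walks are reported up to rotation and full reversal
via a canonical step representation, starting from a single-copy contig so
the symmetry is quotiented out cheaply; a cap (`max_solutions = 16`) stops
runaway enumeration when the repeat layout is genuinely ambiguous.

### Quadripartite annotation

For a plastid, the multiplicity-2 contigs form the collapsed inverted
repeat; the two single-copy arcs between its two traversals are LSC
(longer) and SSC (shorter).  Equal arcs are broken in favour of the
first-traversed arc, with a message.  No multiplicity-2 contig degenerates
to a single LSC segment with a warning; more than one distinct repeat run
is an error directing the user to mate-pair resolution, the mt route.

### Mate-pair repeat resolution

A dispersed mt repeat with `m` copies leaves the walk ambiguous: the
search returns every consistent pairing of upstream with downstream
flanks.  Mate pairs spanning from flank to flank decide it.
`select_major_links()` formalizes "pick the pairing with the most
mate-pair support" as a maximum-weight perfect matching over the candidate
rows: the selected rows (major links) must cover every flanking contig
exactly once and maximize total link count.  This reproduces all published
example decisions and generalizes to repeats with more than two copies.
Ties and infeasible tables are errors demanding manual review, never
silent choices.  `apply_major_links()` then replaces the repeat contig by
one copy per selected link, wired between its flank pair with the ends
taken from the original repeat-flank edges; sequence content
(`length x multiplicity`) is conserved, per-copy depth is the original
divided by the copy number, and the expanded graph admits a unique walk --
the master circle.  Minor links are reported but never assembled;
reconstructing alternative (sub-genomic) mt configurations is out of
scope.

## Sequence reconstruction and reporting

`reconstruct_sequence()` concatenates oriented contig sequences along the
walk; reverse steps contribute the reverse complement.  Joins are zero-gap
by construction of the contig graph, except where an edge (or an explicit
`gap_policy`) declares a single gap/insert base, which is inserted at the
join -- both the "gap base" and "insert base" cases are implemented as the
same edge-join insertion, the simpler of the two readings.

`canonical_form()` -- the lexicographically smallest string over all
rotations of the sequence and of its reverse complement -- makes circular
assemblies comparable regardless of chosen origin and strand.  The least
rotation is found by simultaneous candidate refinement (linear-time in
practice), so canonicalizing a 40 kb genome is instantaneous.
`gc_content()` excludes N from the denominator so unplaced ambiguity does
not bias composition, and reports round to 2 decimals while internal
values stay unrounded.  `assembly_report()` reports contig statistics
counting repeats once (the circle-graph convention) alongside
per-traversal totals, and cross-checks that the reconstructed length
equals traversed contig lengths plus inserted gap bases.

### The inversion-isomer choice

A collapsed-IR contig graph cannot distinguish the two inversion isomers
of a quadripartite plastid (SSC in either orientation): both are valid
closed walks over the same graph, and real plastid DNA is itself a
near-equal mixture of the two.  The pipeline therefore reports the isomer
with the lexicographically smaller canonical form and lists the other
under `alternates`.  The synthetic cp generator emits its planted genome
as the same canonical representative, so "assembly equals planted truth"
is exact rather than true-up-to-isomer.

## What the simulator emulates -- and what it does not

`simulate_assembly()` plants, at desk scale, the study conditions the
method targets: a 16 kb quadripartite cp genome (LSC 8 kb, SSC 2 kb, IR
3 kb x 2; GC 0.37) at 87x, a 40 kb mt genome with two dispersed two-copy
repeats (1.6 kb and 1.2 kb; GC 0.43) at 43x, and 200 kb of nuclear
background in 20 fragments (GC 0.36) at 9x.  Real organellar genomes are
~10x larger; the scaled sizes exercise every code path (collapse, forks,
link resolution, isomers) while keeping a 50-seed experiment in tens of
seconds, and all sizes are configurable.

`shred_to_graph()` cuts each genome at exponentially spaced breakpoints
(mean 1,500 bp, minimum contig 200 bp), forces breakpoints at repeat
boundaries, and collapses identical repeat copies into shared contigs at
`copies x copy_depth` -- the cp IR may shred into a multi-contig run
(cut positions shared between the copies, as a collapsing assembler would
produce), while mt dispersed repeats stay single contigs, matching their
size relative to typical contigs.  A backbone segment between two repeat
placements is guaranteed at least one cut so each repeat copy keeps
distinct flanking contigs.  Per-contig depth gets Gaussian noise with
sd 3: a Poisson read-sampling argument at 340 bp reads puts the sd of a
contig's mean depth near 1.5 (9x, 1.5 kb contig) to 4.5 (87x), so a
constant 3 is a fair middle.  Edge support is Poisson around the copy
depth; spurious cross-genome edges carry support 1 (a single chimeric
read), which is what the `min_support = 2` pruning default is calibrated
to remove.  Mate-pair candidate tables draw true pairings at
Poisson(50) and cross-copy pairings at Poisson(5) links.

Not emulated: sequencing error and homopolymer artifacts, coverage bias
along the genome, plastid-to-mitochondrion transferred segments (the
adoption rule is unit-tested on constructed graphs instead), nuclear
copies of organellar DNA, and multipartite mt isoform structure.  Passing
the planted-recovery suite therefore demonstrates the graph logic --
classification, pruning, walk search, repeat resolution, reconstruction --
under realistic depth noise and chimeric links, not robustness to
assembler consensus errors; on real data those are absorbed upstream by
the assembler.

The subsampling experiment (`subsample_experiment()`) draws reads from the
genome mixture in proportion to copy-depth-weighted genome mass and
reports, per organellar genome, the fraction of positions hit by at least
one read, over a nested (prefix) sample so coverage is monotone in sampled
mass by construction.  Position-based coverage on the truth genomes stands
in for re-running the whole assembly at every data point; at desk scale it
reproduces the qualitative pattern that matters -- the cp genome saturates
at less sampled mass than the mt genome whenever cp copy depth exceeds mt
copy depth.  Absolute megabase thresholds do not transfer from any real
dataset to synthetic scale and are not asserted anywhere.

## Numerical and degenerate-input choices

* Depth thresholds are compared with `>=` at `t_high` and `<=` at `t_low`;
  the MT interval is open on both sides.  Boundary mass is negligible in
  practice and the convention is stated rather than configurable.
* `weighted_median()` returns the smallest value whose cumulative weight
  reaches half the total -- deterministic under ties.
* Sequences are uppercased on input; characters outside A/C/G/T/N are
  errors, never silently dropped.  Depths are written to GFA with 17
  significant digits so graphs round-trip bit-exactly.
* Empty graphs, empty reference sets, all-N sequences, broken cycles and
  infeasible matchings are errors with named offenders, not warnings.
* All generators accept a seed and restore the caller's RNG state; the
  same seed gives byte-identical output.

## Problem sizes used by the test suite

The planted-recovery suite runs 50 seeds of the full two-genome pipeline
(~250 kb of planted sequence per seed), oracle-equivalence checks run
1,000 random link tables and length sets and 30 random small walk
instances against brute-force enumerations, and the classification and
subsampling suites run 50 seeds and a 6-point coverage curve.  The whole
suite completes in a few minutes on one core.

## Known limitations

* Walk search is exponential in principle; the solution cap and the
  smallness of pruned organellar graphs keep it practical, but a graph
  with many unresolved repeats will hit the cap and demand link data.
* Repeat multiplicity is inferred from depth ratios only; a repeat whose
  copies diverge enough to assemble separately, or whose depth falls
  outside the 0.35 tolerance, needs manual multiplicity.
* `select_major_links()` treats the 5'/3' columns of a link table as an
  unordered flank pairing and recovers orientation from the graph; tables
  whose strand convention genuinely matters are not interpreted further.
* The mt "full-path cp contig" removal is reachability-based; it does not
  align contigs to a finished cp genome.
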
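---
title: "Methods: joint sequence-structure analysis of nrDNA ITS regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint sequence-structure analysis of nrDNA ITS regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsstruct)
```

## The problem and the model

The internal transcribed spacers (ITS1, ITS2) of the nuclear ribosomal
cistron evolve quickly at the sequence level but are constrained by the
secondary structures they must fold into during rRNA maturation. ITS2 in
particular shows a conserved pan-eukaryote architecture: four helices
radiating from a central loop, closed on the outside by a proximal stem
formed by hybridization of the flanking 5.8S and 28S sequences, with a
`UGGU` landmark near the apex of Helix III (the longest helix), a U-U
mismatch in Helix II, and an `AAA` spacer between helices II and III. This
conservation makes the *pattern* of substitution informative: a substitution
at a paired site can change both partners while keeping the pair viable
(a compensatory base change, CBC), change one partner while staying within
the allowed pair set (hemi-CBC), or break the pair or hit a loop
(non-structural, Nst). CBCs tend to mark deep splits, hCBCs species groups,
and Nsts closely related species, so classifying and counting them by clade
pair and by helix is a phylogenetic instrument in its own right.

`itsstruct` implements that instrument end to end: region annotation,
structure prediction and template-based homology modeling, synchronized
sequence-structure alignment, event classification and tabulation, consensus
structures and helix statistics, motif and pseudogene screening, diversity
and distance tables, and distance-based trees with bootstrap support. A
structure-aware simulator with a planted event log supplies ground truth so
every analysis step can be validated exactly.

Allowed pairs throughout are the Watson-Crick pairs plus the G-U wobble:
`{AU, UA, GC, CG, GU, UG}`.

## Coordinates

All coordinates are 1-based and inclusive, both internally and in reports.
R's containers are natively 1-based and published positions (e.g. the
printed paired positions 39/70, 47/64, 85/113, 97/101, 148/186) are 1-based,
so a single convention removes an entire class of off-by-one defects.

## Region annotation

HMM-based annotators are not reimplemented. Instead, two conserved motif
anchors locate the 5.8S gene: its start (5.8S Motif I,
`CGAUGAAGAACGUAGC`, mismatch budget 1) and its end (the `CAUAU`
5.8S-ITS2 boundary motif, budget 0 because boundary anchors must be exact).
ITS1 is everything before the 5.8S start, ITS2 everything after its end.
This mirrors how published boundary corrections are themselves motif-driven
(the `CAUAU` verification that led to pruning three nucleotides from a
database 5.8S annotation).

Numerical choices:

* anchor hits are searched inside plausibility windows derived from minimum
  region lengths (defaults ITS1 >= 100, 5.8S >= 150, ITS2 >= 100 nt); the
  boundary anchor window is +/-30 nt around the position expected from a
  160-nt 5.8S;
* with several in-window hits the leftmost is used and a warning emitted;
* an anchor missing within its budget leaves that boundary *unresolved*
  (reported as `NA`), never guessed; a record with no anchor at all is an
  error.

`harmonize_boundaries()` compares an anchor-based annotation with an
external one and records the signed difference per region edge (positive =
external extends upstream, i.e. nucleotides pruned). Because the published
account leaves ambiguous whether a whole 5.8S frame was shifted or a single
edge trimmed, both edges of every region are recorded (attribute
`edge_trims`) and the per-region `trims` map uses each region's
anchor-defined edge (ITS1 start, 5.8S start, ITS2 end).

## Folding

The internal engine is a dynamic program over all nested structures
(minimum hairpin 3, the steric minimum) maximizing either the pair count or
a typed pair score (defaults GC = 3, AU = 2, GU = 1) plus a stacking bonus
(default 1) for helix continuation. These scores are *arbitrary units*:
kcal/mol free energies are only meaningful under a full nearest-neighbor
thermodynamic model, so they are emitted only by the external backend
(the RNAfold binary), whose structure and energy are returned unchanged. An
absent backend is an explicit error, never a silent fallback.

Ties are broken deterministically: the traceback prefers pairing over
bifurcation and, among equal-scoring pairings of a closing position, the
smallest opening index; the stacked continuation is preferred inside a
committed pair. Identical input and parameters therefore always produce the
identical structure.

Before folding ITS2, `add_flanks()` prepends the last 25 nt of 5.8S and
appends the first 25 nt of 28S (both lengths configurable) so the proximal
stem can form; the returned offset maps structure indices back to ITS2
coordinates.

## Template-based homology modeling

`model_from_template()` transfers a template's pairs onto a target through
a global sequence alignment (Biostrings, match 2 / mismatch -1, gap open
10 / extend 0.5): a template pair survives iff both its columns align to
target bases and those bases form an allowed pair. Identity below
`min_identity` (default 0.75, the custom-modeling convention of the ITS2
database, which publishes only "default parameters") fails with "template
too distant". Transfer is idempotent on the template itself, and a CBC or
hCBC in the target never removes a pair - exactly the property that makes
homology modeling appropriate for CBC analysis.

`enumerate_helices()` decomposes a structure: a helix is a maximal run of
nested pairs whose consecutive pairs are separated by at most `bulge_merge`
unpaired nucleotides per strand (default 6, chosen so the packaged template
yields the canonical four-helix architecture; configurable). Helices
attached to the outermost multiloop are numbered I, II, ... 5' to 3'; a
stem enclosing that multiloop is the proximal stem; deeper sub-stems beyond
the merge bound stay inside their helix so the pair partition is exact.
Because published ITS1 architectures include loop descriptions that do not
map one-to-one onto this scheme (a loop "with zero helices"), ITS1
decompositions are reported descriptively and no fixed helix count is
asserted for ITS1.

## Synchronized alignment

Records are encoded in a 12-state alphabet: 4 bases x 3 structural roles
(unpaired, opening partner, closing partner), plus gap. The substitution
score of two states is the sum of a sequence component (match +2,
transition -1, transversion -2) and a structure component (same role +1,
unpaired vs paired -2, open vs close -3); affine gaps cost 5 to open and 1
to extend. The published workflow's alignment tool does not print its joint
matrix, so these are declared parameters, not claims, and are all
configurable (`ss_score_params()`).

Alignment is progressive: pairwise joint-state p-distances feed an NJ guide
tree (midpoint-rooted); profiles merge postorder under an affine-gap
Needleman-Wunsch on expected column scores, with ties preferring
substitution over gaps. Manually adjusted alignments are supported by
loading a gapped alignment directly (`ssalignment_from_gapped()`,
`read_ssaln()`), bypassing the aligner.

`paired_columns()` votes per row: a column pair `(p, q)` is reported when at
least a threshold fraction (default 0.5) of the rows ungapped at `p` open a
pair at `p` whose partner maps to `q`. Gapped rows do not vote - whether the
published analysis treated gaps in paired columns as structural disruption
is unstated, and excluding them from the vote is the conservative choice.

## Event classification

At a paired column, two taxa's states `(b5, b3)` are compared: identical is
silent; both states allowed pairs with both partners changed is a CBC; both
allowed with exactly one partner changed is an hCBC; everything else is Nst.
At unpaired columns, different bases are Nst. Gaps are never Nst: they are
logged as separate indel events, matching the convention of counting indel
sites separately. A double change whose result is not an allowed pair is one
Nst event, not two.

One published call labels a U:A to C:A change an hCBC although C:A is not
an allowed pair; the default classifier calls it Nst, and
`lenient = TRUE` admits C:A/A:C as weak pairs for replication of that
reading.

Group-level tabulation derives one state per group and column (the state
shared by at least `group_threshold` of ungapped members; default 1.0,
unanimity, because the published tables enumerate per-taxon exceptions
rather than majority-voting); polymorphic columns are excluded and listed as
exceptions. Positions are reported both aligned and in per-taxon original
coordinates (the "not-aligned" convention of the published tables).

## Consensus structures and helix statistics

The consensus base of a column is the minimal IUPAC code covering observed
bases (gaps excluded, matching the per-taxon exception style); conservation
is the plurality fraction. Consensus pairs use the 0.5 vote threshold; the
100%-conserved subset (pairs present, with allowed chemistry, in every
ungapped member) is reported separately because both entities appear in the
published material. Per helix, `helix_stats()` reports length in pairs, GC
and G-U pair fractions (of the plurality consensus bases), variability
(columns with >= 2 states / helix columns), and transition / transversion
counts (distinct derived bases per column against the plurality base;
transitions are A-G and C-U).

## Motifs and the pseudogene screen

The packaged catalog: the ITS1 angiosperm core motif `GGCGC` + 3-6 nt
spacer + `GYGCCAAGGAA` (two-block, shared mismatch budget, the canonical
4-nt spacer in the packaged template); 5.8S motifs I-III
(`CGAUGAAGAACGUAGC`, `GAAUUGCAGAAUCC`, `UUUGAACGCA`; budget 1); the
`CAUAU` boundary (budget 0); the ITS2 `UGGU` variants checked on the 5'
side of Helix III; the `AAA` spacer between helices II and III. Because the
conserved `AAGAA` block also occurs inside Motif I, the distance from
`AAGAA` to Motif II is measured from the Helix 1 loop copy, and both
end-to-start and start-to-start readings can be derived from the hit table.

A record passes the pseudogene screen iff the three 5.8S motifs and the
ITS1 core motif are found within budget and every region's GC content
(default 45-60%) and length (defaults ITS1 230-256, 5.8S 160-162,
ITS2 220-228 nt, the observed tribe-level ranges) are in bounds; the
verdict enumerates every failure, and relaxing any bound can only turn
failures into passes (monotonicity).

## Diversity and distances

Diversity indices follow the DnaSP conventions: segregating sites `S`,
parsimony-informative and singleton sites, total mutations `Eta` (distinct
derived bases per site), nucleotide diversity `Pi` as the mean over pairs of
per-pair differences per compared site (pairwise deletion), haplotypes and
Nei's haplotype diversity `h = n(1 - sum p_i^2)/(n - 1)` on gap-free
columns, and indel sites/haplotypes from the gap presence-absence matrix.

Group distance tables use the p-distance with pairwise deletion (the
default of the cited distance software for such tables; a Kimura
2-parameter option is provided for sensitivity), with between-group means
over cross-group pairs, within-group means over intra-group pairs
(singleton groups flagged not-applicable), and standard errors from 1000
seeded bootstrap resamples of alignment columns.

## Trees

NJ (with negative branch lengths clamped to zero and the deficit moved to
the sibling) and UPGMA are the tree builders; the CBC count matrix feeds
UPGMA to produce the CBC tree. Bootstrap support resamples alignment
columns, rebuilds the distance tree per replicate, and reports the
percentage of replicates containing each internal bipartition; runs are
deterministic per seed. Full maximum-likelihood search and model selection
are deliberately out of scope - the alignment writers emit files external
ML tools accept, and their Newick results can be read back for comparison
(`read_newick()`, `rf_distance()`).

## The simulator and what passing tests mean

`generate_family()` evolves a root built from the packaged templates along
a random (or supplied) tree rescaled to a total branch length of 5. Event
counts per branch and class are Poisson with mean rate x branch length;
sites are sampled **without replacement globally across the whole tree**,
so each alignment site carries at most one event. That choice makes planted
counts exactly recoverable from leaf comparisons - the property the
validation suite asserts - at the cost of ignoring multiple hits; rates high
enough to exhaust a site pool are an error advising lower rates, which is
the simulator's version of a collision bound.

Default conditions, chosen once: 12 taxa; rates per unit branch length
CBC 1.2, hCBC 6, pair-breaking Nst 9, loop Nst 9, loop indel 0.8,
pseudogene 0 - i.e. an expected family-wide budget of about 6 CBCs, 30
hCBCs, 90 Nsts and 4 indels, the tribe-scale event budget compressed to
desk size. The root 5.8S length is drawn from {160, 161, 162} (the observed
range); deletions are confined to the spacers because the 5.8S is
length-invariant at this scale; insertions fill a small set of latent loop
slots so the true alignment is defined a priori. Motif blocks are immutable
unless a pseudogene event fires, which ablates 5.8S Motif I and flags all
descendant leaves.

What the simulator does **not** emulate: rate heterogeneity among lineages
and sites, realistic indel length distributions, multiple hits at one site,
recombination/concerted-evolution artifacts, and sequencing error. Passing
the planted-recovery suite therefore shows the *bookkeeping and
classification machinery* is exact, not that real ITS families satisfy
these assumptions.

`make_toy_cbc_set()` is deterministic micro-data: one exemplar per
published taxon/clade, identical everywhere except the five printed paired
positions (39/70, 47/64, 85/113, 97/101, 148/186) carrying the printed
states, so the published CBC/hCBC calls can be reproduced verbatim.

## Problem sizes used by the validation suite

The test suite and the acceptance script run on families of 5-12 taxa,
folding batteries of sequences up to 14 nt (where exhaustive enumeration is
the oracle), 1000-structure round-trip batteries, and bootstrap runs of
25-1000 replicates; these sizes exercise every code path while keeping a
full run in minutes on one core. The published dataset (about 200
accessions) is supported through replication mode - `run_pipeline()` with a
user FASTA and group map - but its headline numbers depend on those
sequences and manual alignment choices and are not asserted by the tests.

## Known limitations

* The internal folding score is not a thermodynamic energy; structures
  competitive under the full nearest-neighbor model may differ.
* Annotation presumes the conserved anchors; heavily diverged or truncated
  amplicons are flagged unresolved rather than annotated.
* The progressive aligner does not realign (no iterative refinement), and
  simultaneous alignment-plus-folding is out of scope.
* Group-level unanimity makes event counts sensitive to single aberrant
  members by design (they surface as exceptions, as in the published
  tables).
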
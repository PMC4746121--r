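---
title: "Methods: circular granulovirus genome characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular granulovirus genome characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvannot)
```

This vignette documents the models, parameter choices and numerical
conventions behind each pipeline stage, the design of the synthetic-genome
generator, and what the passing test suite does and does not demonstrate
about real data.

## Coordinate conventions

All coordinates are 1-based inclusive on the plus strand (GenBank
convention). A feature spanning the origin of a circular genome is stored
"unwrapped": `start` lies in `[1, L]` and `end` may exceed `L`, which keeps
interval arithmetic linear; the GFF3 writer splits such features into two
segments sharing an `ID`. `rotate_to_anchor()` re-anchors the coordinate
system at the ATG of a named gene (granulin by convention), reverse-
complementing first if the anchor lies on the minus strand, so ORF numbering
is always clockwise from granulin regardless of how the record was
deposited.

## ORF calling

An ORF is a methionine-initiated reading frame: ATG to the nearest in-frame
stop (`TAA`/`TAG`/`TGA`), scanned in all six frames with wrap-around across
the origin (an ORF may wrap at most once). For each stop only the longest
candidate (5'-most ATG since the previous stop) is kept. Alternative starts
(GTG/TTG) are not considered.

Two conventions needed fixing where genome reports are typically silent:

* **Length filter.** "At least 150 nt (50 aa)" equates 150 nt with 50
  codons, so by default the filter applies to the coding span ATG..last
  sense codon (a 50-codon ORF passes at a 153-nt total span including its
  stop). `orf_config(count_stop_in_min_len = TRUE)` switches to the other
  reading; the two differ by one codon.
* **"Minimal overlap".** Resolved as longest-first greedy selection: sort
  candidates by decreasing span (ties: earlier start, then plus strand) and
  accept a candidate iff it overlaps every already-accepted ORF by at most
  `max_allowed_overlap_nt` (default 30 nt — granulovirus ORFs often overlap
  by a few codons, and small nonzero allowances change counts by only a few
  ORFs). The allowance is a config knob because published ORF counts from
  annotation servers plus manual curation are not exactly reproducible by
  any single mechanical rule.

Derived statistics are straightforward: the orientation split counts strands
relative to the anchor ORF (anchor counted as "same"); coding density is the
union of ORF spans over the genome length (overlaps counted once; invariant
under rotation); intergenic regions are the complementary gaps on the
circle, with AT content over `{A,T}/{A,C,G,T}` (N excluded); amino-acid
lengths are `(span − 3)/3`, excluding the stop.

## Composition

`gc_content()` excludes `N` from numerator and denominator and errors on
all-N input. `gc_skew_profile()` uses sliding windows that wrap the origin
(default window 1000 nt, step 100 nt — common choices for ~100 kb genomes;
no published convention exists). Skew is `(G − C)/(G + C)` (the sign
convention is recorded in the output); a window with `G + C = 0` is recorded
as skew 0 with a flag. The cumulative skew is a running sum of per-window
`G − C` counts; its minimum and maximum are reported as candidate
replication origin and terminus. No formal origin prediction beyond these
extrema is attempted.

## Promoter-motif scanning

The default motif set is late `TTAAG` and `GATA`, early `CAKT` and
`TATAWAW` (IUPAC codes `K = G/T`, `W = A/T`); the motif table is an ordinary
data frame and fully user-editable, since inventories vary between reports
(in particular whether `GATA` or a `DTAAG`-family motif is meant by a "late"
motif). Matching uses `Biostrings::matchPattern(fixed = "subject")`, so
degeneracy applies to the pattern only.

For each ORF the `window_nt` bases 5' of its ATG on the coding strand are
scanned (default 120 nt, comfortably covering reported offsets such as 8 and
57 nt), on both the window and its reverse complement (template strand),
because early elements are reported on either strand. **Offset convention:**
`offset_nt` is the number of bases strictly between the motif's 3' end and
the A of the ATG, so a motif immediately adjacent to the start codon has
offset 0. This convention is stated prominently because upstream distances
in the literature rarely define whether they include the motif; a
template-strand hit is assigned the offset of the equivalent coding-strand
hit of the reverse-complemented pattern, which makes hits strand-symmetric.
`matched_literal` always reads on the genome plus strand.

## Tandem repeats

`find_tandem_repeats()` is a transparent period-scan rather than a
re-implementation of a published scoring scheme: for each unit length `u`
the sequence is compared against itself shifted by `u`; stretches of the
match vector seeded at runs of at least 5 consecutive matches are extended
greedily while identity stays above `min_identity`, then trimmed to the
best-scoring sub-segment under a match `+1` / mismatch `−5` weighting. The
trimming step is what pins array boundaries: greedy extension alone creeps
into flanking sequence whenever a few chance matches follow the array, which
for short units corrupts the copy number. With weight 5, boundary creep
requires at least six consecutive chance matches after a mismatch
(probability ~`0.27^6` per boundary on random DNA), so copy numbers of
planted perfect arrays are recovered to the reported 0.1 resolution.

Copy number is the aligned span over the unit length, reported to 0.1;
fractional final copies arise naturally (a 37-nt span at unit 3 is 12.3
copies). Same-period overlapping calls are merged, and nested harmonics (a
unit-`2u` call over the same span at no better identity, or any larger-unit
call nested in a smaller-unit call, as with homopolymers) are suppressed in
favour of the smaller unit. Circular genomes are scanned on the doubled
sequence and second-copy duplicates discarded. Identity-fraction thresholds
were chosen over an alignment-score threshold deliberately: they make the
detector's behaviour predictable from binomial tail bounds (below), at the
cost that counts from score-based tools are only approximately reproduced.

Placement is `coding` when the call lies fully inside the ORF coverage,
`noncoding` when it overlaps none, `both` otherwise; the genome fraction is
the union of call spans over the genome length, in percent.

## Imperfect palindromes and hrs

A palindrome call is a pair of arms that reverse-complement each other up to
`max_mismatch` substitutions around a loop of up to `max_loop` nt. For every
(centre, loop) pair the arms are extended outwards; a call is *maximal* when
the next outer pair would push the mismatch count past the budget (or run
off the sequence). All maximal calls are enumerated (the compiled scanner is
exactly equal to a brute-force enumeration over all centre/arm/loop
triples); `dedupe = TRUE` collapses overlapping calls to one per locus,
keeping the longest arm.

`cluster_hrs()` operationalises hrs as single-linkage clusters of palindrome
spans along the circle (gap at most `cluster_gap`, default 1000 nt; at least
`min_cluster = 2` members), numbered `hr1…` clockwise from position 1, with
AT content computed over the region span.

**Genome-scale specificity.** The permissive scanner defaults (arm ≥ 8, ≤ 2
mismatches) are right for inspecting a candidate locus but not for scanning
a 112-kb genome: the expected number of chance maximal calls at arm 8 is of
order 10^3–10^4 per 100 kb (binomial tail `P(≥ a−2 of a pairs match)` at a
pairing probability of 0.25–0.3, times centres × loop lengths), which would
fuse the entire genome into one "cluster". `find_hrs()` therefore uses a
genome-scale profile, arm ≥ 20 with ≤ 2 mismatches, for which the same
calculation gives an expectation well below 0.1 chance calls per 100 kb even
in AT-rich tracts (pairing probability ≈ 0.4). The same reasoning sets the
pipeline's tandem-repeat profile (`min_len` 30, identity 0.85): at the
scanner's own defaults (24/0.80) the expected chance-call rate on i.i.d.
sequence is of order one call per 50–100 kb (dominated by unit lengths 7–9,
where the 24-nt minimum span allows only ~16 comparisons), while at 30/0.85
it drops below 0.05 per 100 kb. Real hr palindromes in granuloviruses are
long (arms of 20–40 nt around a conserved ~10-bp core), so the stricter
profile does not cost sensitivity there.

## Protein features

Translation uses the standard genetic code via Biostrings (minus-strand and
origin-wrapping ORFs handled through the same circular extraction); internal
stops are errors naming the codon. Molecular weights use the standard
average (not monoisotopic) residue masses plus one water, matching how
protein sizes are quoted in kDa in genome reports; an `X` residue is
tolerated only on request, at mass 0. The initiator methionine is included.

`find_cys_motif()` enumerates every cysteine sextuple whose five spacers lie
in the peritrophin-A ranges, overlapping matches included — two adjacent
CBM_14 domains legitimately admit "bridge" sextuples reusing cysteines of
both, so the per-protein *domain count* is defined as the maximal chain of
non-overlapping hits selected greedily from the N-terminus
(`count_cys_domains()`), which reports 2 for a double-domain chitin-binding
protein. Homopolymer (e.g. poly-Q) runs are maximal runs of one residue of a
minimum length.

## Synteny and core genes

Ortholog pairing replaces translated-nucleotide database searches with
reciprocal-best local protein alignment (Smith–Waterman, BLOSUM62, gap open
11 / extend 1); similarity is identities over alignment length, and only
mutual best hits above `min_similarity` are kept, so the table is
one-to-one. Synteny blocks are maximal runs of ortholog pairs monotone in
both genomes' serials, allowing up to `max_gap_genes` skipped genes on
either side (default 2, absorbing lineage-specific insertions/deletions;
use 0 when exact block boundaries matter, as the tests do); descending runs
are inversions; block spans are the hulls of member gene coordinates. Every
pair belongs to exactly one block. The 37-name core-gene reference shipped
in `inst/extdata/core_genes.tsv` is a curated inventory of the genes
conserved across the family (replication, transcription,
packaging/assembly, oral infectivity), with aliases; the audit is
label-based and case/punctuation-insensitive. Repeated families (`bro`) are
suffixed `-a`, `-b`, … by ascending serial.

## Distance phylogenies

`progressive_align()` is a classic progressive aligner: 3-mer distances feed
a UPGMA guide tree; profiles are merged by global profile–profile
Needleman–Wunsch (BLOSUM62, affine gaps open 10 / extend 0.5, column scores
averaged over residue pairs with gap pairs at 0). It is adequate for the
conserved markers used here, not a replacement for a production MSA tool.

Distances use pairwise deletion (gap columns dropped per pair) with either
the raw p-distance or the Poisson correction `−ln(1 − p)` (default). The
published analyses this pipeline mirrors do not state their distance
options, so Poisson + pairwise deletion — the common default for conserved
protein markers — was chosen, and both knobs are switchable. A saturated
pair (`p = 1`) or a pair with no comparable sites is an error rather than an
arbitrary large distance.

`nj_tree()` is the canonical Saitou–Nei algorithm (Q-criterion, standard
distance update, three-point closing formulas) and `upgma_tree()` is
average linkage with ultrametric heights; both break ties deterministically
by the lexicographically smallest taxon pair so results are exactly
reproducible. On additive matrices NJ recovers the generating tree exactly
(branch lengths included); UPGMA output is ultrametric to numerical
precision. Negative branch lengths (possible on non-additive data) are
clamped to 0 when the tree is written. Bootstrap support resamples alignment
columns with replacement under a local seeded RNG (the caller's RNG state is
untouched), builds a replicate tree per draw, and reports the fraction of
replicates containing each internal bipartition of the full-data tree; taxa
are sorted internally so supports are invariant to input order. For
identical sequences every replicate yields the same (arbitrary,
lexicographically tie-broken) topology, so supports are 1 by construction —
the documented convention for that degenerate case.

A genus-wide tree on concatenated polh/gran + lef-8 + lef-9 needs the marker
proteins of the other sequenced baculoviruses and is therefore a documented
workflow (README) rather than a test: the bootstrap machinery itself is
exercised on synthetic two-clade data, where both clades must reach ≥ 0.95
support at 200 replicates.

## The synthetic-genome generator

`simulate_genome()` produces the study conditions: a 112,000-nt circle at
35.2% GC carrying 130 ATG-initiated ORFs (anchor gene at position 1 on the
plus strand, ~53% of genes on the anchor strand, gene lengths 60–404 codons
plus a 1162-aa helicase-like gene), planted promoter motifs at recorded
upstream offsets (late `TTAAG` at 8 nt including one on a chitin-binding-
like gene, early `TATAAAT` at 57 nt, `GATA` and `CAGT` elsewhere), twelve
tandem arrays — a coding (CAG)12.3 array, a coding (CAA)13 poly-Q array and
ten AT-rich noncoding arrays of units 7–38 nt with fractional copies — and
six AT-rich hr cassettes totalling 27 imperfect palindromes (arm 22, loop 5,
1 mismatch), the largest (11 palindromes) in a 757-nt intergenic gap. The
chitin-binding-like gene carries exactly two six-cysteine domains
(spacers 13/5/9/10/13) and the 13-residue poly-Q run. Core-gene labels are
assigned to 37 genes and two genes are labelled `bro` for the naming and
audit operations.

What makes the generator useful is that recovery is guaranteed by
construction, not by hope:

* **No spurious ORFs.** Intergenic spacers are free of `ATG`/`CAT` outside
  planted features; every gene has an in-frame *guard stop* a few bases
  upstream of its ATG (so no upstream in-frame ATG can extend a candidate);
  and a genome-wide repair pass breaks every stop-free stretch of ≥ 141 nt
  in all six frames that is not a planted gene, by writing stop codons into
  free spacer positions or substituting sense codons inside genes (never
  touching planted feature codons, never erasing a stop another frame
  depends on). Since a callable ORF needs a 153-nt stop-free span, planted
  genes are the only candidates, and ORF sensitivity and precision are
  exactly 1.
* **Exact repeat boundaries.** Planted arrays carry anti-match flanking
  bases that break the periodicity at both ends, so detected copy numbers
  equal the planted ones; array units are stop-seeded (`TAA`, `TTA`) and
  verified palindrome-free before planting.
* **Exactly the planted palindromes.** Each hr cassette is verified to
  yield one deduplicated call per planted palindrome under a scan stricter
  than the pipeline's, and a final genome-level pass breaks any chance
  inverted repeat elsewhere (three pairs of its inner arm are mutated, under
  the same stop- and ATG-preserving constraints).
* **Composition.** After assembly the GC content is tuned to the target by
  flipping free spacer bases that are not part of any stop triplet on either
  strand, so the open-frame guarantees survive the adjustment.

Everything is driven by one seeded RNG; the same seed gives a byte-identical
genome.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic codon usage or amino-acid composition
(gene bodies are i.i.d. sense codons); homologous gene families and
paralogs; degenerate, mutation-riddled tandem repeats (planted arrays are
perfect, so detector sensitivity on 80%-identity repeats is exercised only
by the identity threshold, not measured against truth); hr palindromes with
conserved cores shared *between* regions; overlapping genes; and the
coding-density fine structure of real GV genomes (planted density is ~0.84 ±
sampling noise versus 0.85 in the motivating genome). Accession-based checks
against the deposited CnmeGV record cover that ground when the record is
available (README).

## Problem sizes and tolerances

The test suite uses 30-kb / 30-gene genomes for module-level integration
(about 3 s each to generate) and the full 112-kb default genome once, in
the end-to-end recovery test; oracle comparisons use 50 random 2-kb circles
(ORF enumeration), 20 random 300-mers (palindromes), 100 random trees of up
to 12 taxa (NJ additivity, checked at 10^−8) and 20 random matrices (UPGMA
ultrametricity, 10^−9). `scripts/acceptance.R` regenerates the full genome
from the given seed and recomputes every reported quantity; it runs in a few
minutes on one CPU. Copy numbers are asserted to 0.1 (their reporting
resolution, with 0.2 tolerated for boundary effects); molecular weights to
0.05 Da against an independent implementation; distances and branch lengths
to closed forms where they exist.

## Known limitations

* The ORF-count reproduction for a real record depends on the undocumented
  overlap rule of the original curation; the greedy rule with a 30-nt
  allowance is expected to land within a few ORFs, not exactly.
* The tandem-repeat detector's identity-threshold formulation will not
  reproduce score-based tools call-for-call on degenerate repeats.
* `pair_orthologs()` is all-vs-all Smith–Waterman; for proteomes beyond a
  few hundred proteins a k-mer prefilter would be needed.
* The progressive aligner has no iterative refinement; for publication
  phylogenies align markers with a dedicated MSA tool and feed the result to
  `distance_matrix()`/`bootstrap_support()` as a `protein_msa`.
* Linear (non-circular) genomes are supported throughout, but upstream
  windows at contig ends are truncated (flagged in the scan output).
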
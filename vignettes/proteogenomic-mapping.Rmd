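---
title: "Mapping peptides to a genome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping peptides to a genome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmapr)
```

## The problem

Bottom-up proteomics identifies peptides — short tryptic fragments of
expressed proteins. Placing those peptides at exact genomic coordinates
turns them into annotation evidence: a peptide strictly inside a
High-Confidence (HC) gene validates that model; peptides inside
Low-Confidence (LC) models argue for promotion; peptides contained in no
annotated gene ("novel" or orphan peptides) point at unannotated coding
regions. `pepmapr` implements the full loop — translated search, exact
spliced coordinate conversion, classification, evaluation, export — plus a
synthetic-data generator that makes every step testable against exact
ground truth.

## Translated local alignment

### Model

Each peptide is aligned against all six reading-frame translations of each
contig by Smith–Waterman local alignment with affine gaps (Gotoh
three-state dynamic programming, implemented in C++). We deliberately skip
word seeding: at the scale this package targets (kilobase-to-megabase
fixtures, thousands of peptides) exact DP is affordable, and seeding could
only lose alignments, never gain them.

Gap costs use the NCBI convention: a gap of length $g$ costs
$\mathrm{open} + g \cdot \mathrm{extend}$, so "existence 10, extension 1"
charges 11 for the first gapped column. This matters when comparing
configurations: the bundled default (PAM30 with 10/1) is the combination
that won a 12-configuration optimization experiment on a multi-exon test
gene, and the same 12 configurations ship as
`default_sweep_configs()`.

Ties between equally scoring alignments are broken deterministically: the
end cell is the first encountered scanning query then subject positions in
ascending order, and traceback prefers stopping, then diagonal moves, then
closing a gap over extending one. Determinism — not any particular
co-optimal choice — is the contract.

### Statistics

E-values follow Karlin–Altschul: $E = K \cdot m \cdot n \cdot
e^{-\lambda S}$ with $m$ the peptide length (AA) and $n$ the total
database length (nt). Gapped $\lambda$ and $K$ cannot be derived
analytically; the bundled table (`inst/extdata/ka_constants.tsv`) carries
the values NCBI tblastn 2.17 reports for each supported (matrix,
gap-cost) combination, with each matrix's ungapped (ideal) parameters as a
warned fallback. No effective-length edge correction is applied: the
package's filters and every test operate on score ranking and generous
e-value cutoffs, so absolute e-values only need to be on the right scale.
Composition-based statistics (which production BLAST applies by default)
are out of scope, so e-values from this package and from a BLAST run are
not directly comparable — nothing in the package's contracts depends on
such a comparison.

### Filters

A hit is reported when its e-value is at or below the cutoff **and** its
query coverage $100(q_{end}-q_{start}+1)/q_{len}$ meets the minimum. Per
(peptide, contig) the best `max_hsps_per_target` HSPs are kept (at most
one per frame — each frame's DP yields its single best local alignment),
then the best `max_target_seqs` contigs. There is no identity floor:
observed hits run well below 100% identity once gaps appear, and that is
informative, not noise. Defaults (PAM30, 10/1, e-value 0.01, 3 targets,
1 HSP, 25% coverage) mirror the optimized production run and are asserted
by a snapshot test.

## Frames, introns and spliced coordinates

Genomic frames follow the BLAST convention: `+k` reads the forward strand
from offset $k-1$; `-k` reads the reverse complement from offset $k-1$,
which anchors minus-strand frames at the contig *end*. Minus-strand hits
are reported with `sstart > send` (coordinate order encodes strand, as in
BLAST tabular output); downstream writers normalize.

A peptide occupying protein positions $[a, b]$ of a gene corresponds to
CDS nucleotides $[3a-2, 3b]$. `map_peptide_to_genome()` walks that
interval through the exons in transcription order, emitting one genomic
block per exon touched; on the minus strand blocks are computed from exon
ends. The invariant — extracting the blocks, splicing them in
transcription order and translating reproduces the peptide exactly — is
enforced for 100% of generated peptides in the test suite.

An intron whose length is $\not\equiv 0 \pmod 3$ shifts the *genomic*
frame of all downstream exons even though the mRNA frame is continuous.
`exon_frames()` computes each exon's frame from its genomic phase and the
cumulative CDS length, and flags genes where frames differ. Single-frame
local alignment is blind across such junctions: the two sides of a
junction-crossing peptide live in different frame translations, so no
single HSP can cover the peptide. This reproduces, on synthetic fixtures,
the qualitative failure mode observed with production tBLASTn.

### Stitching across frame shifts

`stitch_frameshift()` reassembles junction-crossing peptides from their
per-frame partial hits: two hits of the same peptide on the same contig
and strand, in different frames, contiguous in the query and with
disjoint, consistently ordered genomic footprints within a configurable
genomic gap (default 10 kb, longer than the fixture's introns), merge into
a two-block mapping; chains merge transitively.

One design point deserves emphasis. A natural first rule is to require the
second hit to start within ±1 residue of where the first ends (a junction
can duplicate at most one residue). Empirically that rule is wrong:
Smith–Waterman ends *extend several residues into the intron* whenever the
chance alignment of intron-translated residues is net-positive, so the two
pieces of a junction peptide typically **overlap** in query coordinates —
we observed overlaps up to 9 residues on 18-residue peptides. The
implemented rule therefore tolerates any overlap (the genomic
disjointness, frame difference and ordering conditions carry the
specificity) and limits only *separation*, via `adjacency_tol` (default
1). With this rule, stitching recovers 100% of planted junction-crossing
peptides pooled over ten generator seeds, while strict single-frame search
recovers none. The known cost: a peptide genuinely present at two nearby
repeated loci in different frames would merge incorrectly; the synthetic
fixtures contain no such repeats, and real use should treat merged
mappings as hypotheses for inspection.

Note the search feeding the stitcher must keep at least two HSPs per
(peptide, contig) — with the production default of 1 HSP the second piece
is never reported, which is consistent with the production pipeline's
inability to map these peptides.

## Gene assignment

A hit (coordinates normalized to min/max) is contained in a gene when the
chromosome matches, the hit start is **strictly greater** than the gene
start and the hit end **strictly smaller** than the gene end. The strict
inequalities reproduce the reference pipeline's stated loop verbatim, even
though inclusive bounds would be more conventional; boundary-touching hits
are unassigned. If any containing gene is HC the category is HC, else LC,
else NOVEL — the HC-over-LC priority is implied by the disjoint HC/LC
accounting in the reference results and is our resolution of an
unspecified tie rule; all containing genes are retained in the output so
the decision is auditable. Among several containing genes of the winning
class, the smallest (most specific) span is reported. Containment is
computed with `GenomicRanges::findOverlaps`; the test suite checks it
against a brute-force scan over all genes on 1000+ random hits.

## Evaluation harness

`evaluate()` partitions peptides into correct / wrong / not-found against
ground truth: *correct* requires a hit on the true chromosome whose
footprint covers every true block within `tolerance_nt` (default 0 —
exact boundaries, since the reference comparison was done by eye in a
genome browser and states no tolerance); *wrong* means hits exist but none
qualifies; *not found* means no hit survived the filters. A true intron
counts as *found* when a correct hit carries an alignment gap whose
genomic span overlaps it; the gap denominator counts each (peptide,
crossed intron) pair, our reading of an ambiguous accounting in the
reference (which reports 7 countable gaps for 3 intron-spanning peptides).

`rank_sweep()` orders configurations by correct peptides, then detected
gaps, then elapsed time, with competition ranking for ties. The reference
table's printed rank column is *not* reproducible from its printed columns
(one gap-less configuration outranks a gap-finding one), so the
deterministic rule above is the package's contract and the printed ranks
are not an acceptance target. CPU time is recorded but never asserted.

Intron-length economics are worth understanding when reading results: a
bridged intron of length $L$ costs $\mathrm{open} + (L/3) \cdot
\mathrm{extend}$, so with 10/1 costs only introns up to roughly
$3 \times (\text{peptide match score} - \text{half-peptide score} - 10)$
are ever bridged. On default fixtures (introns 60–300 nt) about half the
intron-spanning peptides get gapped single hits and the rest partial
hits — mirroring the reference observation that gapped hits "only spanned
short introns". The acceptance check for gap structure therefore uses a
short-intron fixture (6–45 nt, all multiples of 3) where the gapped
optimum provably wins, and asserts exactly one gap opening of exactly
intron-length/3 columns.

## Physicochemical properties

Average (not monoisotopic) residue masses, the Kyte–Doolittle hydropathy
scale and a Bjellqvist-style pK set ship as data files; the isoelectric
point is solved by bisection of the Henderson–Hasselbalch net charge over
pH 4.05–12 (the ProtParam search window) to 1e-4 pH units. Frozen
reference values from the ProtParam lineage are asserted to 0.02 pH /
1e-4 Da in the tests. One subtlety: the Bjellqvist set overrides terminal
pKs for specific terminal residues, so *appending* D or E can legitimately
raise pI (the C-terminal pK weakens from 3.55 to 4.55/4.75); monotonicity
of the charge model is therefore tested with mid-sequence insertions.
The miss-risk flag marks peptides with GRAVY outside the open interval
(−2.2, 0.6), aromaticity above 0.14, or length below 8 — thresholds taken
from the observed physicochemistry of peptides that translated search
failed to map; the flag is correlational, not a prediction.

## The synthetic world

`synth_config()` defaults describe the world the tests run in: 3
chromosomes × 50 kb, 24 genes (75% HC), 2–5 exons of 60–180 nt (forced to
multiples of 3), introns of 60–300 nt with a quarter frame-shifting
(echoing a five-exon test gene with one shifted exon), 40% minus-strand
genes, 4 intergenic ORFs, complete tryptic digests (cleave after K/R
unless before P) at 8–30 AA, 3 tissue labels, no mutations. Where the
reference states no value, these were chosen once as plausible desk-scale
analogues of a real annotation and not revisited.

Generation is protein-first: each gene's protein is a concatenation of
tryptic peptides, with an "anchor" peptide deliberately laid across every
exon/exon junction (≥ 8 residues on each side) so that intron-spanning
and junction-crossing peptides exist whenever geometry allows — the
guarantees the acceptance checks rely on are constructed, not hoped for.
Proteins are reverse-translated with uniform synonymous codon choice;
exon/intron layouts are assembled locally and placed on chromosomes with
random spacing; minus-strand genes are reverse-complemented whole.
Ground-truth blocks are computed position-by-position from the local
layout — a deliberately different code path from `map_peptide_to_genome()`
— and the ultimate oracle is sequence identity: extract, splice,
translate, compare.

What the generator does *not* emulate: MS noise, FDR, charge states,
PTMs, I/L ambiguity (sequences are treated verbatim, matching the
upstream pipeline's deduplication), codon-usage bias, repeats/paralogs,
UTRs (CDS-only models by default), non-codon-aligned exon boundaries, and
genome-scale sizes. A green test therefore establishes algorithmic
correctness on clean inputs — coordinate exactness, filter soundness,
classification logic — not robustness to identification noise or
paralogy.

## Numerical conventions

* Percentages are stored at full precision; printed-precision comparisons
  round at the consumer. Footer SUM percentages are recomputed from summed
  numerators/denominators, never averaged. MIN/MAX/AVERAGE footers honour
  per-row exclusion flags (e.g. an unanchored-scaffold bin); SUM rows
  include all rows.
* Quartiles use linear interpolation between order statistics
  (`quantile type 7`, the default of both R and pandas).
* Correlation of constant columns is reported `NA`, never 0.
* BED output is 0-based half-open; scores clamp to [0, 1000]; BED12
  blocks are emitted in ascending genomic order. Records outside their
  contig are dropped with a warning.
* Empty inputs degrade to empty outputs (empty FASTA, empty hit tables,
  empty tissues) rather than errors; contigs shorter than one codon are
  skipped with a warning; zero-length frame translations are skipped
  silently.

## Known limitations

* Exact DP is quadratic; genome-scale searches need the seeded heuristics
  this package intentionally omits.
* E-values are classical Karlin–Altschul without composition-based or
  effective-length corrections.
* Only the first mRNA of a gene is used; isoforms, UTR-aware inference
  and annotation editing are out of scope.
* The stitcher can over-merge across nearby repeated loci (see above).
* pI is a model value (Bjellqvist pKs); other pK sets shift it by up to
  a few tenths of a pH unit.
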
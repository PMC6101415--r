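---
title: "Designing and validating species-diagnostic barcode assays with barcodeDx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating species-diagnostic barcode assays with barcodeDx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeDx)
```

`barcodeDx` turns a species-labeled barcode alignment into a working
multiplex PCR identification assay and validates it in silico. This
vignette explains the models and procedures behind each step, the
parameters that matter, the numerical choices, and what the packaged
synthetic data can and cannot demonstrate.

## The identification problem

A crude drug sold under one vernacular name may derive from several
species, only some of which are of concern (for Krai-Krue-type root drugs:
several *Aristolochia* species containing nephrotoxic aristolochic acids,
alongside harmless substitutes). Sequencing a barcode locus answers the
question definitively but is slow; a multiplex PCR whose band pattern reads
out the species on an agarose gel answers it in hours. The computational
problem is to find sequence differences that are *fixed* within each target
species and absent from everything else, and to turn them into primers that
only extend on their own species.

## Barcode descriptors

`gc_percent()` is `100·(G + C + S) / (non-gap bases)`. The ambiguity code
`S` (C or G) is certainly G/C and counts toward the numerator; every other
ambiguity code enters only the denominator. This keeps the statistic
deterministic on IUPAC input without guessing hidden bases.

`variation_percent()` is columnwise: the percentage of alignment columns
whose rows do not all share one identical state. The gap is a fifth state,
so a column with an indel in any row is variable — deliberately, because
indel-rich spacers like ITS2 owe most of their discriminating power to
insertions/deletions, and a substitution-only count would understate them.
Columns that are gap in every row (artifacts of subsetting) are excluded
from numerator and denominator. Percentages are reported half-up at two
decimals, the precision customary in barcode-comparison tables. On a
gap-free panel of eleven 1428 bp sequences with 47 variable columns this
yields 3.29%, the kind of value typical for rbcL at the genus level;
the indel treatment matters only for spacer loci.

A columnwise definition was chosen over mean pairwise difference because it
is invariant to how many individuals represent each species and reproduces
the conventional "number of variable sites / alignment length" summary.

## Built-in progressive alignment

External alignments (aligned FASTA, Clustal) are first-class inputs. When
none is supplied, `progressive_align()` builds one: optimal global pairwise
alignments with affine gaps (`gap of length k` costs
`gap_open + gap_extend·(k−1)`; defaults 1/−1/−4/−1, conventional DNA
scores) give p-distances, a UPGMA guide tree orders the merges, and
profiles are merged by globally aligning their majority consensus sequences
and propagating the inserted gap columns to every member row — once a gap,
always a gap. Records are processed in lexicographic id order and ties in
the consensus break to the alphabetically first base, so the result is
fully deterministic. The aligner targets desk-scale panels (tens of
records, loci up to a few kb); beyond that an external aligner is the right
tool, and its output is read back in unchanged. The guarantee the package
relies on — de-gapping any output row reproduces the input residues
exactly — is asserted by tests.

## Diagnostic motif detection

A column is diagnostic for species X when (i) every X row carries one
identical state and (ii) that state appears in no other row. Both halves
are deliberately strict:

- **Fixation.** A primer anchored on a polymorphic site would fail on part
  of the species. Where individuals differ at a handful of sites, the
  supported route is `species_consensus()` (majority per column; ties among
  bases become the IUPAC code of the tied set; gap wins only on strict
  majority), mirroring the common practice of designing markers from a
  within-species consensus. An optional `min_target_freq < 1` relaxes
  fixation for exploratory scans.
- **Ambiguity is conservative.** A non-target row with `Y` at a column
  where the target is fixed `T` *may* hide a T, so the column is rejected.
  Ambiguity in the target likewise never yields a candidate allele.

The gap is a legal diagnostic state (a species-private deletion is an
excellent marker), but a motif whose 3′-most state is a gap cannot anchor a
primer and is flagged accordingly. Coordinates are 1-based inclusive
alignment columns, the convention in which published diagnostic positions
are reported; they are always relative to the alignment actually used,
never portable across alignments.

## ARMS primer design

The allele-specific (ARMS) principle: a PCR primer whose 3′-terminal base
mismatches the template is not extended, so placing the 3′ terminus on the
diagnostic allele makes amplification itself the species test.

`design_species_primer()` walks left from the motif's 3′-most column over
the target-species consensus (skipping gap columns), and picks the shortest
length in `len_range` whose Wallace Tm (`2(A+T) + 4(G+C)`) lands in
`tm_range`; if none does, the length minimizing the window violation wins,
shortest on ties. The Wallace rule was chosen over nearest-neighbor
thermodynamics because it is exact arithmetic on 15–25-mers — adequate at
this scale, fully reproducible, and free of parameter tables; the default
Tm window 48–62 °C brackets a 52 °C multiplex annealing temperature.
Default constraints (length 15–25 nt, GC 30–80%, 3′ cross-complement ≤ 4,
band separation ≥ 30 bp) match published panels of 17–21 nt primers with
68/74/135 bp band gaps.

The universal control pair comes from the leftmost and rightmost fully
conserved windows, so the control amplicon spans the variable core and
every species amplicon nests inside it. The internal control separates
"non-target plant" (control band only) from "no/failed template" (no band)
— without it the two are indistinguishable on a gel.

`panel_check()` is report-only: pairwise band separations, the maximal
3′-terminal complementarity run between every primer pair (a proxy for
primer-dimer formation at the extensible ends), and Tm spread.

## In-silico PCR and the decision rule

`find_binding_sites()` scans both strands for footprints with at most
`max_total_mismatches` Hamming mismatches whose 3′-terminal
`seed_3prime_len` bases match exactly. Template IUPAC ambiguity matches a
primer base iff the ambiguity set contains it. The defaults (2 mismatches,
4-base seed, 2 kb maximum product) encode the ARMS observation that
discrimination is dominated by 3′ mismatches; body mismatches mostly cost
efficiency, which the model does not track. Amplification is
presence/absence only — concentrations, efficiency and band intensity are
out of scope, because the assay readout is qualitative.

Every plus-strand site pairing with a minus-strand site entirely 3′ of it
(within the length cap) yields an amplicon of `end − start + 1` bp.
Identically sized products co-migrate and collapse to one band in the lane;
the amplicon table keeps them all. Templates sharing a sample id are pooled
into one lane, emulating mixed genomic DNA. `call_species()` then applies
the decision table (species call only when the control matched and exactly
one species band matched, at a relative size tolerance of 10% — generous on
a 1.7% agarose gel where the designed bands differ by ≥ 28%). Virtual gel
rendering uses the standard semi-log migration model
`a − b·log10(length)`.

## K2P distances, neighbor-joining, bootstrap

Pairwise distances use the Kimura two-parameter closed form
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with transitions {A↔G, C↔T} and
everything else a transversion. Columns where either row is gapped or
ambiguous are deleted *pairwise*, not listwise — listwise deletion would
discard most of an indel-rich spacer alignment. Saturated pairs (either
logarithm argument ≤ 0) raise a distinct error rather than returning
infinity. Tests cross-check the matrix against an independent K80
implementation.

Tree building is Saitou–Nei neighbor-joining (via `ape::nj`), a deliberate
substitution for likelihood tree search: NJ is fully specified,
deterministic and desk-verifiable, and the claims this package supports
(deep ingroup/outgroup splits, species clusters) are distance-recoverable.
Negative branch lengths — an NJ artifact on noisy distances — are clamped
to zero. Bootstrap resamples alignment columns with replacement,
re-distances, re-joins, and reports for each internal bipartition of the
original tree the percentage of replicates containing it; R's default
Mersenne-Twister generator seeded once makes runs reproducible.
`is_monophyletic()` is rooting-free: a group is monophyletic iff some edge
bipartition separates exactly that group.

Likelihood-specific support values from published analyses are not
reproduction targets; only structure that dominates the signal (e.g. a
genus against family-level outgroups) is expected to carry over at 100%.

## The synthetic panel simulator

`simulate_panel()` emulates what the assay exploits in real data: a shared
ancestral locus, species-private fixed motifs (substitutions or
deletions), conserved anchor blocks for control primers, background
interspecific divergence, and intraspecific noise. Two design choices make
truth bookkeeping *exact* rather than approximate:

- Background divergence is planted as two-group column patterns with each
  allele carried by at least two species, which requires ≥ 4 species; with
  2–3 species background substitutions modify the shared ancestor instead.
  Either way no background column is ever species-private, so the planted
  motifs are provably the complete set of diagnostic columns.
- Intraspecific noise never hits conserved blocks or planted motif columns:
  a planted motif is fixed within its species *by definition* (that is what
  "diagnostic" means), and anchors are conserved by definition.

Consequently, at `intra_rate = 0` the diagnostic scan must achieve recall
1.0 with zero false discoveries — asserted over 100 seeded replicates —
and with noise the simulator still reports honest truth for everything it
planted. Defaults (4 species × 3 individuals, 600 bp, intraspecific rate
0, background rate 0.02/column) are in the range of a congeneric barcode
panel; observed intraspecific p-distances match the two-process expectation
`2r(1−r) + ⅔r²` within three standard errors on large fixtures.

What the simulator does **not** model: rDNA concerted evolution and
paralogy, alignment error (its alignments are exact by construction),
sequencing error, heterozygous double peaks, and length heteroplasmy.
Passing on fixtures therefore demonstrates the correctness of the assay
*logic*, not robustness to alignment or data-quality pathology in field
material — external alignments and the consensus tools are the mitigation
for that.

## The packaged demo

`krai_krue_demo()` ships a committed 800-column ITS2-like panel (three
target species plus one non-target substitute, two individuals each,
generating seed recorded; a test regenerates it from scratch and asserts
identity). Control anchors sit at columns 361–380 and 741–760 — the reverse
anchor carries the annealing site of the classic universal ITS4 primer —
and one private substitution motif per species ends at columns 657, 589 and
515 with widths 1, 2 and 3. Primer windows are crafted so the Wallace rule
selects 20-mers (G/C at five fixed window positions, giving Tm(19) = 46 <
48 ≤ Tm(20) = 50), and candidate windows are redrawn until free of 3′
cross-dimers against the rest of the panel, as any designer would iterate.
Geometry then fixes the band sizes: 123, 191 and 265 bp species bands
nested in a 400 bp control — the architecture of the published pentaplex
assay this demo emulates, realized on synthetic sequence. The demo's
intraspecific rate is 0: it isolates assay logic; noise behavior is covered
by the simulator tests.

The control pair is taken from the planted anchors rather than re-derived,
mirroring real assays where the universal control primers pre-exist the
species panel.

## Numerical and interface conventions

- Coordinates 1-based inclusive everywhere; gap normalized to `-` on input
  (`.`, `~` accepted); residues upper-cased.
- Errors are classed conditions (`barcodeDx_format_error`,
  `barcodeDx_no_primer_error`, `barcodeDx_saturation_error`, ...) so
  callers can branch on failure mode; validation errors name the record and
  offset.
- Deterministic tie-breaks throughout: lexicographic ids in the guide tree,
  alphabetically first base in consensus ties, shortest qualifying primer.
- Problem sizes in the shipped tests and acceptance script (panels of 4–13
  taxa, loci of 120–1428 columns, 100 simulation replicates, 1,000
  bootstrap replicates) were chosen as the smallest sizes at which each
  property is non-trivial; all complete in a couple of minutes on one core.

## Known limitations

- Wallace Tm ignores salt and neighbor effects; fine for ranking 15–25-mers,
  not for absolute temperature prediction.
- Hairpin screening is limited to 3′ cross-complementarity runs; full
  secondary-structure thermodynamics is out of scope.
- The in-silico PCR is qualitative and linear-template only.
- NJ topologies on near-tied distances depend on tie-breaking; bootstrap
  support is the intended guard against over-reading them.
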
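# barcodeDx

Species-diagnostic DNA-barcoding assays from labeled alignments.

Herbal crude drugs are routinely traded under vernacular names that cover
several look-alike botanical sources — some of them toxic, such as
aristolochic-acid-bearing *Aristolochia* roots sold as "Krai-Krue". Telling
those species apart from dried root fragments is impossible morphologically
but straightforward from DNA barcodes (rbcL, matK, ITS2, trnH-psbA).
`barcodeDx` implements the complete desk side of such an assay for
molecular taxonomists and pharmacognosists:

1. **Barcode characterization** — per-species ungapped length and GC
   content, and the panel-level percent variation of a locus: the fraction
   of alignment columns whose states are not identical across all rows,
   with the gap counted as a fifth state so indel-rich spacers (ITS2) score
   high, and all-gap columns dropped.
2. **Diagnostic motif detection** — alignment columns whose state is fixed
   within one species and absent from every other species (gap allowed as a
   diagnostic state; non-target IUPAC ambiguity overlapping the candidate
   allele vetoes it). Adjacent diagnostic columns merge into multi-base
   motifs.
3. **ARMS multiplex primer design** — species-specific forward primers
   whose 3′ terminus sits exactly on a diagnostic allele (so mismatched
   templates fail to extend), a universal internal-control pair drawn from
   conserved windows flanking the variable core, Wallace-rule Tm
   (`2(A+T) + 4(G+C)`), and a multiplex compatibility report (band
   separation, 3′ cross-dimers, Tm spread).
4. **In-silico PCR and species calling** — binding-site search under a
   mismatch model with an exact-match 3′ seed, amplicon prediction, virtual
   gel rendering, and the band-pattern decision rule: control + one species
   band → that species; control only → `NON_TARGET`; no control →
   `NO_AMPLIFICATION`; control + several species bands →
   `AMBIGUOUS_MIXTURE`.
5. **Distance phylogenetics** — Kimura two-parameter distances
   `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` (P transitions, Q transversions,
   pairwise deletion), neighbor-joining trees, nonparametric bootstrap
   support, and a rooting-free monophyly test.
6. **Synthetic panels with planted truth** — a seeded simulator that plants
   species-private motifs, conserved anchors, background divergence and
   intraspecific noise, so the whole pipeline is testable end to end with
   no downloads.

## Worked example

The package ships a small synthetic three-species demo panel (plus one
non-target substitute species) whose planted motif layout reproduces the
band architecture of a published pentaplex Krai-Krue assay:

```r
library(barcodeDx)

demo <- krai_krue_demo()
diagnostic_report(demo$alignment)$motifs
#>          target_species start end target_allele background fixed_in_target
#> 1 Aristolochia_pothieri   657 657             C          G            TRUE
#> 2  Aristolochia_pierrei   588 589            TG         AC            TRUE
#> 3   Aristolochia_tagala   513 515           AAC        TTG            TRUE

demo$primer_panel
#> <primer_panel> 5 primers; control 400 bp; bands: Aristolochia_pothieri=123,
#>   Aristolochia_pierrei=191, Aristolochia_tagala=265

res <- multiplex_pcr(demo$primer_panel, demo$panel)
call_species(res$lanes[["Aristolochia_pierrei_ind01"]], demo$primer_panel)
#> <species_call> Aristolochia_pierrei_ind01: [400,191] -> Aristolochia_pierrei
```

Each species yields its private band (123, 191 or 265 bp) together with the
400 bp internal control; a lane showing only the control is a non-target
plant, and a lane with no control at all is a failed/absent template —
the two cases a qualitative gel must keep apart.

The same objects feed the phylogenetic layer:

```r
cons <- species_consensus(demo$alignment)
round(distance_matrix(cons), 4)
#>                       Aristolochia_pothieri Aristolochia_pierrei ...
#> Aristolochia_pothieri                0.0000               0.0038
#> ...
tree <- bootstrap_support(demo$alignment, replicates = 100, seed = 1)
write_newick(tree, "demo.nwk")
```

A thin command-line wrapper (`exec/barcodeDx`) exposes the same pipeline as
subcommands `stats`, `align`, `diagnose`, `design`, `ispcr`, `gel`, `dist`,
`nj` and `simulate`.

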
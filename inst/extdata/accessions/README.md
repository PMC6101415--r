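# Optional accession FASTA drop-in

The package never fetches sequences over the network. To run the
paper-reproduction checks against the deposited GenBank records, place
plain FASTA files here (headers `accession|species|locus`, or supply a
label map):

- `its2_accessions.fasta` — ITS records KP998797 (A. pothieri), KP998796
  (A. pierrei), KP998800 (A. tagala). Used with
  `extdata/published_panel.tsv` for the multiplex band check
  (123 / 191 / 265 bp + 400 bp control). Records trimmed short of the
  ITS4 annealing site are reported as truncated.
- `rbcl_accessions.fasta` — the eleven full-length rbcL records
  (KP903720, KP998764–KP998773) for the 3.29% variation check.
- `rbcl_matk_combined.fasta` — combined rbcL+matK alignment rows for the
  eleven taxa plus the Thottea outgroups (rbcL AB205604/AB205606, matK
  JN415668/JN415674) for the monophyly-under-bootstrap check.

When a file is absent the corresponding checks run on the packaged
synthetic panels instead.
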
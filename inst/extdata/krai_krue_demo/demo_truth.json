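{
  "motifs": [
    {
      "target_species": "Aristolochia_pothieri",
      "start": 657,
      "end": 657,
      "type": "sub",
      "target_allele": "C"
    },
    {
      "target_species": "Aristolochia_pierrei",
      "start": 588,
      "end": 589,
      "type": "sub",
      "target_allele": "TG"
    },
    {
      "target_species": "Aristolochia_tagala",
      "start": 513,
      "end": 515,
      "type": "sub",
      "target_allele": "AAC"
    }
  ],
  "conserved_blocks": [
    {
      "start": 361,
      "end": 380
    },
    {
      "start": 741,
      "end": 760
    }
  ],
  "species": ["Aristolochia_pothieri", "Aristolochia_pierrei", "Aristolochia_tagala", "Jasminum_substitute"],
  "target_species": ["Aristolochia_pothieri", "Aristolochia_pierrei", "Aristolochia_tagala"],
  "seed": 20180801
}
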
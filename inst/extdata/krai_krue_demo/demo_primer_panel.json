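{
  "primers": [
    {
      "name": "Aristolochia_pothieri-dxF",
      "sequence": "CAAAAGAATTCAAATGAAAC",
      "orientation": "forward",
      "role": "species_specific",
      "target_species": "Aristolochia_pothieri",
      "specific_3prime_len": 1,
      "tm_wallace": 50,
      "gc_percent": 25
    },
    {
      "name": "Aristolochia_pierrei-dxF",
      "sequence": "GAATTCTAAAGTTATCTTTG",
      "orientation": "forward",
      "role": "species_specific",
      "target_species": "Aristolochia_pierrei",
      "specific_3prime_len": 2,
      "tm_wallace": 50,
      "gc_percent": 25
    },
    {
      "name": "Aristolochia_tagala-dxF",
      "sequence": "GAATACTTTACATATGAAAC",
      "orientation": "forward",
      "role": "species_specific",
      "target_species": "Aristolochia_tagala",
      "specific_3prime_len": 3,
      "tm_wallace": 50,
      "gc_percent": 25
    },
    {
      "name": "control-F",
      "sequence": "AATTGCAGAATCCCGCGAAC",
      "orientation": "forward",
      "role": "universal_forward",
      "specific_3prime_len": 0,
      "tm_wallace": 60,
      "gc_percent": 50
    },
    {
      "name": "control-R",
      "sequence": "TCCTCCGCTTATTGATATGC",
      "orientation": "reverse",
      "role": "universal_reverse",
      "specific_3prime_len": 0,
      "tm_wallace": 58,
      "gc_percent": 45
    }
  ],
  "expected_bands": {
    "Aristolochia_pothieri": 123,
    "Aristolochia_pierrei": 191,
    "Aristolochia_tagala": 265
  },
  "control_band": 400
}
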
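name	role	sequence	target_species	expected_band
ITS2-poF	species_specific	GCCGCGAGGACCCAATG	Aristolochia_pothieri	123
ITS2-piF	species_specific	GACTACTGGTGGCTCCACGCA	Aristolochia_pierrei	191
ITS2-taF	species_specific	GGCGGGGGCGAGCAGGC	Aristolochia_tagala	265
ITS-Aris-390F	universal_forward	AATTGCAGAATCCCGCGAAC		400
ITS4	universal_reverse	TCCTCCGCTTATTGATATGC		400
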
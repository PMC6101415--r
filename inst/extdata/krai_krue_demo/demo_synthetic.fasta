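>Aristolochia_pothieri_ind01|Aristolochia_pothieri|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAACCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Aristolochia_pothieri_ind02|Aristolochia_pothieri|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAACCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Aristolochia_pierrei_ind01|Aristolochia_pierrei|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTTGGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Aristolochia_pierrei_ind02|Aristolochia_pierrei|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTTGGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Aristolochia_tagala_ind01|Aristolochia_tagala|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGAAACTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Aristolochia_tagala_ind02|Aristolochia_tagala|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGAAACTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Jasminum_substitute_ind01|Jasminum_substitute|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
>Jasminum_substitute_ind02|Jasminum_substitute|ITS2
AATCAGTCTGCGGTCCTACATGCTCCTTTTGGCCCGATGCTTAGGATCTGAGGCTATATGGGTGATGACA
GGAAAGGAGCGGGGCAAGTAAATCTGGAATGACGTTGTATACAGCATAGACGCGACGGGGGCCTGCGGCG
TGCGTGAGTTATTACGAGATACGGGGTTTACGGTGCCATAGGGATATGAGCAAGCCAGTTACAGCTTGAG
GAGCCCATGACTCTGCCGGTATAACGCGTCACGTGAGAGGCGTTCGGCACTAAGGAAGTCATGGCGCCAC
ACATTGCTACTCCATAGCGGCGAGTATAAGGGACGGCTATCTTGGGGGTTGATCGCCAGTTTATAGGCTT
AGGGATAAGTAATTGCAGAATCCCGCGAACCAACTGTTTACGGTCGTGCGTTTCACGCTATATTCCTTCA
CGATTCCAGTGCTTGTCGTGCTTGGGACCTCGTGCGTAGCACTGCTTCAAGGCTTAATTCGGCTACCAAT
CCTAGGAATACTTTACATATGATTGTGATATGGCTGCAAAGCTGAATGCGGACGGACCCTAGTCGCCTTA
CATCAACAGGAATTCTAAAGTTATCTTACGCATGCATCGGGTGGTGATAAGCGGAGCGATGCAGGCGGTG
CGTCAGGCAAAAGAATTCAAATGAAAGCTGGTTGGACCGGAGTCAAGGTCTCGGGACACCGCTAAGATGC
CTAGGGCGCCTCAATGTAATGGCCAATCGGCGATGACTAGGCATATCAATAAGCGGAGGAACCTCCAGCA
TTTTACTTCTACAGCGCTCATTTCAGGACT
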
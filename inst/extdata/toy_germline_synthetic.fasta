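>TRBV1 type=V cys_anchor=54
CTTTTCCCCCGAGTTCGTACATTAGCATCCGCGGCTATCACCACGCCCTCGGTTTGTGCC
>TRBV13-1 type=V cys_anchor=54
GAATGAATTCACTACCAACGTATGCCTTGAGAGCGCGACTACCTCTTTAGTTGGTGTGCC
>TRBV13-2 type=V cys_anchor=54
AACCTAGAAAGTAGGGATATGGATCTGAGAATTGTGACGCCTCGCCCATAAGCCTGTGCC
>TRBV13-3 type=V cys_anchor=54
CATGCGTTACAATAATACGACCACCCTAGGTTAGTTGTAGCCGTAGTGTGGCATTGTGCC
>TRBV19 type=V cys_anchor=54
TCATACACGTGAGAAAACGATATGCCCGACCCCGAGTCATGCCTGATGCTGCAGTGTGCC
>TRBV29 type=V cys_anchor=54
CGTTGATCGGGCATGCTTTTTGTATCCCTTTCCTTTCGAATATATTGTGGTTTTTGTGCC
>TRBVother type=V cys_anchor=54
ACGAATGGTTTACTTGACGTAAAGCTCCTCTGAGACTCCACGTGTCCTAGCGTTTGTGCC
>TRAV11 type=V cys_anchor=54
ACTTCGGAACAGTAAACTGTGCCAATAAACGCGCTAATGCATAGAAATACTGTATGTGTG
>TRAV10 type=V cys_anchor=54
TCCGGGTCATTCTGATCTTGGCGCTCGCGCATGTACTTGCGATCACATTGGGCATGTGCC
>TRBJ1-1 type=J phe_anchor=9
AACACCGAATTCGGTCGTGGCAACGGTAGAGTGCCCTATCCACTAGGAAGCAAGCTAACG
>TRBJ2-1 type=J phe_anchor=9
AATGAGCAGTTTGGTGTAGGCACTCGCTGGCACGACATTTGGCTTCATGGCTCATCTTTT
>TRBJ2-7 type=J phe_anchor=9
TACGAGCAGTTCGGTTATGGCCTCATAACATCGGCAGGGTATTCATGCGGGTCACGAAAT
>TRAJ18 type=J phe_anchor=9
CGTCTGCACTTTGGTTTTGGCTACCCGCCATTAAGATTCTGTTTGACACCTTAGTGCGTG
>TRAJ9 type=J phe_anchor=9
AACAAGCTGTTCGGTGACGGCTAAACTGCATCTGAATGTCGCGTAGTAACGGAAGTGGCC
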
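ATOM      1 N    SER A   1      -6.000   0.000   0.000  1.00  0.00           N
ATOM      2 CA   SER A   1      -5.000   0.000   0.000  1.00  0.00           C
ATOM      3 OG   SER A   1      -3.900   0.000   0.000  1.00  0.00           O
ATOM      4 N    ALA A   2      15.000   0.000   0.000  1.00  0.00           N
ATOM      5 CA   ALA A   2      16.000   0.000   0.000  1.00  0.00           C
ATOM      6 CA   VAL A   3       5.100   0.000   0.000  1.00  0.00           C
ATOM      7 CB   VAL A   3       4.100   0.000   0.000  1.00  0.00           C
HETATM    8 C1   ALE A 100       0.000   0.000   0.000  1.00  0.00           C
HETATM    9 O1   ALE A 100       0.000   0.500   0.000  1.00  0.00           O
END
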
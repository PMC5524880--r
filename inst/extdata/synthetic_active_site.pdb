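REMARK synthetic fixture: His + Lys close pair, two distant glutamates
ATOM      1  CA  HIS A   1       0.000   0.000   1.400  1.00  0.00           C
ATOM      2  NE2 HIS A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      3  CA  LYS A   2       4.000   3.000   1.400  1.00  0.00           C
ATOM      4  NZ  LYS A   2       4.000   3.000   0.000  1.00  0.00           N
ATOM      5  CA  GLY A   3       8.000   0.000   0.000  1.00  0.00           C
ATOM      6  CA  GLU A   4      50.000   0.000   1.400  1.00  0.00           C
ATOM      7  CD  GLU A   4      50.000   0.000   0.000  1.00  0.00           C
ATOM      8  CA  GLU A   5     150.000   0.000   1.400  1.00  0.00           C
ATOM      9  CD  GLU A   5     150.000   0.000   0.000  1.00  0.00           C
END
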
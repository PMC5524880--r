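REMARK synthetic two-residue fixture: two lysine ammonium groups 5 A apart
ATOM      1  CA  LYS A   1      -1.500   0.000   0.000  1.00  0.00           C
ATOM      2  NZ  LYS A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      3  CA  LYS A   2       6.500   0.000   0.000  1.00  0.00           C
ATOM      4  NZ  LYS A   2       5.000   0.000   0.000  1.00  0.00           N
END
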
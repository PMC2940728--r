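MODEL        1
ATOM      1 CA   GLY A   1       0.000   0.000   0.000  1.00  0.00
ATOM      2 CA   GLY A   2       0.000   0.000   2.800  1.00  0.00
ATOM      3 CA   GLY A   3       0.000   0.000   5.600  1.00  0.00
ATOM      4 CA   GLY A   4       0.000   0.000   8.400  1.00  0.00
ATOM      5 CA   GLY A   5       0.000   0.000  11.200  1.00  0.00
ATOM      6 CA   GLY A   6       0.000   0.000  14.000  1.00  0.00
ATOM      7 CA   GLY A   7       0.000   0.000  16.800  1.00  0.00
ATOM      8 CA   GLY A   8       0.000   0.000  19.600  1.00  0.00
ENDMDL
END
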
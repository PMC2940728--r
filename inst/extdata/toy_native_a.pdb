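MODEL        1
ATOM      1 CA   GLY A   1       3.000   0.000   0.000  1.00  0.00
ATOM      2 CA   GLY A   2      -0.521   2.954   1.100  1.00  0.00
ATOM      3 CA   GLY A   3      -2.819  -1.026   2.200  1.00  0.00
ATOM      4 CA   GLY A   4       1.500  -2.598   3.300  1.00  0.00
ATOM      5 CA   GLY A   5       2.298   1.928   4.400  1.00  0.00
ATOM      6 CA   GLY A   6      -2.298   1.928   5.500  1.00  0.00
ATOM      7 CA   GLY A   7      -1.500  -2.598   6.600  1.00  0.00
ATOM      8 CA   GLY A   8       2.819  -1.026   7.700  1.00  0.00
ENDMDL
END
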
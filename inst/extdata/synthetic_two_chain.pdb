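HEADER    SYNTHETIC TOY STRUCTURE
ATOM      1  N   ALA A   1       0.000   1.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.000   1.000   0.000  1.00  0.00           C
ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.50  0.00           C
ATOM      4  CA  GLY A   2       2.100   1.500   0.300  1.00  0.00           C
ATOM      5  CA  SER A   3       3.200   0.900   0.800  1.00  0.00           C
ATOM      6  O   SER A   3       3.500   0.100   0.900  1.00  0.00           O
ATOM      7  CA  LEU B   1       0.500   5.000   1.000  1.00  0.00           C
ATOM      8  CA  VAL B   2       1.600   5.400   1.200  1.00  0.00           C
ATOM      9  CA  THR B   3       2.700   5.100   1.700  1.00  0.00           C
ATOM     10  CA  GLU B   4       3.800   4.800   2.100  1.00  0.00           C
TER
END
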
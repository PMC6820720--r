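HEADER    SYNTHETIC METHYL FRAGMENT (IDEALIZED GEOMETRY, NOT A REAL PDB ENTRY)
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C
ATOM      3  CB  ALA A   1       2.200   1.300   0.000  1.00  0.00           C
ATOM      4  CA  ILE A   2       6.000   0.000   0.000  1.00  0.00           C
ATOM      5  CB  ILE A   2       6.800   1.300   0.000  1.00  0.00           C
ATOM      6  CG1 ILE A   2       8.300   1.100   0.200  1.00  0.00           C
ATOM      7  CG2 ILE A   2       6.400   2.200   1.200  1.00  0.00           C
ATOM      8  CD1 ILE A   2       9.200   2.300   0.400  1.00  0.00           C
ATOM      9  CB  LEU A   3       1.000   6.000   0.500  1.00  0.00           C
ATOM     10  CG  LEU A   3       2.300   6.600   0.900  1.00  0.00           C
ATOM     11  CD1 LEU A   3       3.400   5.700   1.400  1.00  0.00           C
ATOM     12 HD11 LEU A   3       3.662   4.972   0.618  1.00  0.00           H
ATOM     13 HD12 LEU A   3       4.284   6.305   1.649  1.00  0.00           H
ATOM     14 HD13 LEU A   3       3.057   5.165   2.298  1.00  0.00           H
ATOM     15  CD2 LEU A   3       2.800   7.600  -0.200  1.00  0.00           C
ATOM     16 HD21 LEU A   3       2.059   8.403  -0.330  1.00  0.00           H
ATOM     17 HD22 LEU A   3       3.762   8.035   0.110  1.00  0.00           H
ATOM     18 HD23 LEU A   3       2.930   7.063  -1.151  1.00  0.00           H
ATOM     19  CA  VAL A   4       7.000   6.000   0.000  1.00  0.00           C
ATOM     20  CB  VAL A   4       7.800   7.200   0.400  1.00  0.00           C
ATOM     21  CG1 VAL A   4       9.300   7.000   0.600  1.00  0.00           C
ATOM     22  CG2 VAL A   4       7.300   8.300   1.400  1.00  0.00           C
ATOM     23  N   GLY A   5      12.000   0.000   0.000  1.00  0.00           N
ATOM     24  CA  GLY A   5      13.400   0.000   0.200  1.00  0.00           C
END
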
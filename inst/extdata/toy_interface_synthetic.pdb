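HEADER    SYNTHETIC TOY INTERFACE FIXTURE
REMARK    synthetic two-chain fixture for contact-analysis tests
ATOM      1  N   ALA A   1      -1.200   0.900   0.000  1.00 10.00           N
ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C
ATOM      3  CB  ALA A   1       1.500   0.000   0.000  1.00 10.00           C
ATOM      4  C   ALA A   1      -0.500  -1.400   0.000  1.00 10.00           C
ATOM      5  H   ALA A   1       0.000   1.000   0.500  1.00 10.00           H
ATOM      6  CA  ALA B  10       4.500   0.000   0.000  1.00 10.00           C
ATOM      7  CB  ALA B  10       5.800   0.800   0.000  1.00 10.00           C
ATOM      8  CB  ALA B  11       8.500   0.000   0.000  1.00 10.00           C
ATOM      9  CA  ALA B  11       9.900   0.500   0.000  1.00 10.00           C
HETATM   10  O   HOH B  90      30.000   0.000   0.000  1.00 10.00           O
END
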
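ATOM      1  CA  GLY A 530      19.445  11.771   9.536  1.00  0.00
ATOM      2  CA  LYS A 539       0.000   0.000   0.000  1.00  0.00
ATOM      3  CA  ALA A 550     -10.804 -11.885  -8.489  1.00  0.00
ATOM      4  CA  LEU A 560       6.748   7.916 -10.450  1.00  0.00
ATOM      5  CA  GLU A 570       8.111  -3.083  10.812  1.00  0.00
ATOM      6  CA  VAL A 580      17.380 -14.742   7.955  1.00  0.00
ATOM      7  CA  THR A 590      12.848 -16.564 -18.611  1.00  0.00
ATOM      8  CA  ASP A 600     -13.255   6.890 -15.380  1.00  0.00
ATOM      9  CA  ILE A 610       6.471 -13.875  17.539  1.00  0.00
ATOM     10  CA  PHE A 620      15.365   5.026  -2.343  1.00  0.00
ATOM     11  CA  ARG A 630     -13.494   7.480  -0.908  1.00  0.00
ATOM     12  CA  ASN A 640       2.424  -6.624  -5.520  1.00  0.00
ATOM     13  CA  SER A 646      27.000   0.000   0.000  1.00  0.00
ATOM     14  CA  GLN A 655      12.902  -2.902 -18.716  1.00  0.00
END
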
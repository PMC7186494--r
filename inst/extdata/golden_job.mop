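PM7 1SCF EPS=78.40 CHARGE=0 GEO-OK
single point, 3 atoms

N       0.00000000 0      0.00000000 0      0.00000000 0
C       1.47000000 0      0.00000000 0      0.00000000 0
O       2.10000000 0      1.30000000 0      0.00000000 0

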
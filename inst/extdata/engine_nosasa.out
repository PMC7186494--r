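          FINAL HEAT OF FORMATION =        -52.30100 KCAL/MOL =    -218.82738 KJ/MOL
          TOTAL ENERGY            =       -871.00241 EV

 == MOPAC DONE ==
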
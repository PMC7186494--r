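 *******************************************************************************
 ** Semi-empirical single point, PM7 Hamiltonian, COSMO solvation           **
 *******************************************************************************

          COSMO AREA              =        412.37 SQUARE ANGSTROMS
          COSMO VOLUME            =        611.02 CUBIC ANGSTROMS

          FINAL HEAT OF FORMATION =       -171.82451 KCAL/MOL =    -718.91375 KJ/MOL

          TOTAL ENERGY            =      -2831.11485 EV
          DIELECTRIC ENERGY       =         -1.90733 EV
          GRADIENT NORM           =          0.00000

          IONIZATION POTENTIAL    =          9.128407 EV
          MOLECULAR WEIGHT        =        310.3531

          WALL-CLOCK TIME         =          6.215 SECONDS

 == MOPAC DONE ==
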
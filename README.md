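# qmscreen

Semi-empirical quantum-mechanical rescoring of docked ligand libraries,
with screening-power evaluation.

## What it does, and for whom

High-throughput docking ranks thousands of molecules against a receptor
with fast force-field scores, and that scoring stage — not pose generation
— is usually what limits enrichment. `qmscreen` is for computational
chemists who already have docked poses and want to re-rank them with a
quantum-mechanics-based docking score (QMDS) built from semi-empirical
single-point energies (PM7 Hamiltonian with COSMO continuum solvation
through an external engine, or a built-in deterministic toy potential for
development and testing):

```
QMDS = ΔG_o^QM + ΔG_conf^QM(P) + ΔG_conf^QM(L) − TΔS
     ≡ G^QM(PL) − G^QM(P) − G^QM(L) − TΔS
```

with `ΔG_o = G(PL) − G_o(P) − G_o(L)` the interaction energy in the docked
conformation, `ΔG_conf(X) = G_o(X) − G(X)` the strain of protein or ligand
relative to its relaxed free state, and `−TΔS = RT ln Ω` the ligand
conformational-entropy penalty (Ω from a rotamer count 3^N or, by default,
from Monte-Carlo torsional sampling counting distinct conformers within
3 kcal/mol). Four variants cross two switches: complex relaxation
(`QMDS1` raw docked complex / `QMDS2` relaxed under a 50, 10, 5, 1, 0
kcal·mol⁻¹·Å⁻² restraint schedule) and explicit deformation terms (`d`
suffix). QMDS is a ranking score, not an absolute binding free energy.

To keep protein-sized systems tractable, all QM evaluations run on a
reduced binding-site cluster: residues with any heavy atom within 8 Å of
any docked pose, defragmented by deterministic rules and hydrogen-capped
at severed backbone bonds. Screening power is evaluated with enrichment
factors (EF at 1, 2, 5, 10%), ROC curves and AUC, with per-molecule state
collapsing (lowest score among protonation/chirality states) and exclusion
of molecules whose QM jobs failed.

## Worked example

A complete synthetic screen — toy pocket, 20 ligands + 180 decoys with a
designed energetic margin, QMDS1 rescoring, metrics:

```r
library(qmscreen)

pocket <- make_toy_pocket(seed = 0)        # 30-residue shell, charged floor
lib    <- make_library(seed = 0)           # 203 pose states, manifest labels

records <- score_library(pocket, lib$poses, config = backend_config(),
                         variants = "QMDS1")
hitlist <- build_hitlist(records)
hitlist
#> <hitlist> 199 molecules (20 ligands), 1 excluded by QM failure

screening_summary(hitlist)
#>    EF1  EF2  EF5 EF10 AUC n_total hits_total n_excluded
#> 1 9.95 9.95 9.95 9.95   1     199         20          1
```

All 20 ligands outrank all 180 decoys (AUC = 1), so every EF sits at its
saturation value for this composition: with 20 ligands in 199 molecules
the bound is N/hits = 9.95 once the top set holds only ligands (EF(1) = 100
is only reachable when the ligand fraction is at most 1%). One decoy pose
carries a deliberate atom clash; its energy evaluation fails and the
molecule is excluded from the totals rather than aborting the screen.

The same pipeline drives shell workflows through plain files
(PDB/SDF/TSV):

```sh
Rscript inst/scripts/qmds-cli.R synth    --outdir work --seed 0
Rscript inst/scripts/qmds-cli.R score    --receptor work/pocket.pdb \
    --poses work/poses.sdf --manifest work/manifest.tsv --outdir work
Rscript inst/scripts/qmds-cli.R evaluate --scores work/scores.tsv --variant QMDS1
```

For a real target you would replace the synthetic inputs with a prepared
(protonated) receptor PDB, an SDF/MOL2 of docked poses (one
lowest-docking-energy conformation per molecule state) and a tab-separated
manifest `state_id  parent_id  label`, and point `backend_config("engine",
engine_cmd = ...)` at a PM7 engine; without a binary the adapter still
writes job files for external execution and parses the outputs later.

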
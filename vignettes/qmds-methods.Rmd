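---
title: "QMDS rescoring: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QMDS rescoring: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmscreen)
```

## The problem and the model

High-throughput docking produces, for every molecule in a chemical library,
a best pose and a docking score. The score, usually a fast force-field
expression, is the weak link: it decides which molecules are forwarded to
experiment. `qmscreen` implements a rescoring stage that replaces the
force-field score with a quantum-mechanics-based docking score built from
semi-empirical single-point energies with continuum solvation:

$$\mathrm{QMDS} = \Delta G^{QM} - T\Delta S
  = \Delta G_o^{QM} + \Delta G_{conf}^{QM}(P) + \Delta G_{conf}^{QM}(L) - T\Delta S$$

where $\Delta G_o^{QM} = G(PL) - G_o(P) - G_o(L)$ is the interaction energy
with protein, ligand and complex all in the conformation of the docked
complex, and $\Delta G_{conf}(X) = G_o(X) - G(X)$ is the strain
(deformation) of species $X$ relative to its relaxed free state. The two
forms above are algebraically identical; the package computes both and the
test suite asserts their agreement to $10^{-9}$ kcal/mol on every scored
pose, which is a strong end-to-end check on the component bookkeeping.

Four variants are exposed, crossing two choices:

* relaxation — `QMDS1` scores the raw docked complex; `QMDS2` first relaxes
  it through a restrained minimization schedule;
* deformation — the `d` suffix adds the explicit protein and ligand strain
  penalties (which require the free-state energies $G(P)$, $G(L)$).

QMDS values are *rankings*, not absolute binding free energies: single
points on single poses, a classical relaxation, and the absence of
vibrational entropy all bias the absolute scale. Only the ordering of
molecules within one screen is meaningful, which is why the evaluation
module speaks in enrichment factors and ROC/AUC.

## Pipeline stages and their parameters

### Preparation

Protein formal charges follow the standard physiological-pH rules: Asp and
Glu $-1$, Arg and Lys $+1$, His neutral with the tautomer implied by the
input hydrogens; monatomic ions are charged by element (Ca/Zn/Mg $+2$,
Na/K $+1$, Cl $-1$). Chain termini are modeled neutral by default
(`charge_termini = FALSE`), since the inputs this package expects are
pre-protonated receptor preparations where capped or intact termini are the
norm. Crystallographic waters are retained only within 4 Å of the
reference ligand and co-factor ions within 8 Å (`select_environment()`),
measured as heavy-atom minimum distances.

### The reduced system

All QM evaluations run on a binding-site cluster, not the full protein: a
residue is kept when any of its heavy atoms lies within 8 Å (default) of
any heavy atom of *any* pose in the library. One cluster per target keeps
$G_o(P)$ comparable across the whole library; per-pose cutouts would make
scores incommensurable. Hydrogens are ignored on both sides of the
threshold. Thresholds below 6 Å are known to degrade cluster-based scores
badly, so the configuration warns there.

The raw selection is then defragmented by deterministic rules replacing
what is otherwise a manual touch-up: sequence gaps of at most `max_gap = 2`
residues are bridged, fragments shorter than `min_fragment = 2` are
extended (C-terminal side first), and when HELIX/SHEET annotations are
present a boundary inside an annotated element snaps to the element
boundary. Each severed backbone bond is capped with a hydrogen placed on
the former bond vector — 1.01 Å from the fragment nitrogen, 1.09 Å from
the carbonyl carbon — and cap positions are never optimized, matching the
single-point philosophy of the unrelaxed score.

Retained waters and ions are included in every cluster regardless of their
distance to the 8 Å selection: they were already filtered by their own
retention radii, and dropping them per-cluster would silently change the
target's charge.

### Energy backends

The backend contract is a single operation: one geometry with formal
charges in, one `energy_result` out (total = gas + solvation, kcal/mol,
plus an optional solvent-accessible surface area and a converged/failed
status). Two implementations stand behind it:

* **engine adapter** — writes MOPAC-dialect job files (PM7 Hamiltonian,
  single-SCF, COSMO with $\varepsilon = 78.4$, `CHARGE=` from the system,
  the linear-scaling keyword above 300 atoms) and parses the output stream
  for the final heat of formation, the dielectric (solvation) energy and
  the COSMO area. The engine binary is optional at runtime: jobs can be
  written, farmed out elsewhere, and parsed later. A missing termination
  marker or unparseable energy yields a `failed` status, never an error.
  The captured surface area is recorded as metadata only; no scoring term
  consumes it.
* **toy potential** (default) — a deterministic classical energy
  $$G = \sum_{bonds} k_b (r-r_0)^2
      + \sum_{torsions} \tfrac{V_3}{2}(1+\cos 3\varphi)
      + \sum_{pairs} \Big[\epsilon\big((\sigma/r)^{12} - 2(\sigma/r)^6\big)
      + \frac{332.06\, q_i q_j}{4 r^2}\Big] - \tau \sum_i q_i^2$$
  with $k_b = 300$ kcal mol$^{-1}$ Å$^{-2}$, $V_3 = 2$ kcal/mol,
  $\epsilon = 0.1$ kcal/mol, $\sigma = 3.4$ Å, $\tau = 1$ kcal mol$^{-1}$
  e$^{-2}$, a small per-element-pair $r_0$ table, a distance-dependent
  dielectric $4r$ in the Coulomb term and a geometry-independent Born-like
  self-solvation. Nonbonded pairs exclude 1-2 and 1-3 neighbours. The
  analytic gradient covers every geometry-dependent term and is verified
  against central finite differences in the tests.

The toy potential is what makes the package testable at desk scale: every
pipeline property (score identities, failure isolation, entropy recovery,
relaxation contracts, screening metrics) is exercised end-to-end in
seconds, with no external binary and bit-identical results. It is a real,
if minimal, molecular potential — not a placeholder: its closed forms (LJ
minimum exactly $-\epsilon$ at $\sigma$, three equal torsional wells of
depth $V_3$) are what several oracle tests are built on.

Any geometry with two atoms closer than 0.3 Å is reported `failed`, the
same path a non-converging engine job takes: one broken pose must never
abort a screen, it is simply excluded later.

### Ligand conformational entropy

On binding the ligand is assumed to occupy a single conformation, so
$\Delta S = -R\ln\Omega$ with $\Omega$ the number of accessible free-state
conformations and $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$; the
score receives the penalty $-T\Delta S = RT\ln\Omega \ge 0$ at
$T = 298.15$ K (configurable; the method itself does not fix a
temperature).

Two estimators:

* `rot` — $\Omega = 3^N$ over the $N$ rotatable bonds (non-ring single
  bonds between heavy atoms, both ends bearing a further heavy neighbour,
  amide C–N excluded).
* `conf` (default) — Monte-Carlo sampling in torsion space: uniform
  single-torsion proposals, Metropolis acceptance at 300 K, local
  minimization of all torsions after each accepted move, then
  $\Omega$ = the count of distinct conformers within 3 kcal/mol of the
  sampled minimum. Distinctness means some torsion differs by more than
  30° (circular). The default budget is $1000N$ steps with seed 0.

The rotamer count is known to over-estimate low-energy conformers, which
is why `conf` is the scoring default; for probe molecules with truly
independent torsional wells the two coincide ($\Omega = 3^N$), and the
test suite uses exactly that construction as a parameter-recovery check.
On coupled landscapes (the nonbonded term frustrates simultaneous gauche
combinations, the classic pentane effect) the MC count falls below $3^N$;
this is reported, not asserted, as it is the physically expected
behaviour.

Numerical notes: torsional minimization uses BFGS with the analytic
torsion-space gradient (Cartesian gradient chained through the rotation
generator $u\times(x_i-p)$); the optimizer is scaled in radians via
`parscale` because torsional curvature per squared degree is of order
$10^{-3}$ and stalls a unit-scaled quasi-Newton method. A saddle-escape
probe (±20° per torsion) follows each descent, since the 3-fold landscape
has flat saddle points whose vanishing gradient otherwise traps the
minimizer; after a short descent, basins already resolved are matched
within 15° and reuse their known minimum instead of re-minimizing.

### Complex relaxation (the QMDS₂ path)

Residues with any heavy atom within 4 Å of any pose of the library are
movable, plus all ligand atoms; everything else is frozen. Each complex
then undergoes five cycles of local minimization with a harmonic
positional restraint on movable *heavy* atoms whose weight steps down
50, 10, 5, 1, 0 kcal mol$^{-1}$ Å$^{-2}$ — the final cycle is fully
unrestrained, and hydrogens are never restrained. The restraint reference
resets to the cycle-start coordinates each cycle (`reset_reference`
toggles the alternative of keeping the original structure throughout).
Because each cycle's minimizer can only lower its own objective, the
unrestrained energy at cycle ends is non-increasing — asserted in the
tests. Minimization is all-Cartesian (L-BFGS-B, gradient tolerance
$10^{-3}$ kcal mol$^{-1}$ Å$^{-1}$, 500 iterations per cycle) with the
frozen shell standing in for internal-coordinate receptor minimization,
which would require a torsion-tree topology engine well outside this
package's scope; the 4 Å movable-region rule preserves the locality that
scheme is meant to achieve.

Unbound reference states descend from the conformations the method
prescribes: the pocket free state $G(P)$ from the cluster (once per
target, cached), the ligand free state $G(L)$ from its docked conformation
(once per state id). In the relaxed variants the strain of the pocket is
evaluated against the pocket conformation of each relaxed complex; the
free state stays shared.

### Scoring and screening metrics

`score_library()` orchestrates the stages with component caching keyed by
geometry, charges and backend parameters; $G_o(P)$ is computed once per
target and the tests assert it is bit-identical across the library. A
failed component fails exactly the records that need it.

The hit list collapses multiple states of one parent molecule
(protonation/chirality enumerations) to the lowest surviving score; states
that failed the backend are excluded from both numerator and totals, and a
molecule whose every state failed leaves the screen entirely. Ties break
lexicographically by parent id so reruns are byte-identical.

$EF(x)$ uses a ceiling top-set, $N_{x\%} = \lceil x N_{total}/100\rceil$,
so the top set is non-empty for any $x > 0$ and $EF(100) = 1$ exactly; the
rounding rule is declared in the output metadata since different codebases
round differently. AUC integrates the ROC by trapezoid over tied-score
blocks, which equals Mann–Whitney pair counting with half-credit for ties
— the suite checks that identity to $10^{-12}$ against a brute-force pair
count. EF(1) and EF(2) are the headline early-enrichment numbers; EF(5),
EF(10) and AUC complete the default report.

## The synthetic benchmark

`make_toy_pocket()` builds a 30-residue mini-protein on a hemispherical
shell (radius 10 Å) around a concave binding site: reduced residues
(backbone N, CA, C plus one pseudo-side-chain atom CB pointing into the
pocket) with bond lengths equal to the toy reference values, so the pocket
is strain-free by construction. Lys residues line the mouth and twice as
many Asp line the floor, giving a negatively charged floor under a
near-neutral shell; two waters (one inside, one outside the 4 Å retention
radius) and a Ca²⁺ ion in the mouth region exercise the environment rules.
`make_library()` emits rigid diatomic probes of identical composition and
net charge $+1$: ligands seated at the pocket floor where the Asp rim
rewards them electrostatically, decoys displaced 11 Å up the pocket axis
where those contacts are lost. The designed margin between mean ligand and
mean decoy interaction energy is below $-5$ kcal/mol (checked numerically
in the tests). Two ligand parents and one decoy parent are emitted as two
protonation-like states, and the last decoy pose contains a deliberate
atom clash, so state collapsing and failure exclusion are always
exercised.

What passing these tests shows — and what it does not: the synthetic
screen proves the pipeline's *mechanics* (geometry, bookkeeping, caching,
exclusion, metrics) and that the score orders a designed energetic
separation correctly. It says nothing about PM7+COSMO accuracy on real
protein–ligand complexes, conformational sampling of drug-like molecules,
or enrichment on real decoy libraries; those require the external engine
and curated benchmark sets. Problem sizes in the suite (a 30-residue
pocket, 200-molecule libraries, $1000N$-step MC runs) are the package's
default desk-scale working points; all are parameters.

## Degenerate inputs and tie-breaks

* Zero rotatable bonds: the MC path short-circuits, $\Omega = 1$,
  $-T\Delta S = 0$.
* A hit list with one class only: ROC/AUC raise an error; EF requires at
  least one ligand.
* Overlapping atoms (< 0.3 Å): failed energy, failed records, excluded
  molecules — never an abort.
* No reference ligand in environment selection: all waters/ions are
  dropped with a warning.
* Equal scores: stable lexicographic tie-break; equal-energy conformers:
  deduplication keeps the first by energy order.

## Known limitations

* The toy potential has no angle terms; only molecules whose shape is
  fixed by bonds alone (or held by 1-4+ nonbonded contacts) are rigid
  under full minimization. The synthetic library uses diatomic probes for
  exactly this reason.
* Cartesian relaxation with a frozen shell is an approximation to
  internal-coordinate receptor minimization; on the smooth toy landscape
  the final unrestrained cycle can migrate a ligand several ångströms.
* Vibrational entropy and protein conformational entropy are out of scope
  of the score's definition.
* The engine adapter targets one output dialect; other semi-empirical
  codes would need their own parser behind the same `energy_result`
  contract.
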
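---
title: "Models and conventions behind pepdisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind pepdisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdisc)
```

`pepdisc` computes two kinds of quantities for apoA-I mimetic peptide
design: sequence-level amphipathicity metrics, and structural metrics on
molecular configurations of peptide–lipid assemblies. This vignette
records the models, the conventions and defaults they depend on, and what
the synthetic-data machinery can and cannot tell you about real
simulations.

## Sequence metrics

### Hydrophobicity scale and moment

`ww_interface()` ships the Wimley–White water-to-POPC-interface transfer
free energies with the **charged-residue convention**: Glu and Asp carry
their deprotonated values (+2.02 and +1.23 kcal/mol) and Lys and Arg their
protonated values (+0.99, +0.81), with positive meaning interfacially
unfavourable. Termini are excluded from all sequence averages. This is the
convention under which the four ELK designs reproduce their published mean
hydrophobicities (0.59/0.36/0.47/1.02 kcal/mol) and hydrophobic moments
(0.74/0.70/0.52/0.70 kcal/mol) to ±0.01 — the neutral-residue convention
does not.

The hydrophobic moment is the planar vector sum around the helical wheel,

$$\mu_H = \frac{1}{N}\left\lvert\sum_{i=1}^{N} h_i
  \big(\cos i\delta,\ \sin i\delta\big)\right\rvert,$$

with the ideal α-helical twist δ = 100°/residue. Division is by the
residue count N (not by a unitless normalisation), so μH has units of
kcal/mol. The magnitude is invariant under cyclic shifts and sequence
reversal, which the test suite asserts numerically.

### Molecular weight

Average (not monoisotopic) residue masses plus one water for the free
termini. Computed masses sit 0.6–0.8 Da above the published integer values
for all four designs, consistent with those values having been truncated;
the package reports the full-precision mass and tests to ±1 Da.

### Net charge and isoelectric point

Two charge models are deliberately separate:

- `peptide_net_charge()` is the integer design-table model — +1 per
  Lys/Arg, −1 per Glu/Asp, His neutral, free termini cancelling.
- `peptide_charge()` / `peptide_pi()` use the fractional
  Henderson–Hasselbalch model over ionizable sidechains and both termini,
  with pI found by bisection on (0, 14) to 10⁻³ pH. The default pKa table
  (`pka_table()`) follows the EMBOSS values and is swappable.

A known limitation: with the default table the net-neutral and net-negative
designs land within ±0.5 pH of their published pI values (6.71, 6.66, 4.36
vs 6.7, 6.7, 4.6), but the net +3 design computes to ≈ 10.5 where 8.9 was
published. A peptide with six lysines and three glutamates cannot titrate
to neutrality below pH ~10 under any standard pKa set, so the published
value presumably comes from a tool with a different charge model; the
package reports the Henderson–Hasselbalch result and the test suite
asserts only that this design is basic.

### Helical wheel and face angle

`wheel_layout()` places residue i at ((i−1)·100°) mod 360°; an 18-mer
tiles the 20° grid exactly once. Classes: Leu/Ile/Val/Phe/Met/Trp/Cys are
hydrophobic, Glu/Asp/Lys/Arg/His charged, the rest neutral-polar. Ala is
**excluded** from the hydrophobic face by default: it is aliphatic but too
small to extend a Leu face, and with Ala excluded the Ala-containing
design reproduces its published 140° face (its two Ala positions are
isolated from the Leu arc by charged residues either way, so here the flag
does not change the answer; `ala_hydrophobic = TRUE` is available).

`face_angle()` is defined on the quantised wheel as the maximal circular
arc of contiguous hydrophobic slots, reported as the span between extreme
members **plus one 20° residue width**. This span-plus-width rule is the
definition that yields exactly 200° for the ten-Leu design; an arc of k
slots subtends 20k degrees, a lone hydrophobic residue 20°, a fully
hydrophobic wheel 360°.

### CD helpers

`mean_residue_ellipticity()` implements
[θ] = θ·MRW/(10·l·c) with θ in millidegrees, path length in cm,
concentration in mg/mL and a default mean residue weight of 121 Da
(appropriate for these compositions). `helicity_from_mre222()` is a
single-wavelength linear estimator between configurable 0% and 100%
references (defaults −3000 and −39500 deg·cm²·dmol⁻¹), clipped to
[0, 100]. The published helicities cite a formula that is not printed, so
the references are exposed rather than hard-coded; absolute helicities
depend on that choice, differences between peptides much less so.

## Synthetic systems

The builders emulate the four reference geometries so every trajectory
metric can be validated against constructed ground truth without MD
output. Pseudo-lipids are reduced to the atoms the metrics reference —
choline N (±21 Å), phosphate P (±19 Å), two oleoyl-equivalent C2 atoms
(±14.5 Å) and two generic chain carbons — because every published cutoff
names only these roles. Cholesterol is a three-atom `CHOL_C` chain that
participates in no metric. The z axis is the bilayer/disc normal, the
origin the bilayer centre, units Å, area per lipid 65 Å².

Peptides are ideal α-helices (rise 1.5 Å, twist 100°, Cα radius 2.3 Å)
with one pseudo-sidechain atom per Lys/Glu/Leu placed radially at the
residue's wheel azimuth (reach 6.4/3.7/2.6 Å beyond the Cα radius), so the
spatial hydrophobic face matches the wheel diagram by construction.

Default compositions are the study conditions: 90:10:2 for the surface
patch, 80:8:8 (mixed parallel/antiparallel edges, ~70 Å edge) and 60:6:8
(antiparallel) for the slabs, 150:15:24 for the nanodisc. One composition
discrepancy exists in the source material (80 POPC with 10 vs 8
cholesterol for the low-density slab); the builders follow the tabulated
80:8:8. The default disc radius is the value implied by the leaflet lipid
count at 65 Å²/lipid (≈ 41.4 Å); `radius = 46` reproduces the
experimentally observed ~92 Å particle.

`synthesize_trajectory()` adds i.i.d. Gaussian displacements per atom per
frame — noise, not dynamics. There is no energy model, no correlation
time, no drift: trajectories have known ground truth (the base frame) and
known noise, which is exactly what estimator validation needs. Passing
tests therefore demonstrate correctness of the *estimators* (recovery,
unbiasedness, scaling), not realism of membrane fluctuations; published
trajectory averages from microsecond all-atom runs are out of reach at
desk scale and are not asserted anywhere.

The scripted-contact facility pins designated atom pairs at 80% (on) or
150% (off) of their cutoff per a boolean schedule, giving exact lifetime
and per-frame count ground truth.

## Trajectory metrics: conventions

- **Contacts** are pair-based (an atom in two qualifying pairs contributes
  two contacts), matching the "number of contacts" reading; each unordered
  pair counts once, intra-residue pairs never count, and
  `exclude_same_chain = TRUE` restricts to intermolecular pairs. Distances
  use the minimum-image convention on the axes flagged periodic; cutoffs
  at or above half a periodic box length are rejected rather than silently
  wrapped.
- **Lifetimes** are maximal runs of consecutive presence times the frame
  spacing, averaged over all runs of all pairs. Runs touching either end
  of the trajectory count without censoring correction (the simplest
  reading of "average lifetime"). When the frame spacing exceeds the mean
  lifetime a warning flags the estimate as resolution-limited — the regime
  a sparsely saved trajectory falls into.
- **Insertion height** is the signed z distance between the backbone-Cα
  centre of geometry and the mean oleoyl C2 z of the peptide's leaflet,
  positive toward that leaflet's aqueous phase.
- **Dimers** require at least one inter-peptide salt bridge or Leu–Leu
  contact. Orientation is the sign of the dot product of first-to-last Cα
  axes. The register offset is measured along the peptide's *principal*
  Cα axis (the first-to-last vector carries a spurious ~3.5 Å lateral
  component from the azimuthal offset of the terminal residues, enough to
  misclassify perfectly aligned helices); matched means ≤ 1.5 Å (one
  helical rise) — a tolerance chosen here, exposed as `register_tol`.
- **Disc diameter** compares the out-of-plane moment of inertia of the
  selection (unit masses, centroid-centred, principal-axis aligned with
  the smallest positional spread taken as the normal) with a homogeneous
  disc: D = 2√(2 I_z/N). The estimator is exact for homogeneous discs,
  invariant under rigid motion, and biased high for rim-concentrated mass
  (a thin ring gives 2√2·R). The default selection is lipids plus
  cholesterol; including peptides is a caller choice, as the defining
  atom set is ambiguous in the source material.
- **Density maps** are per-frame 2D histograms averaged over frames, in
  atoms/Å²; `sum(density)·bin²` equals the mean selected-atom count per
  frame, which every fixture asserts.
- **Block errors** split the series into 10 equal contiguous blocks
  (trailing remainder dropped, recorded in `n_used`) and report
  SD(block means)/√10. For i.i.d. input the standard error scales as
  n^(−1/2); the suite checks the log–log slope to ±0.05.

## Structure I/O

PDB and multi-model PDB are the only dialects (text formats; no binary
trajectory reader). Roles are encoded in atom/residue names (CA, NZ, CD,
CD1, N, C for peptides; P, N, C2, C1 under residue POP; CHL for
cholesterol), molecule identity in the segid columns, and box lengths,
periodicity flags and frame timing in CRYST1/REMARK header records, so a
write–read round trip restores roles, molecule ids, residue indices (which
are 1-based throughout) and coordinates to the format's 10⁻³ Å. Unknown
atom names degrade to `LIPID_OTHER` with a warning rather than an error.

## Problem sizes and determinism

The shipped tests validate estimators at sizes where their statistical
properties are already sharp: 10⁴-point discs for the 2% diameter check,
100 random fixtures against the O(n²) contact oracle, series of 10²–10⁵
points for the block-error scaling, and 20 replicate 200-frame patches for
height unbiasedness. Every stochastic step takes an explicit seed;
`run_synthetic_suite()` derives per-stage seeds from one top-level seed as
(seed·1009 + stage) mod (2³¹−1), so stages re-run identically in
isolation and the summary JSON is byte-identical across runs.

## Known limitations

- Noise-based trajectories cannot exhibit correlated fluctuations, so
  block-error behaviour on *correlated* series is untested here.
- The pI model cannot reproduce the published value for the net +3 design
  (see above).
- Helicity from CD is only as good as the configured 0%/100% references.
- The slab builders honour the published periodicity as metadata (one
  periodic in-plane axis); the distinction between isotropic and
  semi-isotropic pressure coupling in the source simulations has no
  geometric counterpart here.
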
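---
title: "Analysing disordered-peptide ensembles with idpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing disordered-peptide ensembles with idpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpkit)
```

## The problem

Amyloid-beta (A&beta;) is an intrinsically disordered peptide: it has no
single native structure, and any claim about it is a claim about a
conformational *ensemble*. Replica-exchange molecular dynamics (REMD) is a
standard way to sample such ensembles — parallel simulations at a ladder of
temperatures with periodic Metropolis-accepted swaps between neighbours —
and the system of interest here is A&beta; (the 16-residue N-terminal
fragment and the full 42-mer) carrying a platinum–phenanthroline fragment,
Pt(phen), coordinated at His6 and His14. `idpkit` implements the complete
post-processing pipeline such a study needs: trajectory I/O, superposition
and fluctuation statistics, gyration-tensor shape descriptors, secondary
structure, non-covalent interaction occupancies, contact maps, Ramachandran
analysis, density-based clustering, and replica-exchange statistics.

Because ensembles of disordered peptides cannot be validated against a
reference crystal structure, the package also ships a deterministic
synthetic-conformer generator. Every analysis stage can therefore be tested
against inputs whose ground truth is known exactly, without downloading any
external data.

## Data model

A `Topology` holds per-atom metadata (name, element, 1-based residue index,
residue name, mass, ligand flag); a `Trajectory` adds an
`n_atoms x 3 x n_frames` coordinate array in &Aring;ngstr&ouml;m. Multi-model
PDB is the interchange format: one `MODEL`/`ENDMDL` block per frame,
fixed-column parsing with 3-decimal coordinates, `HETATM` fragments flagged
as ligand, and elements inferred from atom names when the element column is
missing (deposited trajectory files frequently omit it). Residues are
renumbered 1-based in file order so reports read Asp1…Lys16 regardless of
the numbering in the source file. Hydrogens are never required: every
analysis runs on heavy-atom-only input, and the few places that need polar
hydrogens reconstruct them geometrically (below).

Selections use a small grammar (`backbone`, `calpha`, `resid 3-5`,
`name CA CB`, `ligand`, `ring(TYR10)`, …). `ring(PHN)` enumerates the
ligand's three fused six-membered rings, detected from the bond graph so
that deposited fragments with arbitrary atom naming still resolve.

## The synthetic-conformer generator

`build_peptide()` grows an all-heavy-atom peptide from internal coordinates
by natural-extension (NeRF) placement: N–CA 1.458 &Aring;, CA–C 1.525
&Aring;, C–N 1.329 &Aring;, standard valence angles, &omega; fixed at
180&deg;. The requested per-residue (&phi;, &psi;) are reproduced exactly by
construction (the round trip through `dihedrals()` is an identity to
10^-6 degrees, a property test in the suite). Chirality is fixed by the
improper torsion C–N–CA–C&beta; = +120&deg;, which the tests verify for
every residue type. Side chains use one fixed extended rotamer per residue
type — enough for radius-of-gyration, salt-bridge and ring-geometry work,
and fully deterministic; rotamer *sampling* is deliberately out of scope.
Aromatic rings are closed as exact planar polygons rather than by chained
torsion placements, so ring-plane fits are exact on noise-free builds.

Named dihedral templates cover the basins a disordered-peptide Ramachandran
map actually populates: &alpha; (-60, -40), 3,10 (-49, -26), &beta;
(-150, 160), PPII (-75, 150), and fully extended (180, 180). The
&alpha; and basin centres match the Ramachandran conventions used for this
system; the 3,10 values are standard geometry, since only the basin's
existence — not its parameters — is constrained by the application. Two
conventions deserve a note:

* **"Extended" means &phi; = &psi; = 180&deg;.** Construction protocols for
  disordered peptides say "extended" without parameterizing it; the fully
  stretched chain is the stated convention here, giving a 16-residue
  A&beta; fragment a mass-weighted R~g~ of 17.2 &Aring; (~3.6 &Aring; rise
  per residue).
* **The ideal-helix calibration uses the basin centre (-60, -40).** At that
  centre the i+4&rarr;i O&hellip;N separations come out at 3.39 &Aring; —
  bonded by the Kabsch–Sander energy criterion, though longer than the
  2.8–3.2 &Aring; textbook window, which the builder reproduces at the
  canonical helix (-57, -47). Tests assert the energy criterion at the
  basin centre and the distance window at the canonical helix.

`build_phenanthroline()` constructs 1,10-phenanthroline (C12N2, 14 heavy
atoms) as three fused regular hexagons with 1.40 &Aring; aromatic bonds;
the chelating nitrogens are the bay positions of the outer rings.
`include_pt = TRUE` adds the platinum in-plane on the bay bisector at its
2.06 &Aring; Pt–N equilibrium distance, giving the Pt(phen) fragment as it
exists in the simulated complex. The distinction matters for calibration:
the bare ligand's mass-weighted R~g~ is 2.49 &Aring; (an MMFF-optimized
phenanthroline gives the same value to within 0.02 &Aring;), while the
Pt-containing fragment — platinum is heavy and sits at the ligand's edge —
has R~g~ = 2.28 &Aring;. A reported ligand R~g~ of 2.3 &Aring; is therefore
a *fragment* quantity, and the calibration target treats it as such.

`compose_ensemble()` turns an `ensemble_spec` into a labelled trajectory:
class counts by largest-remainder apportionment of the requested fractions
(so a 40/60 request at n = 500 is exactly 200/300), a seeded shuffle for
frame order, per-residue random dihedrals from the &beta;/PPII/extended
basins with &plusmn;20&deg; jitter for `coil` frames, and i.i.d. Gaussian
coordinate noise. Interactions (salt bridges, hydrogen bonds, ligand
stacking poses) are *injected* into exactly `round(occupancy x n_frames)`
seeded-chosen frames by rigidly repositioning the relevant side chain or
ligand; noise is applied first and the injection re-posed on the noisy
coordinates, so the realized occupancy is exact at every noise level. The
generator emulates the *geometric signatures* detectors must recover — it
performs no energy minimization or dynamics, side-chain poses after
injection can be sterically strained, and frames are statistically
independent (no autocorrelation). Passing tests therefore demonstrate
correct detection and bookkeeping, not forcefield realism; agreement with
physical ensembles is a separate, data-dependent question.

## Geometry

Superposition uses the Kabsch SVD construction with the determinant
correction that excludes reflections; the test suite cross-checks RMSD
values against an independent quaternion (Horn) implementation at 10^-9
tolerance. RMSF aligns all frames to the running mean structure (two
passes) before measuring fluctuations — the dominant convention — and
reports per-residue values as the C&alpha; RMSF, matching how per-residue
flexibility is conventionally plotted.

The gyration tensor `S = sum_i w_i (x_i - xbar)(x_i - xbar)^T / sum_i w_i`
is mass-weighted by default (switchable). Its descending eigenvalues sum to
R~g~^2 exactly. Two anisotropy conventions circulate; this package's
`anisotropy` is `(lambda2 + lambda3) / (2 lambda1)`, which is 0 for an
ideal linear chain and 1 for a fully symmetric distribution — the
convention used in the application domain — while the more common relative
shape anisotropy &kappa;^2 (1 for a line, 0 for a sphere) is exported
alongside as `kappa2` to avoid ambiguity.

Harmonic metal-site terms evaluate `E = k (r - r0)^2` and
`E = k (theta - theta0)^2`. The bundled Pt parameters are
[2.06 &Aring;, 107] and [2.05 &Aring;, 127 kcal mol^-1 &Aring;^-2] for
Pt–N~phen~ and Pt–N~His~, with chelate-distorted angle terms (81&deg;/169
through 176&deg;/167). Angle force constants of that magnitude are only
physically plausible per rad^2 (167 kcal mol^-1 deg^-2 would make a
1&deg; bend cost 167 kcal/mol), so radians are the default displacement
unit, with a flag for the literal per-degree reading.

## Secondary structure

`assign_dssp()` is a from-scratch Kabsch–Sander implementation. Backbone
amide hydrogens are reconstructed at 1.01 &Aring; along the direction
opposing the bisector of N's bonds to C(i-1) and C&alpha; — the
reconstruction the algorithm itself defines — with chain-start and proline
donors excluded. The electrostatic bond energy is

    E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol

with a bond when E < -0.5 kcal/mol. n-turns (n = 3, 4, 5) come from
i+n&rarr;i bonds; two consecutive turns make minimal G/H/I helices;
parallel and antiparallel bridges follow the classic patterns (note the
bookkeeping direction: Kabsch–Sander's Hbond(i, j) is CO(i)&larr;NH(j)),
ladders of two or more consecutive bridges become E and isolated bridges B;
T fills unlabelled turn interiors; S marks bends where the C&alpha;
direction changes by more than 70&deg;. Label collisions resolve with
priority H > E/B > G > I > T > S, and peptide-bond breaks (C–N > 2.5
&Aring;) interrupt donors, turns and bends, so two docked strands with
distinct chain identifiers are handled correctly. Grouped summaries follow
the reporting convention helix = H+G+I, sheet = E+B, other = T+S+C.

The suite validates the assignment constructively (ideal helices &rarr; H,
3,10 builds &rarr; G, docked two-strand sheets &rarr; E with the correct
parallel/antiparallel sense) and cross-validates against an independent
established implementation (mdtraj's DSSP) on a mixed synthetic ensemble,
requiring &ge;95% per-residue agreement on the simplified H/E/C alphabet;
in practice agreement is 100%.

## Interactions

* **Hydrogen bonds** (geometric detector, distinct from the Kabsch–Sander
  energy used for secondary structure): heavy donor–acceptor distance
  &le; 3.0 &Aring; and donor–H&hellip;acceptor angle &ge; 135&deg;. No
  single criterion is universal, so both cutoffs are arguments and the
  defaults are fixed and documented for reproducibility. Polar hydrogens
  are reconstructed where geometry determines them (amide, guanidinium,
  ammonium — staggered, imidazole/indole — in-plane bisector, amide NH~2~ —
  in-plane &plusmn;120&deg;); rotatable hydroxyls (Ser/Thr/Tyr) are
  underdetermined and are treated as pointing at the candidate acceptor,
  i.e. distance-only — a deliberate, documented approximation.
  Backbone–backbone bonds are classified by donor-minus-acceptor offset
  (i+3&rarr;i, i+4&rarr;i, i+5&rarr;i — the 3,10-, &alpha;- and
  &pi;-helical signatures).
* **Salt bridges**: any O–N contact < 3.2 &Aring; between charged groups —
  Asp/Glu carboxylates and the C-terminal carboxylate versus Lys N&zeta;,
  Arg N&epsilon;/N&eta; and the N-terminal amine. His is treated as neutral
  (physiological-pH protonation; in the Pt systems His6/13/14 are
  metal-coordinated or neutral). Occupancy is the fraction of frames with
  any qualifying contact.
* **Ligand contacts** expose both monitoring conventions: the
  C&alpha;/C&beta;/C&gamma;-to-ligand-carbon minimum distance (reported as
  mean &plusmn; SD) and the any-heavy-atom minimum from which the < 5
  &Aring; contact fraction is computed. The two differ, and conflating them
  changes contact fractions by several percentage points.
* **&pi;-stacking**: ring centroids are unweighted means, plane normals
  come from least-squares (SVD) fits, interplanar angles fold to
  [0&deg;, 90&deg;]. The search reports the closest-contact frame per ring
  pair (the closest of phenanthroline's three rings is recorded), and a
  frame counts as stacked for occupancy at centroid distance &le; 4.5
  &Aring; and angle &le; 30&deg; — conventional face-to-face criteria,
  both exposed as arguments.

## Clustering and Ramachandran analysis

Pairwise frame distances are best-fit backbone RMSDs, each pair superposed
independently. DBSCAN runs directly on that matrix with &epsilon; = 0.8 and
MinPoints = 5 as defaults; &epsilon; is interpreted in &Aring;ngstr&ouml;m
of backbone RMSD, its natural unit given the metric. Border points join the
first cluster that reaches them in scan order (classic DBSCAN), which makes
labels deterministic given frame order — the property the label-stability
tests rely on; an independent brute-force reachability implementation
serves as the test oracle. Cluster representatives are medoids (minimum
summed intra-cluster distance, ties to the lowest frame index).

Ramachandran pairs are binned on a 5&deg; grid and attributed to named
basins by nearest centre within a 30&deg; Chebyshev radius (circular):
&alpha;R (-60, -40), PPII (-75, 150), &beta; (-150, 160), &gamma;'
(-80, +80), &alpha;L (+60, +40). The &alpha;L centre is the standard
convention; applications typically mention left-handed helical content
without printing a centre.

## REMD utilities

Temperature ladders are geometric, `T_i = T_min (T_max/T_min)^(i/(n-1))`
(equal log-spacing), with 270–615 K defaults. Production ladders tuned by
heat-capacity-aware generators will not coincide with the geometric ladder;
published replica temperatures such as 299.3 K are therefore treated as
inputs (`nearest_temperature()` finds the replica closest to a 300 K
target, ties to the lower temperature), never regenerated. Exchange logs
are plain text (`attempt i j accepted`); `exchange_frequency()` reports
both the overall acceptance fraction and per-neighbour-pair fractions,
since "exchange frequency" is used ambiguously in the literature and the
two statistics answer different questions. The Metropolis criterion
`p = min(1, exp[(1/kT_i - 1/kT_j)(E_i - E_j)])` satisfies detailed balance
exactly, which the suite checks both algebraically and by Monte-Carlo
simulation against the closed-form expectation.

## Numerical choices and degenerate inputs

Superposition requires &ge;3 non-collinear points; gyration of a single
atom returns R~g~ = 0 with anisotropy defined as 1 (fully symmetric);
collinear sets give anisotropy exactly 0. Eigenvalues are clipped at zero
against floating-point noise, distance matrices at zero before square
roots. Dihedrals use the IUPAC sign convention and live in (-180&deg;,
180&deg;]; termini and chain breaks report `NA`. Peptides shorter than five
residues cannot host any Kabsch–Sander pattern and are labelled all-coil
with a warning. CSV exports use fixed 4-decimal formatting so reruns are
byte-comparable; all stochastic stages consume a single integer seed, and
identical seeds give identical output across runs.

Problem sizes in the shipped tests are chosen to keep the full suite under
a minute on one core while leaving no stage untested: property loops use
5-point random sets (100 repetitions), clustering oracles 50-frame
matrices, occupancy recovery 60-frame ensembles, and the helix/coil
composition recovery 500 frames — at which the binomial standard error of
a 40% fraction (~2.2% per frame-set, far less across 10 interior residues)
sits comfortably inside the 2-percentage-point assertion.

## Known limitations

* The builder's single-rotamer side chains and translation-based
  interaction injections produce locally strained geometry; synthetic
  ensembles validate detectors, not physics.
* DSSP variants differ in helix/bridge precedence details; this
  implementation fixes one documented priority ordering, so
  percentage-level agreement with other implementations on borderline
  residues is approximate (the cross-validation test uses the simplified
  alphabet for that reason).
* The hydroxyl-donor convention makes Ser/Thr/Tyr hydrogen bonds
  effectively distance-only.
* Binary trajectory formats (DCD/XTC/NetCDF), mmCIF, multi-chain
  assemblies beyond two docked strands, altloc records and solvent are out
  of scope.
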
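# idpkit

Conformational-ensemble analysis for intrinsically disordered peptides, in
R. The package targets studies of amyloid-beta (Aβ16/Aβ42) carrying a
coordinated platinum–phenanthroline fragment, sampled by replica-exchange
molecular dynamics (REMD), but every tool works on any multi-model PDB
trajectory of a single peptide chain with an optional ligand.

Disordered peptides have no native structure: the object of study is the
ensemble, and the analyses are ensemble statistics.

* **Superposition & deviations** — Kabsch (SVD) best-fit superposition;
  per-frame RMSD against a fixed reference; per-residue RMSF about the
  iteratively aligned mean structure.
* **Shape** — radius of gyration
  `Rg² = Σ mᵢ|xᵢ − x̄|² / Σ mᵢ` and the gyration tensor
  `S = Σ mᵢ (xᵢ − x̄)(xᵢ − x̄)ᵀ / Σ mᵢ` with eigenvalues
  λ₁ ≥ λ₂ ≥ λ₃; anisotropy `(λ₂+λ₃)/(2λ₁)` (0 = linear chain,
  1 = fully symmetric) with the conventional κ² alongside.
* **Secondary structure** — a from-scratch Kabsch–Sander (DSSP)
  implementation: amide-H reconstruction, electrostatic bond energy
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` with bonds below
  −0.5 kcal/mol, n-turns, helices (H/G/I), bridges and ladders (E/B),
  turns, bends; grouped as helix = H+G+I, sheet = E+B, other = T+S+C.
* **Interactions** — hydrogen bonds (3.0 Å / 135° geometric criterion,
  classified i+3→i / i+4→i / i+5→i), salt bridges (any charged-group O–N
  contact < 3.2 Å), peptide–ligand contact fractions (< 5 Å), π-stacking
  (ring-centroid distance and interplanar angle), Cα contact maps — all as
  fraction-of-frames occupancy tables.
* **Ensemble structure** — pairwise best-fit backbone-RMSD matrices,
  DBSCAN clustering (ε = 0.8 Å, MinPoints = 5) with medoid
  representatives, Ramachandran histograms with named-basin fractions.
* **REMD utilities** — geometric temperature ladders (270–615 K defaults),
  exchange-log acceptance statistics, the Metropolis exchange criterion.
* **Synthetic conformers** — a deterministic generator that builds ideal
  peptides from internal coordinates at prescribed φ/ψ, an idealized
  planar phenanthroline (with or without its Pt), posed stacking
  geometries, and labelled ensembles with interactions injected at exact
  occupancies, so every stage above is testable against known ground
  truth.

## Worked example

```r
library(idpkit)
seqs <- abeta_sequences()          # Abeta16 / Abeta42 sequences

# ideal-geometry calibration
gyration(build_phenanthroline(include_pt = TRUE))$rg   # 2.28 A
gyration(build_peptide(seqs$abeta16, c(180, 180)))$rg  # 17.21 A (extended)
gyration(build_peptide(seqs$abeta16, c(-60, -40)))$rg  # 8.60 A (alpha-helix)

# a labelled synthetic ensemble: 40% helical / 60% coil frames, with a
# Glu3-Arg5 salt bridge present in 76% of frames
spec <- ensemble_spec(seqs$abeta16, n_frames = 200,
                      class_fractions = c(alpha = 0.4, coil = 0.6),
                      noise_sigma = 0.1, seed = 42,
                      injections = list(list(type = "salt_bridge",
                                             acidic_res = 3, basic_res = 5,
                                             distance = 3.0, occupancy = 0.76)))
ens <- compose_ensemble(spec)

ss_summary(assign_dssp(ens$trajectory))$grouped
#> helix sheet other
#>  34.8   0.0  65.2
head(salt_bridges(ens$trajectory)[, c("key", "occupancy")], 3)
#>          key occupancy
#>    Glu3-Arg5      0.76
#>    Asp1-Arg5      0.00
#>   Asp1-Lys16      0.00
```

The grouped helix content (34.8%) is the 40% helical frames seen through
whole-sequence averaging — termini never acquire helix labels — and the
detected salt-bridge occupancy recovers the injected 0.76 exactly. Writing
the ensemble out with `write_pdb_models()` and running
`run_full_report(analysis_config(...))` produces the full CSV/JSON bundle
(RMSD/Rg, RMSF, shape descriptors, secondary structure, hydrogen bonds,
salt bridges, contact map, Ramachandran fractions, clusters) with a
manifest; a command-line wrapper over the same functions is in
`inst/scripts/idpkit.R`.

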
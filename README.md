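# ppiiens

Conformational-ensemble analysis of polyproline-II (PPII) content in
mucin-domain peptides.

## The problem

The mucin domain of lubricin (PRG4), the glycoprotein that lubricates
articular cartilage, is built from KEPAPTTP-like tandem repeats whose
threonines carry O-linked GalNAc-Gal glycans. Its proline richness
forbids regular alpha-helix and beta-sheet, but not the polyproline type
II helix — a left-handed, three-residues-per-turn conformation at
backbone dihedrals near (φ, ψ) = (−75°, 145°). Whether PPII dominates,
and whether glycosylation reinforces it, is assessed from conformational
ensembles of model peptides such as the 18-mer PKEPAPTTTKEPAPTTPK
(residues 393–410; four of its five threonines glycosylated, Thr401
bare).

`ppiiens` provides the full analysis chain for such ensembles, for
structural-bioinformatics users who want each stage as a tested,
scriptable R function:

* **Model building** — sequence handling, O-glycosylation site
  assignment, ideal-geometry backbone coordinates from dihedral
  assignments (exact NeRF chain extension), helix-parameter fits,
  multi-model PDB input/output.
* **Synthetic ensembles** — per-residue wrapped-normal basin mixtures
  (PPII / beta / alphaR / alphaL) with a configurable
  glycosylation-dependent weight shift alphaR → PPII, plus a toy
  replica-exchange Monte Carlo sampler on geometric temperature ladders
  with Metropolis configuration swaps.
* **Ramachandran free-energy surfaces** — 2D dihedral histograms over the
  full torus and Boltzmann inversion relative to the modal bin,
  ΔG(φ, ψ) = −k_B·T·ln[P(φ, ψ)/P_max].
* **Region populations** — explicit-boundary classification into alphaR,
  beta, PPII, alphaL and coil (circular semantics, strict bounds),
  per-residue populations with moving-block-bootstrap confidence
  intervals, and a two-ensemble comparison test at α = 0.05.
* **Convergence diagnostics** — per-frame radius of gyration
  (Rg = √[(1/M)·Σ mᵢ·(rᵢ − R)²]) split into two intervals, 50-bin
  histogram-intersection overlap, pass at ≥ 90%.

## Worked example

```r
library(ppiiens)

model <- mucin_model(glycosylated = TRUE)
model
#> peptide_model: PKEPAPTTTKEPAPTTPK
#>   residues 393 - 410 (18 residues)
#>   O-glycosylation sites: 399, 400, 407, 408

hp <- helix_parameters(build_backbone(mucin_model()))
#> twist -120.2 deg/residue, 2.99 residues/turn, left-handed

rep <- run_pipeline(default_pipeline_config(seed = 1))
rep$convergence
#> overlap_report: 92.0% overlap (50 bins, 2500 + 2500 frames)
#>   threshold 90%: PASS (convergent sampling)
summary(rep$fes)
#> free_energy_surface: 72x72 bins at 300 K, P_max = 0.00878
#>   occupied bins: 1467 of 5184; max defined dG = 3.978 kcal/mol
#>   global minimum bin centre: phi -77.5, psi 147.5 -> PPII
```

Reading the numbers: the ideal-geometry chain built at the canonical PPII
dihedrals is a left-handed helix with three residues per turn; the
synthetic 300 K ensemble is stationary (interval Rg histograms overlap
92%, above the 90% convergence criterion); and the free-energy surface
has its global minimum in the PPII region, with all other occupied bins
within ~4 kcal/mol of it. `run_glyco_comparison()` additionally flags the
glycosylated threonines as significantly PPII-enriched and
alphaR-depleted relative to the bare peptide.

See `vignette("ppii-ensemble-analysis")` for the model, its assumptions
and every tunable parameter.

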
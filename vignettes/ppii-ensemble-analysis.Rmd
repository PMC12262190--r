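---
title: "Analysing polyproline-II content in mucin-domain peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing polyproline-II content in mucin-domain peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiiens)
```

## The scientific problem

Lubricin (PRG4), the boundary lubricant of articular cartilage, carries a
large central mucin domain built from KEPAPTTP-like tandem repeats whose
threonines are densely O-glycosylated with GalNAc-Gal disaccharides. The
domain's proline richness rules out regular alpha-helix and beta-sheet, yet
it need not be fully disordered: the polyproline type II (PPII) helix — a
left-handed helix with backbone dihedrals near (phi, psi) = (-75°, 145°)
and three residues per turn, stabilised by backbone solvation rather than
hydrogen bonding — is the natural candidate, and proline, alanine and
lysine (five of the eight repeat residues) all have high intrinsic PPII
propensity.

`ppiiens` implements the analysis chain with which such a hypothesis is
examined on conformational ensembles of model peptides: the 18-mer
mucin-domain subsection (residues 393–410, PKEPAPTTTKEPAPTTPK, with four
of its five threonines glycosylated — Thr401 is known to be bare) and a
TTTT tetrapeptide. The package supplies every stage as a tested function:
peptide model construction, synthetic ensemble generation, a toy
replica-exchange Monte Carlo sampler, Ramachandran free-energy surfaces,
secondary-structure region populations with uncertainty, and a
radius-of-gyration convergence diagnostic.

Production ensembles of this kind come from explicit-solvent
replica-exchange molecular dynamics. That machinery is deliberately *not*
reimplemented here; the package's synthetic generator and toy sampler
reproduce the statistical structure the analysis assumes, so every
analysis function can be validated against exact oracles at desk scale.

## Peptide models and ideal-geometry backbones

A `peptide_model` couples a sequence to residue numbering, glycosylation
site flags and a per-residue dihedral assignment. Glycans are represented
only as site flags and as ensemble-statistics shifts — no glycan atoms are
ever built, and sidechains, hydrogens and solvent are out of scope.

`build_backbone()` converts a dihedral assignment into Cartesian N, CA, C,
O coordinates by sequential natural-extension (NeRF) chain placement with
Engh–Huber-style ideal geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å;
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°; trans peptide bonds,
omega = 180°). The builder is exactly invertible: re-measuring phi/psi
from the coordinates reproduces the assignment to below 1e-6° at every
interior residue, which the test suite exercises on random assignments.

```{r backbone}
model <- mucin_model(glycosylated = TRUE)
model
bb <- build_backbone(model)
helix_parameters(bb)
```

For the canonical PPII assignment the helix fit (axis estimated from the
second differences of the CA trace, twist as the signed rotation of the
radial vectors about that axis) returns three residues per turn and a
negative twist, i.e. a left-handed helix; a canonical alpha-helix input
(-57, -47) gives ~3.6 residues per turn, right-handed.

## The synthetic ensemble generator — what it emulates

Each residue's (phi, psi) distribution is a weighted mixture of
secondary-structure *basins* (PPII, beta, alphaR, alphaL), each an
isotropic wrapped-normal centred inside the corresponding classification
rectangle. The concentration parameter kappa maps to an angular standard
deviation of (180/pi)/sqrt(kappa) degrees — the large-kappa von Mises
limit — and defaults to kappa = 12 (about 16.5°), a realistic width for
Ramachandran basins at 300 K.

Basin centres default to PPII (-75, 145) (the canonical PPII point), beta
(-135, 135), alphaR (-63, -60) and alphaL (60, 45); all four sit inside
their classification rectangles so that configured weights and classified
populations agree when basins are tight. The alphaR centre was placed at
psi = -60° (rather than at the textbook alpha-helical psi ≈ -45°) because
the alphaR classification band used here requires psi < -50°; a centre on
the band edge would make population recovery impossible by construction.

Default per-residue weights are PPII-dominant and residue-type aware
(prolines almost pure PPII/beta; threonines keep a 0.35 alphaR component).
Glycosylation acts purely statistically: at a glycosylated site,
`glyco_weight_shift` (default 0.3) of probability mass moves from alphaR
into PPII, emulating the steric destabilisation of the compact alphaR
conformation by the bulky O-linked glycan. These defaults are the
package's standard study conditions; they are configuration, not fitted
quantities.

What the generator does *not* emulate: temporal autocorrelation (frames
are i.i.d. unless the toy sampler is used), inter-residue cooperativity
(residues are independent, so the neighbour-coupling effect seen for
unglycosylated threonines flanked by glycosylated ones is not modelled),
and any sequence-dependent coupling between phi and psi within a basin.
Passing tests therefore validate the *analysis machinery*, not claims
about real glycopeptide ensembles.

## The toy replica-exchange sampler

`remd_run()` runs parallel Metropolis samplers on the energy landscape
U(phi, psi) = -kB·T_ref·ln(mixture density), one replica per rung of a
geometric temperature ladder (`make_ladder()`; presets: 64 replicas
spanning 300–455.95 K, 32 spanning 300–452.32 K, and a desk-scale 8-rung
default). Proposals are symmetric wrapped Gaussians of width 25° per
angle (no Hastings correction needed); every `exchange_interval` sweeps
(default 10, the stand-in for "attempt exchanges every picosecond"),
neighbouring temperatures attempt configuration swaps on alternating
even/odd pairs with the Metropolis probability
min(1, exp[(1/kB·T_i − 1/kB·T_j)(U_i − U_j)]). Trajectories are recorded
per temperature slot, so each output trajectory samples one fixed
temperature.

Because residues are independent and the landscape is an explicit
mixture, the stationary distribution at T = T_ref is *exactly* the
mixture density. The tests exploit this: a long fixed-temperature run is
compared against 2°-grid quadrature of the density, and the
total-variation distance on a coarse binning must stay below 0.05.
Randomness is controlled by one explicit seed.

## Ramachandran free-energy surfaces

`histogram2d()` bins pooled (phi, psi) pairs on a uniform grid over
[-180, 180)² (default 72×72, i.e. 5° bins — fine enough to resolve every
region rectangle; the bin count is configurable). `free_energy_surface()`
performs Boltzmann inversion relative to the modal bin,

$$\Delta G(\phi,\psi) = -k_B T \,\ln\frac{P(\phi,\psi)}{P_{max}},$$

with kB = 0.0019872041 kcal mol⁻¹ K⁻¹ and T defaulting to 300 K (the
analysis temperature). The modal bin is exactly 0, every defined bin is
nonnegative, empty bins are reported as +Inf (undefined), and
exp(-ΔG/kBT)·P_max recovers P to 1e-12 — all asserted in the suite.

## Region classification and populations

The named regions are rectangles on the (phi, psi) torus:

| region | phi | psi |
|---|---|---|
| alphaR | (-160, -20) | (-120, -50) |
| beta   | (-180, -90) | (50, 240)   |
| PPII   | (-90, 20)   | (50, 240)   |
| alphaL | (30, 100)   | (0, 80)     |

with "coil" as the catch-all. Bounds above 180° wrap: psi < 240° admits
psi in (50°, 180°] together with [-180°, -120°) on the reported scale.
All inequalities are strict as printed; an angle exactly on a bound is a
measure-zero event and falls to coil. Disjointness of the named regions
is verified by an exhaustive 1° torus scan in the tests.

`residue_populations()` gives per-residue label fractions;
`population_ci()` adds percentile confidence intervals from a
moving-block bootstrap over frames (block length 1 = i.i.d. bootstrap;
longer blocks preserve autocorrelation in Monte Carlo trajectories).
`compare_populations()` bootstraps two ensembles independently and calls
a difference significant at level alpha (default 0.05) when its
(1 − alpha) percentile CI excludes zero. The procedure is per residue and
per region, with no multiplicity correction — calls are reported
individually, and the suite checks both power (a constructed
alphaR→PPII shift of 0.3 is detected with the right directions) and
type-I calibration under the null at reduced replicates.

```{r compare}
base <- c(PPII = 0.45, alphaR = 0.35, beta = 0.15, alphaL = 0.05)
plain <- residue_ensemble_spec(base)
glyc  <- residue_ensemble_spec(base, glycosylated = TRUE)
ta <- sample_ensemble(plain, 4000, seed = 1)
tb <- sample_ensemble(glyc,  4000, seed = 2)
compare_populations(ta, tb, n_boot = 300, seed = 3)
```

## Convergence diagnostic

`convergence_report()` computes the per-frame radius of gyration over the
backbone heavy atoms (standard masses; the carbonyl O is included — the
diagnostic needs only internal consistency, so the exact atom selection
is a convention), splits the series into two independent intervals
(halves by default), histograms both on a common 50-bin grid spanning the
union range, and scores the histogram intersection
$\sum_b \min(p_b, q_b)$ — the simplest estimator of distributional
overlap. Sampling is called convergent at or above the 0.90 threshold. A
degenerate pair occupying fewer than two bins is flagged and never
reported as a pass. On stationary synthetic ensembles of the 18-mer
(5000-frame halves) the overlap lands around 94–96%; concatenating two
different-condition ensembles drives it far below 90%.

## The pipeline

`run_pipeline()` chains the stages in protocol order — model, ensemble
spec, sampling (i.i.d. or toy REMD, keeping the analysis-temperature
replica), burn-in discard (default: the first half of the frames, the
standard discard for a 200 ns run analysed over its last 100 ns),
backbone build, Rg convergence, free-energy surface, populations with
CIs — and returns a report carrying a provenance block (config hash,
package and R versions). `run_glyco_comparison()` runs both glycosylation
arms and the population comparison. Configurations are plain nested lists,
serialisable to YAML (`read_pipeline_config()` merges a partial file over
the defaults); every run requires an explicit seed and is bit-reproducible
given it.

## Numerical choices and problem sizes

* Angles: degrees, IUPAC sign convention, always wrapped to [-180, 180).
* Wrapped-normal densities sum images over k = -6..6; truncation error is
  far below 1e-12 at the spreads used.
* The default suite runs at desk scale: 10,000-frame i.i.d. ensembles for
  the convergence worked example, 20,000–25,000 sweeps for the
  fixed-temperature Boltzmann check, 20,000 frames for weight-recovery
  and shift-detection checks, 30 null replicates for type-I calibration.
  These sizes keep Monte Carlo error comfortably inside each assertion's
  tolerance.
* Ties at bin edges on the last Rg histogram bin are closed on the right.

## Known limitations

* The free-energy surfaces carry no multi-temperature reweighting
  (no WHAM/MBAR); only the analysis-temperature replica is used.
* No DSSP-style hydrogen-bond secondary-structure assignment; the region
  classification is purely dihedral.
* The regional free-energy magnitudes reported from large explicit-solvent
  simulations (fractions of a kcal/mol to a few kcal/mol) are not targets
  of the synthetic conditions; the package reproduces the *procedure* and
  its worked-example identities, not those production numbers.
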
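---
title: "Methods: Fab structural and ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fab structural and ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fablens)
```

This vignette documents the models, conventions and numerical choices behind
`fablens`, in the spirit of a methods section: what each quantity means, which
knobs matter, and what the synthetic ground truth does and does not
demonstrate about real data.

## The system and the quantities

An antibody Fab consists of a heavy-chain fragment (VH + CH1) paired with a
light chain (VL + CL). Two degrees of freedom dominate comparisons between
Fab structures:

* the **elbow angle** between the variable module (VH/VL) and the constant
  module (CH1/CL), which reports the hinge bend of the molecule, and
* the **solvent exposure of aggregation-prone regions (APRs)**, short residue
  windows whose burial protects against aggregation.

Around these sit standard observables: matched-residue Cα RMSD between
structures, per-residue RMSF over trajectory windows, the radius of gyration,
and SAXS profiles with reduced-χ² fits against experimental curves.

## Domain annotation

`annotate_fab()` assigns the four domains by residue ranges. The defaults —
VL = residues 1–109 of the light chain, VH = 1–117 of the heavy chain, with
CL/CH1 as the remainder of each chain — follow the common Fab numbering
convention in which the variable domains open each chain. Both boundaries are
overridable; overriding a variable boundary moves the start of the paired
constant domain unless that is set explicitly. Residue identity everywhere is
(chain, author residue number, insertion code); concatenated through-numbering
is never used internally.

## Pseudo-dyad axes and the elbow angle

Each Fab module is approximately twofold symmetric: a rotation of about 180°
superposes VH onto VL, and CH1 onto CL. `pseudo_dyad()` computes that
rotation by a Kabsch fit over a **fixed residue correspondence**: the Cα at
offset *k* from the start of the heavy-chain domain pairs with the Cα at
offset *k* from the start of the light-chain domain, over the offsets present
in both. On gap-free domains this is exactly "i-th with i-th, trimmed to the
shorter domain" (VH 1–117 against VL 1–109 gives 109 pairs); when a loop is
unresolved, its offsets simply drop out instead of shearing the pairing. The
paired Ig domains share a fold with near-collinear numbering, so an
offset-based pairing is adequate; a structure-based alignment would change
the axis by well under the tolerance that matters here (about 2°). A fit
whose rotation angle falls below 150° earns a "poor pseudo-symmetry" warning
— the axis of a rotation far from 180° no longer represents a dyad.

The **elbow angle** is the intersection angle of the two dyad axes. A fitted
rotation axis has an arbitrary sign, so both axes are first oriented to have
a non-negative projection onto the vector from the constant-region Cα
centroid to the variable-region Cα centroid; the angle is then
`acos(â_V · â_C)`, reported in (0°, 180°]. Two degenerate situations are
handled explicitly:

* an axis within 10° of perpendicular to the orientation vector makes the
  sign choice ill-conditioned; a convention warning is attached (for typical
  Fab elbow angles of 140–160° the axes sit 70–80° from the orientation
  vector, so this warning is informational, not fatal);
* when both projections are numerically negligible and the oriented axes come
  out nearly *parallel* (angle < 90°), the antiparallel branch `180° − θ` is
  taken. This keeps the straight-Fab limit at 180° instead of collapsing it
  to 0°, and only engages when the projection test carries no information.

Angles above 180° (the extended crystallographic convention) are not
representable; Fab elbow angles in the 120–180° range are unaffected. This is
a documented limitation.

## Superposition, RMSD and RMSF

`kabsch_fit()` solves the weighted least-squares superposition through the
SVD of the weighted covariance matrix and never returns a reflection (the
smallest singular direction is flipped when the determinant demands it).
Cα fits default to uniform weights, the common convention for Cα RMSD.
`rmsd_matched_ca()` matches residues across two annotated structures by
identical (chain role, residue number, insertion code) and restricts both the
fit and the RMSD to the chosen selection (all four domains, variable only,
constant only, or an explicit domain set).

`rmsf_windowed()` computes per-residue RMSF within a time window against the
window-mean structure, with one mean→fit→re-mean iteration: frames are first
fitted to the raw coordinate mean, a refined mean is formed from the fitted
frames, and frames are refitted to it. This reference is less biased than
frame 1 and removes rigid-body motion, so pure tumbling gives RMSF ≈ 0. The
window convention is half-open `[start, end)`, with the trajectory's final
instant included when the window ends exactly there.

## Solvent-accessible surface area

`shrake_rupley()` samples each atom's probe-extended sphere (radius
`r_i + r_probe`) with a deterministic golden-spiral point set and counts the
fraction of points outside every neighbour's extended sphere. Two numerical
refinements matter:

* each atom's point set receives a fixed quasi-random orientation derived
  from its index (a Shoemake quaternion from low-discrepancy sequences), so
  quadrature errors decorrelate across atoms and totals become insensitive to
  global rotation of the structure (relative changes ~10⁻⁴ at 960 points);
* points within one point-spacing of a burial boundary contribute
  fractionally (linear transition over `h = 2R√(π/N)`), which suppresses the
  aliasing error of a hard in/out count by roughly a factor of two at equal
  N. At the default 960 points, per-atom values sit within ~1% of a
  dense-quadrature reference on bonded-atom geometries.

Defaults: radii C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å; probe 1.4 Å;
960 points. All are configurable (`radii_set()`), and unknown elements either
use a caller-supplied fallback radius or raise an error listing the offending
elements. Hydrogens participate only when present in the input, so crystal
structures (no H) and simulation frames (with H) differ systematically; atom
counts are carried in the outputs to keep that visible. SASA is reported in
Å² with an nm² convenience column.

APR windows are residue ranges on the heavy or light chain; the default table
contains the four windows with elevated low-pH exposure in the study system
(heavy 173–188, light 129–139, 47–51, 31–36), and further windows can be
supplied as a TSV. A window referencing absent residues carries an explicit
`missing_residues` annotation rather than being silently truncated.
`window_average()` computes the per-repeat time mean over a window and then
the cross-repeat mean and SEM (sample SD / √n) — SEM always refers to
variation *across repeats*, never across frames.

## Trajectories and repeat statistics

Trajectories are ordered coordinate frames over one topology with an explicit
`dt_ns` (the frame-saving interval is always a user input, never guessed) and
a repeat label. Multi-model PDB and DCD files are read via `bio3d`; XTC is
not supported — convert first. Repeat aggregation requires identical time
grids and performs no interpolation: silent resampling hides errors, so
mismatched grids are an error. Equilibration handling is likewise explicit: a
`discard_ns` parameter drops initial frames from aggregated statistics
(nothing is hard-coded).

Inter-chain hydrogen bonds use conventional geometric criteria — donor–
acceptor (N/O) distance ≤ 3.5 Å, and D–H⋯A angle ≥ 120° when hydrogens are
present — deduplicated to residue pairs across the heavy/light interface.
These counts are diagnostics; they depend on cutoff choices and are not
calibrated against any external standard.

## SAXS: forward model and fitting

`debye_profile()` evaluates the orientation-averaged Debye sum with constant
form factors: per-atom electron counts in `atomic` mode, or per-residue
electron counts placed at the Cα in `residue_cg` mode (the default for
trajectories, where the O(N²) pair sum dominates). Pair distances can be
binned (default 0.5 Å) — at that width binned intensities stay within 0.5% of
the exact double sum for q ≤ 0.3 Å⁻¹ — and `bin_width = 0` keeps the exact
sum. This is a **vacuum** model: no excluded-volume or hydration-shell terms.
Absolute χ² values against real, solvent-subtracted data therefore depend on
solvent treatment and are not comparable across forward models; the fitting
machinery is validated on self-consistent synthetic data instead.

`chi_square_fit()` interpolates the calculated profile linearly onto the
experimental q grid (experimental σ is never interpolated; points outside the
calculated range are excluded and counted), applies the closed-form optimal
scale `c = Σ(I_c I_e/σ²)/Σ(I_c²/σ²)`, and reports
`χ² = Σ((c·I_c − I_e)/σ)²/(N−1)` — the reduced-χ² convention with one fitted
parameter. An additive-background variant exists but is off by default; a
free background can absorb genuine misfit. Fitting a profile against a curve
generated from it with σ(q) = 2% of I(q) yields a mean reduced χ² of 1
within a few percent over 50 noise realisations, which is the package's
calibration check. `guinier_rg()` iterates the standard `ln I` vs `q²` fit
until `q_max·Rg ≤ 1.3` (configurable) and errors rather than extrapolating
when fewer than 5 points remain.

`top_n_frames()` ranks frames by χ² across repeats with a deterministic tie
break (repeat label, then earlier time), computes the pairwise matched-Cα
RMSD matrix of the winners, and can write them as a multi-model PDB.

## The synthetic generator: what it does and does not show

`build_toy_fab()` constructs four compact random clusters (Gaussian-placed
points pruned to a sphere, minimum spacing 2.5 Å) and creates each module's
partner domain as an exact 180° copy about a designed dyad axis. The two axes
subtend exactly the designed elbow angle under the package's orientation
convention, and the module centres sit at arm's length `L` from a hinge point
with separation `2L·sin(elbow/2)` — so a straight Fab is maximally extended
and opening the hinge strictly increases Rg, mirroring the qualitative
behaviour of the real molecule. `make_hinge_trajectory()` rotates the
variable module about the hinge normal to follow a scheduled elbow-angle
series, then adds independent Gaussian coordinate noise; repeats differ only
by a deterministic seed offset. `synth_saxs_curve()` adds Gaussian noise of
σ(q) = `noise_fraction`·I(q) to the Debye profile of a known structure and
records the true σ. `build_synthetic_crystal_form()` combines these into
stand-ins for the two crystal forms of the study system: designed elbow
angles of 156° (triclinic-like) and 145° (hexagonal-like), a CH1 loop gap of
6 or 4 residues starting after residue 131, and a heavy chain truncated
before the 11-residue C-terminal hinge span of its 228-residue full sequence.

What passing against this ground truth shows: the geometry, statistics and
fitting machinery are numerically correct, deterministic under seeds, and
recover designed values within stated tolerances (elbow to 0.5° noise-free
and 2° at σ = 0.2 Å over 5 designed angles × 3 seeds; planted best-fit frames
recovered exactly from a 600-frame ensemble). What it does not show: anything
about real Ig folds. The clusters have no β-sandwich topology, no sequence-
structure relationship, no side chains and no solvent, so sequence-dependent
conclusions (e.g. absolute SASA magnitudes or charge values) do not transfer.
Comparisons against the deposited crystal structures require the coordinate
files themselves, which are not redistributed here.

## Charge bookkeeping

`total_formal_charge()` is a deliberate null model: every ionisable group
takes its textbook model pKa (Asp 3.8, Glu 4.2, His 6.0, Cys 8.3, Tyr 10.1,
Lys 10.5, Arg 12.5; N-terminus 8.0, C-terminus 3.1), is protonated iff
pH < pKa, and contributes +1 (protonated base) or −1 (deprotonated acid).
The result is exactly monotone non-increasing in pH. Structure-based pKa
prediction shifts individual pKas by several units in buried or coupled
sites, so this null model is expected to disagree with structure-based
charges, increasingly so at extreme pH; it exists to make charge *trends*
and protonation thresholds testable, not to replace a Poisson–Boltzmann or
empirical pKa method.

## Problem sizes and tolerances used in the checks

The test-suite and acceptance-script sizes were chosen so the full suite runs
in about a minute: toy Fabs of 20–130 atoms per domain, trajectories of 5–500
frames, 6 repeats where repeat statistics matter, a 600-frame ensemble
(6 × 100) for planted-frame recovery, 50 noise realisations for the χ²
calibration, 10⁵ points for the uniform-sphere Rg law, and a 9°-step Euler
grid for the brute-force superposition oracle. Tolerances quoted above are
asserted in the tests at exactly those values; none is tightened or loosened
relative to what the method is claimed to deliver.

## Known limitations

* Elbow angles are confined to (0°, 180°]; the >180° convention is absent.
* The SAXS model is vacuum-only; absolute χ² against real curves is model-
  dependent.
* No sequence alignment: cross-structure matching requires shared author
  numbering.
* No flexible or outlier-rejecting superposition.
* XTC trajectories are not read; DCD and multi-model PDB are.
* SASA has no analytic (power-diagram) mode; accuracy is quadrature-limited,
  with the defaults characterised above.
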
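---
title: "Template-based model building in high-resolution cryo-EM maps: methods and design"
author: "cryobuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based model building in high-resolution cryo-EM maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

At resolutions of about 3.5 Å or better, a single-particle cryo-EM density
map contains enough information to trace a protein's main chain directly:
α-helices and β-strands are individually recognisable, and Cα positions can
be inferred from the local density pattern. `cryobuild` automates this
interpretation in two stages:

1. **Secondary-structure stage.** Pre-computed helix and strand density
   templates are searched in the working map, each placement is refined as a
   rigid body, and the placements are then used to calibrate the map's
   global voxel size, which can be mis-set by up to ~5 % by microscope
   magnification errors.
2. **Cα stage.** A well-determined reference map is brought onto the working
   map's amplitude scale, a log-likelihood (LLK) density target around Cα
   positions is learned from the reference map and its deposited model, and
   Cαs are extended from both ends of the placed secondary structures into
   main-chain fragments. If the sequence is supplied, residue types are
   assigned from per-type LLK targets.

All stages are exercised on packaged synthetic fixtures with exact ground
truth, so the whole pipeline is testable without any external deposition.

# Templates

A template is a standard secondary-structure segment (a 6-residue ideal
helix or a 4-residue ideal strand) together with two scalar fields on a
standard grid centred on the segment's main-chain centre of mass (COM):

* the **mean map**: every window of the template length inside an annotated
  SSE of the training model is superposed (main-chain atoms N, Cα, C, O)
  onto the standard segment; windows with RMSD < 0.5 Å are kept, the
  training map is sampled at the transformed grid points with third-order
  (separable cubic B-spline) interpolation, and the samples are averaged
  per grid point;
* the **correlation map**: grid points are binned by distance to the
  nearest standard-segment atom into 30 groups of 0.5 Å (distances ≥ 15 Å
  are excluded); within each group, the Pearson correlation between each
  window's samples and the mean map is computed and averaged over windows,
  and the group value is broadcast back to its grid points. The correlation
  map therefore measures how *reproducible* the density is at each distance
  from the segment, and is used as a per-point weight.

Design choices the construction leaves open and how we resolved them:

* The RMSD gate is applied over main-chain atoms in Å; the atom selection
  and unit are not forced by the construction itself.
* The standard grid spacing is 0.5 Å — finer than any target voxel size, so
  template resampling never limits accuracy.
* Windows slide by one residue; overlapping windows of a long helix all
  count as training segments.
* The per-group correlation is computed per window and then averaged
  (rather than pooled across windows), matching the scheme this family of
  templates descends from.
* Training at 2.5 Å low-pass filtering is the shipped default; it gave the
  best voxel-calibration accuracy among 2.5/3.0/3.5 Å in our experiments.

# Search, scoring and pose refinement

The **fast search** scores a decimated translation grid (every other voxel,
restricted to the densest quintile of the map) against a quasi-uniform
orientation grid (72 axis directions × 8 rolls ≈ 600 poses), using only the
map values at the template's Cα/CB positions — a deliberately crude but
very fast pre-screen. Because those probe scores rank positions well but
orientations poorly, each surviving candidate centre is re-scored over the
full orientation grid with the weighted CC (below), and snapped to the best
neighbouring voxel.

The **weighted CC** between a placed template and the map is a weighted
Pearson correlation: map density is interpolated at the pose-transformed
standard-grid points and correlated with the mean map under per-point
weights `max(corrMap, 0)` (anticorrelated far-shell points would otherwise
dominate; clamping them to zero keeps the statistic focused on reproducible
signal). Points that fall outside the map count as zero density.

Each candidate is then refined by **Nelder–Mead** over six parameters
(a rotation vector applied about the current pose — no gimbal problems near
the optimum — plus a translation), maximising the weighted CC. Parameters
are scaled so one simplex unit is 0.25 rad / 1 Å, giving the default
initial simplex a sensible physical size; up to three restarts are taken
while they improve the CC by more than 1e-4. The refined CC is never
reported below the starting CC. Finally the **top selection** collapses
duplicate poses (COM within 2 Å and segment axis within 15°, antiparallel
axes considered equal), drops placements with CC ≤ 0.3 and keeps at most
20, exactly the acceptance rule of the secondary-structure stage.

For speed, the inner loops evaluate the CC on a trimmed support (weights
above 0.02–0.05, deterministically subsampled to 400–3000 points depending
on the loop); the user-facing `weightedCC()` always uses the full support.

# Voxel-size calibration

A magnification error multiplies every physical distance in the map by an
unknown factor. To estimate it without an atomic model, the refined SSE
placements are used as internal rulers: for every factor *m* in
{0.900, 0.901, …, 1.100} the header voxel size is provisionally multiplied
by *m*, the placement translations are compensated by the same factor (the
map rescales about its coordinate origin, so a placement at **t** moves to
*m* **t**), the weighted CC of every placement is accumulated, and the peak
of the accumulated CC identifies the correction. Helix- and strand-derived
estimates are combined by a weighted average with weights equal to the
number of "good" placements (CC > 0.3) of each kind.

Three numerical choices matter here:

* **Deterministic scan.** The offset compensation tracks a pure
  magnification change exactly, so the per-factor CC can be evaluated
  directly at the compensated poses. Re-running a simplex at every factor
  instead injects optimiser jitter of the same order as the shallow
  curvature of the CC profile near its peak (~1e-3 per percent) and only
  blurs the argmax; we therefore default to the pure evaluation, with the
  per-factor simplex available as an option. The grid argmax is sharpened
  by parabolic interpolation through its two neighbours.
* **Blur bias and self-calibration.** An ensemble-mean template is
  slightly blurrier than any individual map window (window environments,
  side-chain composition, and the varying axial continuation beyond a
  segment's ends all average into softened features). Correlation-maximal
  magnification between a blurred template and sharp data does not sit at
  1: for matched Gaussian profiles it sits at
  `sqrt(1 + sigma_blur^2 / sigma_feature^2)`. On small training ensembles
  this bias reaches a few percent — far above the accuracy the stage needs.
  Because the training pair has known scale, the bias is measurable: the
  full placement pipeline is run on the training map itself and the
  resulting peak factor (exactly 1 for an unbiased template) is stored with
  the template as its calibration.
* **Response slope.** Poses found and refined under a mis-set header absorb
  part of the scale error, shrinking the measured correction by ~5–15 %.
  This, too, is measured at build time, as in any two-point instrument
  calibration: the training map is perturbed by the edges of the stated
  ±5 % magnification-error regime (factors 0.95 and 1.05) and the scan's
  log-response slope is recorded per side. Production scans invert the
  calibrated response. On the packaged fixtures this brings the corrected
  voxel size within 0.5 % of truth across the whole ±5 % regime, and the
  unperturbed map scans to a factor of 1.000.

A peak on the boundary of the scan grid is flagged rather than silently
returned — a true magnification error beyond ±10 % is outside the regime
the method is built for.

# Reference-map scaling ("map simulation")

The LLK targets must be trained on a map whose amplitudes behave like the
working map's. The reference map is therefore rescaled per resolution
shell: radially averaged Fourier amplitudes give each map's Guinier curve
(ln F̄ versus d⁻², one shell per Fourier pixel, DC excluded, maps
mean-subtracted first), and the reference amplitudes are multiplied by
`exp(lnF_work − lnF_ref)`, linearly interpolated between shell centres for
off-centre voxels, with phases untouched. Below 10 Å resolution the
correction is clamped at its value near 10 Å — the strong, poorly
comparable low-resolution terms would otherwise dominate the scaled map.
The result is low-pass filtered to the working resolution. The defining
contract, which the tests assert, is that the scaled reference's Guinier
curve matches the working curve over the 10–3 Å band; the operation is
idempotent up to numerical tolerance.

"Mean amplitude per shell" is used; RMS per shell is the obvious
alternative and differs only by a near-constant factor for these fields.

# LLK targets and Cα extension

For every interior Cα of the reference model, an orthonormal local frame
is built from the triplet Cα(i−1), Cα(i), Cα(i+1) (chain direction,
bisector, normal; a fallback perpendicular handles near-straight chains).
The scaled reference map is sampled at a fixed offset lattice in this frame
(radius 4 Å, 1 Å spacing, 257 offsets), accumulating a per-offset mean and
variance; the variance is floored at 1e-6 of the map variance. The score of
a candidate pose is the Gaussian log-likelihood
`−Σ_j [(ρ_j − μ_j)² / 2σ_j² + ½ ln σ_j²]`; offsets outside the map count
as zero density plus a constant penalty, so poses leaving the map score
strongly negative but finite. Per-residue-type targets are accumulated the
same way on a larger lattice (radius 6 Å) that reaches the side-chain
region.

Extension proposes next-Cα candidates on spherical shells of 3.4/3.8/4.2 Å
around the chain end (60 directions), subject to chain geometry
(Cα(i−1)–Cα(i+1) ≥ 4.5 Å; no non-consecutive pair closer than 3 Å), and
scores each candidate by the LLK of the completed triplet frame at the
current end plus a small standardised-density bonus at the candidate (the
candidate itself has no successor yet, so its own frame is not defined).
The best candidate is accepted while it beats an adaptive threshold set to
mean − 2 sd of the seed's interior scores. Extension runs forward first and
then backward against the full forward chain, so the two growth directions
cannot collide. Fragments are merged by trimming or dropping overlapping
traces (keeping the higher mean LLK) and joining compatible free ends
(3.0–4.2 Å, consistent direction); the chain-geometry invariants are
enforced by the fragment class itself.

Sequence assignment scores every alignment of the sequence onto a fragment
(both directions) as the summed per-position type-LLK over interior
positions and accepts the best alignment only when it beats the runner-up
by 5 % of its magnitude — ambiguous stretches (e.g. poly-alanine) are
deliberately left unassigned. The estimated residue count (given directly
or as molecular mass / 110 Da) caps the total number of traced residues.

# Synthetic fixtures

The fixture generator provides ideal-geometry building blocks and a
deterministic Gaussian-atom map simulator:

* ideal helices (φ = −57.8°, ψ = −47.0°: 1.5 Å rise, ~3.6 residues/turn,
  2.3 Å Cα radius) and strands (φ = −130°, ψ = 125°: ~3.4 Å/residue,
  near-collinear Cα trace), built from standard covalent geometry;
* a toy working fold (three 15-residue helices in a bundle plus a
  four-strand sheet, 77 residues, each SSE its own chain) and an
  independent reference fold (five 18-residue helices on a pentagon plus a
  four-strand sheet, 138 residues) so that LLK training and evaluation
  never share a structure;
* a map simulator in which each atom contributes an isotropic Gaussian of
  mass equal to its element's atomic number and width set by a global
  B factor (40 Å² default; σ² = B/8π²), normalised so the integrated
  density is exactly proportional to the summed weights; maps are low-pass
  filtered to the nominal resolution (2.5 Å default at 1 Å voxels) and may
  carry seeded Gaussian noise. Side chains are represented by single
  centroid pseudo-atoms carrying the summed heavy-atom weight of the side
  chain at an elevated B factor, smearing them over roughly the real side
  chain's footprint.

What the fixtures do *not* emulate: experimental noise spectra, local
resolution variation, detergent or solvent density, conformational
heterogeneity, and real electron scattering factors. Passing tests
demonstrate the algorithms' correctness and internal consistency under a
known forward model, not performance on experimental depositions.

Fixture problem sizes were chosen so the full acceptance battery (an
11-point magnification sweep, secondary-structure detection, and a
complete tracing run) completes comfortably on a single CPU: ~40×55×40
voxel maps, 77/138-residue folds.

# Degenerate inputs and edge policies

* Out-of-grid interpolation returns a sentinel (`NA`), scored as "no
  density" by all callers; template support may poke outside small maps.
* MRC axis permutations are resolved at read time; when both the origin
  fields and the start indices are set and disagree, the origin fields win
  with a warning.
* Near-collinear superposition targets are flagged (the in-plane rotation
  is undetermined).
* Distance groups with fewer than two grid points, and training windows
  with more than half their support outside the map, are dropped with
  warnings; templates require at least three usable windows.
* An empty map yields low-confidence search candidates rather than an
  error; a scan peaking on the grid boundary is flagged unreliable.

# Known limitations

* Loop regions between SSEs are traced only as far as the LLK threshold
  carries; no topology assembly across gaps is attempted.
* Side-chain assignment is at residue-type level; no rotamer building or
  real-space refinement of the final model is performed.
* Magnification correction is isotropic, matching the physics of a global
  magnification error.
* The self-calibration of the voxel-size scan assumes the working map's
  feature statistics resemble the training map's; with templates trained on
  a structurally very different map the residual bias can grow to the
  ~1–2 % level.
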
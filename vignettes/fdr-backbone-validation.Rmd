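---
title: "FDR confidence maps and backbone validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDR confidence maps and backbone validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdrmap)
```

## The statistical model

A cryo-EM density map is treated as a field of test statistics. Voxels that
contain only background are modelled as i.i.d. draws from a single Gaussian
null N(μ, σ²); voxels covered by the molecule carry additional positive
density (the map is assumed sharpened, so molecular signal raises voxel
values). The null parameters are estimated from noise cubes placed outside
the particle, each voxel gets the right-tailed p-value
p = 1 − Φ((v − μ)/σ), and the p-values are adjusted across all m voxels of
the grid with a step-up false discovery rate procedure. The **confidence**
of a voxel is c = 1 − q, where q is its adjusted p-value. Thresholding the
confidence map at c ≥ 0.99 therefore bounds the expected fraction of
background voxels among those passing at 1%.

Two FDR procedures are provided:

* **Benjamini–Yekutieli (default).** q₍ᵢ₎ = min over j ≥ i of
  c(m) · m · p₍ⱼ₎ / j with c(m) = Σᵢ 1/i. The harmonic factor makes the
  guarantee valid under *arbitrary* dependence — the right regime for voxel
  grids, where neighbouring values are strongly correlated by the point
  spread of the reconstruction and any filtering.
* **Benjamini–Hochberg** (`method = "bh"`), the same step-up without the
  harmonic factor; anti-conservative under general dependence but useful
  for sensitivity analysis. BY q-values dominate BH q-values elementwise,
  so BY confidences are never higher.

The test is one-sided. After sharpening, molecular signal is positive
density, and a two-sided test would award confidence to deep negative
artifacts; positivity also makes the confidence monotone in the raw voxel
value, which downstream code relies on.

Why FDR at the voxel level rather than a contour? A single iso-level cannot
follow local resolution variation: in a poorly resolved periphery true
signal sits barely above noise while the core is far above it. The FDR
machinery adapts automatically — weak-but-consistent signal can still reach
high confidence, and the 1% guarantee holds map-wide.

## Background estimation

Four cubes are placed by default at the −x, +x, −y, +y face midpoints of the
box, one voxel in from the face, and are required to lie entirely outside a
central **guard sphere** of radius `guard_fraction × min(box extent)`
(default 0.35) assumed to contain the particle. The default cube edge is the
largest odd integer ≤ 0.125 × the smallest grid dimension (floor 5 voxels).
Which four of the six axis-face positions are used is a convention, not a
statistical necessity; both the positions and the edge are user-overridable
via `noise_regions()` for elongated particles, and `check_noise_regions()`
flags cubes whose mean is more than k (default 5) standard errors above the
pooled mean of the other cubes — the signature of a cube overlapping
molecular signal — as well as degenerate (zero-spread) cubes. Users should
inspect this diagnostic for specimens that are long in one direction.

A zero pooled standard deviation is a hard error rather than a warning:
masked, solvent-flattened maps have no background left, and every
confidence downstream would be meaningless.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `association_radius` | 1.0 | Å | voxels within this distance of an atom are associated with it |
| `aggregation` | `max` | — | reduction over the associated voxels (`max`, `mean`, `nearest`) |
| `mode` | `backbone` | — | protein N/Cα/C (nucleic C1′…P); `ca_only` for Cα-trace models |
| `method` | `by` | — | FDR adjustment (`by` or `bh`) |
| `threshold` | 0.9 | confidence | pruning cutoff; scores below it indicate likely mistrace |
| `flank` | 1 | residues | neighbours removed on each side of a pruned polymer residue |
| `edge_voxels` | auto | voxels | noise-cube edge (odd, ≥ 3) |
| `guard_fraction` | 0.35 | — | guard-sphere radius as a fraction of the smallest box extent |

The per-atom aggregation deserves a note: with voxels associated "within
1 Å", several rules are defensible. `max` is the default because the
question being asked is "is there *any* molecular signal at this atom
position?", and the maximum is robust for atoms at contour edges where the
1 Å ball straddles the signal boundary; `mean` and `nearest` are provided
for sensitivity analysis. The residue aggregate is always the arithmetic
mean over its scored atoms. The backbone carbonyl oxygen is excluded from
protein scoring because its density is systematically weak at resolutions
worse than ~3 Å and would depress scores of perfectly traced residues.

Z-scores are computed per chain over scored residues (waters excluded).
They are advisory only: in a well-built model most residues score exactly
1.0, the distribution is nowhere near normal, and the absolute score is the
better mistrace detector. This is why pruning uses the absolute 0.9 cutoff.

## Geometry conventions

Voxel indices are 0-based in the public API (the MRC convention), and the
map origin is the world coordinate of the **center** of voxel (0,0,0);
distances for the association rule are measured to voxel centers, which
makes the 1 Å radius semantics unambiguous. On reading MRC2014 files the
grid is reordered to crystallographic X,Y,Z order whatever the storage axis
permutation, so scoring is invariant to how the file was laid out. The
origin is taken from the MRC origin record when any component is nonzero,
otherwise from nstart × voxel size — the common single-particle convention;
deposited maps using unusual combinations of both records should be checked
against the model overlap warning emitted by `cmd_validate()`. Anisotropic
voxel sizes are supported throughout (true Euclidean distances in Å).

Model handling: alternate locations collapse to the highest-occupancy
conformer (ties: first in file); hydrogens are kept but never scored;
asterisk-style nucleic atom names (C1*) are normalised to primes; residues
named like ligands but carrying ≥ 5 of the 9 nucleic backbone atoms are
scored as nucleic, so common modified nucleotides keep a meaningful score
without a chemical dictionary. Insertion codes are part of residue identity
everywhere. Atoms outside the map grid score 0.0 and set a flag rather than
erroring — models frequently overhang trimmed boxes.

## Pruning semantics

"Preceding and following" residues are defined by adjacency in the chain's
residue list in file order, not by residue-number arithmetic: numbering
gaps and insertion codes then behave predictably, windows truncate at chain
ends and never cross chains. Ligands and waters below threshold are removed
without flanking (chemical adjacency is undefined for them), and unscored
residues are retained. Pruning is deliberately not idempotent in the
mathematical sense — flanking residues may themselves score well — but
re-pruning a pruned model with the same scores removes nothing, which is
the property the iterative building loop needs.

## The synthetic scene generator

Scenes emulate exactly what the statistics need and nothing more: a
straight poly-alanine-like chain (Cα every 3.8 Å, N/C at ±1.46/1.52 Å along
the axis, carbonyl O offset 1.23 Å) rendered as isotropic Gaussian atoms of
width σ = 1 Å and peak `amplitude`, embedded in i.i.d. Gaussian background
of unit sd, with SNR defined as amplitude/noise sd. The ground-truth mask
is the union of 2.5σ balls around the atoms. Scene presets at SNR 3/5/10
loosely correspond to poor/typical/good local map quality. The chain runs
along the box diagonal so the default face-midpoint noise cubes are
guaranteed signal-free, and an 8-voxel margin between model and box faces
is enforced at render time. Mistraces are fabricated by rigidly displacing
chosen residues of the *model* while the *density* is always rendered from
the true chain; the default offset (0, 0, −8) Å puts a displaced residue
about 6.5 Å off the chain axis, far outside the truth mask.

What the scenes do **not** emulate: electron form factors, B-factor
falloff, CTF effects, local resolution variation, masking artifacts, or
correlated (coloured) noise. Passing tests on scenes therefore demonstrate
that the statistics and the pipeline are correct under the stated model —
i.i.d. Gaussian background with positive signal — not that the 1% FDR
guarantee is tight on any particular experimental reconstruction, where
noise correlation makes BY conservative in a resolution-dependent way.

## Numerical choices

* All statistics run in double precision; maps are written back as 32-bit
  floats (MRC mode 2).
* p-values are floored at the smallest positive double so the step-up
  arithmetic never sees an exact zero from `pnorm` underflow.
* The step-up running minimum is applied from the largest p downward and
  clipped at 1, guaranteeing monotone q-values; ties in raw map values
  therefore always produce identical confidences.
* Gaussian atoms are evaluated out to 5σ (truncated mass < 0.01%).
* The Gaussian-integral check on rendered maps and the noise-sd checks in
  the tests use 2–3 standard-error tolerances at their respective sample
  sizes.
* All randomness flows through explicit seeds (`withr::with_seed`); no
  function perturbs the session's global random state.

## Problem sizes used in the test suite

The suite exercises the full pipeline on 64³ scenes at SNR 5 (20 seeds for
the empirical-FDR and mistrace-recovery properties), 100 pure-noise 48³
maps for the global-null guard, 500 random arrays against a brute-force
O(m²) step-up oracle, and brute-force voxel-radius scans on grids up to
32³. These sizes keep every statistical check at ≥ 3 standard errors of
resolving power while the whole suite runs in about a minute.

## Known limitations

* The score validates *positions against signal*, not model-to-map fit: a
  residue inside the molecular volume but locally misfitted (wrong rotamer,
  shifted within density) can still score 1.0. Use fit metrics
  (Q-score/SMOC/CCC-style) alongside.
* A single global noise Gaussian is fitted; windowed, locally varying noise
  models are out of scope.
* Confidence values concentrate at 0 and 1 by construction, so per-chain
  z-scores are weakly informative (see above).
* MRC2014 only (mode 0/1/2 read, mode 2 written); no resampling, box
  trimming or local sharpening.
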
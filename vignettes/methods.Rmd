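---
title: "Assembling protein-nucleic-acid complexes into cryo-EM maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling protein-nucleic-acid complexes into cryo-EM maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A cryo-EM reconstruction of a protein-nucleic-acid (NA) complex is a 3-D
scalar field sampled on a voxel lattice. Individually modeled chains -- from
structure predictors or prior crystallography -- must be placed into that
field to produce an atomic model of the whole assembly. `emapfit` implements
this as a four-stage pipeline:

1. **Segmentation.** A trainable 3-D encoder-decoder labels every voxel as
   protein (0), NA (1) or background (2), and the map is split into a
   protein map and an NA map that conserve density exactly.
2. **Chain fitting.** Each chain is fitted into the segmented map matching
   its molecule kind by multi-start rigid-body optimization of a composite
   correlation score; chains are processed longest first, and density
   already explained by a well-fitted chain (global CC above a threshold,
   initially 0.6, lowered by 0.1 per round down to 0.3) is masked to zero
   before later chains are fitted. Up to five candidate poses per chain are
   retained.
3. **Assembly.** One candidate per chain is selected by integer-coded
   differential evolution against the energy
   `E = -CC(complex, map) + lambda * clash`, computed on the original
   (unsegmented) map; at or below 1024 combinations the search switches to
   exhaustive enumeration, which is exact.
4. **Joint refinement.** All rigid units -- protein domains and whole NA
   chains -- are refined simultaneously by L-BFGS on the same energy; NA
   chains move only as rigid bodies, so duplex base pairing supplied as a
   single rigid unit is preserved bit-exactly.

# Scores

All map-model comparison is done against a density simulated from the model:
every heavy atom contributes an isotropic Gaussian of width
`sigma = resolution / (pi * sqrt(2))` (the convention used by common
map-simulation tools) with amplitude proportional to its atomic number.
Hydrogens are ignored throughout; maps at the targeted resolutions do not
resolve them.

* **Global CC** is the Pearson correlation between experimental and
  simulated density over the voxels where either exceeds `1e-6`. Scoring
  over the full box would reward agreement about empty space; scoring over
  the union support does not.
* **Local (per-residue) CC** restricts the correlation to voxels within 3 A
  of the atoms of a nine-residue window centered at each residue (clipped at
  chain ends). The per-residue values localize fit errors; their mean enters
  the composite score.
* **iFSC** is the trapezoidal mean of the Fourier shell correlation between
  simulated and experimental density over the band from 1/10 to
  1/resolution inverse Angstrom.
* The **composite fitting score** is the normalized weighted sum of the
  three, equal weights by default. The weighting is exposed because no
  single convention dominates practice; all recovery experiments in the test
  suite pass with equal weights.
* The **clash score** counts inter-chain heavy-atom pairs closer than 3 A,
  divided by the atom count (a per-atom clash rate), using a cell list so
  cost is near-linear; a brute-force all-pairs count is the test oracle.
* **TM-score** and **Kabsch RMSD** compare a model against a reference with
  matched residues (representative atoms CA and C3'). TM-score uses
  `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5), normalized by the
  reference length, maximized by iterative fragment-seeded superposition and
  cross-checked against an exhaustive-seed oracle.

# Numerical choices that matter

**Hierarchical pose search.** At 5 A nominal resolution the simulation
kernel has sigma of roughly 1.1 A, and the correlation basin around the true
pose is only a few degrees and a few Angstrom wide -- much narrower than the
45-degree Euler enumeration lattice. Refining enumerated poses directly at
native resolution fails measurably: a composite prescreen at native
resolution can rank every true-basin start below the survivor cutoff.
`fit_chain` therefore screens and coarse-refines every enumerated start
against a low-pass-filtered copy of the map (effective resolution at least
three times nominal, at least 12 A, on a lattice of at least 2 A, scored
with one representative atom per residue), where the basin spans tens of
degrees and \~15 A; the best survivors (128 per candidate site, scaled up
for multi-site maps) are then refined at native resolution with the full
composite score. All finite-difference gradients are central (steps 0.25 A
/ 1 degree at native resolution, 1 A / 4 degrees on the coarse map):
one-sided differences pick up a curvature bias near a rotation optimum
that measurably stalls the line search. Convergence is |delta score| <
1e-5 or the iteration cap; an ascent guard ensures a refined pose never
scores below its start.

**Translation seeds.** Seeds are the map's density centroid plus, whenever
the map's density-weighted radius of gyration exceeds the model's by more
than 5%, the local maxima of smoothed map copies at several model-tied
scales (Rg, Rg/2 and Rg/4, floor 3 A; peaks closer than Rg/2 merged; at
most 8 auxiliary seeds). Chain-scale smoothing marks whole-molecule blobs
but can merge adjacent chains into one maximum; sub-chain scales keep
adjacent blobs separate but can fragment an extended chain into segment
peaks -- the union covers both regimes. The 5% margin replaces an earlier
20% margin that failed to trigger for two adjacent chains of similar
size.

**Rotation seeds.** The z-y-z Euler lattice at the given angular step with
beta spanning the closed interval [0, 180] and exact duplicates removed
(quaternion double cover handled). At 90 degrees this yields exactly the 24
proper rotations of the cube; at the default 45 degrees, 208 unique
rotations.

**The composite's FSC term** is evaluated on a fixed 32^3 cubic lattice
covering the map box (the in-package radix-2 FFT runs on powers of two), so
each of the thousands of objective evaluations inside L-BFGS stays around a
millisecond. The public `fsc_curve()` operates on the native lattice via
`stats::fft` and is the reporting path.

**Normalization** zeroes density below the contour level and scales so the
98th percentile of the remaining positive voxels maps to 1 (values above it
clip to 1). The percentile is the order statistic (type-1 quantile), not the
interpolated default, which makes normalization exactly idempotent. The
percentile is computed over the signal region only, so it does not depend on
how much empty padding the box carries.

**Masking** zeroes voxels within 3 A of the fitted chain's heavy atoms --
the same proximity radius used for voxel labeling -- and only the best
candidate of a placed chain masks.

**Degenerate inputs.** An all-zero (or all-below-contour) map raises a
degenerate-map error everywhere a density statistic is needed; a chain with
both amino-acid and nucleotide content above 25% raises a classification
error requiring an explicit `kind`; insertion codes are rejected; refusal to
move is a valid outcome of every gated refinement.

# The segmenter

The network is a three-level nested encoder-decoder over 64^3 chunks:
two stride-2 3^3 convolutions (widths w and 2w), a 3^3 mid-level
convolution, a 1^1 decoder over the concatenation of the first-level
features with the upsampled mid-level features, and a 1^1 classification
head over the concatenation of the raw input with both upsampled feature
streams. Because 1x1 convolutions commute with nearest-neighbour
upsampling, the decoder and head are applied at their native lattices and
only 3-channel logits are ever assembled at full resolution; training one
chunk costs about 70 ms on one CPU core at the default base width 16
(~29k parameters). This is deliberately far smaller than a full-scale
segmentation network: the synthetic task below is texture separation
(helix tubes vs duplex ridges vs background) and a compact model trains on
a desktop CPU in minutes while still leaving the width configurable for
larger data.

Training uses class-weighted cross-entropy (weights default to inverse
voxel frequency on the training set), Adam with one chunk per step,
learning rate 5e-4 reduced by half after 5 epochs without validation
improvement down to a floor of 1e-6, and the checkpoint with the lowest
validation loss is returned. Maps are preprocessed to 1 A voxels,
contour-zeroed and percentile-normalized; chunks lie on a stride-32 lattice
and all-zero chunks are dropped. At inference, per-class probabilities are
averaged arithmetically over all chunks covering a voxel, the argmax is
taken, and zero-density voxels are forced to background.

A non-learning fallback, `label_by_chains()`, labels voxels by proximity to
user-supplied approximate placements; it exists so the pipeline can be
exercised without any training and is not the trained method.

# The synthetic-complex generator

Downstream stages are tested against generated complexes, so the generator
is first-class, seeded, and bit-reproducible:

* **Protein chains** are kinked ideal alpha-helices (rise 1.5 A, 100
  degrees/residue, radius 2.3 A) with full N/CA/C/O backbones; kinks every
  `segment_length` residues (default 40) fold the helix into a compact
  bundle while consecutive CA-CA distances stay at 3.8 A, including across
  kinks (the kink is a rigid rotation of the remaining construction about
  the current CA plus a lateral displacement bridged by a turn residue).
* **NA duplexes** are idealized B-form (rise 3.4 A, twist 36 degrees/bp)
  with 6-atom backbones, a C1' and simplified base atoms per nucleotide --
  purines carry one ring atom more than pyrimidines. The base atoms matter:
  a backbone-only duplex is exactly dyad-symmetric, its density cannot
  distinguish a 180-degree flip, and pose recovery would be ill-posed. Both
  strands form one rigid chain, as a duplex supplied as a single PDB file
  would.
* **Layout** places chains with random orientations at the smallest offset
  that keeps all inter-chain heavy-atom distances at or above 4 A.
* **Maps** are sums of atomic Gaussians (amplitude proportional to atomic
  number) on a lattice padded 8 A beyond the model; optional i.i.d. voxel
  noise is scaled to a fraction of the map maximum, clipped at zero, and
  the map's recommended contour level is recorded as three times the noise
  standard deviation -- the conventional "3 sigma" interpretation
  threshold that real depositions carry.
* **Ground-truth labels** mark voxels within 3 A of a backbone atom
  (N/CA/C/O for protein; P/O5'/C5'/C4'/C3'/O3' for NA) with the class of
  the nearest such atom.

What these fixtures do *not* emulate: side chains, B-factors, realistic
scattering form factors, solvent, local-resolution variation, and the
conformational heterogeneity of real reconstructions. Passing the test
suite therefore demonstrates the machinery -- scores with the documented
optima, search that finds them, assembly that combines them, a segmenter
that learns the voxel classes -- under controlled conditions, not
benchmark-level accuracy on experimental maps.

# Experiment sizes

The test suite runs, on one CPU core: single-chain recovery over 20
randomized start poses (120-residue chain, noise-free 5 A map); a full
pipeline reassembly of the standard test complex (protein chains of 150 and
90 residues plus a rigid 30-bp duplex, 5 A map with 5% noise, ground-truth
labels standing in for a trained segmenter); segmenter training on 200
chunks for 30 epochs at base width 16 with held-out-map accuracy; and the
masking and domain-refinement ablations described below.
`scripts/acceptance.R` recomputes the same quantities with 8 recovery seeds
and a 150-chunk / 20-epoch training run; all sizes are the package's
standard desk-scale experiment sizes.

# Ablation fixtures

**Masking.** Chain A is a 100-residue bundle; chain B's *model* is an exact
copy of A's first 60 residues, while B's *true* conformation -- which
shaped the map density at B's own site -- is hinged 25 degrees. The
exact-match sub-region of A's density then genuinely outscores B's own
site (refined composite about 0.71 vs 0.34), so the unmasked fit falls
into that decoy and is wrong by tens of Angstrom; masking A's region
after its (confident) fit forces B into its own site. The comparison is
averaged over randomized input placements.

**Domain refinement.** A 160-residue chain of compact 20-residue helical
segments is split into two domains at residue 81; the input model has the
second domain rotated 30 degrees about the boundary CA while the map comes
from the unrotated truth. The rigid fit necessarily compromises; per-domain
refinement (coarse stage against the low-pass map, then native-resolution
polish, accepted only when the whole-chain composite improves and every
linker CA-CA gap stays under 8 A) recovers both domains to well under an
Angstrom.

# Known limitations

* Chain models are fitted as given: no side-chain building, no geometry
  regularization, no sequence reassignment between homologous chains.
* The automatic domain parser is a single-cut spectral bisection of the CA
  contact graph; explicit boundaries always take precedence and are
  recommended for anything beyond clean two-domain cases.
* The fitting score is correlation-based; maps whose hand-edness or
  magnification is wrong will not be diagnosed.
* Homo-oligomeric ambiguity is resolved only by masking order and clash,
  not by symmetry inference.
* MRC input is restricted to mode-2 (float32) volumes, the interchange
  format for EM density.
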
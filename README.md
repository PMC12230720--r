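# emapfit

Assembly of protein–nucleic-acid (NA) complex models from cryo-EM density
maps, for structural biologists who have a reconstructed map plus
individually modeled chains (from structure predictors or prior
structures) and need the assembled complex.

The pipeline couples map segmentation with chain- and domain-level
model-to-map fitting:

1. a trainable 3-D encoder–decoder labels every voxel as protein (0),
   NA (1) or background (2), splitting the map into a protein map and an
   NA map;
2. each chain is fitted into the segmented map of its molecule kind by
   multi-start rigid-body L-BFGS, maximizing a composite score
   `S = (CC_global + mean CC_local + iFSC) / 3`, where `CC` is the Pearson
   correlation between the experimental density and a density simulated
   from the model (atomic Gaussians, `sigma = d / (pi sqrt 2)` at
   resolution `d`), `CC_local` is computed per residue over nine-residue
   windows, and iFSC integrates the Fourier shell correlation over
   [1/10, 1/d] Å⁻¹. Chains are processed longest first with a decaying
   acceptance threshold (0.6 → 0.3); density explained by a well-fitted
   chain is masked before the next chain is fitted, and the top five poses
   per chain are kept;
3. one pose per chain is selected by integer-coded differential evolution
   against `E = -CC(complex, map) + lambda · clash` (exhaustive, hence
   exact, at ≤ 1024 combinations);
4. all rigid units — protein domains and whole NA chains — are refined
   jointly; NA chains stay rigid throughout, so duplex base pairing
   supplied as one unit is preserved.

Quality is reported as global and per-residue CC, iFSC, clash rate, and —
against a reference — TM-score and RMSD. A seeded synthetic-complex
generator (kinked helical proteins, B-form duplexes, simulated maps with
ground-truth voxel labels and poses) makes every stage testable without
external data.

## Worked example

```r
library(emapfit)

# a small synthetic complex: one 80-residue protein + a 12-bp DNA duplex
spec <- toy_complex_spec(protein_lengths = 80, na_bp = 12,
                         resolution = 5, noise_sigma = 0.05, seed = 42)
cx  <- make_toy_complex(spec)
map <- simulate_map(cx, resolution = 5, voxel_size = 1)
map <- add_noise(map, spec$noise_sigma, seed = 42)
map <- normalize_map(map)

# ground-truth voxel labels stand in for a trained segmenter here;
# train one with make_segmentation_dataset() + train_segmenter()
labels <- ground_truth_labels(cx, map)

# scramble the input chains, then reassemble them into the map
chains <- lapply(seq_along(cx$chains), function(i) {
  set.seed(i); apply_pose(cx$chains[[i]], pose(rnorm(4), runif(3, -10, 10)))
})
res <- run_pipeline(map, chains, labels = labels, seed = 1)

tm_score(res$model, cx)
global_cc(res$model, res$map)
```

Output:

```
<density_map> 49 x 63 x 104 voxels @ 1 A, origin (-14.2, -38.8, -38.5), resolution 5 A
<label_volume> 49 x 63 x 104 voxels: 8078 protein, 5772 NA, 307198 other
<complex_model> 2 chains (A:protein, B:NA)
TM-score vs truth: 1.000
complex global CC: 0.969
chain A RMSD to truth: 0.03 A
chain B RMSD to truth: 0.04 A
```

The TM-score of 1.000 and sub-0.1 Å chain RMSDs say both chains were
returned to their ground-truth placements; the complex CC of 0.97 is the
correlation between the map and the density simulated from the final model
(1.0 would require a noise-free map).

Training the segmenter on synthetic data:

```r
chunks <- make_segmentation_dataset(224, seed = 1)
seg <- train_segmenter(chunks[1:200], chunks[201:224],
                       seg_train_config(epochs = 30, base_width = 16))
labels <- segment_map(map, seg)   # instead of ground-truth labels
```

A thin command-line front end (`inst/cli/emapfit`) wraps the same
functions: `simulate`, `train-seg`, `segment`, `fit-assemble`, `evaluate`.

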
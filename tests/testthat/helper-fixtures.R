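# Shared fixtures, built once per test run (generation is deterministic).

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- force(expr)
  .fx_env[[name]]
}

# single 120-residue kinked-helix protein, noise-free 5 A map at 1 A voxels
fx_single <- function() fx("single", {
  spec <- toy_complex_spec(protein_lengths = 120, na_bp = integer(0),
                           seed = 5, noise_sigma = 0)
  cx <- make_toy_complex(spec)
  map <- normalize_map(simulate_map(cx, resolution = 5, voxel_size = 1))
  list(complex = cx, map = map, chain = cx$chains[[1]])
})

# small protein-NA complex with noise (the standard test complex, scaled
# down for unit tests)
fx_small_pn <- function() fx("small_pn", {
  spec <- toy_complex_spec(protein_lengths = c(70), na_bp = 15, seed = 9,
                           noise_sigma = 0.05)
  cx <- make_toy_complex(spec)
  map <- simulate_map(cx, resolution = 5, voxel_size = 1)
  map <- add_noise(map, spec$noise_sigma, seed = 3)
  map <- normalize_map(map)
  labels <- ground_truth_labels(cx, map)
  list(complex = cx, map = map, labels = labels,
       halves = split_map(map, labels))
})

# brute-force inter-unit clash pair count (test oracle)
brute_clash_pairs <- function(xyz, unit, cutoff) {
  d <- as.matrix(dist(xyz))
  sum(d[outer(unit, unit, "!=")] < cutoff) / 2
}

# random rigid pose (normalized random quaternion + bounded translation)
random_pose <- function(seed, tmax = 10) {
  with_seed_test(seed, pose(rnorm(4), runif(3, -tmax, tmax)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pairwise-distance preservation check
max_pairdist_change <- function(a, b) {
  ia <- as.matrix(dist(a)); ib <- as.matrix(dist(b))
  max(abs(ia - ib))
}

# rotate all residues after `at_res` about that residue's CA (hinge bend)
rotate_tail <- function(ch, at_res, angle_deg, axis = c(0, 0, 1)) {
  at <- ch$atoms
  pivot <- unlist(at[at$resno == at_res & at$elety == "CA",
                     c("x", "y", "z")])[1:3]
  R <- pose_rotation_matrix(pose(emapfit:::quat_from_axis_angle(
    axis, angle_deg * pi / 180)))
  sel <- at$resno > at_res
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  at[sel, c("x", "y", "z")] <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2,
                                     pivot, "+")
  ch$atoms <- at
  ch
}
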
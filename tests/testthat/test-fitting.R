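# Pose initialization, L-BFGS refinement and chain fitting. The expensive
# recovery experiments (20-seed single chain, masking ablation, hinge
# refinement) live in the acceptance suite.

test_that("rotation enumeration at 90 degrees yields the 24 cube rotations", {
  rots <- emapfit:::rotation_seeds(90)
  expect_length(rots, 24)
  # pairwise distinct
  for (i in seq_along(rots)) for (j in seq_len(i - 1)) {
    d <- abs(sum(rots[[i]] * rots[[j]]))
    expect_gt(2 * acos(min(1, d)) * 180 / pi, 1)
  }
})

test_that("translation seeds follow the map-vs-model gyration rule", {
  fixt <- fx_single()
  # single-chain map: one translation seed at the density centroid
  ip <- init_poses(fixt$chain, fixt$map, angular_step = 90)
  tr <- unique(round(t(vapply(ip, function(p) p$t, numeric(3))), 6))
  expect_equal(nrow(tr), 1)
  seed_com <- tr[1, ] + colMeans(coords(fixt$chain))
  truth_com <- colMeans(coords(fixt$chain))
  expect_lt(sqrt(sum((seed_com - truth_com)^2)), 1.5)
  # a map holding two widely separated copies has Rg >> chain Rg and must
  # produce more than one translation seed
  far <- fixt$chain
  far$atoms$x <- far$atoms$x + 60
  far$chain_id <- "B"
  two <- complex_model(list(fixt$chain, far))
  m2 <- normalize_map(simulate_map(two, 5, 1))
  ip2 <- init_poses(fixt$chain, m2, angular_step = 90)
  tr2 <- unique(round(t(vapply(ip2, function(p) p$t, numeric(3))), 1))
  expect_gt(nrow(tr2), 1)
})

test_that("refinement from the truth pose stays at the truth pose", {
  fixt <- fx_single()
  cand <- refine_pose_lbfgs(fixt$chain, fixt$map, pose_identity())
  d <- pose_distance(cand$pose, pose_identity())
  expect_lt(d["shift"], 0.2)
  expect_lt(d["angle"], 1)
})

test_that("refinement never returns a pose scoring below its start", {
  fixt <- fx_single()
  for (s in 1:4) {
    start <- with_seed_test(s, pose(rnorm(4), runif(3, -6, 6)))
    start_score <- composite_fit_score(apply_pose(fixt$chain, start),
                                       fixt$map)
    cand <- refine_pose_lbfgs(fixt$chain, fixt$map, start)
    expect_gte(cand$composite, as.numeric(start_score) - 1e-9)
  }
})

test_that("fit_chain keeps at most five deduplicated, sorted candidates", {
  fixt <- fx_single()
  ch <- apply_pose(fixt$chain, random_pose(21, tmax = 15))
  fr <- fit_chain(ch, fixt$map, screen_keep = 48)
  expect_lte(length(fr$candidates), 5)
  comps <- vapply(fr$candidates, function(c) c$composite, 0)
  expect_true(all(diff(comps) <= 1e-12))
  # candidates are mutually distinct poses
  for (i in seq_along(fr$candidates)) for (j in seq_len(i - 1)) {
    d <- pose_distance(fr$candidates[[i]]$pose, fr$candidates[[j]]$pose)
    expect_true(d["shift"] >= 2 || d["angle"] >= 10)
  }
})

test_that("two identical copies in a map land the top candidates in both sites", {
  ch <- make_protein_chain(60, seed = 31)
  copy <- ch
  copy$atoms$x <- copy$atoms$x + 35
  copy$chain_id <- "B"
  two <- complex_model(list(ch, copy))
  m <- normalize_map(simulate_map(two, 5, 1))
  fr <- fit_chain(ch, m, screen_keep = 64)
  stopifnot(length(fr$candidates) >= 2)
  com <- colMeans(coords(ch))
  c1 <- emapfit:::pose_coords(coords(ch), fr$candidates[[1]]$pose, com)
  c2 <- emapfit:::pose_coords(coords(ch), fr$candidates[[2]]$pose, com)
  sep <- abs(mean(c1[, 1]) - mean(c2[, 1]))
  expect_gt(sep, 20)  # the two best candidates occupy the two copies
})

test_that("iterative fitting processes chains longest first", {
  spec <- toy_complex_spec(protein_lengths = c(60, 90), na_bp = integer(0),
                           seed = 41, noise_sigma = 0)
  cx <- make_toy_complex(spec)
  m <- normalize_map(simulate_map(cx, 5, 1))
  lab <- ground_truth_labels(cx, m)
  halves <- split_map(m, lab)
  fits <- iterative_fit_all(cx$chains, halves$protein, halves$na,
                            screen_keep = 48)
  lens <- vapply(names(fits), function(id) n_residues(cx$chains[[id]]), 0L)
  expect_true(all(diff(lens) <= 0))
  expect_true(all(vapply(fits, function(f) f$placed, TRUE)))
})

test_that("single-domain chains pass through domain refinement unchanged", {
  fixt <- fx_single()
  ch <- fixt$chain
  ch$domains <- partition_domains(ch, boundaries = NULL, min_part = 200)
  expect_equal(nrow(ch$domains), 1)
  out <- domain_refine(ch, fixt$map, pose_identity())
  expect_equal(coords(out), coords(ch), tolerance = 1e-12)
  dna <- make_na_duplex(8, seed = 1)
  expect_error(domain_refine(dna, fixt$map, pose_identity()), "rigid")
})
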
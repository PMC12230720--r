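# Map-correlation scores, FSC, composite score, clash score, RMSD and
# TM-score.

test_that("global CC: self-correlation, anti-correlation, affine invariance", {
  fixt <- fx_single()
  raw <- simulate_map(fixt$complex, 5, 1)
  expect_gte(suppressWarnings(global_cc(fixt$complex, raw)), 0.999)
  neg <- raw; neg$grid <- -neg$grid
  expect_lte(suppressWarnings(global_cc(fixt$complex, neg)), -0.999)
  # scaling and offsetting the map inside its support leaves CC unchanged
  aff <- raw
  sup <- aff$grid > 1e-6
  aff$grid[sup] <- 3.7 * aff$grid[sup] + 0.5
  expect_equal(suppressWarnings(global_cc(fixt$complex, aff)),
               suppressWarnings(global_cc(fixt$complex, raw)),
               tolerance = 1e-9)
})

test_that("global CC is invariant under a joint rigid transform", {
  fixt <- fx_single()
  cc0 <- suppressWarnings(global_cc(fixt$chain, fixt$map))
  # translate both model and map by a whole-voxel shift
  shift <- c(3, -2, 5)
  m2 <- fixt$map; m2$origin <- m2$origin + shift
  ch2 <- fixt$chain
  ch2$atoms$x <- ch2$atoms$x + shift[1]
  ch2$atoms$y <- ch2$atoms$y + shift[2]
  ch2$atoms$z <- ch2$atoms$z + shift[3]
  expect_equal(suppressWarnings(global_cc(ch2, m2)), cc0, tolerance = 1e-9)
})

test_that("local CC: clipped windows, good fit high, displaced fit low", {
  fixt <- fx_single()
  prc <- local_cc(fixt$chain, fixt$map)
  expect_equal(nrow(prc), n_residues(fixt$chain))
  expect_true(all(prc$cc >= -1 & prc$cc <= 1))
  expect_true(all(prc$cc >= 0.9))
  moved <- apply_pose(fixt$chain, pose(translation = c(10, 0, 0)))
  prc2 <- local_cc(moved, fixt$map)
  expect_lt(median(prc2$cc), 0.5)
  # on a 5-residue chain every nine-residue window clips to the whole
  # chain, so all residues report the same CC
  short <- make_protein_chain(12, seed = 3)
  short$atoms <- short$atoms[short$atoms$resno <= 5, ]
  m <- simulate_map(short, 5, 1)
  prc3 <- local_cc(short, m)
  expect_equal(nrow(prc3), 5)
  expect_true(max(prc3$cc) - min(prc3$cc) < 1e-9)
})

test_that("FSC: self is one, scale invariant, decays under noise", {
  fixt <- fx_single()
  m <- fixt$map
  self <- fsc_curve(m, m)
  expect_true(all(abs(self$fsc[self$n > 0 & self$fsc != 0] - 1) < 1e-9))
  expect_true(all(self$fsc %in% c(0, 1) | abs(self$fsc - 1) < 1e-9))
  scaled <- m; scaled$grid <- 4.2 * scaled$grid
  sc <- fsc_curve(m, scaled)
  expect_equal(sc$fsc, self$fsc, tolerance = 1e-9)
  noisy <- with_seed_test(5, {
    n <- m; n$grid <- n$grid + array(rnorm(length(m$grid),
                                           sd = 0.5 * max(m$grid)),
                                     dim = dim(m$grid)); n
  })
  fn <- fsc_curve(m, noisy)
  lo <- mean(fn$fsc[2:4])
  hi <- mean(tail(fn$fsc, 5))
  expect_gt(lo, 0.9)
  expect_lt(hi, 0.5)
  bad <- density_map(array(1, c(8, 8, 8)), m$voxel_size, c(0, 0, 0), 5)
  expect_error(fsc_curve(m, bad), "shape")
})

test_that("integrated FSC: constants and pose sensitivity", {
  fixt <- fx_single()
  m <- fixt$map
  expect_equal(integrated_fsc(fsc_curve(m, m), 0.05, 0.2), 1, tolerance = 1e-9)
  flat <- data.frame(freq = seq(0, 0.25, by = 0.01), fsc = 0.5, n = 10)
  expect_equal(integrated_fsc(flat, 0.05, 0.2), 0.5)
  expect_error(integrated_fsc(flat, 0.2, 0.1), "empty")
  sim_t <- emapfit:::simulate_map_on_grid(fixt$complex, m)
  moved <- apply_pose(fixt$chain, pose(translation = c(8, 0, 0)))
  sim_m <- emapfit:::simulate_map_on_grid(complex_model(list(moved)), m)
  i_t <- integrated_fsc(fsc_curve(m, sim_t), 0.1, 0.2)
  i_m <- integrated_fsc(fsc_curve(m, sim_m), 0.1, 0.2)
  expect_gt(i_t, i_m)
})

test_that("composite score: degenerate weights and normalization", {
  fixt <- fx_single()
  comp_cc <- composite_fit_score(fixt$chain, fixt$map, weights = c(1, 0, 0))
  expect_equal(as.numeric(comp_cc),
               suppressWarnings(global_cc(fixt$chain, fixt$map)),
               tolerance = 1e-12)
  w1 <- composite_fit_score(fixt$chain, fixt$map, weights = c(2, 2, 2))
  w2 <- composite_fit_score(fixt$chain, fixt$map, weights = c(1, 1, 1) / 3)
  expect_equal(as.numeric(w1), as.numeric(w2), tolerance = 1e-12)
  comps <- attr(w2, "components")
  expect_equal(as.numeric(w2), mean(comps), tolerance = 1e-12)
  expect_error(composite_fit_score(fixt$chain, fixt$map, weights = c(0, 0, 0)))
})

test_that("clash score: separated, superposed, and grid-vs-brute-force", {
  a <- make_protein_chain(40, seed = 1)
  b <- make_protein_chain(40, seed = 1, chain_id = "B")
  b_far <- b; b_far$atoms$x <- b_far$atoms$x + 100
  expect_equal(clash_score(complex_model(list(a, b_far))), 0)
  expect_equal(clash_score(complex_model(list(a))), 0)
  # exact superposition: every atom clashes with its own copy at least
  superposed <- clash_score(complex_model(list(a, b)))
  expect_gte(superposed, 0.5)
  # grid-accelerated count equals brute force on random configurations
  for (s in 1:4) {
    xyz <- with_seed_test(s, matrix(runif(3 * 500, 0, 25), ncol = 3))
    unit <- rep(1:3, length.out = 500)
    grid_pairs <- emapfit:::cpp_clash_pairs(xyz, unit, 3)
    expect_equal(grid_pairs, brute_clash_pairs(xyz, unit, 3))
  }
})

test_that("Kabsch RMSD: identity, rigid invariance, two-point closed form", {
  xyz <- with_seed_test(2, matrix(rnorm(60), ncol = 3))
  expect_equal(rmsd_kabsch(xyz, xyz), 0, tolerance = 1e-12)
  p <- random_pose(4)
  R <- pose_rotation_matrix(p)
  moved <- sweep(xyz %*% t(R), 2, p$t, "+")
  expect_lt(rmsd_kabsch(xyz, moved, superpose = TRUE), 1e-9)
  expect_gt(rmsd_kabsch(xyz, moved, superpose = FALSE), 1)
  # two points at distance d vs two coincident points: optimal RMSD = d/2
  d <- 3.4
  suppressWarnings({
    r2 <- rmsd_kabsch(rbind(c(0, 0, 0), c(d, 0, 0)),
                      rbind(c(5, 5, 5), c(5, 5, 5)), superpose = TRUE)
  })
  expect_equal(r2, d / 2, tolerance = 1e-9)
})

test_that("TM-score: identity, displacement, and the brute-force seed oracle", {
  ch <- make_protein_chain(100, seed = 13)
  cx <- complex_model(list(ch))
  expect_equal(tm_score(cx, cx), 1, tolerance = 1e-9)
  # displace the second half by 20 A
  broken <- ch
  sel <- broken$atoms$resno > 50
  broken$atoms$x[sel] <- broken$atoms$x[sel] + 20
  bx <- complex_model(list(broken))
  tm <- tm_score(bx, cx)
  expect_gt(tm, 0.3)   # half the structure still matches
  expect_lt(tm, 0.8)
  # brute-force oracle: every contiguous window seed at several lengths
  ca_m <- coords(broken)[broken$atoms$elety == "CA", ]
  ca_r <- coords(ch)[ch$atoms$elety == "CA", ]
  d0 <- emapfit:::tm_d0(100)
  best <- 0
  for (w in c(5, 10, 25, 50, 100)) {
    for (s in seq_len(100 - w + 1)) {
      best <- max(best, emapfit:::tm_iterate(ca_m, ca_r, s:(s + w - 1),
                                             d0, 100))
    }
  }
  expect_lt(abs(tm - best), 0.02)
  # rigid transforms of both structures leave the score unchanged
  p <- random_pose(9)
  moved <- complex_model(list(apply_pose(broken, p,
                                         center = colMeans(coords(broken)))))
  ref_moved <- complex_model(list(apply_pose(ch, p,
                                             center = colMeans(coords(broken)))))
  expect_equal(tm_score(moved, ref_moved), tm, tolerance = 1e-6)
})
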
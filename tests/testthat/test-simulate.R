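# Synthetic complex generator: geometry, determinism, map simulation,
# noise, ground-truth labels.

test_that("generated helical chains have ideal CA-CA spacing", {
  spec <- toy_complex_spec(protein_lengths = 60, na_bp = integer(0),
                           seed = 1, noise_sigma = 0)
  cx <- make_toy_complex(spec)
  ca <- coords(cx$chains[[1]])[cx$chains[[1]]$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 60)
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) <= 0.1))
})

test_that("generation is deterministic and respects chain composition", {
  spec <- toy_complex_spec(protein_lengths = c(40, 30), na_bp = 10, seed = 7)
  a <- make_toy_complex(spec)
  b <- make_toy_complex(spec)
  expect_identical(coords(a), coords(b))
  kinds <- vapply(a$chains, function(c) c$kind, "")
  expect_equal(unname(kinds), c("protein", "protein", "NA"))
  # layout keeps the inter-chain gap
  for (i in 1:2) for (j in (i + 1):3) {
    dmin <- min(as.matrix(
      dist(rbind(coords(a$chains[[i]]), coords(a$chains[[j]])))
    )[seq_len(nrow(coords(a$chains[[i]]))),
      -seq_len(nrow(coords(a$chains[[i]])))])
    expect_gte(dmin, 2.5)
  }
})

test_that("a single atom simulates an isotropic kernel with the stated width", {
  at <- data.frame(elety = "CA", resno = 1, resid = "ALA", elesy = "C",
                   x = 0, y = 0, z = 0)
  ch <- chain_model(at, kind = "protein")
  m4 <- simulate_map(ch, resolution = 4, voxel_size = 1, pad = 10)
  g <- m4$grid
  ctr <- which(g == max(g), arr.ind = TRUE)[1, ]
  # maximum at the atom voxel
  expect_equal(unname(m4$origin + (ctr - 1) * m4$voxel_size), c(0, 0, 0))
  # isotropy: value at +r equals value at -r
  for (r in 1:3) {
    expect_equal(g[ctr[1] + r, ctr[2], ctr[3]], g[ctr[1] - r, ctr[2], ctr[3]],
                 tolerance = 1e-9)
    expect_equal(g[ctr[1] + r, ctr[2], ctr[3]], g[ctr[1], ctr[2] + r, ctr[3]],
                 tolerance = 1e-9)
  }
  # doubling the resolution doubles the half-max radius (within a voxel)
  half_radius <- function(m) {
    g <- m$grid
    ctr <- which(g == max(g), arr.ind = TRUE)[1, ]
    prof <- g[ctr[1]:dim(g)[1], ctr[2], ctr[3]]
    sum(prof >= max(g) / 2) - 1
  }
  m8 <- simulate_map(ch, resolution = 8, voxel_size = 1, pad = 14)
  expect_lte(abs(half_radius(m8) - 2 * half_radius(m4)), 1)
  expect_error(simulate_map(ch, resolution = 1.5, voxel_size = 1), "Nyquist")
})

test_that("simulated maps are self-consistent and linear in the model", {
  fixt <- fx_single()
  raw <- simulate_map(fixt$complex, resolution = 5, voxel_size = 1)
  expect_gte(suppressWarnings(global_cc(fixt$complex, raw)), 0.99)
  # linearity: density of A+B equals density of A plus density of B
  spec <- toy_complex_spec(protein_lengths = c(30, 30), na_bp = integer(0),
                           seed = 3, noise_sigma = 0)
  cx <- make_toy_complex(spec)
  both <- simulate_map(cx, 5, 1)
  a <- emapfit:::simulate_map_on_grid(complex_model(cx$chains[1]), both)
  b <- emapfit:::simulate_map_on_grid(complex_model(cx$chains[2]), both)
  expect_equal(both$grid, a$grid + b$grid, tolerance = 1e-9)
})

test_that("noise is seeded, clipped at zero, and records a contour level", {
  fixt <- fx_single()
  raw <- simulate_map(fixt$complex, 5, 1)
  expect_identical(add_noise(raw, 0), raw)
  n1 <- add_noise(raw, 0.1, seed = 4)
  n2 <- add_noise(raw, 0.1, seed = 4)
  expect_identical(n1$grid, n2$grid)
  expect_true(all(n1$grid >= 0))
  expect_gt(n1$contour_level, 0)
  # a flat zero map has zero peak, so the noise scale collapses to zero
  zero <- density_map(array(0, c(8, 8, 8)), 1, c(0, 0, 0), 5)
  expect_identical(add_noise(zero, 0.1, seed = 1)$grid, zero$grid)
})

test_that("ground-truth labels follow the 3-Angstrom backbone proximity rule", {
  at <- data.frame(elety = "CA", resno = 1, resid = "ALA", elesy = "C",
                   x = 10, y = 10, z = 10)
  ch <- chain_model(at, kind = "protein")
  cx <- complex_model(list(ch))
  m <- density_map(array(1, c(21, 21, 21)), 1, c(0, 0, 0), 5)
  lab <- ground_truth_labels(cx, m)
  expect_true(all(lab$labels %in% c(0L, 2L)))  # no NA atoms -> no label 1
  # voxel 2 A from the atom -> protein (0); voxel 4 A away -> other (2)
  expect_equal(lab$labels[13, 11, 11], 0L)
  expect_equal(lab$labels[15, 11, 11], 2L)
  # every protein/NA voxel lies within 3 A of a backbone atom
  idx <- which(lab$labels != 2L, arr.ind = TRUE)
  d <- sqrt(rowSums(sweep((idx - 1) * 1, 2, c(10, 10, 10))^2))
  expect_true(all(d <= 3 + 1e-9))
})

test_that("labels separate protein and NA by nearest backbone atom", {
  fixt <- fx_small_pn()
  lab <- fixt$labels
  expect_setequal(unique(as.integer(lab$labels)), 0:2)
  # the NA-labeled density correlates with the NA chain, not the protein
  na_chain <- Filter(function(c) c$kind == "NA", fixt$complex$chains)[[1]]
  cc_na <- suppressWarnings(global_cc(na_chain, fixt$halves$na))
  cc_prot <- suppressWarnings(global_cc(na_chain, fixt$halves$protein))
  expect_gt(cc_na, cc_prot)
})

test_that("the ground-truth pose is the score optimum among perturbations", {
  fixt <- fx_single()
  truth_score <- composite_fit_score(fixt$chain, fixt$map)
  worse <- 0
  for (s in 1:25) {
    p <- with_seed_test(s, pose(emapfit:::quat_from_axis_angle(
      rnorm(3), runif(1, 0.1, 0.6)), runif(3, -4, 4)))
    pert <- apply_pose(fixt$chain, p)
    if (composite_fit_score(pert, fixt$map) >= truth_score)
      worse <- worse + 1
  }
  expect_equal(worse, 0)
})
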
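# Chain parsing, classification, pose algebra, rigid transforms, radius of
# gyration and domain partitioning.

test_that("pose algebra: inverse, composition, double cover", {
  for (s in 1:5) {
    p <- random_pose(s)
    pi_ <- pose_inverse(p)
    idp <- pose_compose(pi_, p)
    expect_lt(pose_angle(idp), 1e-9)
    expect_lt(sqrt(sum(idp$t^2)), 1e-9)
    # q and -q encode the same rotation
    pneg <- pose(-p$q, p$t)
    expect_equal(pose_rotation_matrix(p), pose_rotation_matrix(pneg),
                 tolerance = 1e-12)
    # associativity
    a <- random_pose(s + 10); b <- random_pose(s + 20)
    left <- pose_compose(pose_compose(a, b), p)
    right <- pose_compose(a, pose_compose(b, p))
    expect_lt(max(pose_distance(left, right)), 1e-9)
  }
  expect_equal(pose_compose(pose_identity(), random_pose(1))$q,
               random_pose(1)$q)
})

test_that("apply_pose is rigid and invertible; analytic 180-degree case", {
  ch <- make_protein_chain(40, seed = 2)
  p <- random_pose(3)
  moved <- apply_pose(ch, p)
  expect_lt(max_pairdist_change(coords(ch), coords(moved)), 1e-9)
  back <- apply_pose(moved, pose_inverse(p), center = colMeans(coords(ch)))
  expect_lt(max(abs(coords(back) - coords(ch))), 1e-8)
  # 180-degree rotation about z maps (1,0,0) to (-1,0,0) about a COM at 0
  at <- data.frame(elety = c("CA", "CA"), resno = 1:2,
                   resid = "ALA", elesy = "C",
                   x = c(1, -1), y = 0, z = 0)
  two <- chain_model(at, kind = "protein")
  rot <- apply_pose(two, pose_from_euler(180, 0, 0))
  expect_equal(coords(rot)[1, ], c(x = -1, y = 0, z = 0), tolerance = 1e-12)
})

test_that("radius of gyration: analytic cases and the uniform ball", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  expect_warning(r0 <- radius_of_gyration(rbind(c(1, 1, 1), c(1, 1, 1))),
                 "coincident")
  expect_equal(r0, 0)
  # 3000 points uniform in a radius-10 ball: Rg -> 10 * sqrt(3/5)
  pts <- with_seed_test(8, {
    p <- matrix(runif(3 * 12000, -10, 10), ncol = 3)
    p[rowSums(p^2) <= 100, ][1:3000, ]
  })
  expect_equal(radius_of_gyration(pts), 10 * sqrt(3 / 5), tolerance = 0.02)
})

test_that("chain classification by residue content", {
  poly_ala <- chain_model(data.frame(elety = "CA", resno = 1:10,
                                     resid = "ALA", elesy = "C",
                                     x = 3.8 * (1:10), y = 0, z = 0))
  expect_equal(poly_ala$kind, "protein")
  dna <- chain_model(data.frame(elety = "P", resno = 1:8,
                                resid = rep(c("DA", "DT", "DG", "DC"), 2),
                                elesy = "P", x = 7 * (1:8), y = 0, z = 0))
  expect_equal(dna$kind, "NA")
  expect_true(dna$rigid)  # NA chains are rigid by contract
  mixed <- data.frame(elety = "CA", resno = 1:10,
                      resid = c(rep("ALA", 5), rep("DA", 5)), elesy = "C",
                      x = 3.8 * (1:10), y = 0, z = 0)
  expect_error(chain_model(mixed), "mixed chain")
})

test_that("PDB round-trip through write_complex_pdb / read_chains", {
  spec <- toy_complex_spec(protein_lengths = c(30), na_bp = 8, seed = 4,
                           noise_sigma = 0)
  cx <- make_toy_complex(spec)
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(cx, f, scores = list(A = list(cc = 0.9)))
  expect_true(any(grepl("REMARK 3", readLines(f))))
  back <- read_chains(f)
  expect_length(back, 2)
  kinds <- sort(vapply(back, function(c) c$kind, ""))
  expect_equal(kinds, c("NA", "protein"))
  orig <- coords(cx)
  again <- do.call(rbind, lapply(back, coords))
  expect_equal(dim(again), dim(orig))
  expect_lt(max(abs(sort(again[, 1]) - sort(orig[, 1]))), 1e-3)
  unlink(f)
})

test_that("HETATM-only files are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(read_chains(f), "no ATOM records")
  unlink(f)
})

test_that("a two-chain duplex file read as a rigid unit becomes one NA chain", {
  duplex <- make_na_duplex(8, seed = 2)
  # write the two strands as separate PDB chains
  n <- max(duplex$atoms$resno) / 2
  s1 <- duplex$atoms[duplex$atoms$resno <= n, ]
  s2 <- duplex$atoms[duplex$atoms$resno > n, ]
  s2$resno <- s2$resno - n
  two <- complex_model(list(chain_model(s1, chain_id = "X", kind = "NA"),
                            chain_model(s2, chain_id = "Y", kind = "NA")))
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(two, f)
  rigid <- read_chains(f, rigid_unit = TRUE)
  expect_length(rigid, 1)
  expect_equal(rigid[[1]]$kind, "NA")
  expect_true(rigid[[1]]$rigid)
  expect_equal(nrow(rigid[[1]]$atoms), nrow(duplex$atoms))
  unlink(f)
})

test_that("explicit domain boundaries split exactly", {
  ch <- make_protein_chain(200, seed = 6)
  seg <- partition_domains(ch, boundaries = 101)
  expect_equal(seg$start, c(1, 101))
  expect_equal(seg$end, c(100, 200))
  expect_error(partition_domains(ch, boundaries = 999), "outside")
  one <- partition_domains(make_protein_chain(50, seed = 1))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1, 50))
})

test_that("automatic partition finds a two-globule linker", {
  g1 <- make_protein_chain(80, seed = 11)
  g2 <- make_protein_chain(80, seed = 12)
  a1 <- g1$atoms
  a2 <- g2$atoms
  # separate the globules and bridge them with a 5-residue linker
  shift <- c(40, 0, 0)
  a2$x <- a2$x - mean(a2$x) + shift[1]
  a2$y <- a2$y - mean(a2$y); a2$z <- a2$z - mean(a2$z)
  a1$x <- a1$x - mean(a1$x); a1$y <- a1$y - mean(a1$y)
  a1$z <- a1$z - mean(a1$z)
  end1 <- unlist(a1[a1$resno == 80 & a1$elety == "CA", c("x", "y", "z")])
  start2 <- unlist(a2[a2$resno == 1 & a2$elety == "CA", c("x", "y", "z")])
  linker <- do.call(rbind, lapply(1:5, function(i) {
    pos <- end1 + (start2 - end1) * i / 6
    data.frame(elety = "CA", resno = 80 + i, resid = "GLY", elesy = "C",
               x = pos[1], y = pos[2], z = pos[3])
  }))
  a2$resno <- a2$resno + 85
  ch <- chain_model(rbind(a1, linker, a2), kind = "protein")
  seg <- partition_domains(ch)
  expect_equal(nrow(seg), 2)
  # split within +-5 residues of the linker (residues 81-85)
  expect_gte(seg$end[1], 76)
  expect_lte(seg$end[1], 90)
  # partition covers the chain exactly once
  expect_equal(seg$start[1], 1)
  expect_equal(seg$end[2], 165)
  expect_equal(seg$start[2], seg$end[1] + 1)
})
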
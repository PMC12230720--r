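# Density-map container, MRC2014 input/output, resampling, normalization,
# chunking and masking.

make_random_map <- function(seed = 1, d = c(12, 10, 14), voxel = 1.5,
                            origin = c(-3, 2, 5)) {
  with_seed_test(seed, density_map(array(runif(prod(d)), dim = d),
                                   voxel_size = voxel, origin = origin,
                                   resolution = 6))
}

test_that("MRC round-trip preserves grid, voxel size and origin", {
  m <- make_random_map()
  f <- tempfile(fileext = ".mrc")
  write_mrc(m, f)
  m2 <- read_mrc(f, resolution = m$resolution)
  expect_equal(dim(m2$grid), dim(m$grid))
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)  # float32 storage
  expect_equal(m2$voxel_size, m$voxel_size, tolerance = 1e-6)
  expect_equal(m2$origin, m$origin, tolerance = 1e-5)
  unlink(f)
})

test_that("an independent MRC reader (gemmi) agrees with write_mrc", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  m <- make_random_map(seed = 2)
  f <- tempfile(fileext = ".mrc")
  write_mrc(m, f)
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "import gemmi; g = gemmi.read_ccp4_map('", f, "'); ",
    "import numpy as np; a = np.array(g.grid, copy=False); ",
    "print(a.shape[0], a.shape[1], a.shape[2], float(a.sum()), ",
    "g.grid.spacing[0])"))), stdout = TRUE, stderr = TRUE),
    error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0, "gemmi unavailable")
  vals <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(vals[1:3], dim(m$grid))
  expect_equal(vals[4], sum(m$grid), tolerance = 1e-5)
  expect_equal(vals[5], m$voxel_size, tolerance = 1e-5)
  unlink(f)
})

test_that("axis-permuted MRC files are rearranged to canonical order", {
  m <- make_random_map(seed = 3, voxel = 1)
  # write a file whose columns run along physical y, rows along z,
  # sections along x (MAPC/MAPR/MAPS = 2, 3, 1)
  perm_grid <- aperm(m$grid, c(2, 3, 1))
  d <- dim(perm_grid)
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L); wi(c(0L, 0L, 0L))
  wi(dim(m$grid))                       # MX MY MZ along physical axes
  wf(dim(m$grid) * m$voxel_size); wf(c(90, 90, 90))
  wi(c(2L, 3L, 1L))                     # MAPC MAPR MAPS
  wf(c(min(perm_grid), max(perm_grid), mean(perm_grid)))
  wi(c(1L, 0L)); wi(rep(0L, 24))
  seek(con, 4 * 49); wf(m$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(sd(as.numeric(perm_grid))); wi(0L); writeBin(raw(800), con)
  wf(as.numeric(perm_grid))
  close(con)
  m2 <- read_mrc(f)
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)
  unlink(f)
})

test_that("truncated MRC files raise a format error, no partial map", {
  m <- make_random_map(seed = 4)
  f <- tempfile(fileext = ".mrc")
  write_mrc(m, f)
  raw_all <- readBin(f, "raw", file.size(f))
  writeBin(raw_all[1:(1024 + 100)], f)  # cut mid-data
  expect_error(read_mrc(f), "truncated")
  unlink(f)
})

test_that("resampling: identity, constants, and a linear ramp", {
  m <- make_random_map(seed = 5)
  same <- resample_map(m, m$voxel_size)
  expect_equal(same$grid, m$grid, tolerance = 1e-9)
  const <- density_map(array(2.5, dim = c(10, 10, 10)), 2, c(0, 0, 0), 6)
  rc <- resample_map(const, 1.3)
  inner <- rc$grid[3:12, 3:12, 3:12]
  expect_true(all(abs(inner - 2.5) < 1e-9))
  # f(x) = x sampled at 2 A, resampled to 1 A: interior matches the ramp
  d <- c(12, 9, 9)
  xs <- (seq_len(d[1]) - 1) * 2
  ramp <- density_map(array(rep(xs, prod(d[2:3])), dim = d), 2, c(0, 0, 0), 6)
  r1 <- resample_map(ramp, 1)
  xi <- (seq_len(dim(r1$grid)[1]) - 1) * 1
  interior <- 2:(dim(r1$grid)[1] - 2)
  expect_equal(r1$grid[interior, 5, 5], xi[interior], tolerance = 1e-9)
  expect_error(resample_map(m, 100), "below 8 voxels")
})

test_that("normalization thresholds, scales to the 98th percentile, clips", {
  d <- c(10, 10, 10)
  vals <- seq(0, 100, length.out = prod(d))
  m <- density_map(array(vals, dim = d), 1, c(0, 0, 0), 5)
  n <- normalize_map(m)
  expect_equal(max(n$grid), 1)
  expect_true(all(n$grid >= 0 & n$grid <= 1))
  nz <- n$grid[n$grid > 0]
  expect_gte(mean(nz == 1), 0.02)   # everything above the 98th pct clips
  # idempotence
  n2 <- normalize_map(n)
  expect_equal(n2$grid, n$grid, tolerance = 1e-12)
  # contour thresholding zeroes values below the level
  nc <- normalize_map(m, contour_level = 50)
  expect_true(all(nc$grid[m$grid < 50] == 0))
  expect_error(normalize_map(m, contour_level = 1000), "degenerate")
})

test_that("chunking covers every voxel on a stride-32 lattice", {
  m64 <- density_map(array(runif(64^3), dim = c(64, 64, 64)), 1, c(0, 0, 0), 5)
  ch <- chunk_map(m64)
  expect_length(ch, 8)  # corners 0 and 32 per axis
  m96 <- density_map(array(runif(50 * 96 * 96), dim = c(96, 96, 96))[1:96, , ] * 0 + 1,
                     1, c(0, 0, 0), 5)
  m96$grid <- array(runif(96^3), dim = c(96, 96, 96))
  ch96 <- chunk_map(m96)
  expect_length(ch96, 27)  # corners 0, 32, 64 per axis
  corners <- t(vapply(ch96, function(c) c$corner, numeric(3)))
  expect_true(all(corners %% 32 == 0))
  # coverage: the corner-(0,0,0) chunk reproduces the map block, and every
  # voxel lies inside at least one chunk
  expect_equal(ch96[[1]]$data, m96$grid[1:64, 1:64, 1:64])
  covered <- array(FALSE, dim = dim(m96$grid))
  for (c in ch96) {
    xr <- (c$corner[1] + 1):min(c$corner[1] + 64, 96)
    covered[xr, (c$corner[2] + 1):min(c$corner[2] + 64, 96),
            (c$corner[3] + 1):min(c$corner[3] + 64, 96)] <- TRUE
  }
  expect_true(all(covered))
  # boundary chunks are zero-padded
  last <- ch96[[length(ch96)]]
  expect_true(all(last$data[34:64, , ] == 0))
})

test_that("masking zeroes exactly the voxels within the radius", {
  d <- c(9, 9, 9)
  m <- density_map(array(1, dim = d), 1, c(0, 0, 0), 5)
  atom <- matrix(c(4, 4, 4), 1, 3)  # at a voxel center
  mm <- mask_region(m, atom, radius = 2)
  # integer lattice points with |v| <= 2: exactly 33
  expect_equal(sum(mm$grid == 0), 33)
  idx <- which(mm$grid == 0, arr.ind = TRUE) - 1
  expect_true(all(rowSums(sweep(idx, 2, c(4, 4, 4))^2) <= 4))
  # idempotent, never increases values
  mm2 <- mask_region(mm, atom, radius = 2)
  expect_identical(mm2$grid, mm$grid)
  expect_true(all(mm$grid <= m$grid))
  expect_warning(mask_region(m, matrix(0, 0, 3)), "empty")
})

test_that("masking a fitted chain lowers its own correlation", {
  fixt <- fx_single()
  cc_before <- suppressWarnings(global_cc(fixt$chain, fixt$map))
  masked <- mask_region(fixt$map, coords(fixt$chain), radius = 3)
  cc_after <- suppressWarnings(global_cc(fixt$chain, masked))
  expect_lt(cc_after, cc_before)
})

test_that("map radius of gyration matches point-mass expectations", {
  d <- c(15, 8, 8)
  g <- array(0, dim = d)
  g[3, 4, 4] <- 1
  m1 <- density_map(g, 1, c(0, 0, 0), 5)
  expect_equal(map_radius_of_gyration(m1), 0)
  g[13, 4, 4] <- 1  # two equal masses 10 A apart
  m2 <- density_map(g, 1, c(0, 0, 0), 5)
  expect_equal(map_radius_of_gyration(m2), 5)
  expect_error(map_radius_of_gyration(density_map(array(0, c(8, 8, 8)),
                                                  1, c(0, 0, 0), 5)),
               "degenerate")
})
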
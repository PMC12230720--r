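#' Density maps
#'
#' A `density_map` holds a 3-D grid of density values on an isotropic voxel
#' lattice. The grid is stored x-fastest: `grid[i, j, k]` sits at physical
#' position `origin + (c(i, j, k) - 1) * voxel_size` (Angstrom). Maps read
#' from MRC files with a permuted axis order (MAPC/MAPR/MAPS) are rearranged
#' to this canonical storage on input.
#'
#' @param grid 3-D numeric array of density values.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical coordinate (Angstrom) of the first voxel center.
#' @param resolution nominal map resolution in Angstrom (> 0).
#' @param contour_level density threshold treated as the noise floor.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        resolution = 5, contour_level = 0) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  if (!is.finite(resolution) || resolution <= 0) stop("resolution must be > 0")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), resolution = resolution,
                 contour_level = contour_level),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map> %d x %d x %d voxels @ %.3g A, origin (%.1f, %.1f, %.1f), resolution %.2g A\n",
    d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3],
    x$resolution))
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

# MRC2014 header layout (56 int/float words + 10 x 80-char labels).
# Only mode 2 (float32) volumes are handled; that is what EM software
# exchanges for density maps.
.mrc_read_header <- function(con) {
  hdr <- readBin(con, "raw", n = 1024)
  if (length(hdr) < 1024) stop("MRC format error: header truncated")
  ints <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "integer",
                              n = length(i), size = 4, endian = "little")
  flts <- function(i) readBin(hdr[(4 * (i - 1) + 1):(4 * i)], "numeric",
                              n = length(i), size = 4, endian = "little")
  map_tag <- rawToChar(hdr[(4 * 52 + 1):(4 * 52 + 3)])
  list(nxyz = vapply(1:3, function(i) ints(i), 0L),
       mode = ints(4),
       nstart = vapply(5:7, function(i) ints(i), 0L),
       mxyz = vapply(8:10, function(i) ints(i), 0L),
       cella = vapply(11:13, function(i) flts(i), 0),
       mapcrs = vapply(17:19, function(i) ints(i), 0L),
       origin = vapply(50:52, function(i) flts(i), 0),
       map_tag = map_tag)
}

#' Read an MRC2014 density map
#'
#' Honors the MAPC/MAPR/MAPS axis permutation (data are rearranged into
#' canonical x-fastest storage), derives the voxel size from the cell
#' dimensions, and takes the physical origin from the ORIGIN header field
#' when it is nonzero, otherwise from NXSTART/NYSTART/NZSTART times the
#' voxel size. Gzip-compressed files are accepted.
#'
#' @param path path to a `.mrc` / `.map` file (optionally `.gz`).
#' @param resolution nominal resolution to attach (Angstrom); MRC files do
#'   not carry one.
#' @param contour_level contour level to attach (default 0).
#' @return A [density_map].
#' @export
read_mrc <- function(path, resolution = 5, contour_level = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con)
  if (!identical(h$map_tag, "MAP")) {
    # older files may omit the tag; only fail on clearly corrupt dims
    if (any(h$nxyz <= 0) || any(h$nxyz > 4000))
      stop("MRC format error: bad dimensions field NX/NY/NZ")
  }
  if (h$mode != 2L)
    stop("MRC format error: unsupported MODE ", h$mode, " (need float32, mode 2)")
  if (any(sort(h$mapcrs) != 1:3))
    stop("MRC format error: bad axis correspondence field MAPC/MAPR/MAPS")
  if (any(h$mxyz <= 0)) stop("MRC format error: bad sampling field MX/MY/MZ")
  n <- prod(h$nxyz)
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) < n) stop("MRC format error: data section truncated")
  arr <- array(vals, dim = h$nxyz)
  # file dims are (columns, rows, sections) along physical axes mapcrs;
  # rearrange so dimension k of the result is physical axis k
  perm <- match(1:3, h$mapcrs)
  arr <- aperm(arr, perm)
  nstart <- h$nstart[perm]
  voxel3 <- h$cella / h$mxyz
  voxel <- voxel3[1]
  if (max(abs(voxel3 - voxel)) > 1e-3 * voxel) {
    warning("anisotropic voxels (", paste(signif(voxel3, 4), collapse = ", "),
            " A); resample before fitting")
    voxel <- mean(voxel3)
  }
  org <- if (any(abs(h$origin) > 1e-6)) h$origin else nstart * voxel3
  density_map(arr, voxel_size = voxel, origin = org,
              resolution = resolution, contour_level = contour_level)
}

#' Write a density map as MRC2014
#'
#' Always writes canonical axis order (MAPC/MAPR/MAPS = 1/2/3), mode 2
#' (float32), with the physical origin in the ORIGIN field.
#'
#' @param map a [density_map].
#' @param path output path.
#' @export
write_mrc <- function(map, path) {
  stopifnot(is_density_map(map))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(map$grid)
  wi(d)                          # NX NY NZ
  wi(2L)                         # MODE float32
  wi(c(0L, 0L, 0L))              # NXSTART
  wi(d)                          # MX MY MZ
  wf(d * map$voxel_size)         # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(1:3)                        # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v))) # DMIN DMAX DMEAN
  wi(c(1L, 0L))                  # ISPG, NSYMBT
  wi(rep(0L, 24))                # extra (incl. EXTTYP); word 28 = NVERSION
  seek(con, 4 * 27)
  wi(20140L)                     # NVERSION
  seek(con, 4 * 49)
  wf(map$origin)                 # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(v))                      # RMS
  wi(0L)                         # NLABL
  writeBin(raw(800), con)        # labels
  wf(v)
  invisible(path)
}

#' Resample a map onto a new isotropic voxel size
#'
#' Trilinear interpolation onto a lattice with the same physical origin and
#' (as near as possible) the same physical extent.
#'
#' @param map a [density_map].
#' @param target_voxel new voxel edge length in Angstrom.
#' @return A [density_map] on the new lattice.
#' @export
resample_map <- function(map, target_voxel) {
  stopifnot(is_density_map(map))
  if (!is.finite(target_voxel) || target_voxel <= 0)
    stop("target_voxel must be > 0")
  d <- dim(map$grid)
  extent <- (d - 1) * map$voxel_size
  nd <- pmax(1L, as.integer(round(extent / target_voxel)) + 1L)
  if (any(nd < 8))
    stop("target_voxel too large: an axis would fall below 8 voxels")
  out <- cpp_resample_trilinear(as.numeric(map$grid), dim(map$grid),
                                map$origin, map$voxel_size,
                                nd, map$origin, target_voxel)
  density_map(array(out, dim = nd), voxel_size = target_voxel,
              origin = map$origin, resolution = map$resolution,
              contour_level = map$contour_level)
}

#' Contour-threshold and normalize a map
#'
#' Density below the contour level is set to zero; the remaining values are
#' scaled linearly so that 0 maps to 0 and the 98th-percentile value of the
#' retained (strictly positive after thresholding) voxels maps to 1, with
#' larger values clipped to 1. The percentile is computed over the signal
#' region only, so it does not depend on how much empty box padding the map
#' carries. Idempotent.
#'
#' @param map a [density_map].
#' @param contour_level noise-floor threshold (defaults to the map's own
#'   `contour_level`, itself 0 by default).
#' @param probs percentile used as the normalization maximum.
#' @return A normalized [density_map] with values in \[0, 1\].
#' @export
normalize_map <- function(map, contour_level = NULL, probs = 0.98) {
  stopifnot(is_density_map(map))
  cl <- if (is.null(contour_level)) map$contour_level else contour_level
  if (!is.finite(cl)) stop("contour_level must be finite")
  g <- map$grid
  g[g < cl] <- 0
  pos <- g[g > max(cl, 0)]
  if (length(pos) == 0)
    stop("degenerate map: no density above the contour level")
  # order-statistic percentile (no interpolation), so that normalization
  # is exactly idempotent: the scaling value maps to exactly 1 and stays
  # the percentile value of the clipped distribution
  p98 <- as.numeric(quantile(pos, probs = probs, names = FALSE, type = 1))
  if (p98 <= 0) stop("degenerate map: normalization percentile is zero")
  g <- pmin(g / p98, 1)
  out <- density_map(g, voxel_size = map$voxel_size, origin = map$origin,
                     resolution = map$resolution, contour_level = 0)
  attr(out, "normalized") <- TRUE
  out
}

#' Cut a map into overlapping cubic chunks
#'
#' Chunks of `size`^3 voxels anchored on a stride-`stride` lattice starting
#' at the map corner; chunks that extend past the map boundary are
#' zero-padded, and every voxel of the parent map is covered by at least one
#' chunk. For segmentation the map should already be on a 1 Angstrom lattice,
#' so the stride in voxels equals the stride in Angstrom.
#'
#' @param map a [density_map].
#' @param size chunk edge, voxels (default 64).
#' @param stride lattice stride, voxels (default 32).
#' @return List of chunks, each a list with `data` (`size`^3 array) and
#'   `corner` (0-based integer grid offset within the parent map).
#' @export
chunk_map <- function(map, size = 64L, stride = 32L) {
  stopifnot(is_density_map(map))
  d <- dim(map$grid)
  corners <- lapply(d, function(n) as.integer(seq(0L, n - 1L, by = stride)))
  out <- list()
  for (cz in corners[[3]]) for (cy in corners[[2]]) for (cx in corners[[1]]) {
    blk <- array(0, dim = c(size, size, size))
    xr <- (cx + 1):min(cx + size, d[1])
    yr <- (cy + 1):min(cy + size, d[2])
    zr <- (cz + 1):min(cz + size, d[3])
    blk[seq_along(xr), seq_along(yr), seq_along(zr)] <- map$grid[xr, yr, zr]
    out[[length(out) + 1L]] <- list(data = blk, corner = c(cx, cy, cz))
  }
  out
}

#' Mask a map region around atom coordinates
#'
#' Every voxel whose center lies within `radius` of any input coordinate is
#' set to zero; all other voxels are unchanged. Used to remove density
#' already explained by a fitted chain before fitting the next one.
#' Idempotent.
#'
#' @param map a [density_map].
#' @param coords n x 3 matrix of atom positions (Angstrom).
#' @param radius masking radius in Angstrom (default 3, matching the
#'   labeling proximity).
#' @export
mask_region <- function(map, coords, radius = 3) {
  stopifnot(is_density_map(map))
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) {
    warning("empty coordinate list: map returned unchanged")
    return(map)
  }
  g <- cpp_mask_coords(as.numeric(map$grid), dim(map$grid), map$origin,
                       map$voxel_size, coords, radius)
  map$grid <- array(g, dim = dim(map$grid))
  map
}

#' Density-weighted radius of gyration of a map
#'
#' Radius of gyration of the voxel centers weighted by density. Used to
#' decide whether a chain occupies the whole map or a sub-region when
#' placing initial poses.
#'
#' @param map a [density_map] with nonzero voxels.
#' @return Radius of gyration in Angstrom.
#' @export
map_radius_of_gyration <- function(map) {
  stopifnot(is_density_map(map))
  w <- as.numeric(map$grid)
  keep <- w > 0
  if (!any(keep)) stop("degenerate map: all voxels are zero")
  d <- dim(map$grid)
  idx <- which(keep)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  xyz <- cbind(i, j, k) * map$voxel_size +
    matrix(map$origin, length(idx), 3, byrow = TRUE)
  radius_of_gyration(xyz, w[keep])
}

# density centroid in physical coordinates
map_centroid <- function(map) {
  w <- as.numeric(map$grid)
  keep <- w > 0
  if (!any(keep)) stop("degenerate map: all voxels are zero")
  d <- dim(map$grid)
  idx <- which(keep)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  xyz <- cbind(i, j, k) * map$voxel_size +
    matrix(map$origin, length(idx), 3, byrow = TRUE)
  colSums(xyz * w[keep]) / sum(w[keep])
}
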
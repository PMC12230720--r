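# Synthetic protein/NA complexes with plausible backbone geometry, plus
# simulated density maps, ground-truth voxel labels and poses. Everything
# downstream (segmentation, fitting, assembly, scoring) is tested against
# these fixtures, so generation is fully deterministic given the seed.

# run code under a temporary RNG state; never touches the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.element_z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

atomic_numbers <- function(elesy) {
  z <- .element_z[toupper(elesy)]
  z[is.na(z)] <- 7
  as.numeric(z)
}

#' Specification of a synthetic complex
#'
#' Defaults describe the standard test complex: two kinked helical protein
#' chains (150 and 90 residues) and one rigid 30-bp B-form DNA duplex, a
#' 5 Angstrom map and 5% Gaussian noise.
#'
#' @param protein_lengths residues per protein chain (may be empty).
#' @param na_bp base pairs per NA duplex (one rigid duplex per entry; may
#'   be empty).
#' @param resolution nominal map resolution, Angstrom.
#' @param voxel_size map voxel size, Angstrom.
#' @param noise_sigma noise standard deviation as a fraction of the map
#'   maximum.
#' @param seed RNG seed; regeneration with the same seed is bit-identical.
#' @param gap minimum inter-chain heavy-atom gap, Angstrom.
#' @param segment_length residues per helical segment before a kink.
#' @export
toy_complex_spec <- function(protein_lengths = c(150, 90), na_bp = 30,
                             resolution = 5, voxel_size = 1,
                             noise_sigma = 0.05, seed = 1, gap = 4,
                             segment_length = 40) {
  structure(list(protein_lengths = protein_lengths, na_bp = na_bp,
                 resolution = resolution, voxel_size = voxel_size,
                 noise_sigma = noise_sigma, seed = seed, gap = gap,
                 segment_length = segment_length),
            class = "toy_complex_spec")
}

# CA trace of a kinked alpha-helix: ideal helix (rise 1.5 A, 100 deg per
# residue, radius 2.3 A) folded back on itself every `segment_length`
# residues. Kinks are rigid rotations of the remaining construction about
# the current CA plus a lateral displacement bridged by turn residues, so
# every consecutive CA-CA distance stays at the ideal 3.8 A.
helix_ca_trace <- function(n_res, segment_length = 40, kink_azimuths = NULL) {
  rise <- 1.5; twist <- 100 * pi / 180; r <- 2.3
  step <- sqrt((2 * r * sin(twist / 2))^2 + rise^2)  # ~3.8 A
  O <- c(0, 0, 0); e1 <- c(1, 0, 0); e2 <- c(0, 1, 0); u <- c(0, 0, 1)
  theta <- 0; s <- 0
  ca <- matrix(NA_real_, n_res, 3)
  n_seg <- max(1L, ceiling(n_res / segment_length))
  if (is.null(kink_azimuths)) kink_azimuths <- seq_len(n_seg) * 137.5 * pi / 180
  kink_at <- if (n_seg > 1) cumsum(rep(segment_length, n_seg - 1)) else integer(0)
  i <- 1; kink_i <- 1
  rot_about <- function(axis, ang) {
    q <- quat_from_axis_angle(axis, ang)
    quat_to_matrix(q)
  }
  while (i <= n_res) {
    ca[i, ] <- O + s * u + r * (cos(theta) * e1 + sin(theta) * e2)
    if (i %in% kink_at && i + 2 <= n_res) {
      P <- ca[i, ]
      az <- kink_azimuths[kink_i]; kink_i <- kink_i + 1
      n_axis <- cos(az) * e1 + sin(az) * e2
      R <- rot_about(n_axis, 140 * pi / 180)
      # rotate the whole construction frame about the current CA
      O <- as.numeric(R %*% (O - P)) + P
      e1 <- as.numeric(R %*% e1); e2 <- as.numeric(R %*% e2)
      u <- as.numeric(R %*% u)
      # one helix step in the rotated frame
      th2 <- theta + twist; s2 <- s + rise
      Q0 <- O + s2 * u + r * (cos(th2) * e1 + sin(th2) * e2)
      v <- Q0 - P
      # push the new segment laterally so helices pack without clashing;
      # the displacement is sized so the joint spans exactly two CA steps
      perp <- u - sum(u * (v / sqrt(sum(v^2)))) * (v / sqrt(sum(v^2)))
      if (sqrt(sum(perp^2)) < 1e-6) perp <- e1
      nvec <- perp / sqrt(sum(perp^2))
      b <- sum(nvec * v)
      disc <- b^2 + (2 * step)^2 - sum(v^2)
      delta <- -b + sqrt(max(disc, 0))
      O <- O + delta * nvec
      theta <- th2; s <- s2
      Q <- O + s * u + r * (cos(theta) * e1 + sin(theta) * e2)
      # bridging turn residue at the midpoint (both spacings = step)
      if (i + 1 <= n_res) ca[i + 1, ] <- (P + Q) / 2
      if (i + 2 <= n_res) ca[i + 2, ] <- Q
      i <- i + 3; theta <- theta + twist; s <- s + rise
    } else {
      i <- i + 1; theta <- theta + twist; s <- s + rise
    }
  }
  ca
}

# Full backbone (N, CA, C, O) from a CA trace; N/C sit near the virtual
# CA-CA bonds so consecutive-atom distances are plausible.
protein_backbone_from_ca <- function(ca, resid = NULL) {
  n <- nrow(ca)
  vnext <- rbind(ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE], c(0, 0, 0))
  vnext[n, ] <- vnext[n - 1, ]
  vprev <- -rbind(c(0, 0, 0), vnext[-n, , drop = FALSE])
  vprev[1, ] <- -vnext[1, ]
  unitize <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-9)
  vn <- unitize(vnext); vp <- unitize(vprev)
  perp <- cbind(vn[, 2] * vp[, 3] - vn[, 3] * vp[, 2],
                vn[, 3] * vp[, 1] - vn[, 1] * vp[, 3],
                vn[, 1] * vp[, 2] - vn[, 2] * vp[, 1])
  bad <- sqrt(rowSums(perp^2)) < 1e-6
  perp[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3, byrow = TRUE)
  perp <- unitize(perp)
  Npos <- ca + 1.25 * vp + 0.55 * perp
  Cpos <- ca + 1.25 * vn + 0.55 * perp
  Opos <- Cpos + 1.23 * perp
  if (is.null(resid))
    resid <- sample(c("ALA", "LEU", "GLU", "LYS", "SER", "VAL", "ARG", "ASP"),
                    n, replace = TRUE)
  data.frame(
    elety = rep(c("N", "CA", "C", "O"), n),
    resno = rep(seq_len(n), each = 4),
    resid = rep(resid, each = 4),
    elesy = rep(c("N", "C", "C", "O"), n),
    x = as.numeric(t(cbind(Npos[, 1], ca[, 1], Cpos[, 1], Opos[, 1]))),
    y = as.numeric(t(cbind(Npos[, 2], ca[, 2], Cpos[, 2], Opos[, 2]))),
    z = as.numeric(t(cbind(Npos[, 3], ca[, 3], Cpos[, 3], Opos[, 3]))),
    stringsAsFactors = FALSE)
}

#' Build one synthetic protein chain
#'
#' Kinked ideal alpha-helix backbone (N, CA, C, O); consecutive CA-CA
#' distances are 3.8 Angstrom throughout, including across kinks.
#'
#' @param n_res number of residues (>= 10).
#' @param chain_id chain identifier.
#' @param segment_length residues per helical segment.
#' @param seed RNG seed (residue identities, kink azimuths).
#' @return A [chain_model] of kind `"protein"`.
#' @export
make_protein_chain <- function(n_res, chain_id = "A", segment_length = 40,
                               seed = 1) {
  if (n_res < 10) stop("chain length must be at least 10 residues")
  with_seed(seed, {
    n_seg <- max(1L, ceiling(n_res / segment_length))
    az <- runif(n_seg, 0, 2 * pi)
    ca <- helix_ca_trace(n_res, segment_length, kink_azimuths = az)
    chain_model(protein_backbone_from_ca(ca), chain_id = chain_id,
                kind = "protein")
  })
}

# cylindrical placement of one B-form backbone atom set
.na_atom_geom <- data.frame(
  elety = c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "C1'"),
  elesy = c("P", "O", "C", "C", "C", "O", "C"),
  r = c(9.0, 8.7, 8.4, 7.7, 7.7, 8.1, 5.8),
  dphi = c(0, 7, 14, 20, 26, 31, 14) * pi / 180,
  dz = c(0, -0.9, -1.7, -2.0, -2.7, -3.3, -1.2),
  stringsAsFactors = FALSE)

# simplified base atoms reaching from the sugar toward the helix axis;
# purines (two fused rings, 9-10 heavy atoms in reality) carry more ring
# atoms than pyrimidines, so base-pair density is asymmetric across the
# duplex dyad for a random sequence, as in real maps -- without this a
# backbone-only duplex cannot distinguish a 180-degree flip
.na_base_geom <- function(resid) {
  purine <- resid %in% c("DA", "DG", "A", "G")
  if (purine)
    data.frame(elety = c("N9", "C8", "C4", "N3", "C6"),
               elesy = c("N", "C", "C", "N", "C"),
               r = c(4.8, 4.4, 3.2, 2.4, 1.6),
               dphi = c(14, 22, 14, 8, 14) * pi / 180,
               dz = rep(-1.2, 5), stringsAsFactors = FALSE)
  else
    data.frame(elety = c("N1", "C2", "C4"), elesy = c("N", "C", "C"),
               r = c(4.8, 3.8, 2.6), dphi = c(14, 10, 14) * pi / 180,
               dz = rep(-1.2, 3), stringsAsFactors = FALSE)
}

#' Build one synthetic double-stranded NA chain
#'
#' Idealized B-form duplex backbone (P, O5', C5', C4', C3', O3', C1' plus
#' simplified base atoms per nucleotide; rise 3.4 Angstrom, twist 36
#' degrees per base pair). Both strands are returned as a single rigid
#' [chain_model] (residues 1..n for strand one, n+1..2n for the
#' antiparallel complement), mirroring a duplex supplied as one PDB file.
#'
#' By default strand one is a homopurine tract (random DA/DG), the
#' complement homopyrimidine -- the classic poly-purine:poly-pyrimidine
#' construct. With a uniformly random sequence the purine/pyrimidine
#' asymmetry largely cancels along the helix and the duplex orientation
#' (180-degree dyad flip) becomes unidentifiable from moderate-resolution
#' density, which would make ground-truth pose recovery ill-posed.
#'
#' @param n_bp number of base pairs (>= 5).
#' @param chain_id chain identifier.
#' @param seed RNG seed (base identities).
#' @param purine_strand keep all purines on strand one (default); set
#'   FALSE for a uniformly random sequence.
#' @return A rigid [chain_model] of kind `"NA"`.
#' @export
make_na_duplex <- function(n_bp, chain_id = "C", seed = 1,
                           purine_strand = TRUE) {
  if (n_bp < 5) stop("duplex must have at least 5 base pairs")
  with_seed(seed, {
    bases <- if (purine_strand)
      sample(c("DA", "DG"), n_bp, replace = TRUE)
    else sample(c("DA", "DT", "DG", "DC"), n_bp, replace = TRUE)
    comp <- unname(c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")[bases])
    rise <- 3.4; twist <- 36 * pi / 180
    rows <- list()
    for (i in seq_len(n_bp)) {
      th <- (i - 1) * twist; z <- (i - 1) * rise
      g <- rbind(.na_atom_geom, .na_base_geom(bases[i]))
      rownames(g) <- NULL
      rows[[i]] <- data.frame(
        elety = g$elety, resno = i, resid = bases[i], elesy = g$elesy,
        x = g$r * cos(th + g$dphi), y = g$r * sin(th + g$dphi),
        z = z + g$dz, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_bp)) {
      th <- (i - 1) * twist + 140 * pi / 180; z <- (i - 1) * rise
      g <- rbind(.na_atom_geom, .na_base_geom(comp[i]))
      rownames(g) <- NULL
      rows[[n_bp + i]] <- data.frame(
        elety = g$elety, resno = 2 * n_bp - i + 1, resid = comp[i],
        elesy = g$elesy,
        x = g$r * cos(th - g$dphi), y = g$r * sin(th - g$dphi),
        z = z - g$dz, stringsAsFactors = FALSE)
    }
    chain_model(do.call(rbind, rows), chain_id = chain_id, kind = "NA",
                rigid = TRUE)
  })
}

min_interchain_distance <- function(a, b) {
  # coarse-to-fine: bounding-sphere prefilter then exact pair minimum
  ca <- colMeans(a); cb <- colMeans(b)
  ra <- sqrt(max(rowSums(sweep(a, 2, ca)^2)))
  rb <- sqrt(max(rowSums(sweep(b, 2, cb)^2)))
  gap <- sqrt(sum((ca - cb)^2)) - ra - rb
  if (gap > 0) return(gap)
  min(sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0)))
}

#' Generate a synthetic multi-chain complex
#'
#' Chains are built from the `spec` object and placed without inter-chain
#' clashes: each chain is randomly oriented and moved outward along a
#' random direction until the minimum inter-chain heavy-atom distance
#' reaches `spec$gap` (4 Angstrom by default); generation is deterministic
#' given `spec$seed`. Chains as returned sit at their ground-truth
#' placement.
#'
#' @param spec a [toy_complex_spec].
#' @return A [complex_model]; chains carry a `truth_pose` attribute
#'   (identity, since they are emitted in the map frame).
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  chains <- list()
  ids <- LETTERS
  k <- 0
  for (len in spec$protein_lengths) {
    k <- k + 1
    chains[[k]] <- make_protein_chain(len, chain_id = ids[k],
                                      segment_length = spec$segment_length,
                                      seed = spec$seed * 101 + k)
  }
  for (bp in spec$na_bp) {
    k <- k + 1
    chains[[k]] <- make_na_duplex(bp, chain_id = ids[k],
                                  seed = spec$seed * 101 + k)
  }
  if (k == 0) stop("spec contains no chains")
  with_seed(spec$seed, {
    placed <- list()
    for (i in seq_along(chains)) {
      ch <- chains[[i]]
      xyz <- coords(ch)
      xyz <- sweep(xyz, 2, colMeans(xyz))  # center on own COM
      if (i == 1) {
        ok <- TRUE
      } else {
        ok <- FALSE
        prev <- lapply(placed, coords)
        for (attempt in seq_len(1000)) {
          q <- runif(4, -1, 1)
          if (sum(q^2) < 1e-8 || sum(q^2) > 1) next
          R <- quat_to_matrix(q / sqrt(sum(q^2)))
          dv <- rnorm(3); dv <- dv / sqrt(sum(dv^2))
          rot <- xyz %*% t(R)
          r_all <- max(vapply(prev, function(p)
            sqrt(max(rowSums(p^2))), 0))  # previous chains are near origin
          r_self <- sqrt(max(rowSums(rot^2)))
          for (off in seq(2, r_all + r_self + spec$gap + 2, by = 1)) {
            cand <- sweep(rot, 2, off * dv, "+")
            dmin <- min(vapply(prev, function(p)
              min_interchain_distance(p, cand), 0))
            if (dmin >= spec$gap) { xyz <- cand; ok <- TRUE; break }
          }
          if (ok) break
        }
      }
      if (!ok) stop("layout failed after 1000 attempts; use a larger box ",
                    "or fewer chains")
      ch$atoms$x <- xyz[, 1]; ch$atoms$y <- xyz[, 2]; ch$atoms$z <- xyz[, 3]
      attr(ch, "truth_pose") <- pose_identity()
      placed[[i]] <- ch
    }
    complex_model(placed)
  })
}

#' Simulate a density map from a model
#'
#' Each heavy atom contributes an isotropic Gaussian with
#' `sigma = resolution / (pi * sqrt(2))` and amplitude proportional to its
#' atomic number; contributions are summed on the voxel lattice. The box is
#' padded at least `pad` Angstrom beyond the model extent.
#'
#' @param model a [complex_model] or [chain_model].
#' @param resolution nominal resolution, Angstrom; must be at least twice
#'   the voxel size (Nyquist).
#' @param voxel_size voxel edge, Angstrom.
#' @param pad box padding, Angstrom.
#' @param cutoff_sigma kernel truncation radius in sigmas.
#' @return A [density_map].
#' @export
simulate_map <- function(model, resolution = 5, voxel_size = 1, pad = 8,
                         cutoff_sigma = 3) {
  if (is_chain_model(model)) model <- complex_model(list(model))
  stopifnot(is_complex_model(model))
  if (resolution < 2 * voxel_size)
    stop("resolution must be at least twice the voxel size (Nyquist)")
  xyz <- coords(model)
  amp <- atomic_numbers(unlist(lapply(model$chains,
                                      function(c) c$atoms$elesy)))
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  nd <- pmax(8L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  sigma <- resolution / (pi * sqrt(2))
  g <- cpp_sim_density(xyz, amp, sigma, nd, lo, voxel_size, cutoff_sigma)
  density_map(array(g, dim = nd), voxel_size = voxel_size, origin = lo,
              resolution = resolution, contour_level = 0)
}

#' Add Gaussian noise to a map
#'
#' Independent voxel noise with standard deviation `noise_sigma` times the
#' map maximum; negative results are clipped to zero. The map's
#' `contour_level` is set to twice the noise standard deviation — the
#' analogue of the recommended contour level deposited with experimental
#' maps, below which density is treated as noise. Deterministic for a
#' given seed.
#'
#' @param map a [density_map].
#' @param noise_sigma noise level as a fraction of the map maximum (>= 0).
#' @param seed RNG seed.
#' @param contour_sigmas recommended contour level in units of the noise
#'   standard deviation.
#' @export
add_noise <- function(map, noise_sigma, seed = 1, contour_sigmas = 3) {
  stopifnot(is_density_map(map), noise_sigma >= 0)
  if (noise_sigma == 0) return(map)
  s <- noise_sigma * max(map$grid)
  if (s == 0) return(map)
  with_seed(seed, {
    map$grid <- array(pmax(0, map$grid + rnorm(length(map$grid), sd = s)),
                      dim = dim(map$grid))
  })
  map$contour_level <- contour_sigmas * s
  map
}

#' Label volumes
#'
#' Per-voxel class assignment aligned to a density-map grid: 0 = protein,
#' 1 = nucleic acid, 2 = other/background.
#'
#' @param labels 3-D integer array with values in `{0, 1, 2}`.
#' @param voxel_size,origin lattice geometry, as in [density_map].
#' @param probs optional per-class probabilities (3 x n_voxels matrix,
#'   columns summing to 1).
#' @export
label_volume <- function(labels, voxel_size, origin, probs = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3,
            all(labels %in% 0:2))
  structure(list(labels = labels, voxel_size = voxel_size,
                 origin = as.numeric(origin), probs = probs),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tb <- tabulate(as.integer(x$labels) + 1L, 3)
  cat(sprintf("<label_volume> %s voxels: %d protein, %d NA, %d other\n",
              paste(dim(x$labels), collapse = " x "), tb[1], tb[2], tb[3]))
  invisible(x)
}

#' Ground-truth voxel labels for a synthetic complex
#'
#' Voxels within `radius` of a backbone atom are labeled by the molecule
#' class of the nearest such atom (protein = 0, NA = 1); all remaining
#' voxels are 2. Backbone atoms are N, CA, C, O for protein and P, O5',
#' C5', C4', C3', O3' for NA.
#'
#' @param model a [complex_model] in the map frame.
#' @param map the [density_map] defining the lattice.
#' @param radius proximity radius, Angstrom (default 3).
#' @return A [label_volume].
#' @export
ground_truth_labels <- function(model, map, radius = 3) {
  stopifnot(is_complex_model(model), is_density_map(map))
  pc <- list(); nc <- list()
  for (ch in model$chains) {
    bb <- if (ch$kind == "protein") .prot_backbone else .na_backbone
    sel <- ch$atoms$elety %in% bb
    m <- as.matrix(ch$atoms[sel, c("x", "y", "z")])
    if (ch$kind == "protein") pc[[length(pc) + 1]] <- m
    else nc[[length(nc) + 1]] <- m
  }
  none <- matrix(0, 0, 3)
  lab <- cpp_labels_nearest(dim(map$grid), map$origin, map$voxel_size,
                            if (length(pc)) do.call(rbind, pc) else none,
                            if (length(nc)) do.call(rbind, nc) else none,
                            radius)
  label_volume(array(lab, dim = dim(map$grid)), map$voxel_size, map$origin)
}
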
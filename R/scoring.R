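# Model-to-map and model-to-model quality measures. The map-correlation
# scores all compare the experimental map against a density simulated from
# the model with the same Gaussian kernel used by simulate_map(), over the
# support where either map is nonzero (scoring empty space would reward
# agreement about nothing).

# Build the C++ scoring context for a fixed atom set against a fixed map.
# Atoms must be ordered with residues contiguous; residue indices are
# assigned per (chain, resno) group in order of appearance.
new_score_ctx <- function(map, atoms, resolution = NULL, loc_radius = 3,
                          frag_half = 4L, cutoff_sigma = 3,
                          coarse_n = 32L, band = NULL, support_eps = 1e-6) {
  stopifnot(is_density_map(map))
  res <- if (is.null(resolution)) map$resolution else resolution
  if (is.null(band)) band <- c(0.1, 1 / res)
  amp <- atomic_numbers(atoms$elesy)
  key <- paste(atoms$chain_key, atoms$resno)
  res_idx <- as.integer(factor(key, levels = unique(key))) - 1L
  ptr <- cpp_score_ctx(as.numeric(map$grid), dim(map$grid), map$origin,
                       map$voxel_size, res, amp, res_idx, loc_radius,
                       frag_half, cutoff_sigma, coarse_n, band[1], band[2],
                       support_eps)
  list(ptr = ptr, n_atoms = nrow(atoms), n_res = length(unique(key)),
       res_keys = unique(key))
}

# atom table of a model with a chain_key column (for residue grouping)
model_atoms <- function(model) {
  if (is_chain_model(model)) model <- complex_model(list(model))
  do.call(rbind, lapply(model$chains, function(ch) {
    at <- ch$atoms
    at$chain_key <- ch$chain_id
    at
  }))
}

score_eval <- function(ctx, xyz, weights = c(1, 1, 1) / 3, loc_stride = 1L,
                       per_residue = FALSE) {
  cpp_score_eval(ctx$ptr, xyz, weights, as.integer(loc_stride), per_residue)
}

#' Global model-to-map correlation
#'
#' Pearson correlation between the experimental map and a density simulated
#' from the model on the same lattice, over voxels where either map exceeds
#' a small support threshold.
#'
#' @param model a [chain_model] or [complex_model] in the map frame.
#' @param map a [density_map].
#' @param resolution kernel resolution for the simulated density (defaults
#'   to the map's nominal resolution).
#' @return Correlation in \[-1, 1\]; 0 (with a warning) for a
#'   zero-variance support region.
#' @export
global_cc <- function(model, map, resolution = NULL) {
  at <- model_atoms(model)
  ctx <- new_score_ctx(map, at, resolution = resolution)
  v <- score_eval(ctx, as.matrix(at[, c("x", "y", "z")]),
                  weights = c(1, 0, 0))$global_cc
  if (v == 0) warning("zero-variance support region: CC = 0")
  v
}

#' Per-residue local correlation
#'
#' For each residue the correlation is computed over voxels within
#' `loc_radius` of the atoms of a nine-residue fragment centered at the
#' residue (clipped at chain ends). This is the per-residue CC reported in
#' fit summaries.
#'
#' @param chain a [chain_model] (or [complex_model]).
#' @param map a [density_map].
#' @param loc_radius support radius around fragment atoms, Angstrom.
#' @param frag_half half-width of the fragment window (4 gives nine
#'   residues).
#' @return Data frame with `chain`, `resno` and `cc`.
#' @export
local_cc <- function(chain, map, loc_radius = 3, frag_half = 4L) {
  at <- model_atoms(chain)
  ctx <- new_score_ctx(map, at, loc_radius = loc_radius,
                       frag_half = frag_half)
  r <- score_eval(ctx, as.matrix(at[, c("x", "y", "z")]),
                  weights = c(0, 1, 0), per_residue = TRUE)
  keys <- strsplit(ctx$res_keys, " ")
  data.frame(chain = vapply(keys, `[`, "", 1),
             resno = as.integer(vapply(keys, `[`, "", 2)),
             cc = r$per_residue_cc, stringsAsFactors = FALSE)
}

#' Fourier shell correlation between two maps
#'
#' Normalized cross-correlation of Fourier coefficients in concentric
#' shells of one frequency-voxel width, from DC to Nyquist.
#'
#' @param map_a,map_b [density_map]s on identical lattices.
#' @return Data frame with `freq` (1/Angstrom), `fsc` and `n` (voxels per
#'   shell).
#' @export
fsc_curve <- function(map_a, map_b) {
  stopifnot(is_density_map(map_a), is_density_map(map_b))
  if (!identical(dim(map_a$grid), dim(map_b$grid)) ||
      abs(map_a$voxel_size - map_b$voxel_size) > 1e-9)
    stop("maps must share grid shape and voxel size")
  d <- dim(map_a$grid)
  Fa <- fft(map_a$grid); Fb <- fft(map_b$grid)
  fr <- function(n) {
    k <- 0:(n - 1)
    ifelse(k <= n / 2, k, k - n) / (n * map_a$voxel_size)
  }
  fx <- fr(d[1]); fy <- fr(d[2]); fz <- fr(d[3])
  rad <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
  df <- 1 / (max(d) * map_a$voxel_size)
  shell <- as.integer(round(rad / df))
  nyq <- 1 / (2 * map_a$voxel_size)
  ns <- floor(nyq / df)
  keep <- shell <= ns
  num <- Re(Fa * Conj(Fb))
  pa <- Mod(Fa)^2; pb <- Mod(Fb)^2
  s <- shell[keep] + 1L
  sn <- tabulate(s, ns + 1L)
  snum <- as.numeric(rowsum(num[keep], s))
  spa <- as.numeric(rowsum(pa[keep], s))
  spb <- as.numeric(rowsum(pb[keep], s))
  den <- sqrt(spa * spb)
  data.frame(freq = (0:ns) * df,
             fsc = ifelse(den > 0, snum / den, 0),
             n = sn)
}

#' Integrated Fourier shell correlation
#'
#' Trapezoidal mean of an FSC curve over a frequency band; the default band
#' runs from 1/10 to 1/resolution inverse Angstrom.
#'
#' @param curve output of [fsc_curve()].
#' @param freq_min,freq_max band limits in 1/Angstrom.
#' @return Dimensionless iFSC.
#' @export
integrated_fsc <- function(curve, freq_min = 0.1, freq_max = 0.2) {
  if (freq_min >= freq_max) stop("empty frequency band")
  sel <- curve$freq >= freq_min - 1e-12 & curve$freq <= freq_max + 1e-12
  if (!any(sel)) stop("no FSC shells inside the band [", freq_min, ", ",
                      freq_max, "]")
  f <- curve$freq[sel]; y <- curve$fsc[sel]
  if (length(f) == 1) return(y)
  sum(diff(f) * (head(y, -1) + y[-1]) / 2) / (max(f) - min(f))
}

#' Composite model-to-map fitting score
#'
#' Normalized weighted sum of the global CC, the mean local (nine-residue
#' window) CC, and the integrated FSC between the simulated and
#' experimental density. This is the objective maximized by the rigid-body
#' pose optimizer. The FSC term is evaluated on a fixed 32^3 coarse lattice
#' covering the map box (documented numerical choice; keeps each
#' evaluation cheap enough for multi-start optimization).
#'
#' @param chain a [chain_model] (or [complex_model]) in the map frame.
#' @param map a [density_map].
#' @param weights nonnegative weights for (global CC, mean local CC, iFSC);
#'   normalized to sum to one. Default equal weights.
#' @return Composite score (scalar) with the three components attached as
#'   the `"components"` attribute.
#' @export
composite_fit_score <- function(chain, map, weights = c(1, 1, 1) / 3) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  at <- model_atoms(chain)
  ctx <- new_score_ctx(map, at)
  r <- score_eval(ctx, as.matrix(at[, c("x", "y", "z")]), weights = weights)
  structure(r$composite,
            components = c(global_cc = r$global_cc,
                           mean_local_cc = r$mean_local_cc, ifsc = r$ifsc))
}

#' Steric clash score
#'
#' Number of inter-unit heavy-atom pairs closer than `cutoff`, divided by
#' the total heavy-atom count (a per-atom clash rate). Units are chains;
#' computed with a cell list so the cost is near-linear in atom count.
#'
#' @param model a [complex_model].
#' @param cutoff clash distance, Angstrom (default 3).
#' @return Nonnegative clash rate; 0 for a single-chain complex.
#' @export
clash_score <- function(model, cutoff = 3) {
  stopifnot(is_complex_model(model), cutoff > 0)
  if (length(model$chains) < 2) return(0)
  xyz <- coords(model)
  unit <- rep(seq_along(model$chains),
              vapply(model$chains, function(c) nrow(c$atoms), 0L))
  cpp_clash_pairs(xyz, unit, cutoff) / nrow(xyz)
}

#' RMSD with optional Kabsch superposition
#'
#' @param a,b matched n x 3 coordinate matrices.
#' @param superpose apply the optimal least-squares rotation/translation
#'   (with reflection guard) before computing the deviation.
#' @return RMSD in Angstrom.
#' @export
rmsd_kabsch <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  if (nrow(a) < 3 && superpose)
    warning("fewer than 3 points: superposition may be degenerate")
  if (superpose) {
    fit <- kabsch_fit(a, b)
    a <- fit$transformed
  }
  sqrt(mean(rowSums((a - b)^2)))
}

# optimal rigid transform mapping a onto b (least squares, no reflection)
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(a0) %*% b0
  s <- svd(H)
  if (s$d[2] < 1e-10) warning("degenerate (rank < 2) point set")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, transformed = sweep(a0 %*% R, 2, cb, "+"),
       center_a = ca, center_b = cb)
}

# matched representative-atom coordinates (CA / C3') of two complexes
tm_correspondence <- function(model, reference) {
  rep_atoms <- function(m) {
    do.call(rbind, lapply(m$chains, function(ch) {
      nm <- if (ch$kind == "protein") "CA" else "C3'"
      at <- ch$atoms[ch$atoms$elety == nm, , drop = FALSE]
      if (nrow(at) == 0) return(NULL)
      data.frame(key = paste(ch$chain_id, at$resno), x = at$x, y = at$y,
                 z = at$z, stringsAsFactors = FALSE)
    }))
  }
  am <- rep_atoms(model); ar <- rep_atoms(reference)
  common <- intersect(am$key, ar$key)
  if (length(common) == 0) stop("no common residues between model and reference")
  list(model = as.matrix(am[match(common, am$key), c("x", "y", "z")]),
       reference = as.matrix(ar[match(common, ar$key), c("x", "y", "z")]),
       L_ref = nrow(ar))
}

tm_d0 <- function(L) max(0.5, 1.24 * (max(L, 16) - 15)^(1 / 3) - 1.8)

# TM-score of pre-matched coordinate sets given a seed subset: iterative
# superposition on the close-residue subset until stable
tm_iterate <- function(xm, xr, seed_idx, d0, L_norm, max_iter = 20) {
  idx <- seed_idx
  best <- 0
  for (it in seq_len(max_iter)) {
    if (length(idx) < 3) break
    fit <- kabsch_fit(xm[idx, , drop = FALSE], xr[idx, , drop = FALSE])
    moved <- sweep(sweep(xm, 2, fit$center_a) %*% fit$R, 2, fit$center_b, "+")
    d <- sqrt(rowSums((moved - xr)^2))
    best <- max(best, sum(1 / (1 + (d / d0)^2)) / L_norm)
    cut <- d0
    new_idx <- which(d < cut)
    while (length(new_idx) < 3 && cut < max(d)) {
      cut <- cut + 0.5
      new_idx <- which(d < cut)
    }
    if (identical(new_idx, idx)) break
    idx <- new_idx
  }
  best
}

#' TM-score between two complexes
#'
#' Length-normalized topological similarity in (0, 1\]. Residues are
#' matched by chain id and residue number; representative atoms are CA for
#' protein and C3' for NA. The score is maximized over superpositions by
#' iterative fragment-seeded superposition with
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5), normalized by the
#' reference length.
#'
#' @param model,reference [complex_model]s (or [chain_model]s) with a
#'   shared residue numbering.
#' @param seed_lengths fragment seed lengths tried during the search;
#'   `NULL` picks a standard ladder.
#' @return TM-score in (0, 1\].
#' @export
tm_score <- function(model, reference, seed_lengths = NULL) {
  if (is_chain_model(model)) model <- complex_model(list(model))
  if (is_chain_model(reference)) reference <- complex_model(list(reference))
  mc <- tm_correspondence(model, reference)
  n <- nrow(mc$model)
  d0 <- tm_d0(mc$L_ref)
  if (is.null(seed_lengths))
    seed_lengths <- unique(pmax(4, c(n, floor(n / 2), floor(n / 4), 8)))
  best <- 0
  for (w in seed_lengths) {
    if (w > n) w <- n
    starts <- unique(c(seq(1, n - w + 1, by = max(1, floor(w / 2))), n - w + 1))
    for (s in starts) {
      idx <- s:(s + w - 1)
      best <- max(best, tm_iterate(mc$model, mc$reference, idx, d0, mc$L_ref))
    }
  }
  best
}
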
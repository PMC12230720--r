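# Rigid-body fitting of single chains into (segmented) maps: multi-start
# pose enumeration, L-BFGS refinement of the composite score, top-5
# candidate retention, and the iterative longest-first fitting loop with
# map masking and a decaying acceptance threshold.

#' Iterative fitting schedule
#'
#' A chain is considered well fitted when its global CC exceeds the current
#' threshold; the threshold starts at `threshold_init` (0.6) and decreases
#' by `threshold_step` each round down to `threshold_floor`.
#'
#' @param threshold_init initial acceptance threshold (0.6).
#' @param threshold_step per-round decrement.
#' @param threshold_floor minimum threshold.
#' @param max_rounds maximum number of fitting rounds.
#' @export
fit_schedule <- function(threshold_init = 0.6, threshold_step = 0.1,
                         threshold_floor = 0.3, max_rounds = 4) {
  stopifnot(threshold_floor <= threshold_init, threshold_step > 0)
  structure(list(threshold_init = threshold_init,
                 threshold_step = threshold_step,
                 threshold_floor = threshold_floor,
                 max_rounds = as.integer(max_rounds)),
            class = "fit_schedule")
}

# deduplicated rotation lattice: z-y-z Euler angles at `step` degrees
# (beta spans the closed interval [0, 180], where the lattice is highly
# degenerate); duplicate rotations (quaternion double cover handled)
# are removed
rotation_seeds <- function(step = 45, dedup_deg = 0.1) {
  alphas <- seq(0, 360 - step, by = step)
  betas <- seq(0, 180, by = step)
  qs <- list()
  for (b in betas) for (a in alphas) for (g in alphas) {
    q <- pose_from_euler(a, b, g)$q
    dup <- FALSE
    for (p in qs) {
      d <- abs(sum(p * q))
      if (2 * acos(min(1, d)) * 180 / pi < dedup_deg) { dup <- TRUE; break }
    }
    if (!dup) qs[[length(qs) + 1]] <- q
  }
  qs
}

# cache the default lattices (deduplication is O(n^2) and pure)
.rot_cache <- new.env(parent = emptyenv())
rotation_seeds_cached <- function(step) {
  key <- as.character(step)
  if (is.null(.rot_cache[[key]])) .rot_cache[[key]] <- rotation_seeds(step)
  .rot_cache[[key]]
}

#' Enumerate initial poses for a chain in a map
#'
#' Translation seeds: the density centroid of the map, plus, when the map
#' radius of gyration exceeds the model's by more than 5% (the chain then
#' occupies a sub-region), local maxima of smoothed copies of the map at
#' several model-tied scales (Rg, Rg/2, Rg/4 with a 3 Angstrom floor;
#' peaks closer than Rg/2 merged; up to `max_centers` auxiliary seeds).
#' Rotation seeds: the deduplicated z-y-z Euler lattice at
#' `angular_step`. The Cartesian product is capped at `max_poses` by a
#' composite-score prescreen.
#'
#' @param chain a [chain_model].
#' @param map a [density_map] with nonzero voxels.
#' @param angular_step Euler lattice step, degrees (default 45).
#' @param max_poses cap on returned poses (default 512).
#' @param max_centers maximum auxiliary translation seeds.
#' @param weights composite-score weights for the prescreen.
#' @return List of [pose]s (ordered by prescreen score when capped).
#' @export
init_poses <- function(chain, map, angular_step = 45, max_poses = 512,
                       max_centers = 8, weights = c(1, 1, 1) / 3) {
  stopifnot(is_chain_model(chain), is_density_map(map))
  xyz <- coords(chain)
  com <- colMeans(xyz)
  chain_rg <- radius_of_gyration(xyz)
  map_rg <- map_radius_of_gyration(map)
  centers <- list(map_centroid(map))
  if (map_rg > 1.05 * chain_rg) {
    # peaks of the smoothed map at several model-tied scales: chain-scale
    # smoothing (Rg) marks whole-molecule blobs but can merge adjacent
    # chains; sub-chain scales (Rg/2, Rg/4, floor 3 A) keep adjacent blobs
    # separate but can fragment one chain into segments -- the union
    # covers both regimes
    for (scale in unique(pmax(3, chain_rg / c(1, 2, 4)))) {
      sm <- cpp_smooth_gaussian(as.numeric(map$grid), dim(map$grid),
                                scale / map$voxel_size)
      pk <- cpp_local_maxima(sm, dim(map$grid),
                             (chain_rg / 2) / map$voxel_size, max_centers)
      if (nrow(pk) > 0)
        for (r in seq_len(nrow(pk)))
          centers[[length(centers) + 1]] <-
            map$origin + pk[r, 1:3] * map$voxel_size
    }
  }
  # drop near-duplicate centers; cap at max_centers auxiliary seeds
  uniq <- list(centers[[1]])
  for (cen in centers[-1]) {
    if (length(uniq) > max_centers) break
    if (all(vapply(uniq, function(u) sqrt(sum((u - cen)^2)), 0) >
            chain_rg / 2))
      uniq[[length(uniq) + 1]] <- cen
  }
  rots <- rotation_seeds_cached(angular_step)
  poses <- list()
  for (cen in uniq) for (q in rots)
    poses[[length(poses) + 1]] <- pose(q, cen - com)
  if (length(poses) > max_poses) {
    at <- model_atoms(chain)
    ctx <- new_score_ctx(map, at)
    R0 <- xyz
    sc <- vapply(poses, function(p) {
      R <- quat_to_matrix(p$q)
      newxyz <- sweep(sweep(R0, 2, com) %*% t(R), 2, com + p$t, "+")
      score_eval(ctx, newxyz, weights, loc_stride = 3L)$composite
    }, 0)
    poses <- poses[order(sc, decreasing = TRUE)[seq_len(max_poses)]]
  }
  poses
}

# transform chain coordinates by a pose about a fixed center
pose_coords <- function(xyz, p, center) {
  R <- quat_to_matrix(p$q)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + p$t, "+")
}

# central-difference gradient steps for the 6-parameter pose chart
.fd_steps <- c(rep(0.25, 3), rep(1 * pi / 180, 3))
# wider steps for the smoothed-map coarse stage
.fd_steps_coarse <- c(rep(1, 3), rep(4 * pi / 180, 3))

# core L-BFGS refinement against a prebuilt scoring context. Gradients
# default to central differences: one-sided differences pick up a pure
# curvature bias near a rotation optimum that stalls the line search.
# The coarse stage runs with a loose convergence factor (it only ranks
# basins); the full stage converges at |delta f| ~ 1e-5
refine_pose_ctx <- function(ctx, xyz, com, start, weights, maxit,
                            loc_stride = 3L, factr = 4.5e10,
                            fd = c("central", "forward"),
                            steps = .fd_steps) {
  fd <- match.arg(fd)
  .fd_steps <- steps
  # fast chart application (avoids per-evaluation pose construction)
  xyz0 <- sweep(xyz, 2, com)
  base_q <- start$q
  base_t <- com + start$t
  fn <- function(par) {
    ang <- sqrt(sum(par[4:6]^2))
    qd <- if (ang < 1e-15) base_q
    else quat_multiply(c(cos(ang / 2), sin(ang / 2) * par[4:6] / ang),
                       base_q)
    cand <- sweep(xyz0 %*% t(quat_to_matrix(qd)), 2, base_t + par[1:3], "+")
    -score_eval(ctx, cand, weights, loc_stride = loc_stride)$composite
  }
  gr <- if (fd == "central") function(par) {
    g <- numeric(6)
    for (i in 1:6) {
      e <- numeric(6); e[i] <- .fd_steps[i]
      g[i] <- (fn(par + e) - fn(par - e)) / (2 * .fd_steps[i])
    }
    g
  } else function(par) {
    fb <- fn(par)
    g <- numeric(6)
    for (i in 1:6) {
      e <- numeric(6); e[i] <- .fd_steps[i]
      g[i] <- (fn(par + e) - fb) / .fd_steps[i]
    }
    g
  }
  f0 <- fn(numeric(6))
  if (!is.finite(f0))
    return(list(pose = start, value = -Inf, converged = FALSE))
  opt <- tryCatch(
    optim(numeric(6), fn, gr, method = "L-BFGS-B",
          control = list(maxit = maxit, factr = factr)),
    error = function(e) list(par = numeric(6), value = f0, convergence = 1L))
  if (!is.finite(opt$value) || opt$value > f0) {
    # ascent guard: never return a pose worse than the start
    return(list(pose = start, value = -f0, converged = FALSE))
  }
  list(pose = pose_from_chart(opt$par, start), value = -opt$value,
       converged = opt$convergence == 0L)
}

fit_candidate <- function(pose, full, converged) {
  list(pose = pose, composite = full$composite, global_cc = full$global_cc,
       mean_local_cc = full$mean_local_cc, ifsc = full$ifsc,
       converged = converged)
}

#' Refine one pose by rigid-body L-BFGS
#'
#' Local maximization of the composite fitting score over the 6-parameter
#' pose chart (3 translations, 3 axis-angle rotations about the start
#' orientation), with central finite-difference gradients (steps 0.25
#' Angstrom / 1 degree). The returned candidate never scores below the
#' start pose. During optimization the local-CC term is evaluated on every
#' third sliding window (a quadrature choice; the final reported scores use
#' all windows).
#'
#' @param chain a [chain_model].
#' @param map a [density_map].
#' @param start starting [pose].
#' @param weights composite-score weights.
#' @param maxit L-BFGS iteration cap (default 200; convergence is usually
#'   much earlier at |delta score| < 1e-5).
#' @return A fit candidate: `pose`, `composite`, `global_cc`,
#'   `mean_local_cc`, `ifsc`, `converged`.
#' @export
refine_pose_lbfgs <- function(chain, map, start, weights = c(1, 1, 1) / 3,
                              maxit = 200) {
  at <- model_atoms(chain)
  ctx <- new_score_ctx(map, at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  com <- colMeans(xyz)
  r <- refine_pose_ctx(ctx, xyz, com, start, weights, maxit)
  full <- score_eval(ctx, pose_coords(xyz, r$pose, com), weights)
  fit_candidate(r$pose, full, r$converged)
}

# low-pass-filtered copy of a map for the coarse search stage: extra
# Gaussian blur to the requested effective resolution, resampled to (at
# least) a 2 Angstrom lattice
coarse_search_map <- function(map, res_search, coarse_voxel = 2) {
  if (res_search <= map$resolution) {
    cm <- map
  } else {
    sig_map <- map$resolution / (pi * sqrt(2))
    sig_eff <- res_search / (pi * sqrt(2))
    sig_add <- sqrt(sig_eff^2 - sig_map^2)
    cm <- map
    cm$grid <- array(cpp_smooth_gaussian(as.numeric(map$grid), dim(map$grid),
                                         sig_add / map$voxel_size),
                     dim = dim(map$grid))
    cm$resolution <- res_search
  }
  if (cm$voxel_size < coarse_voxel) cm <- resample_map(cm, coarse_voxel)
  cm
}

# one representative atom per residue (CA for protein, P/C4' for NA) for
# cheap coarse-stage scoring
coarse_atoms <- function(at) {
  pref <- c("CA", "P", "C4'", "C1'")
  keep <- unlist(lapply(split(seq_len(nrow(at)),
                              factor(paste(at$chain_key, at$resno),
                                     levels = unique(paste(at$chain_key,
                                                           at$resno)))),
                        function(rows) {
    m <- match(pref, at$elety[rows])
    rows[if (any(!is.na(m))) m[!is.na(m)][1] else 1]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

# poses within (shift_tol, angle_tol) of an already-kept candidate merge
dedup_candidates <- function(cands, shift_tol = 2, angle_tol = 10) {
  keep <- list()
  for (cd in cands) {
    dup <- FALSE
    for (k in keep) {
      d <- pose_distance(cd$pose, k$pose)
      if (d["shift"] < shift_tol && d["angle"] < angle_tol) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1]] <- cd
  }
  keep
}

#' Fit one chain into a map
#'
#' Hierarchical multi-start search:
#' all enumerated starts are screened against a low-pass-filtered copy of
#' the map, the best `screen_keep` get a coarse L-BFGS polish there, and
#' the most promising `n_full` (ranked by the native-resolution composite)
#' are fully refined. Near-duplicate poses (within 2 Angstrom / 10
#' degrees) are merged and the top `keep` candidates by composite score
#' are returned, sorted.
#'
#' @param chain a [chain_model].
#' @param map the [density_map] appropriate to the chain's kind.
#' @param angular_step Euler lattice step for [init_poses()].
#' @param weights composite-score weights.
#' @param keep candidates retained (default 5).
#' @param n_full starts given full refinement.
#' @param short_maxit,full_maxit iteration caps for the two stages.
#' @param max_poses cap on initial poses.
#' @param screen_keep starts surviving the coarse-map prescreen into the
#'   coarse refinement stage.
#' @param res_search effective resolution (Angstrom) of the low-pass
#'   filtered map used by the coarse search stage; defaults to three times
#'   the map resolution (at least 12 Angstrom).
#' @return A `fit_result`: `chain_id`, sorted `candidates` (each as in
#'   [refine_pose_lbfgs()]), and the input `chain`.
#' @export
fit_chain <- function(chain, map, angular_step = 45, weights = c(1, 1, 1) / 3,
                      keep = 5, n_full = 8, short_maxit = 10,
                      full_maxit = 40, max_poses = 4096, screen_keep = 128,
                      res_search = NULL) {
  if (is.null(res_search)) res_search <- max(3 * map$resolution, 12)
  at <- model_atoms(chain)
  ctx <- new_score_ctx(map, at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  com <- colMeans(xyz)
  starts <- init_poses(chain, map, angular_step = angular_step,
                       max_poses = max_poses, weights = weights)
  # coarse stage: the native-resolution correlation basin is only a few
  # degrees / Angstrom wide, far narrower than the enumeration lattice, so
  # the multi-start search runs against a low-pass-filtered copy of the map
  # (effective resolution >= 3x nominal) on a 2 Angstrom lattice, scored
  # with one representative atom per residue; survivors are then refined at
  # native resolution with the full composite.
  cmap <- coarse_search_map(map, res_search)
  cat_ <- coarse_atoms(at)
  cctx <- new_score_ctx(cmap, cat_, cutoff_sigma = 2.5)
  cxyz <- as.matrix(cat_[, c("x", "y", "z")])
  # multi-site maps (several translation seeds) get a wider, deeper coarse
  # stage: the search space grows with the number of candidate sites
  n_seeds <- nrow(unique(round(t(vapply(starts, function(p) p$t,
                                        numeric(3))), 3)))
  if (n_seeds > 1) {
    screen_keep <- min(768, max(screen_keep, 96 * n_seeds))
    short_maxit <- short_maxit + 4
    n_full <- max(n_full, 16)
  }
  pre <- vapply(starts, function(p)
    score_eval(cctx, pose_coords(cxyz, p, com), c(1, 0, 0))$global_cc, 0)
  starts <- starts[order(pre, decreasing = TRUE)]
  starts <- starts[seq_len(min(screen_keep, length(starts)))]
  # central differences: near a rotation optimum, forward differences pick
  # up a curvature bias that poisons the search direction and stalls the
  # line search
  short <- lapply(starts, function(p)
    refine_pose_ctx(cctx, cxyz, com, p, c(1, 0, 0), maxit = short_maxit,
                    factr = 1e12, fd = "central", steps = .fd_steps_coarse))
  rank_comp <- vapply(short, function(s)
    score_eval(ctx, pose_coords(xyz, s$pose, com), weights,
               loc_stride = 3L)$composite, 0)
  ord <- order(rank_comp, decreasing = TRUE)
  # full-refinement starts: best-ranked first, but enforcing pose
  # diversity (>= 4 Angstrom or 15 degrees apart) so every distinct
  # density site keeps at least one fully refined candidate
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= n_full) break
    distinct <- all(vapply(chosen, function(j) {
      d <- pose_distance(short[[i]]$pose, short[[j]]$pose)
      d["shift"] >= 4 || d["angle"] >= 15
    }, TRUE))
    if (distinct) chosen <- c(chosen, i)
  }
  for (i in ord) {
    if (length(chosen) >= n_full) break
    if (!(i %in% chosen)) chosen <- c(chosen, i)
  }
  # native-resolution refinement in two phases: a moderate polish of every
  # chosen start, then the full budget for the best three polished poses
  # (re-ranking after the polish is what makes the winner reliable)
  refined <- lapply(chosen, function(i)
    refine_pose_ctx(ctx, xyz, com, short[[i]]$pose, weights,
                    maxit = min(full_maxit, 15)))
  ord2 <- order(vapply(refined, function(r) r$value, 0), decreasing = TRUE)
  for (k in ord2[seq_len(min(3, length(ord2)))]) {
    refined[[k]] <- refine_pose_ctx(ctx, xyz, com, refined[[k]]$pose,
                                    weights, maxit = full_maxit)
  }
  # pool with the remaining coarse-stage poses so distinct basins survive
  for (i in setdiff(ord, chosen)) {
    s <- short[[i]]
    s$value <- rank_comp[i]
    refined[[length(refined) + 1]] <- s
  }
  refined <- refined[order(vapply(refined, function(r) r$value, 0),
                           decreasing = TRUE)]
  refined <- dedup_candidates(refined)
  refined <- refined[seq_len(min(keep, length(refined)))]
  cands <- lapply(refined, function(r) {
    full <- score_eval(ctx, pose_coords(xyz, r$pose, com), weights)
    fit_candidate(r$pose, full, isTRUE(r$converged))
  })
  cands <- cands[order(vapply(cands, function(c) c$composite, 0),
                       decreasing = TRUE)]
  if (length(cands) == 0 ||
      !any(is.finite(vapply(cands, function(c) c$composite, 0))))
    stop("fit failure: no candidate with a finite score for chain ",
         chain$chain_id)
  structure(list(chain_id = chain$chain_id, candidates = cands,
                 chain = chain), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chain %s: %d candidates, best composite %.3f (CC %.3f)\n",
              x$chain_id, length(x$candidates), x$candidates[[1]]$composite,
              x$candidates[[1]]$global_cc))
  invisible(x)
}

#' Fit all chains iteratively with map masking
#'
#' Chains are processed in descending residue-count order against the
#' segmented map matching their kind. After each chain whose best global CC
#' reaches the current threshold, its map region is masked (density set to
#' zero within `mask_radius` of its fitted atoms) before later chains are
#' fitted. Chains below threshold are retried in later rounds with the
#' threshold lowered per the schedule; every chain ends with a fit result,
#' flagged low-confidence when it never reached the floor.
#'
#' @param chains list of [chain_model]s.
#' @param protein_map,na_map segmented [density_map]s from [split_map()].
#' @param schedule a [fit_schedule].
#' @param mask_radius masking radius, Angstrom.
#' @param mask (logical) disable to skip masking (ablation).
#' @param ... passed to [fit_chain()].
#' @return Named list of fit results; each carries `placed`,
#'   `round_placed` and `low_confidence` fields.
#' @export
iterative_fit_all <- function(chains, protein_map, na_map,
                              schedule = fit_schedule(), mask_radius = 3,
                              mask = TRUE, ...) {
  stopifnot(all(vapply(chains, is_chain_model, TRUE)))
  lens <- vapply(chains, n_residues, 0L)
  ord <- order(lens, decreasing = TRUE)
  chains <- chains[ord]
  maps <- list(protein = protein_map, "NA" = na_map)
  results <- list()
  pending <- seq_along(chains)
  for (round in seq_len(schedule$max_rounds)) {
    thr <- max(schedule$threshold_floor,
               schedule$threshold_init - (round - 1) * schedule$threshold_step)
    still <- integer(0)
    for (i in pending) {
      ch <- chains[[i]]
      mk <- if (ch$kind == "protein") "protein" else "NA"
      fit <- fit_chain(ch, maps[[mk]], ...)
      fit$round <- round
      if (fit$candidates[[1]]$global_cc >= thr) {
        fit$placed <- TRUE
        fit$round_placed <- round
        fit$low_confidence <- FALSE
        if (mask) {
          placed_chain <- apply_pose(ch, fit$candidates[[1]]$pose)
          maps[[mk]] <- mask_region(maps[[mk]], coords(placed_chain),
                                    radius = mask_radius)
        }
      } else {
        fit$placed <- FALSE
        fit$low_confidence <- TRUE
        still <- c(still, i)
      }
      results[[ch$chain_id]] <- fit
    }
    pending <- still
    if (length(pending) == 0) break
    if (thr <= schedule$threshold_floor) break
  }
  results
}

# linker continuity: largest CA-CA (or backbone) gap across each domain
# boundary after moving domains
max_linker_gap <- function(atoms, segments) {
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  gaps <- numeric(0)
  seg <- segments[order(segments$start), ]
  for (i in seq_len(nrow(seg) - 1)) {
    a <- ca[ca$resno == seg$end[i], c("x", "y", "z")]
    b <- ca[ca$resno == seg$start[i + 1], c("x", "y", "z")]
    if (nrow(a) && nrow(b))
      gaps <- c(gaps, sqrt(sum((as.numeric(a[1, ]) - as.numeric(b[1, ]))^2)))
  }
  if (length(gaps)) max(gaps) else 0
}

#' Domain-level flexible refinement of a rigidly fitted protein chain
#'
#' Starting from the rigid-body pose, each domain gets an independent 6-DOF
#' L-BFGS refinement of the whole-chain composite score. A domain's move is
#' accepted only when the composite improves and every inter-domain linker
#' CA-CA gap stays below `max_gap`; otherwise the rigid placement is kept
#' (refusing to move is a valid outcome). NA chains are rigid by contract
#' and must not be passed here.
#'
#' @param chain a protein [chain_model] (with or without a precomputed
#'   domain partition; domains are parsed automatically otherwise).
#' @param map the [density_map] the chain was fitted into.
#' @param pose the rigid-fit [pose].
#' @param weights composite-score weights.
#' @param max_gap linker gap limit, Angstrom (default 8).
#' @param maxit per-domain L-BFGS iteration cap.
#' @return The placed [chain_model] with refined domain coordinates; the
#'   accepted per-domain poses and the final composite are attached as
#'   attributes `domain_poses` and `composite`.
#' @export
domain_refine <- function(chain, map, pose, weights = c(1, 1, 1) / 3,
                          max_gap = 8, maxit = 40) {
  stopifnot(is_chain_model(chain))
  if (chain$kind != "protein")
    stop("domain refinement applies to protein chains only (NA is rigid)")
  placed <- apply_pose(chain, pose)
  segments <- if (!is.null(chain$domains)) chain$domains
  else partition_domains(chain)
  placed$domains <- segments
  at <- model_atoms(placed)
  ctx <- new_score_ctx(map, at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  base <- score_eval(ctx, xyz, weights)
  best_score <- base$composite
  domain_poses <- list()
  if (nrow(segments) > 1) {
    # a misoriented domain can sit far outside the native-resolution score
    # basin, so each domain is first pulled in against the low-pass
    # filtered map, then polished at native resolution
    cmap <- coarse_search_map(map, max(3 * map$resolution, 12))
    cctx <- new_score_ctx(cmap, at)
    for (d in seq_len(nrow(segments))) {
      sel <- at$resno >= segments$start[d] & at$resno <= segments$end[d]
      # rotate about the hinge (the CA where the domain meets its
      # neighbor), so a pure hinge-bend error needs no compensating
      # translation
      hinge_res <- if (d > 1) segments$start[d] else segments$end[d]
      hinge_ca <- xyz[at$resno == hinge_res & at$elety == "CA", , drop = FALSE]
      dcom <- if (nrow(hinge_ca) > 0) as.numeric(hinge_ca[1, ])
      else colMeans(xyz[sel, , drop = FALSE])
      obj <- function(par, use_ctx, stride, w = weights) {
        p <- pose_from_chart(par, pose_identity())
        cand <- xyz
        cand[sel, ] <- pose_coords(xyz[sel, , drop = FALSE], p, dcom)
        -score_eval(use_ctx, cand, w, loc_stride = stride)$composite
      }
      fn_c <- function(par) obj(par, cctx, 4L, w = c(1, 0, 0))
      gr_c <- function(par) {
        g <- numeric(6)
        for (i in 1:6) {
          e <- numeric(6); e[i] <- .fd_steps_coarse[i]
          g[i] <- (fn_c(par + e) - fn_c(par - e)) / (2 * .fd_steps_coarse[i])
        }
        g
      }
      # multi-start: the coarse landscape still has traps for large hinge
      # errors, so besides the current orientation a small set of rotation
      # perturbation seeds (30 degrees about four axes) is tried
      seeds <- list(numeric(6))
      for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3)))
        for (sgn in c(1, -1))
          seeds[[length(seeds) + 1]] <- c(0, 0, 0, sgn * (30 * pi / 180) * ax)
      oc <- NULL
      for (s in seeds) {
        o <- optim(s, fn_c, gr_c, method = "L-BFGS-B",
                   control = list(maxit = maxit, factr = 1e12))
        if (is.null(oc) || o$value < oc$value) oc <- o
      }
      fn <- function(par) obj(par, ctx, 3L)
      gr <- function(par) {
        g <- numeric(6)
        for (i in 1:6) {
          e <- numeric(6); e[i] <- .fd_steps[i]
          g[i] <- (fn(par + e) - fn(par - e)) / (2 * .fd_steps[i])
        }
        g
      }
      opt <- optim(oc$par, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = maxit, factr = 4.5e10))
      p <- pose_from_chart(opt$par, pose_identity())
      cand <- xyz
      cand[sel, ] <- pose_coords(xyz[sel, , drop = FALSE], p, dcom)
      full <- score_eval(ctx, cand, weights)
      cand_at <- placed$atoms
      cand_at$x <- cand[, 1]; cand_at$y <- cand[, 2]; cand_at$z <- cand[, 3]
      if (full$composite > best_score &&
          max_linker_gap(cand_at, segments) < max_gap) {
        xyz <- cand
        best_score <- full$composite
        domain_poses[[d]] <- p
      } else {
        domain_poses[[d]] <- pose_identity()
      }
    }
  }
  placed$atoms$x <- xyz[, 1]; placed$atoms$y <- xyz[, 2]
  placed$atoms$z <- xyz[, 3]
  attr(placed, "domain_poses") <- domain_poses
  attr(placed, "composite") <- best_score
  placed
}
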
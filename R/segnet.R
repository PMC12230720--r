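# Trainable protein/NA/background map segmentation. The network is a
# compact three-level nested encoder-decoder (see src/segnet.cpp for the
# exact topology); training uses class-weighted cross-entropy with Adam and
# a reduce-on-plateau learning-rate schedule, keeping the checkpoint with
# the lowest validation loss.

#' Segmentation training configuration
#'
#' @param epochs training epochs (the full-scale recipe uses 200; the
#'   desk-scale synthetic task converges in ~30).
#' @param lr_init,lr_min initial and floor learning rate (5e-4 / 1e-6).
#' @param lr_factor,lr_patience reduce-on-plateau schedule: multiply the
#'   learning rate by `lr_factor` when the validation loss has not improved
#'   for `lr_patience` epochs.
#' @param class_weights per-class loss weights (protein, NA, other);
#'   `NULL` = inverse voxel frequency on the training set.
#' @param base_width channel width of the first encoder level.
#' @param seed RNG seed for weight initialization and chunk shuffling.
#' @export
seg_train_config <- function(epochs = 200, lr_init = 5e-4, lr_min = 1e-6,
                             lr_factor = 0.5, lr_patience = 5,
                             class_weights = NULL, base_width = 16L,
                             seed = 1) {
  stopifnot(epochs >= 1, lr_min <= lr_init)
  structure(list(epochs = as.integer(epochs), lr_init = lr_init,
                 lr_min = lr_min, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 class_weights = class_weights,
                 base_width = as.integer(base_width), seed = seed),
            class = "seg_train_config")
}

# He-style initialization of all weight blocks
seg_init_weights <- function(base_width, seed) {
  w <- base_width
  with_seed(seed, {
    init <- function(r, c) matrix(rnorm(r * c, sd = sqrt(2 / c)), r, c)
    list(W1 = init(w, 27), b1 = rep(0, w),
         W2 = init(2 * w, 27 * w), b2 = rep(0, 2 * w),
         W3 = init(w, 54 * w), b3 = rep(0, w),
         W4a = init(w, w), W4b = init(w, w), b4 = rep(0, w),
         W5x = rnorm(3, sd = 0.1), W5u = init(3, w), W5v = init(3, w),
         b5 = rep(0, 3))
  })
}

#' Pair density and label chunks for training
#'
#' Cuts a preprocessed map (1 Angstrom voxels, contour-zeroed, normalized)
#' and its aligned label volume into overlapping 64^3 chunks on the
#' stride-32 lattice; chunks whose density is entirely zero are dropped.
#'
#' @param map a normalized [density_map].
#' @param labels the aligned [label_volume].
#' @param size,stride chunk geometry (voxels).
#' @return List of `list(density = , labels = , corner = )` chunk pairs.
#' @export
prepare_training_chunks <- function(map, labels, size = 64L, stride = 32L) {
  stopifnot(is_density_map(map), inherits(labels, "label_volume"))
  if (!identical(dim(map$grid), dim(labels$labels)) ||
      max(abs(map$origin - labels$origin)) > 1e-6)
    stop("map and label grids are misaligned")
  mc <- chunk_map(map, size = size, stride = stride)
  # label chunks padded with background (2), not 0
  lc <- chunk_map(density_map(labels$labels - 2, map$voxel_size, map$origin,
                              map$resolution), size = size, stride = stride)
  out <- list()
  for (i in seq_along(mc)) {
    if (all(mc[[i]]$data == 0)) next
    out[[length(out) + 1L]] <- list(density = mc[[i]]$data,
                                    labels = array(as.integer(lc[[i]]$data + 2),
                                                   dim = dim(lc[[i]]$data)),
                                    corner = mc[[i]]$corner)
  }
  out
}

#' Generate a synthetic segmentation training set
#'
#' Builds a stream of small synthetic complexes (protein-only, NA-only and
#' mixed), simulates their maps at 1 Angstrom voxels with the requested
#' noise, normalizes, computes ground-truth labels, and cuts chunk pairs
#' until `n_chunks` are collected.
#'
#' @param n_chunks number of chunk pairs to return.
#' @param seed RNG seed.
#' @param resolution map resolution, Angstrom.
#' @param noise_sigma map noise level.
#' @return List of chunk pairs as in [prepare_training_chunks()].
#' @export
make_segmentation_dataset <- function(n_chunks, seed = 1, resolution = 5,
                                      noise_sigma = 0.05) {
  out <- list()
  i <- 0
  while (length(out) < n_chunks) {
    i <- i + 1
    kind <- i %% 3
    spec <- if (kind == 0)
      toy_complex_spec(protein_lengths = c(80), na_bp = integer(0),
                       seed = seed * 1000 + i, resolution = resolution,
                       noise_sigma = noise_sigma)
    else if (kind == 1)
      toy_complex_spec(protein_lengths = integer(0), na_bp = 25,
                       seed = seed * 1000 + i, resolution = resolution,
                       noise_sigma = noise_sigma)
    else
      toy_complex_spec(protein_lengths = c(70), na_bp = 20,
                       seed = seed * 1000 + i, resolution = resolution,
                       noise_sigma = noise_sigma)
    cx <- make_toy_complex(spec)
    m <- simulate_map(cx, resolution = resolution, voxel_size = 1)
    m <- add_noise(m, noise_sigma, seed = spec$seed + 7)
    m <- normalize_map(m)
    lab <- ground_truth_labels(cx, m)
    out <- c(out, prepare_training_chunks(m, lab))
  }
  out[seq_len(n_chunks)]
}

#' Train the map segmenter
#'
#' Class-weighted cross-entropy, Adam updates (one chunk per step), and a
#' reduce-on-plateau learning-rate schedule from `lr_init` toward `lr_min`.
#' The checkpoint with the lowest validation loss is returned. Training is
#' deterministic for a fixed config seed.
#'
#' @param train,valid non-overlapping lists of chunk pairs
#'   (see [prepare_training_chunks()]).
#' @param config a [seg_train_config].
#' @param verbose print per-epoch losses.
#' @return A `segmenter`: list with `weights`, `base_width`, `config` and a
#'   per-epoch `log` data frame (train/valid loss, valid accuracy, lr).
#' @export
train_segmenter <- function(train, valid, config = seg_train_config(),
                            verbose = FALSE) {
  stopifnot(length(train) > 0, length(valid) > 0)
  cw <- config$class_weights
  if (is.null(cw)) {
    counts <- c(0, 0, 0)
    for (ch in train)
      counts <- counts + tabulate(as.integer(ch$labels) + 1L, 3)
    cw <- sum(counts) / (3 * pmax(counts, 1))
    cw <- cw / mean(cw)
  }
  W <- seg_init_weights(config$base_width, config$seed)
  mom <- lapply(W, function(x) x * 0)
  vel <- lapply(W, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$lr_init
  step <- 0
  log <- data.frame()
  best_valid <- Inf; best_W <- W; since_improve <- 0
  n0 <- as.integer(round(length(train[[1]]$density)^(1 / 3)))
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$seed * 10000 + epoch,
                     sample(length(train)))
    tr_loss <- 0
    for (i in ord) {
      g <- cpp_seg_grad(W, as.numeric(train[[i]]$density),
                        as.integer(train[[i]]$labels), cw, n0)
      tr_loss <- tr_loss + g$loss
      step <- step + 1
      for (nm in names(W)) {
        gr <- g$grads[[nm]]
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tr_loss <- tr_loss / length(train)
    va_loss <- 0; va_acc <- 0
    for (ch in valid) {
      e <- cpp_seg_eval(W, as.numeric(ch$density), as.integer(ch$labels),
                        cw, n0)
      va_loss <- va_loss + e$loss; va_acc <- va_acc + e$acc
    }
    va_loss <- va_loss / length(valid); va_acc <- va_acc / length(valid)
    if (!is.finite(va_loss) || !is.finite(tr_loss))
      stop("training diverged at epoch ", epoch, " (train loss ", tr_loss,
           ", validation loss ", va_loss, "); lower the learning rate")
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tr_loss,
                                 valid_loss = va_loss, valid_acc = va_acc,
                                 lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  valid %.4f  acc %.3f  lr %.2g",
                      epoch, tr_loss, va_loss, va_acc, lr))
    if (va_loss < best_valid - 1e-6) {
      best_valid <- va_loss; best_W <- W; since_improve <- 0
    } else {
      since_improve <- since_improve + 1
      if (since_improve >= config$lr_patience) {
        lr <- max(config$lr_min, lr * config$lr_factor)
        since_improve <- 0
      }
    }
  }
  structure(list(weights = best_W, base_width = config$base_width,
                 class_weights = cw, config = config, log = log),
            class = "segmenter")
}

#' @export
print.segmenter <- function(x, ...) {
  cat(sprintf("<segmenter> base width %d, %d epochs trained, best valid loss %.4f\n",
              x$base_width, nrow(x$log), min(x$log$valid_loss)))
  invisible(x)
}

#' Segment a map into protein / NA / background
#'
#' The map is cut into overlapping 64^3 chunks (stride 32); per-chunk class
#' probabilities are averaged at every voxel over all covering chunks, then
#' the argmax is taken. Voxels with zero density are forced to background.
#' Deterministic for fixed weights.
#'
#' @param map a normalized 1-Angstrom-voxel [density_map].
#' @param segmenter a trained segmenter from [train_segmenter()].
#' @return A [label_volume] with per-class probabilities attached.
#' @export
segment_map <- function(map, segmenter) {
  stopifnot(is_density_map(map), inherits(segmenter, "segmenter"))
  d <- dim(map$grid)
  chunks <- chunk_map(map, size = 64L, stride = 32L)
  acc <- array(0, dim = c(3, prod(d)))
  cnt <- numeric(prod(d))
  for (ch in chunks) {
    pr <- cpp_seg_forward(segmenter$weights, as.numeric(ch$data), 64L)
    # voxel indices of this chunk inside the parent map
    xr <- (ch$corner[1] + 1):min(ch$corner[1] + 64, d[1])
    yr <- (ch$corner[2] + 1):min(ch$corner[2] + 64, d[2])
    zr <- (ch$corner[3] + 1):min(ch$corner[3] + 64, d[3])
    sub <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    pidx <- (sub[, 1] - 1) + d[1] * ((sub[, 2] - 1) + d[2] * (sub[, 3] - 1)) + 1
    csub <- as.matrix(expand.grid(x = seq_along(xr), y = seq_along(yr),
                                  z = seq_along(zr)))
    cidx <- (csub[, 1] - 1) + 64 * ((csub[, 2] - 1) + 64 * (csub[, 3] - 1)) + 1
    acc[, pidx] <- acc[, pidx] + pr[, cidx]
    cnt[pidx] <- cnt[pidx] + 1
  }
  probs <- sweep(acc, 2, pmax(cnt, 1), "/")
  lab <- max.col(t(probs)) - 1L
  lab[as.numeric(map$grid) <= 0] <- 2L
  label_volume(array(lab, dim = d), map$voxel_size, map$origin, probs = probs)
}

#' Split a map into protein and NA maps by voxel labels
#'
#' The protein map keeps density only at label-0 voxels, the NA map only at
#' label-1 voxels; the split conserves density exactly (the two maps plus
#' the label-2-masked remainder reconstruct the input).
#'
#' @param map a [density_map].
#' @param labels an aligned [label_volume].
#' @return List with `protein` and `na` [density_map]s.
#' @export
split_map <- function(map, labels) {
  stopifnot(is_density_map(map), inherits(labels, "label_volume"))
  if (!identical(dim(map$grid), dim(labels$labels)))
    stop("map and label grids are misaligned")
  pm <- map; nm <- map
  pm$grid <- map$grid * (labels$labels == 0L)
  nm$grid <- map$grid * (labels$labels == 1L)
  list(protein = pm, na = nm)
}

#' Label a map from approximately placed chains (non-ML fallback)
#'
#' Labels voxels by proximity to the backbone atoms of user-supplied
#' (approximately placed) chains, exactly as [ground_truth_labels()] does.
#' This is a pipeline-testing convenience for users who can provide rough
#' placements; it is not the trained segmentation method.
#'
#' @param map a [density_map].
#' @param model a [complex_model] roughly placed in the map frame.
#' @param radius proximity radius, Angstrom.
#' @return A [label_volume].
#' @export
label_by_chains <- function(map, model, radius = 3)
  ground_truth_labels(model, map, radius = radius)
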
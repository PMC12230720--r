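# Complex assembly: pick one retained pose per chain by integer-coded
# differential evolution against a density-plus-clash energy (exhaustive
# enumeration below a cutoff, where the optimum is exact), then refine all
# rigid units jointly.

#' Differential evolution configuration
#'
#' @param population population size (>= 4).
#' @param F differential weight in (0, 2].
#' @param CR crossover rate in \[0, 1\].
#' @param generations number of generations.
#' @param seed RNG seed.
#' @param exhaustive_cutoff switch to exhaustive enumeration when the
#'   total number of selections is at most this (exact optimum).
#' @export
de_config <- function(population = 40, F = 0.7, CR = 0.9, generations = 200,
                      seed = 1, exhaustive_cutoff = 1024) {
  stopifnot(population >= 4, F > 0, F <= 2, CR >= 0, CR <= 1)
  structure(list(population = as.integer(population), F = F, CR = CR,
                 generations = as.integer(generations), seed = seed,
                 exhaustive_cutoff = exhaustive_cutoff),
            class = "de_config")
}

# decode a selection vector (one candidate index per chain) into a placed
# complex
decode_selection <- function(fit_results, selection) {
  chains <- vector("list", length(fit_results))
  for (i in seq_along(fit_results)) {
    fr <- fit_results[[i]]
    cand <- fr$candidates[[selection[i]]]
    chains[[i]] <- apply_pose(fr$chain, cand$pose)
  }
  complex_model(chains)
}

#' Assembly energy of a candidate-pose selection
#'
#' `energy = -global_cc(complex, map) + lambda_clash * clash_score(complex)`
#' evaluated against the original (unsegmented, unmasked) map so protein
#' and NA placements are judged jointly; lower is better.
#'
#' @param fit_results list of fit results (one per chain).
#' @param selection integer vector of candidate indices (1-based).
#' @param map the full [density_map].
#' @param lambda_clash clash weight (default 1).
#' @param ctx optional prebuilt scoring context (internal reuse).
#' @return Scalar energy.
#' @export
assembly_energy <- function(fit_results, selection, map, lambda_clash = 1,
                            ctx = NULL) {
  model <- decode_selection(fit_results, selection)
  gcc <- if (is.null(ctx)) {
    suppressWarnings(global_cc(model, map))
  } else {
    score_eval(ctx, coords(model), weights = c(1, 0, 0))$global_cc
  }
  -gcc + lambda_clash * clash_score(model)
}

#' Select one pose per chain by differential evolution
#'
#' Integer-coded DE (rand/1/bin with rounding and reflection into the valid
#' index range) over selection vectors; when the total number of
#' combinations is at most the config cutoff the search switches to
#' exhaustive enumeration and returns the exact optimum. Deterministic for
#' a fixed seed.
#'
#' @param fit_results named list of fit results from [iterative_fit_all()]
#'   or [fit_chain()].
#' @param map the full [density_map].
#' @param config a [de_config].
#' @param lambda_clash clash weight.
#' @return An `assembly_state`: `selection` (named), `energy`, and the
#'   decoded [complex_model].
#' @export
assemble_de <- function(fit_results, map, config = de_config(),
                        lambda_clash = 1) {
  stopifnot(length(fit_results) >= 1)
  ncand <- vapply(fit_results, function(f) length(f$candidates), 0L)
  if (any(ncand < 1)) stop("every chain needs at least one candidate")
  # shared scoring context over the concatenated atoms (coordinates vary
  # with the selection but the atom set does not)
  at <- do.call(rbind, lapply(fit_results, function(f) model_atoms(f$chain)))
  ctx <- new_score_ctx(map, at)
  energy <- function(sel) assembly_energy(fit_results, sel, map,
                                          lambda_clash, ctx = ctx)
  total <- prod(ncand)
  if (total <= config$exhaustive_cutoff) {
    grid <- as.matrix(expand.grid(lapply(ncand, seq_len)))
    vals <- apply(grid, 1, energy)
    best <- which.min(vals)
    sel <- as.integer(grid[best, ])
  } else {
    sel <- with_seed(config$seed, {
      np <- config$population
      d <- length(ncand)
      pop <- matrix(0L, np, d)
      pop[1, ] <- 1L  # greedy top-1 selection always in the population
      for (i in 2:np) pop[i, ] <- vapply(ncand, function(n)
        sample.int(n, 1), 0L)
      fit <- apply(pop, 1, energy)
      for (gen in seq_len(config$generations)) {
        for (i in seq_len(np)) {
          idx <- sample(setdiff(seq_len(np), i), 3)
          mut <- pop[idx[1], ] + config$F * (pop[idx[2], ] - pop[idx[3], ])
          mut <- round(mut)
          # reflect into [1, ncand]
          for (j in seq_len(d)) {
            while (mut[j] < 1 || mut[j] > ncand[j]) {
              if (mut[j] < 1) mut[j] <- 2 - mut[j]
              if (mut[j] > ncand[j]) mut[j] <- 2 * ncand[j] - mut[j]
            }
          }
          cross <- runif(d) < config$CR
          cross[sample.int(d, 1)] <- TRUE
          trial <- ifelse(cross, mut, pop[i, ])
          ev <- energy(as.integer(trial))
          if (ev <= fit[i]) { pop[i, ] <- as.integer(trial); fit[i] <- ev }
        }
      }
      pop[which.min(fit), ]
    })
  }
  model <- decode_selection(fit_results, sel)
  structure(list(selection = setNames(as.integer(sel), names(fit_results)),
                 energy = energy(as.integer(sel)), model = model,
                 fit_results = fit_results, lambda_clash = lambda_clash),
            class = "assembly_state")
}

#' @export
print.assembly_state <- function(x, ...) {
  cat(sprintf("<assembly_state> energy %.4f, selection (%s)\n", x$energy,
              paste(x$selection, collapse = ", ")))
  invisible(x)
}

#' Joint refinement of all rigid units
#'
#' One L-BFGS run over the 6-DOF poses of every rigid unit simultaneously
#' (protein domains as independent units, NA chains as single rigid
#' bodies), minimizing the assembly energy on the full map. The refined
#' model is accepted only if the energy improves; otherwise the input model
#' is returned unchanged. NA intra-unit geometry is exactly preserved.
#'
#' @param state an `assembly_state` from [assemble_de()].
#' @param map the full [density_map].
#' @param use_domains split protein chains into domains (default TRUE).
#' @param maxit L-BFGS iteration cap.
#' @param lambda_clash clash weight (defaults to the state's).
#' @return The refined [complex_model] with the final energy attached as
#'   attribute `energy`.
#' @export
global_refine <- function(state, map, use_domains = TRUE, maxit = 50,
                          lambda_clash = NULL) {
  stopifnot(inherits(state, "assembly_state"), is_density_map(map))
  if (is.null(lambda_clash)) lambda_clash <- state$lambda_clash
  model <- state$model
  at <- model_atoms(model)
  ctx <- new_score_ctx(map, at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  nat <- vapply(model$chains, function(c) nrow(c$atoms), 0L)
  chain_of_atom <- rep(seq_along(model$chains), nat)
  # rigid units: protein domains (when partitioned) or whole chains
  unit_of_atom <- integer(nrow(at))
  u <- 0
  for (i in seq_along(model$chains)) {
    ch <- model$chains[[i]]
    rows <- which(chain_of_atom == i)
    if (ch$kind == "protein" && use_domains) {
      seg <- if (!is.null(ch$domains)) ch$domains else partition_domains(ch)
      for (d in seq_len(nrow(seg))) {
        u <- u + 1
        unit_of_atom[rows[ch$atoms$resno >= seg$start[d] &
                            ch$atoms$resno <= seg$end[d]]] <- u
      }
    } else {
      u <- u + 1
      unit_of_atom[rows] <- u
    }
  }
  nunit <- u
  ucom <- lapply(seq_len(nunit), function(k)
    colMeans(xyz[unit_of_atom == k, , drop = FALSE]))
  decode <- function(par) {
    out <- xyz
    for (k in seq_len(nunit)) {
      pk <- par[(6 * (k - 1) + 1):(6 * k)]
      p <- pose_from_chart(pk, pose_identity())
      sel <- unit_of_atom == k
      out[sel, ] <- pose_coords(xyz[sel, , drop = FALSE], p, ucom[[k]])
    }
    out
  }
  energy_xyz <- function(cand) {
    gcc <- score_eval(ctx, cand, weights = c(1, 0, 0))$global_cc
    clash <- cpp_clash_pairs(cand, chain_of_atom, 3) / nrow(cand)
    -gcc + lambda_clash * clash
  }
  fn <- function(par) energy_xyz(decode(par))
  steps <- rep(.fd_steps, nunit)
  gr <- function(par) {
    g <- numeric(length(par))
    for (i in seq_along(par)) {
      e <- numeric(length(par)); e[i] <- steps[i]
      g[i] <- (fn(par + e) - fn(par - e)) / (2 * steps[i])
    }
    g
  }
  e0 <- fn(numeric(6 * nunit))
  opt <- tryCatch(
    optim(numeric(6 * nunit), fn, gr, method = "L-BFGS-B",
          control = list(maxit = maxit, factr = 4.5e10)),
    error = function(e) list(par = numeric(6 * nunit), value = e0))
  if (!is.finite(opt$value) || opt$value >= e0) {
    out <- model
    attr(out, "energy") <- e0
    return(out)
  }
  new_xyz <- decode(opt$par)
  pos <- 0
  for (i in seq_along(model$chains)) {
    rows <- which(chain_of_atom == i)
    model$chains[[i]]$atoms$x <- new_xyz[rows, 1]
    model$chains[[i]]$atoms$y <- new_xyz[rows, 2]
    model$chains[[i]]$atoms$z <- new_xyz[rows, 3]
    pos <- pos + length(rows)
  }
  attr(model, "energy") <- opt$value
  model
}
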
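# End-to-end pipeline: segment (or accept labels) -> iterative chain
# fitting -> differential-evolution assembly -> joint refinement ->
# report.

#' Assemble a complex from a map and chain models
#'
#' Runs the full pipeline: the map is resampled to `voxel_size` and
#' normalized; protein/NA regions are separated using `labels` (from
#' [segment_map()], [ground_truth_labels()] or [label_by_chains()]); chains
#' are fitted iteratively with masking; one pose per chain is selected by
#' differential evolution; and all rigid units are refined jointly.
#'
#' @param map a [density_map].
#' @param chains list of [chain_model]s.
#' @param labels a [label_volume] aligned to the preprocessed map, or a
#'   `segmenter` to compute one, or `NULL` for a protein-only map (all
#'   nonzero voxels treated as protein).
#' @param voxel_size working voxel size, Angstrom (default 1; the server
#'   default of 2 trades accuracy for speed).
#' @param schedule a [fit_schedule].
#' @param de a [de_config].
#' @param domain_fit apply domain-level flexible fitting to protein chains.
#' @param iterative use the iterative masking strategy (disable to fit all
#'   chains against the unmasked segmented maps).
#' @param seed seed for the assembly DE.
#' @param ... passed to [fit_chain()].
#' @return List with the final `model` ([complex_model]), `fits`, the
#'   `assembly` state, and the preprocessed `map`.
#' @export
run_pipeline <- function(map, chains, labels = NULL, voxel_size = 1,
                         schedule = fit_schedule(), de = NULL,
                         domain_fit = TRUE, iterative = TRUE, seed = 1,
                         ...) {
  stopifnot(is_density_map(map))
  if (abs(map$voxel_size - voxel_size) > 1e-9)
    map <- resample_map(map, voxel_size)
  if (!isTRUE(attr(map, "normalized"))) map <- normalize_map(map)
  if (inherits(labels, "segmenter")) labels <- segment_map(map, labels)
  if (is.null(labels)) {
    lab <- array(ifelse(map$grid > 0, 0L, 2L), dim = dim(map$grid))
    labels <- label_volume(lab, map$voxel_size, map$origin)
  }
  halves <- split_map(map, labels)
  sched <- if (iterative) schedule else
    fit_schedule(threshold_init = schedule$threshold_floor,
                 threshold_step = schedule$threshold_step,
                 threshold_floor = schedule$threshold_floor, max_rounds = 1)
  fits <- iterative_fit_all(chains, halves$protein, halves$na,
                            schedule = sched, mask = iterative, ...)
  if (domain_fit) {
    for (id in names(fits)) {
      fr <- fits[[id]]
      if (fr$chain$kind != "protein") next
      if (n_residues(fr$chain) < 120) next  # single-domain chains unchanged
      best <- fr$candidates[[1]]
      refined <- domain_refine(fr$chain, halves$protein, best$pose)
      if (attr(refined, "composite") > best$composite) {
        # store as an updated chain with identity pose candidate
        fr$chain <- refined
        fr$candidates[[1]]$pose <- pose_identity()
        fr$candidates[[1]]$composite <- attr(refined, "composite")
        fits[[id]] <- fr
      }
    }
  }
  if (is.null(de)) de <- de_config(seed = seed)
  state <- assemble_de(fits, map, config = de)
  model <- global_refine(state, map, use_domains = domain_fit)
  list(model = model, fits = fits, assembly = state, map = map)
}

#' Final model output: PDB plus quality report
#'
#' Writes the assembled model as PDB and returns (and optionally writes) a
#' quality report: global CC and iFSC for the complex and for each chain,
#' and the per-residue CC table.
#'
#' @param model a [complex_model].
#' @param map the (preprocessed) [density_map].
#' @param pdb_path optional output PDB path.
#' @param report_path optional output JSON report path; a TSV of
#'   per-residue CC is written next to it.
#' @return The report as a list (`complex`, `chains`, `per_residue_cc`).
#' @export
build_output <- function(model, map, pdb_path = NULL, report_path = NULL) {
  stopifnot(is_complex_model(model), is_density_map(map))
  sim_full <- simulate_map_on_grid(model, map)
  fsc <- fsc_curve(map, sim_full)
  band_hi <- min(1 / map$resolution, 1 / (2 * map$voxel_size))
  comp <- list(global_cc = suppressWarnings(global_cc(model, map)),
               ifsc = integrated_fsc(fsc, 0.1, band_hi),
               clash = clash_score(model))
  chains <- lapply(model$chains, function(ch) {
    sim_c <- simulate_map_on_grid(complex_model(list(ch)), map)
    list(global_cc = suppressWarnings(global_cc(ch, map)),
         ifsc = integrated_fsc(fsc_curve(map, sim_c), 0.1, band_hi))
  })
  prc <- local_cc(model, map)
  report <- list(complex = comp, chains = chains, per_residue_cc = prc)
  scores <- lapply(chains, function(x) list(cc = x$global_cc, ifsc = x$ifsc))
  if (!is.null(pdb_path)) write_complex_pdb(model, pdb_path, scores = scores)
  if (!is.null(report_path)) {
    jsonlite::write_json(list(complex = comp,
                              chains = chains),
                         report_path, auto_unbox = TRUE, digits = NA)
    write.table(prc, sub("\\.json$", "_per_residue_cc.tsv", report_path),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}

# simulate a model's density on an existing map lattice
simulate_map_on_grid <- function(model, map) {
  xyz <- coords(model)
  amp <- atomic_numbers(unlist(lapply(model$chains,
                                      function(c) c$atoms$elesy)))
  sigma <- map$resolution / (pi * sqrt(2))
  g <- cpp_sim_density(xyz, amp, sigma, dim(map$grid), map$origin,
                       map$voxel_size, 3)
  density_map(array(g, dim = dim(map$grid)), map$voxel_size, map$origin,
              map$resolution)
}
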
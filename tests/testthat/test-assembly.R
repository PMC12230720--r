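# Differential-evolution pose selection, assembly energy, and joint
# refinement.

# fit results with known candidate poses around the truth placement
synthetic_fits <- function(cx, map, n_decoys = 2, jitter = 8) {
  fits <- list()
  for (i in seq_along(cx$chains)) {
    ch <- cx$chains[[i]]
    cands <- list(list(pose = pose_identity(), composite = 1,
                       global_cc = 1, mean_local_cc = 1, ifsc = 1,
                       converged = TRUE))
    for (k in seq_len(n_decoys)) {
      p <- with_seed_test(100 * i + k, pose(rnorm(4), runif(3, -jitter,
                                                            jitter)))
      cands[[k + 1]] <- list(pose = p, composite = 0.3, global_cc = 0.3,
                             mean_local_cc = 0.3, ifsc = 0.3,
                             converged = TRUE)
    }
    # shuffle so the truth candidate is not always first
    ord <- with_seed_test(i, sample(length(cands)))
    fits[[ch$chain_id]] <- structure(list(chain_id = ch$chain_id,
                                          candidates = cands[ord],
                                          chain = ch),
                                     class = "fit_result")
  }
  fits
}

test_that("assembly energy: -CC at zero clash weight, clash monotonicity", {
  fixt <- fx_small_pn()
  fits <- synthetic_fits(fixt$complex, fixt$map)
  sel <- rep(1L, length(fits))
  e0 <- assembly_energy(fits, sel, fixt$map, lambda_clash = 0)
  model <- emapfit:::decode_selection(fits, sel)
  expect_equal(e0, -suppressWarnings(global_cc(model, fixt$map)),
               tolerance = 1e-12)
  # moving one chain onto another raises the energy at positive weight
  overlap_fits <- fits
  onto <- pose(translation = colMeans(coords(fits[[1]]$chain)) -
                 colMeans(coords(fits[[2]]$chain)))
  overlap_fits[[2]]$candidates[[1]]$pose <- onto
  e_ok <- assembly_energy(fits, sel, fixt$map, lambda_clash = 1)
  e_bad <- assembly_energy(overlap_fits, sel, fixt$map, lambda_clash = 1)
  expect_gt(e_bad, e_ok)
})

test_that("a singleton search space returns immediately", {
  fixt <- fx_small_pn()
  ch <- fixt$complex$chains[[1]]
  fits <- list(A = structure(list(chain_id = "A", candidates = list(
    list(pose = pose_identity(), composite = 1, global_cc = 1,
         mean_local_cc = 1, ifsc = 1, converged = TRUE)), chain = ch),
    class = "fit_result"))
  st <- assemble_de(fits, fixt$map)
  expect_equal(unname(st$selection), 1L)
})

test_that("below the enumeration cutoff the optimum is exact (brute force)", {
  fixt <- fx_small_pn()
  fits <- synthetic_fits(fixt$complex, fixt$map, n_decoys = 2)
  st <- assemble_de(fits, fixt$map)
  # independent brute force over all combinations
  ncand <- vapply(fits, function(f) length(f$candidates), 0L)
  grid <- as.matrix(expand.grid(lapply(ncand, seq_len)))
  vals <- apply(grid, 1, function(sel)
    assembly_energy(fits, as.integer(sel), fixt$map))
  expect_equal(st$energy, min(vals), tolerance = 1e-12)
  expect_equal(unname(st$selection), as.integer(grid[which.min(vals), ]))
  # the exact optimum recovers the truth candidates
  truth_sel <- vapply(fits, function(f)
    which(vapply(f$candidates, function(c)
      pose_angle(c$pose) < 1e-6 && sum(c$pose$t^2) < 1e-12, TRUE)), 0L)
  expect_equal(st$selection, truth_sel)
})

test_that("DE above the cutoff is seeded, valid, and beats greedy top-1", {
  fixt <- fx_small_pn()
  fits <- synthetic_fits(fixt$complex, fixt$map, n_decoys = 4)
  cfg <- de_config(population = 12, generations = 15, seed = 3,
                   exhaustive_cutoff = 4)  # force the DE path
  st1 <- assemble_de(fits, fixt$map, cfg)
  st2 <- assemble_de(fits, fixt$map, cfg)
  expect_identical(st1$selection, st2$selection)
  ncand <- vapply(fits, function(f) length(f$candidates), 0L)
  expect_true(all(st1$selection >= 1 & st1$selection <= ncand))
  greedy <- vapply(fits, function(f)
    which.max(vapply(f$candidates, function(c) c$composite, 0)), 0L)
  e_greedy <- assembly_energy(fits, as.integer(greedy), fixt$map)
  expect_lte(st1$energy, e_greedy + 1e-12)
})

test_that("global refinement lowers energy and repairs small displacements", {
  fixt <- fx_small_pn()
  fits <- list()
  for (ch in fixt$complex$chains) {
    p <- with_seed_test(match(ch$chain_id, names(fixt$complex$chains)),
                        pose(emapfit:::quat_from_axis_angle(rnorm(3), 0.04),
                             runif(3, -1, 1)))
    fits[[ch$chain_id]] <- structure(list(chain_id = ch$chain_id,
                                          candidates = list(list(
      pose = p, composite = 0.8, global_cc = 0.8, mean_local_cc = 0.8,
      ifsc = 0.8, converged = TRUE)), chain = ch), class = "fit_result")
  }
  st <- assemble_de(fits, fixt$map)
  refined <- global_refine(st, fixt$map, use_domains = FALSE)
  expect_lte(attr(refined, "energy"), st$energy + 1e-9)
  for (id in names(refined$chains)) {
    before <- rmsd_kabsch(coords(st$model$chains[[id]]),
                          coords(fixt$complex$chains[[id]]),
                          superpose = FALSE)
    after <- rmsd_kabsch(coords(refined$chains[[id]]),
                         coords(fixt$complex$chains[[id]]),
                         superpose = FALSE)
    expect_lt(after, before)
  }
  # NA internal geometry is untouched by refinement
  na_id <- names(Filter(function(c) c$kind == "NA", fixt$complex$chains))
  expect_lt(max_pairdist_change(coords(refined$chains[[na_id]]),
                                coords(fixt$complex$chains[[na_id]])), 1e-9)
})

test_that("build_output reports one CC entry per chain plus the complex", {
  fixt <- fx_small_pn()
  f_pdb <- tempfile(fileext = ".pdb")
  f_json <- tempfile(fileext = ".json")
  rep <- build_output(fixt$complex, fixt$map, f_pdb, f_json)
  expect_named(rep, c("complex", "chains", "per_residue_cc"))
  expect_length(rep$chains, length(fixt$complex$chains))
  total_res <- sum(vapply(fixt$complex$chains, n_residues, 0L))
  expect_equal(nrow(rep$per_residue_cc), total_res)
  expect_true(file.exists(f_pdb))
  expect_true(file.exists(f_json))
  expect_true(file.exists(sub("\\.json$", "_per_residue_cc.tsv", f_json)))
  parsed <- jsonlite::read_json(f_json)
  expect_true(is.numeric(parsed$complex$global_cc))
  unlink(c(f_pdb, f_json, sub("\\.json$", "_per_residue_cc.tsv", f_json)))
})
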
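test_that("identical spec and seed give bit-identical PDB text", {
  spec <- synthetic_structure_spec(shell_radii = c(0, 2.2, 4.2), seed = 13)
  g1 <- generate_structure(spec)
  g2 <- generate_structure(spec)
  expect_identical(write_pdb(g1$structure), write_pdb(g2$structure))
  g3 <- generate_structure(synthetic_structure_spec(
    shell_radii = c(0, 2.2, 4.2), seed = 14))
  expect_false(identical(g1$structure$atoms$b, g3$structure$atoms$b))
})

test_that("a spec with no voids produces no cavities", {
  g <- generate_structure(
    synthetic_structure_spec(shell_radii = c(0, 2.2, 4.2, 6.2), seed = 4))
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5))
  expect_equal(nrow(cs$cavities), 0L)
})

test_that("a carved void is recovered near its ground-truth volume", {
  g <- generate_structure(
    synthetic_structure_spec(shell_radii = c(0, 2.0, 3.6, 5.2, 6.8, 8.4),
                             void_centers = list(c(0, 0, 2.5)),
                             void_free_radii = 2.0, seed = 21), "onevoid")
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.4))
  expect_equal(nrow(cs$cavities), 1L)
  # the carved void contains the inscribed free sphere but is lumpier than
  # it, so the swept volume brackets the ground-truth sphere from above
  expect_gt(cs$cavities$volume, 0.9 * g$ground_truth$expected_void_volume)
  expect_lt(cs$cavities$volume, 1.6 * g$ground_truth$expected_void_volume)
})

test_that("voids touching the outer boundary are rejected", {
  expect_error(
    generate_structure(synthetic_structure_spec(
      shell_radii = c(0, 2.2, 4.2, 6.2),
      void_centers = list(c(3.0, 0, 0)), void_free_radii = 2.0)),
    "solvent-connected")
})

test_that("generated frequency vectors always sum to one and are seeded", {
  spec <- two_group_spec(n_per_group = 20, seed = 5)
  coh <- generate_two_group_frequencies(spec)
  for (g in coh) {
    expect_equal(g$f_surface + g$f_boundary + g$f_core, rep(1, 20),
                 tolerance = 1e-12)
    expect_true(all(g[, c("f_surface", "f_boundary", "f_core")] >= 0))
  }
  coh2 <- generate_two_group_frequencies(spec)
  expect_identical(coh, coh2)
})

test_that("group means are recovered on a large cohort", {
  spec <- two_group_spec(n_per_group = 400, seed = 8)
  coh <- generate_two_group_frequencies(spec)
  # truncation+renormalization distorts means only mildly at sd 0.13
  expect_equal(mean(coh$th$f_core), spec$mean_freqs_th[3], tolerance = 0.03)
  expect_equal(mean(coh$me$f_boundary), spec$mean_freqs_me[2],
               tolerance = 0.05)
  expect_equal(mean(coh$th$flex_core), spec$flex_means_th[3],
               tolerance = 0.03)
})

test_that("rigid-core group 1 shows a negative core flexibility gap", {
  # the qualitative structure of the thermophile/mesophile contrast:
  # group 1 drawn with the lower core flexibility mean
  neg <- vapply(1:100, function(s) {
    coh <- generate_two_group_frequencies(two_group_spec(seed = s))
    mean(coh$th$flex_core) - mean(coh$me$flex_core) < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("the full synthetic pipeline is seed-deterministic end to end", {
  run_once <- function() {
    dir <- tempfile(); dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    g <- generate_structure(
      synthetic_structure_spec(shell_radii = c(0, 2.0, 3.6, 5.2, 6.8),
                               void_centers = list(c(0, 0, 1.5)),
                               void_free_radii = 1.8, seed = 31), "p")
    writeLines(write_pdb(g$structure), file.path(dir, "p.pdb"))
    man <- data.frame(thermo_file = "p.pdb", thermo_chain = "A",
                      meso_file = "p.pdb", meso_chain = "A",
                      identity_percent = 50)
    out <- file.path(dir, "out")
    suppressWarnings(run_compare(man, pipeline_config(grid_spacing = 0.5),
                                 base_dir = dir, out_dir = out))
    lapply(sort(list.files(out, full.names = TRUE)), readLines)
  }
  expect_identical(run_once(), run_once())
})
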
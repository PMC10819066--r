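test_that("grid configuration is validated", {
  expect_error(grid_spec(spacing = 1.5, probe_radius = 1.4), "smaller than")
  expect_error(grid_spec(spacing = 0), "spacing > 0")
  st <- atoms_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))
  expect_error(detect_cavities(st), "fewer than 4 atoms")
})

test_that("a compact solid cluster has no interior cavity", {
  g <- solid_fixture()
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5))
  expect_equal(nrow(cs$cavities), 0L)
})

test_that("a carved interior void is found with oracle-matching volume", {
  g <- two_void_fixture()
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5))
  orc <- oracle_voids(g$structure, spacing = 0.5)
  # two disjoint voids separated by a solid wall, both routes agree
  expect_equal(nrow(cs$cavities), 2L)
  expect_equal(orc$n_cavities, 2L)
  expect_equal(sort(cs$cavities$volume), sort(orc$volumes), tolerance = 1e-9)
  # volume conservation: cavities fit in the box not occupied by atoms
  expect_lt(sum(cs$cavities$volume), orc$box_volume - orc$atom_volume)
})

test_that("no cavity voxel is reachable from the box boundary", {
  # definitional: the oracle's solvent sweep must not touch cavity voxels;
  # equivalently, re-detecting after opening a channel removes the cavity
  g <- two_void_fixture()
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5))
  st <- g$structure
  # drill a wide channel from the first void center along +x to the outside
  ctr <- g$ground_truth$void_centers[[1]]
  a <- st$atoms
  keep <- !(a$y^2 + a$z^2 < 3.2^2 & a$x > ctr[1])
  st$atoms <- a[keep, , drop = FALSE]
  cs2 <- detect_cavities(st, grid_spec(spacing = 0.5))
  expect_lt(nrow(cs2$cavities), nrow(cs$cavities))
})

test_that("voxel face counting gives cube and bar areas", {
  dims <- c(5L, 5L, 5L)
  mid <- 3L + 5L * 2L + 25L * 2L       # single voxel
  expect_equal(voxel_surface_area(mid, dims, 0.6), 6 * 0.6^2)
  expect_equal(voxel_surface_area(c(mid, mid + 1L), dims, 0.6), 10 * 0.6^2)
})

test_that("halving the spacing changes the shell void volume by < 10%", {
  g <- shell_fixture()
  v8 <- detect_cavities(g$structure, grid_spec(spacing = 0.8))$cavities$volume
  v4 <- detect_cavities(g$structure, grid_spec(spacing = 0.4))$cavities$volume
  expect_length(v8, 1L)
  expect_length(v4, 1L)
  expect_lt(abs(v8 - v4) / v4, 0.10)
})

test_that("cavity detection is translation invariant", {
  g <- two_void_fixture()
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5))
  st <- g$structure
  st$atoms$x <- st$atoms$x + 3.17
  st$atoms$y <- st$atoms$y - 2.71
  st$atoms$z <- st$atoms$z + 5.03
  cs2 <- detect_cavities(st, grid_spec(spacing = 0.5))
  expect_equal(nrow(cs2$cavities), nrow(cs$cavities))
  # within one voxel layer of the void surface
  layer <- cs$cavities$surface_area / (2 / 3) * 0.5
  expect_true(all(abs(sort(cs2$cavities$volume) - sort(cs$cavities$volume)) <
                    layer[order(cs$cavities$volume)]))
})

test_that("lining residues grow monotonically with the contact margin", {
  g <- shell_fixture()
  st <- g$structure
  cs <- detect_cavities(st, grid_spec(spacing = 0.5))
  l0 <- lining_residues(cs, st, 1L, contact_margin = 0)
  l5 <- lining_residues(cs, st, 1L, contact_margin = 0.5)
  expect_true(all(l0 %in% l5))
  # the default lining set is the innermost wall shell, no distal residue
  rid <- residue_ids(st)
  wall <- unique(rid[g$ground_truth$shell == min(g$ground_truth$shell)])
  expect_true(all(l5 %in% wall))
  expect_gte(length(l5), 3L)
})

test_that("the minimum-lining rule discards sparse components", {
  g <- shell_fixture()
  cs <- detect_cavities(g$structure, grid_spec(spacing = 0.5),
                        min_lining = 1000L)
  expect_equal(nrow(cs$cavities), 0L)
})
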
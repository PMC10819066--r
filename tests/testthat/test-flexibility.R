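test_that("per-chain z-scoring reproduces the hand-computed case", {
  st <- atoms_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                        b = c(10, 20, 30))
  nb <- normalize_b_factors(st)
  # population sigma = sqrt(200/3) = 8.1650
  expect_equal(nb$b_prime, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
})

test_that("normalization invariants hold to 1e-9 on arbitrary chains", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    b <- stats::runif(n, 5, 80)
    st <- atoms_structure(cbind(seq_len(n) * 4, 0, 0), b = b)
    nb <- normalize_b_factors(st)
    expect_lt(abs(mean(nb$b_prime)), 1e-9)
    expect_lt(abs(sqrt(mean((nb$b_prime - mean(nb$b_prime))^2)) - 1), 1e-9)
    # affine invariance: B -> a*B + c leaves B' unchanged
    st2 <- st; st2$atoms$b <- 3.7 * b + 11.1
    expect_equal(normalize_b_factors(st2)$b_prime, nb$b_prime,
                 tolerance = 1e-9)
  }
})

test_that("constant B factors are a degenerate-chain error", {
  st <- atoms_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                        b = c(15, 15, 15))
  expect_error(normalize_b_factors(st), "sigma = 0")
})

test_that("residues without a C-alpha are skipped with a warning", {
  st <- atoms_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                        b = c(10, 20, 30))
  st$atoms$is_calpha[2] <- FALSE
  st$atoms$name[2] <- "CB"
  expect_warning(nb <- normalize_b_factors(st), "without C-alpha")
  expect_equal(nrow(nb), 2L)
  # <B> and sigma over the remaining two C-alphas only: 10, 30 -> +/-1
  expect_equal(sort(nb$b_prime), c(-1, 1))
})

test_that("cavity flexibility averages lining residues, skipping absentees", {
  nb <- data.frame(residue_id = c("A:1", "A:2", "A:3"),
                   b_prime = c(-1, 0, 1))
  expect_equal(cavity_flexibility(c("A:1", "A:2", "A:3"), nb), 0)
  nb2 <- data.frame(residue_id = c("A:1", "A:2"), b_prime = c(-0.5, -0.7))
  expect_warning(f <- cavity_flexibility(c("A:1", "A:2", "A:9"), nb2),
                 "skipped")
  expect_equal(f, -0.6)
  expect_error(suppressWarnings(cavity_flexibility("A:9", nb2)), "undefined")
})

test_that("region flexibility index pools residues and flags empty regions", {
  cs <- structure(list(
    cavities = data.frame(cavity_id = 1:2, region = c("core", "boundary"),
                          flexibility = c(-0.5, 0.2)),
    lining = list(c("A:1", "A:2", "A:3"), c("A:4", "A:5", "A:6"))),
    class = "cavity_set")
  nb <- data.frame(residue_id = paste0("A:", 1:6),
                   b_prime = c(-1, -0.5, 0, 0.1, 0.2, 0.3))
  idx <- region_flexibility_index(list(cs), list(nb))
  expect_equal(unname(idx["core"]), -0.5)
  expect_equal(unname(idx["boundary"]), 0.2)
  expect_true(is.na(idx["surface"]))
  # single cavity per region: by_residue equals by_cavity
  idx2 <- region_flexibility_index(list(cs), list(nb), pooling = "by_cavity")
  expect_equal(idx, idx2)
})

test_that("rigid synthetic cores yield lower core flexibility than surface", {
  # interior shells get systematically lower B than the outer shell
  g <- generate_structure(
    synthetic_structure_spec(shell_radii = c(2.0, 3.8, 5.7, 7.4),
                             void_centers = list(c(0, 0, 0)),
                             void_free_radii = 4.0,
                             b_surface_mean = 45, b_core_mean = 15, b_sd = 4,
                             seed = 11), "rigidcore")
  st <- g$structure
  nb <- normalize_b_factors(st)
  rid <- residue_ids(st)
  outer_shell <- max(g$ground_truth$shell)
  core_b <- nb$b_prime[nb$residue_id %in% rid[g$ground_truth$shell < outer_shell]]
  surf_b <- nb$b_prime[nb$residue_id %in% rid[g$ground_truth$shell == outer_shell]]
  expect_lt(mean(core_b), mean(surf_b))
})
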
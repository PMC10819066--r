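test_that("the two-group statistic equals its closed form on random input", {
  set.seed(7)
  for (i in 1:1000) {
    x1 <- stats::runif(1, -2, 2); x2 <- stats::runif(1, -2, 2)
    s1 <- stats::runif(1, 0.01, 3); s2 <- stats::runif(1, 0.01, 3)
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    direct <- (x1 - x2) / sqrt(s1^2 / n1 + s2^2 / n2)
    expect_equal(t_statistic(x1, x2, s1, s2, n1, n2), direct,
                 tolerance = 1e-12)
  }
})

test_that("swapping the groups negates t; edge cases are handled", {
  expect_equal(t_statistic(1, 0, 1, 1, 20, 20), sqrt(10), tolerance = 1e-9)
  expect_equal(t_statistic(1, 0, 1, 1, 20, 20),
               -t_statistic(0, 1, 1, 1, 20, 20))
  expect_equal(t_statistic(0.4, 0.4, 0.2, 0.5, 10, 12), 0)
  expect_error(t_statistic(1, 0, 0, 0, 20, 20), "undefined")
  expect_error(t_statistic(1, 0, 1, 1, 1, 20), ">= 2")
})

test_that("large-sample critical levels come from the fixed one-tailed row", {
  cr <- critical_levels(38)
  expect_equal(as.vector(cr), c(1.282, 1.645, 1.960, 2.326, 2.576))
  expect_equal(names(cr), c("0.1", "0.05", "0.025", "0.01", "0.005"))
  # strictly increasing as alpha decreases
  expect_true(all(diff(as.vector(cr)) > 0))
  # small df falls back to the exact inverse CDF
  cr10 <- critical_levels(10)
  expect_equal(as.vector(cr10),
               stats::qt(1 - c(0.1, 0.05, 0.025, 0.01, 0.005), 10))
  expect_error(critical_levels(0), "df")
})

test_that("directional significance calls follow the one-tailed cutoffs", {
  expect_equal(unname(significance_call(1.8386, 38, 0.05)), "thermo_greater")
  expect_equal(unname(significance_call(-1.7621, 38, 0.05)), "meso_greater")
  expect_equal(unname(significance_call(0.5, 38, 0.05)), "not_significant")
  # monotone: significant at stricter alpha implies significant at looser
  calls <- significance_call(2.4, 38)
  sig <- calls != "not_significant"
  expect_true(all(diff(as.integer(!sig)) >= 0))
})

test_that("group summaries reproduce per-protein and per-residue rates", {
  # 20 proteins, 369 cavities, 6628 residues in total
  set.seed(1)
  counts <- c(rep(18, 11), rep(19, 9))     # sums to 369
  res <- c(rep(331, 12), rep(332, 8))      # sums to 6628
  profiles <- lapply(1:20, function(i) {
    k <- counts[i]
    regs <- sample(c("surface", "boundary", "core"), k, replace = TRUE,
                   prob = c(0.01, 0.72, 0.27))
    cav <- data.frame(cavity_id = seq_len(k), voxel_count = 1L,
                      volume = stats::runif(k, 10, 50),
                      surface_area = stats::runif(k, 20, 80),
                      n_lining = 3L, mean_osp = 0.4, region = regs,
                      flexibility = stats::rnorm(k))
    structure(list(protein_id = paste0("p", i), n_residues = res[i],
                   cavity_set = structure(list(cavities = cav,
                                               lining = rep(list(character(0)), k)),
                                          class = "cavity_set"),
                   normalized = data.frame(residue_id = character(0),
                                           b_prime = numeric(0)),
                   freqs = region_frequencies(regs, paste0("p", i))),
              class = "protein_cavity_profile")
  })
  gs <- build_group_summary(profiles, "thermophilic")
  expect_equal(gs$n_cavities_total, 369)
  expect_equal(gs$cavities_per_protein, 18.45)
  expect_equal(round(gs$cavities_per_residue, 3), 0.056)
  expect_equal(sum(gs$mean_freq), 1, tolerance = 1e-12)
  expect_true(all(gs$sd_freq >= 0))
})

test_that("published summary tables reproduce their printed t values", {
  path <- system.file("extdata", "region_frequency_summary.tsv",
                      package = "cavstat")
  tab <- utils::read.delim(path)
  out <- ttest_from_summary(tab)
  expect_equal(out$df, rep(38L, 3))
  expect_equal(out$t[out$region == "boundary"], -1.7621, tolerance = 2e-3)
  expect_equal(out$t[out$region == "core"], 1.8386, tolerance = 2e-3)
  calls <- attr(out, "calls")
  expect_equal(unname(calls["boundary", "0.05"]), "meso_greater")
  expect_equal(unname(calls["core", "0.05"]), "thermo_greater")
  expect_equal(unname(calls["surface", "0.1"]), "not_significant")
})

test_that("volume classes split at the stated thresholds", {
  expect_equal(unname(volume_split(c(10, 20, 60))), c(2, 0, 1))
  expect_equal(unname(volume_split(c(30, 50))), c(0, 2, 0))
  expect_equal(unname(volume_split(numeric(0))), c(0, 0, 0))
  expect_error(volume_split(c(1, 2), small_max = 60, large_min = 50))
})
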
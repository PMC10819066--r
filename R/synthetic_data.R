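# run `expr` with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards; all package randomness flows through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic pseudo-protein structure
#'
#' Describes a compact cluster of pseudo-atoms on concentric spherical
#' shells, with optional interior voids of known position and free radius,
#' and a two-level B-factor model (more mobile surface shell, more rigid
#' interior). The defaults give a tight cluster the size of a small protein
#' domain with realistic crystallographic B factors (surface around 40
#' Angstrom^2, core around 20, SD 8).
#'
#' @param shell_radii radii of the concentric shells, Angstrom (a radius of
#'   0 places a single central atom).
#' @param atoms_per_shell atom counts per shell; default scales with shell
#'   area for near-constant surface density.
#' @param atom_radius van der Waals radius of every pseudo-atom, Angstrom.
#' @param void_centers list of 3-vectors (or an n x 3 matrix), void centers.
#' @param void_free_radii target free radius of each void, Angstrom: after
#'   carving, no atom surface lies closer to the void center. Must exceed
#'   the 1.4 probe for the void to be detectable.
#' @param b_surface_mean,b_core_mean,b_sd B-factor model, Angstrom^2: the
#'   outermost shell draws from `Normal(b_surface_mean, b_sd)`, all interior
#'   shells from `Normal(b_core_mean, b_sd)`.
#' @param atoms_per_residue 1 (default; every pseudo-residue is a lone
#'   C-alpha) or 3 (adds two offset heavy atoms per residue, exercising the
#'   heavy-atom lining rule).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   structure.
#' @return a `synthetic_structure_spec` list.
#' @export
synthetic_structure_spec <- function(shell_radii = c(0, 2.2, 4.2, 6.2, 8.2),
                                     atoms_per_shell = NULL,
                                     atom_radius = 1.7,
                                     void_centers = list(),
                                     void_free_radii = numeric(0),
                                     b_surface_mean = 40, b_core_mean = 20,
                                     b_sd = 8,
                                     atoms_per_residue = 1L,
                                     seed = 1L) {
  if (is.matrix(void_centers)) {
    void_centers <- lapply(seq_len(nrow(void_centers)),
                           function(i) void_centers[i, ])
  }
  stopifnot(length(void_centers) == length(void_free_radii),
            atom_radius > 0, b_sd >= 0, atoms_per_residue %in% c(1L, 3L),
            all(shell_radii >= 0))
  if (is.null(atoms_per_shell)) {
    # ~1 atom per 2.6 A^2 of shell area keeps gaps below the probe diameter
    atoms_per_shell <- pmax(1L, as.integer(ceiling(4 * pi * shell_radii^2 / 2.6)))
  }
  stopifnot(length(atoms_per_shell) == length(shell_radii),
            all(atoms_per_shell >= 1L))
  structure(list(shell_radii = shell_radii,
                 atoms_per_shell = as.integer(atoms_per_shell),
                 atom_radius = atom_radius,
                 void_centers = void_centers,
                 void_free_radii = void_free_radii,
                 b_surface_mean = b_surface_mean, b_core_mean = b_core_mean,
                 b_sd = b_sd, atoms_per_residue = as.integer(atoms_per_residue),
                 seed = as.integer(seed)),
            class = "synthetic_structure_spec")
}

#' Generate a synthetic pseudo-protein with voids of known geometry
#'
#' Atoms are placed on deterministic Fibonacci lattices over the spec's
#' concentric shells; atoms whose center lies within
#' `void_free_radius + atom_radius` of a void center are removed, carving
#' an interior void whose achieved free radius (distance from the void
#' center to the nearest remaining atom surface) is recorded as ground
#' truth. B factors are drawn per atom from the shell-dependent normal
#' model; the outermost shell is the "surface", everything inside is
#' "core". One pseudo-residue per lattice site, chain A, every residue's
#' first atom flagged C-alpha.
#'
#' @param spec a [synthetic_structure_spec()].
#' @param structure_id identifier for the structure.
#' @return list with `structure` (a `protein_structure`, radii assigned)
#'   and `ground_truth`: per-void achieved free radius and expected
#'   probe-swept volume `4/3 pi r^3`, plus each atom's shell and B model.
#' @export
generate_structure <- function(spec, structure_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_structure_spec"))
  r_out <- max(spec$shell_radii)
  for (k in seq_along(spec$void_centers)) {
    ctr <- spec$void_centers[[k]]
    if (sqrt(sum(ctr^2)) + spec$void_free_radii[k] + 1.4 >
        r_out - spec$atom_radius) {
      stop("void ", k, " overlaps the outer boundary; it would be ",
           "solvent-connected", call. = FALSE)
    }
  }
  pos <- do.call(rbind, lapply(seq_along(spec$shell_radii), function(s) {
    R <- spec$shell_radii[s]
    n <- spec$atoms_per_shell[s]
    p <- if (R == 0) matrix(0, 1, 3) else fibonacci_sphere(n) * R
    cbind(p, shell = s)
  }))
  keep <- rep(TRUE, nrow(pos))
  for (k in seq_along(spec$void_centers)) {
    ctr <- spec$void_centers[[k]]
    d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 +
                (pos[, 3] - ctr[3])^2)
    keep <- keep & d >= spec$void_free_radii[k] + spec$atom_radius
  }
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) < 4L) stop("carving removed nearly all atoms", call. = FALSE)

  outer_shell <- max(pos[, 4])
  is_surface <- pos[, 4] == outer_shell
  b <- with_seed(spec$seed, {
    stats::rnorm(nrow(pos),
                 mean = ifelse(is_surface, spec$b_surface_mean, spec$b_core_mean),
                 sd = spec$b_sd)
  })
  b <- pmax(b, 2)  # B factors are positive in real structures

  n_res <- nrow(pos)
  apr <- spec$atoms_per_residue
  if (apr == 1L) {
    atoms <- data.frame(
      serial = seq_len(n_res), name = "CA", element = "C", resid = "ALA",
      chain = "A", resno = seq_len(n_res), ins = "",
      x = pos[, 1], y = pos[, 2], z = pos[, 3], b = b, occ = 1,
      stringsAsFactors = FALSE
    )
  } else {
    # 3-atom residues: CA plus two offset heavy atoms sharing the residue's B
    off <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(0, 0.9, 0))
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      data.frame(
        serial = (i - 1L) * 3L + 1:3, name = c("CA", "CB", "CG"),
        element = "C", resid = "ALA", chain = "A", resno = i, ins = "",
        x = pos[i, 1] + off[, 1], y = pos[i, 2] + off[, 2],
        z = pos[i, 3] + off[, 3], b = b[i], occ = 1,
        stringsAsFactors = FALSE
      )
    }))
  }
  atoms$vdw_radius <- spec$atom_radius
  atoms$is_calpha <- atoms$name == "CA"
  st <- new_protein_structure(atoms, structure_id)

  achieved <- vapply(seq_along(spec$void_centers), function(k) {
    ctr <- spec$void_centers[[k]]
    d <- sqrt((atoms$x - ctr[1])^2 + (atoms$y - ctr[2])^2 +
                (atoms$z - ctr[3])^2)
    min(d) - spec$atom_radius
  }, numeric(1))
  list(structure = st,
       ground_truth = list(
         void_centers = spec$void_centers,
         free_radii = achieved,
         expected_void_volume = 4 / 3 * pi * achieved^3,
         shell = pos[, 4], is_surface = is_surface, b = b))
}

#' Specification of a synthetic two-group cavity-frequency cohort
#'
#' Emulates the data-generating structure behind a paired
#' thermophilic/mesophilic comparison: per-protein region-frequency vectors
#' scattered around group means (truncated-normal noise on the two minor
#' fractions, the dominant fraction closing each vector to exactly 1, so
#' the per-region noise SD is directly `freq_sd`), plus per-region
#' normalized-B flexibility samples. Defaults reproduce the published comparison's conditions: 20
#' proteins per group; thermophilic frequency means (surface, boundary,
#' core) = (0.0081, 0.7253, 0.2673) (renormalized to sum 1), mesophilic
#' (0.0091, 0.8025, 0.1884); per-region frequency noise SD 0.13, the scale
#' of the published per-region SDs (0.11-0.16); flexibility means
#' (-0.0034, -0.2428, -0.6484) and (0.1985, -0.2047, -0.5111). Each
#' flexibility sample stands for one protein's regional average of
#' normalized B over its cavity-lining residues, so its SD is the spread of
#' a within-protein mean: with per-residue normalized-B spread near 0.5 and
#' on the order of ten lining residues per region, that is about
#' 0.5/sqrt(10), the default `flex_sd = 0.16`.
#'
#' @param n_per_group proteins per group (>= 2; default 20).
#' @param mean_freqs_th,mean_freqs_me length-3 group mean frequency vectors
#'   (surface, boundary, core); renormalized to sum exactly 1.
#' @param freq_sd scale of between-protein frequency noise; a scalar or one
#'   value per region. The default follows the published per-region SD
#'   scales: about 0.025 for the near-zero surface fraction and 0.13 for
#'   boundary and core.
#' @param flex_means_th,flex_means_me per-region flexibility means,
#'   normalized-B units.
#' @param flex_sd SD of flexibility samples.
#' @param seed integer seed.
#' @return a `two_group_spec` list.
#' @export
two_group_spec <- function(n_per_group = 20L,
                           mean_freqs_th = c(0.0081, 0.7253, 0.2673),
                           mean_freqs_me = c(0.0091, 0.8025, 0.1884),
                           freq_sd = c(0.025, 0.13, 0.13),
                           flex_means_th = c(-0.0034, -0.2428, -0.6484),
                           flex_means_me = c(0.1985, -0.2047, -0.5111),
                           flex_sd = 0.16,
                           seed = 1L) {
  stopifnot(n_per_group >= 2L, length(mean_freqs_th) == 3L,
            length(mean_freqs_me) == 3L, all(freq_sd >= 0), flex_sd >= 0,
            length(freq_sd) %in% c(1L, 3L),
            all(mean_freqs_th >= 0), all(mean_freqs_me >= 0))
  structure(list(n_per_group = as.integer(n_per_group),
                 mean_freqs_th = mean_freqs_th / sum(mean_freqs_th),
                 mean_freqs_me = mean_freqs_me / sum(mean_freqs_me),
                 freq_sd = rep_len(freq_sd, 3L),
                 flex_means_th = flex_means_th, flex_means_me = flex_means_me,
                 flex_sd = flex_sd, seed = as.integer(seed)),
            class = "two_group_spec")
}

# One group's per-protein frequency matrix. Truncated-normal noise is
# applied to the two minor fractions and the dominant fraction closes each
# vector to 1; this keeps the per-region SD of the noised fractions
# directly at freq_sd (renormalizing all three would shrink it). Vectors
# renormalize only in the rare case the noised minors exceed 1.
.sample_freqs <- function(n, mean_freqs, freq_sd) {
  filler <- which.max(mean_freqs)
  minors <- setdiff(1:3, filler)
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    f <- numeric(3L)
    f[minors] <- pmax(0, mean_freqs[minors] +
                        stats::rnorm(2L, 0, freq_sd[minors]))
    rest <- 1 - sum(f[minors])
    if (rest >= 0) {
      f[filler] <- rest
    } else {
      f[minors] <- f[minors] / sum(f[minors])
      f[filler] <- 0
    }
    out[i, ] <- f
  }
  colnames(out) <- c("f_surface", "f_boundary", "f_core")
  out
}

#' Generate a synthetic two-group frequency/flexibility cohort
#'
#' @param spec a [two_group_spec()].
#' @return list with `th` and `me`, each a data frame of per-protein region
#'   frequencies (`protein_id`, `f_surface`, `f_boundary`, `f_core`, each
#'   row summing to exactly 1) plus per-region flexibility samples
#'   (`flex_surface`, `flex_boundary`, `flex_core`).
#' @export
generate_two_group_frequencies <- function(spec) {
  stopifnot(inherits(spec, "two_group_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_group
    make <- function(tag, mf, fl) {
      f <- .sample_freqs(n, mf, spec$freq_sd)
      flex <- sapply(fl, function(m) stats::rnorm(n, m, spec$flex_sd))
      colnames(flex) <- c("flex_surface", "flex_boundary", "flex_core")
      data.frame(protein_id = paste0(tag, seq_len(n)), f, flex,
                 stringsAsFactors = FALSE)
    }
    list(th = make("th", spec$mean_freqs_th, spec$flex_means_th),
         me = make("me", spec$mean_freqs_me, spec$flex_means_me))
  })
}
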
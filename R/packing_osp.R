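# Quasi-uniform points on the unit sphere: deterministic Fibonacci lattice.
# Reproducible without random numbers; n >= 1.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue occluded surface packing (OSP)
#'
#' Places quasi-uniform dots on each heavy atom's van der Waals sphere,
#' discards dots buried inside another atom, and casts a ray from every
#' remaining dot along the outward normal. A ray is occluded if it meets
#' another atom's van der Waals surface within `ray_limit` (one water
#' diameter); an occluded dot contributes weight `1 - L/ray_limit`, where
#' `L` is the distance to the hit. The residue's OSP is the summed weight
#' over all its atoms' dots divided by the residue's non-buried dot count
#' (dots pooled across atoms, so larger atoms weigh more), clamped to
#' `[0, 1]`. Fully exposed residues score 0; residues wrapped by contacting
#' neighbors approach 1.
#'
#' @param structure a `protein_structure` with radii assigned.
#' @param dot_density surface dots per Angstrom^2 (default 3).
#' @param ray_limit occlusion distance cap in Angstrom (default 2.8, one
#'   water diameter).
#' @param include_intra_residue count occlusion by atoms of the same residue
#'   (default `TRUE`; the purely geometric definition).
#' @return data frame with `residue_id`, `osp`, `n_dots` (non-buried dots).
#'   Residues with no heavy atoms are skipped with a warning upstream (they
#'   cannot occur in a parsed structure, which keeps heavy atoms only).
#' @export
compute_residue_osp <- function(structure, dot_density = 3, ray_limit = 2.8,
                                include_intra_residue = TRUE) {
  if (dot_density <= 0) stop("dot_density must be positive", call. = FALSE)
  if (ray_limit <= 0) stop("ray_limit must be positive", call. = FALSE)
  a <- structure$atoms
  if (any(is.na(a$vdw_radius))) {
    stop("radii not assigned; call assign_radii() first", call. = FALSE)
  }
  rid <- residue_ids(structure)
  cx <- a$x; cy <- a$y; cz <- a$z; r <- a$vdw_radius
  n_atoms <- nrow(a)
  occl <- numeric(n_atoms)   # summed occlusion weight per atom
  ndot <- integer(n_atoms)   # non-buried dot count per atom

  # dots per atom scale with surface area
  nd_all <- pmax(12L, as.integer(round(dot_density * 4 * pi * r^2)))
  dot_cache <- new.env(parent = emptyenv())

  for (i in seq_len(n_atoms)) {
    nd <- nd_all[i]
    key <- as.character(nd)
    u <- get0(key, envir = dot_cache)
    if (is.null(u)) {
      u <- fibonacci_sphere(nd)
      assign(key, u, envir = dot_cache)
    }
    px <- cx[i] + r[i] * u[, 1L]
    py <- cy[i] + r[i] * u[, 2L]
    pz <- cz[i] + r[i] * u[, 3L]

    # neighbors able to bury a dot or intercept a ray
    dx <- cx - cx[i]; dy <- cy - cy[i]; dz <- cz - cz[i]
    d2 <- dx * dx + dy * dy + dz * dz
    reach <- r[i] + ray_limit + r
    nb <- which(d2 <= reach * reach)
    nb <- nb[nb != i]
    if (!include_intra_residue) nb <- nb[rid[nb] != rid[i]]
    if (!length(nb)) {
      ndot[i] <- nd
      next
    }

    buried <- logical(nd)
    thit <- rep(Inf, nd)
    for (j in nb) {
      mx <- cx[j] - px; my <- cy[j] - py; mz <- cz[j] - pz
      m2 <- mx * mx + my * my + mz * mz
      inside <- m2 < r[j]^2
      buried <- buried | inside
      # ray p + t*u, t > 0: smallest root of |p + t u - c_j| = r_j
      b <- mx * u[, 1L] + my * u[, 2L] + mz * u[, 3L]
      disc <- b * b - (m2 - r[j]^2)
      ok <- !inside & disc >= 0
      if (any(ok)) {
        t1 <- b[ok] - sqrt(disc[ok])
        ok2 <- t1 > 0 & t1 <= ray_limit
        if (any(ok2)) {
          idx <- which(ok)[ok2]
          thit[idx] <- pmin(thit[idx], t1[ok2])
        }
      }
    }
    keep <- !buried
    ndot[i] <- sum(keep)
    tk <- thit[keep]
    tk <- tk[is.finite(tk)]
    occl[i] <- sum(1 - tk / ray_limit)
  }

  agg_occ <- tapply(occl, rid, sum)
  agg_dot <- tapply(ndot, rid, sum)
  ids <- names(agg_occ)
  skip <- agg_dot == 0
  if (any(skip)) {
    warning(sum(skip), " residue(s) with no unburied surface dots skipped",
            call. = FALSE)
  }
  osp <- pmin(1, pmax(0, as.numeric(agg_occ[!skip]) / as.numeric(agg_dot[!skip])))
  out <- data.frame(residue_id = ids[!skip], osp = osp,
                    n_dots = as.integer(agg_dot[!skip]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean OSP of a cavity's lining residues
#'
#' @param lining character vector of lining residue identifiers.
#' @param residue_osps data frame from [compute_residue_osp()].
#' @return unweighted arithmetic mean OSP in `[0, 1]`.
#' @export
cavity_osp <- function(lining, residue_osps) {
  idx <- match(lining, residue_osps$residue_id)
  if (anyNA(idx)) {
    stop("lining residue(s) missing from OSP table: ",
         paste(lining[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mean(residue_osps$osp[idx])
}

#' Fill per-cavity mean OSP from a residue OSP table
#'
#' @param cavity_set result of [detect_cavities()].
#' @param residue_osps data frame from [compute_residue_osp()].
#' @return the cavity set with `cavities$mean_osp` filled.
#' @export
annotate_osp <- function(cavity_set, residue_osps) {
  cavity_set$cavities$mean_osp <- vapply(
    cavity_set$lining, cavity_osp, numeric(1), residue_osps = residue_osps)
  cavity_set
}
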
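#' Classify a cavity's burial region from its mean OSP
#'
#' Three-region structure index on the occluded-surface-packing scale:
#' surface for OSP in `[0, 0.250)`, boundary for `[0.250, 0.500)`, core for
#' `[0.500, 1]`. The index's top class nominally ends at 0.750; values above
#' that are maximally buried and are folded into core. Intervals are
#' half-open (closed below), the only unambiguous reading of the published
#' overlapping range notation.
#'
#' @param mean_osp numeric vector of mean OSP values in `[0, 1]`.
#' @param bounds class boundaries, default `c(0.250, 0.500)`.
#' @return character vector of `"surface"`, `"boundary"`, `"core"`.
#' @export
classify_region <- function(mean_osp, bounds = c(0.250, 0.500)) {
  if (any(!is.finite(mean_osp)) || any(mean_osp < 0) || any(mean_osp > 1)) {
    stop("mean_osp must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
  out <- rep("core", length(mean_osp))
  out[mean_osp < bounds[2L]] <- "boundary"
  out[mean_osp < bounds[1L]] <- "surface"
  out
}

#' Fill per-cavity region labels from mean OSP
#'
#' @param cavity_set a `cavity_set` with `mean_osp` filled
#'   (see [annotate_osp()]).
#' @param bounds passed to [classify_region()].
#' @return the cavity set with `cavities$region` filled.
#' @export
annotate_region <- function(cavity_set, bounds = c(0.250, 0.500)) {
  if (nrow(cavity_set$cavities) && anyNA(cavity_set$cavities$mean_osp)) {
    stop("mean_osp not filled; run annotate_osp() first", call. = FALSE)
  }
  cavity_set$cavities$region <-
    if (nrow(cavity_set$cavities)) {
      classify_region(cavity_set$cavities$mean_osp, bounds)
    } else character(0)
  cavity_set
}

#' Per-protein cavity region frequencies
#'
#' Fraction of one protein's cavities falling in each region. Frequencies
#' sum to exactly 1 when the protein has at least one cavity; a protein with
#' no cavities yields an all-`NA` record flagged by `n_cavities = 0`.
#'
#' @param regions character vector of region labels (one per cavity), or an
#'   annotated `cavity_set`.
#' @param protein_id identifier stored in the output.
#' @return one-row data frame: `protein_id`, `n_cavities`, `n_surface`,
#'   `n_boundary`, `n_core`, `f_surface`, `f_boundary`, `f_core`.
#' @export
region_frequencies <- function(regions, protein_id = NA_character_) {
  if (inherits(regions, "cavity_set")) {
    if (is.na(protein_id)) protein_id <- regions$structure_id
    regions <- regions$cavities$region
  }
  bad <- setdiff(unique(regions), c("surface", "boundary", "core"))
  if (length(bad)) stop("unknown region label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- length(regions)
  counts <- c(surface = sum(regions == "surface"),
              boundary = sum(regions == "boundary"),
              core = sum(regions == "core"))
  # core closes the vector so the three fractions sum to exactly 1
  f <- if (n > 0) {
    c(counts[["surface"]] / n, counts[["boundary"]] / n,
      1 - counts[["surface"]] / n - counts[["boundary"]] / n)
  } else rep(NA_real_, 3L)
  data.frame(protein_id = protein_id, n_cavities = n,
             n_surface = counts[["surface"]], n_boundary = counts[["boundary"]],
             n_core = counts[["core"]],
             f_surface = f[[1L]], f_boundary = f[[2L]], f_core = f[[3L]],
             stringsAsFactors = FALSE)
}
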
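#' Normalize B factors per chain
#'
#' Converts raw crystallographic B factors of C-alpha atoms to per-chain
#' z-scores: `B' = (B - <B>) / sigma`, where `<B>` and `sigma` (population
#' standard deviation, divide by n) are taken over all C-alpha atoms of the
#' chain. Normalization makes flexibility comparable across structures of
#' different resolution. Residues without a C-alpha atom are skipped with a
#' warning and excluded from `<B>` and `sigma`.
#'
#' @param structure a `protein_structure`.
#' @return data frame with `residue_id`, `chain`, `b` (raw, Angstrom^2) and
#'   `b_prime` (dimensionless). Per chain, `b_prime` has mean 0 and
#'   population SD 1.
#' @export
normalize_b_factors <- function(structure) {
  a <- structure$atoms
  rid <- residue_ids(structure)
  res_key <- !duplicated(rid)
  ca <- a$is_calpha
  missing_ca <- setdiff(rid[res_key], rid[ca])
  if (length(missing_ca)) {
    warning("residue(s) without C-alpha skipped in B-factor normalization: ",
            paste(missing_ca, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(residue_id = rid[ca], chain = a$chain[ca], b = a$b[ca],
                    stringsAsFactors = FALSE)
  out$b_prime <- NA_real_
  for (ch in unique(out$chain)) {
    sel <- out$chain == ch
    b <- out$b[sel]
    if (length(b) < 2L) {
      stop("chain '", ch, "' has fewer than 2 C-alpha atoms", call. = FALSE)
    }
    mu <- mean(b)
    sigma <- sqrt(mean((b - mu)^2))
    if (sigma == 0) {
      stop("chain '", ch, "' has constant B factors (sigma = 0); ",
           "normalized B is undefined", call. = FALSE)
    }
    out$b_prime[sel] <- (b - mu) / sigma
  }
  rownames(out) <- NULL
  out
}

#' Flexibility of one cavity
#'
#' Unweighted mean normalized B factor (`b_prime`) over the cavity's lining
#' residues. Lining residues absent from the normalized table (no C-alpha)
#' are skipped with a warning; if none remain the flexibility is undefined
#' and an error is raised.
#'
#' @param lining character vector of lining residue identifiers.
#' @param normalized data frame from [normalize_b_factors()].
#' @return mean `b_prime`, in normalized-B units.
#' @export
cavity_flexibility <- function(lining, normalized) {
  idx <- match(lining, normalized$residue_id)
  if (anyNA(idx)) {
    warning("lining residue(s) without normalized B skipped: ",
            paste(lining[is.na(idx)], collapse = ", "), call. = FALSE)
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) {
    stop("flexibility undefined: no lining residue has a normalized B factor",
         call. = FALSE)
  }
  mean(normalized$b_prime[idx])
}

#' Fill per-cavity flexibility from a normalized B table
#'
#' @param cavity_set result of [detect_cavities()].
#' @param normalized data frame from [normalize_b_factors()].
#' @return the cavity set with `cavities$flexibility` filled (`NA` with a
#'   warning where undefined).
#' @export
annotate_flexibility <- function(cavity_set, normalized) {
  cavity_set$cavities$flexibility <- vapply(
    cavity_set$lining,
    function(l) tryCatch(cavity_flexibility(l, normalized),
                         error = function(e) NA_real_),
    numeric(1))
  cavity_set
}

#' Region flexibility index for a group of structures
#'
#' Pools cavity-lining residues' normalized B factors by cavity region
#' across all structures of a group and averages per region. Two pooling
#' modes: `"by_residue"` (default) averages over every lining residue of
#' every cavity in the region (residues lining several cavities count once
#' per cavity); `"by_cavity"` averages the per-cavity flexibility values.
#' For a region containing a single cavity the two modes coincide.
#'
#' @param cavity_sets list of annotated `cavity_set` objects (regions
#'   assigned; see [annotate_region()]).
#' @param normalized_list list of matching normalized-B data frames.
#' @param pooling `"by_residue"` or `"by_cavity"`.
#' @return named numeric vector `c(surface=, boundary=, core=)`; empty
#'   regions are `NA` (missing, not zero).
#' @export
region_flexibility_index <- function(cavity_sets, normalized_list,
                                     pooling = c("by_residue", "by_cavity")) {
  pooling <- match.arg(pooling)
  regions <- c("surface", "boundary", "core")
  acc <- stats::setNames(vector("list", 3L), regions)
  for (k in seq_along(cavity_sets)) {
    cs <- cavity_sets[[k]]
    nb <- normalized_list[[k]]
    if (!nrow(cs$cavities)) next
    for (i in seq_len(nrow(cs$cavities))) {
      reg <- cs$cavities$region[i]
      if (is.na(reg)) stop("cavity without region label; run annotate_region()",
                           call. = FALSE)
      vals <- if (pooling == "by_residue") {
        idx <- match(cs$lining[[i]], nb$residue_id)
        nb$b_prime[idx[!is.na(idx)]]
      } else {
        f <- cs$cavities$flexibility[i]
        if (is.na(f)) numeric(0) else f
      }
      acc[[reg]] <- c(acc[[reg]], vals)
    }
  }
  vapply(acc, function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
}
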
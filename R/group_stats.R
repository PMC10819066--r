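# Fixed one-tailed critical levels for effectively infinite samples
# (df > 30): the normal-approximation row used throughout the comparison.
.crit_inf <- c("0.1" = 1.282, "0.05" = 1.645, "0.025" = 1.960,
               "0.01" = 2.326, "0.005" = 2.576)

#' Two-group t statistic on a per-protein trait
#'
#' Unequal-variance two-sample statistic
#' `t = (X_th - X_me) / sqrt(S_th^2/N_th + S_me^2/N_me)`,
#' positive when the thermophilic group mean exceeds the mesophilic one.
#' Group SDs are taken across proteins (denominator n - 1 upstream).
#'
#' @param x_th,x_me group means of the trait.
#' @param s_th,s_me group standard deviations (non-negative, not both zero).
#' @param n_th,n_me group sizes (>= 2).
#' @return the t value.
#' @export
t_statistic <- function(x_th, x_me, s_th, s_me, n_th, n_me) {
  if (n_th < 2 || n_me < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (s_th < 0 || s_me < 0) stop("SDs must be non-negative", call. = FALSE)
  if (s_th == 0 && s_me == 0) {
    stop("both group SDs are zero; t statistic undefined", call. = FALSE)
  }
  (x_th - x_me) / sqrt(s_th^2 / n_th + s_me^2 / n_me)
}

#' One-tailed critical t levels
#'
#' For df > 30 the fixed large-sample row (1.282 / 1.645 / 1.960 / 2.326 /
#' 2.576 at alpha 0.1 / 0.05 / 0.025 / 0.01 / 0.005) is returned; for
#' df <= 30 values come from the one-tailed t inverse CDF. The exact
#' inverse-t values are attached as attribute `"exact"` for transparency.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha_levels significance levels (default the five standard ones).
#' @return named numeric vector of critical t values, names are the alphas.
#' @export
critical_levels <- function(df, alpha_levels = c(0.1, 0.05, 0.025, 0.01, 0.005)) {
  if (!is.finite(df) || df < 1) stop("df must be >= 1", call. = FALSE)
  key <- as.character(alpha_levels)
  exact <- stats::setNames(stats::qt(1 - alpha_levels, df), key)
  out <- if (df > 30 && all(key %in% names(.crit_inf))) {
    stats::setNames(.crit_inf[key], key)
  } else {
    exact
  }
  attr(out, "exact") <- exact
  out
}

#' Directional significance call for a one-tailed t comparison
#'
#' @param t the t statistic (positive favors the thermophilic group).
#' @param df degrees of freedom.
#' @param alpha significance level(s).
#' @return character vector over `alpha`: `"thermo_greater"` when
#'   `t > +crit`, `"meso_greater"` when `t < -crit`, else
#'   `"not_significant"`.
#' @export
significance_call <- function(t, df, alpha = c(0.1, 0.05, 0.025, 0.01, 0.005)) {
  crit <- critical_levels(df, alpha)
  if (is.na(t)) {
    return(stats::setNames(rep(NA_character_, length(crit)), names(crit)))
  }
  out <- ifelse(t > crit, "thermo_greater",
                ifelse(t < -crit, "meso_greater", "not_significant"))
  stats::setNames(as.character(out), names(crit))
}

#' Summarize one group of cavity profiles
#'
#' Aggregates per-protein cavity profiles (see [profile_structure()]) into a
#' group summary: cavity totals and per-protein / per-residue rates, mean
#' cavity volume and surface area, per-region mean frequency and SD across
#' proteins (denominator n - 1), and per-region flexibility indices in both
#' pooling modes.
#'
#' @param profiles list of `protein_cavity_profile` objects.
#' @param group_name label stored on the summary.
#' @return a `group_summary` list.
#' @export
build_group_summary <- function(profiles, group_name = "group") {
  stopifnot(length(profiles) >= 1L)
  n_prot <- length(profiles)
  freqs <- do.call(rbind, lapply(profiles, `[[`, "freqs"))
  n_cav <- sum(freqs$n_cavities)
  n_res <- sum(vapply(profiles, `[[`, numeric(1), "n_residues"))
  cav_all <- do.call(rbind, lapply(profiles, function(p) p$cavity_set$cavities))

  fmat <- as.matrix(freqs[freqs$n_cavities > 0,
                          c("f_surface", "f_boundary", "f_core"), drop = FALSE])
  mean_freq <- colMeans(fmat)
  sd_freq <- if (nrow(fmat) >= 2L) apply(fmat, 2L, stats::sd) else
    rep(NA_real_, 3L)
  names(mean_freq) <- names(sd_freq) <- c("surface", "boundary", "core")

  flex_res <- region_flexibility_index(
    lapply(profiles, `[[`, "cavity_set"),
    lapply(profiles, `[[`, "normalized"), pooling = "by_residue")
  flex_cav <- region_flexibility_index(
    lapply(profiles, `[[`, "cavity_set"),
    lapply(profiles, `[[`, "normalized"), pooling = "by_cavity")

  structure(list(
    group_name = group_name,
    n_proteins = n_prot,
    n_cavities_total = n_cav,
    n_residues_total = n_res,
    cavities_per_protein = n_cav / n_prot,
    cavities_per_residue = n_cav / n_res,
    mean_volume = if (nrow(cav_all)) mean(cav_all$volume) else NA_real_,
    mean_area = if (nrow(cav_all)) mean(cav_all$surface_area) else NA_real_,
    mean_freq = mean_freq,
    sd_freq = sd_freq,
    flexibility_by_residue = flex_res,
    flexibility_by_cavity = flex_cav,
    freq_table = freqs
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary '", x$group_name, "': ", x$n_proteins, " proteins, ",
      x$n_cavities_total, " cavities (", round(x$cavities_per_protein, 2),
      "/protein, ", round(x$cavities_per_residue, 3), "/residue)\n", sep = "")
  cat("  mean cavity volume ", round(x$mean_volume, 2), " A^3, area ",
      round(x$mean_area, 2), " A^2\n", sep = "")
  tab <- rbind(frequency = round(x$mean_freq, 4), sd = round(x$sd_freq, 4),
               flexibility = round(x$flexibility_by_residue, 4))
  print(tab)
  invisible(x)
}

#' Region-wise comparison of two group summaries
#'
#' Builds the region comparison table: per-region mean frequency, SD and
#' flexibility index for both groups, the two-group t statistic on the
#' frequencies, `df = N_th + N_me - 2`, and directional significance calls
#' at the requested levels.
#'
#' @param summary_th,summary_me `group_summary` objects for the thermophilic
#'   and mesophilic group.
#' @param alpha_levels significance levels for the calls.
#' @return a `region_comparison`: list with `table` (one row per region) and
#'   `calls` (region x alpha matrix of directional calls), plus `df`.
#' @export
compare_groups <- function(summary_th, summary_me,
                           alpha_levels = c(0.1, 0.05, 0.025, 0.01, 0.005)) {
  regions <- c("surface", "boundary", "core")
  df <- summary_th$n_proteins + summary_me$n_proteins - 2L
  t_val <- vapply(regions, function(r) {
    # a region where both groups are perfectly constant has no t statistic
    tryCatch(
      t_statistic(summary_th$mean_freq[[r]], summary_me$mean_freq[[r]],
                  summary_th$sd_freq[[r]], summary_me$sd_freq[[r]],
                  summary_th$n_proteins, summary_me$n_proteins),
      error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(
    region = regions,
    freq_th = as.numeric(summary_th$mean_freq),
    sd_th = as.numeric(summary_th$sd_freq),
    flex_th = as.numeric(summary_th$flexibility_by_residue),
    freq_me = as.numeric(summary_me$mean_freq),
    sd_me = as.numeric(summary_me$sd_freq),
    flex_me = as.numeric(summary_me$flexibility_by_residue),
    t = as.numeric(t_val),
    stringsAsFactors = FALSE
  )
  calls <- if (df >= 1) {
    t(vapply(t_val, significance_call, character(length(alpha_levels)),
             df = df, alpha = alpha_levels))
  } else {
    matrix(NA_character_, 3L, length(alpha_levels),
           dimnames = list(NULL, as.character(alpha_levels)))
  }
  rownames(calls) <- regions
  structure(list(table = tab, calls = calls, df = df),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("region_comparison (df = ", x$df, ")\n", sep = "")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' t statistics from a printed group-summary table
#'
#' Validates the statistical layer directly against published group means
#' and SDs, with no structures involved. The input mirrors a region summary
#' table: one row per trait with both groups' means, SDs and sizes.
#'
#' @param summary data frame with columns `trait` (or `region`), `mean_th`,
#'   `sd_th`, `n_th`, `mean_me`, `sd_me`, `n_me`.
#' @param alpha_levels significance levels for the calls.
#' @return the input with `t`, `df` columns appended plus a `calls`
#'   attribute (trait x alpha matrix).
#' @export
ttest_from_summary <- function(summary,
                               alpha_levels = c(0.1, 0.05, 0.025, 0.01, 0.005)) {
  if (!"trait" %in% names(summary) && "region" %in% names(summary)) {
    summary$trait <- summary$region
  }
  need <- c("trait", "mean_th", "sd_th", "n_th", "mean_me", "sd_me", "n_me")
  stopifnot(all(need %in% names(summary)))
  summary$t <- mapply(function(...) {
    tryCatch(t_statistic(...), error = function(e) NA_real_)
  }, summary$mean_th, summary$mean_me,
  summary$sd_th, summary$sd_me, summary$n_th, summary$n_me)
  summary$df <- as.integer(summary$n_th + summary$n_me - 2L)
  calls <- t(mapply(significance_call, summary$t, summary$df,
                    MoreArgs = list(alpha = alpha_levels)))
  rownames(calls) <- summary$trait
  attr(summary, "calls") <- calls
  summary
}

#' Split cavities into small / intermediate / large volume classes
#'
#' @param volumes numeric vector of cavity volumes (Angstrom^3), or a
#'   `cavity_set`.
#' @param small_max upper bound of the small class, exclusive (default 30).
#' @param large_min lower bound of the large class, exclusive (default 50).
#' @return named integer vector `c(n_small, n_mid, n_large)`: counts with
#'   volume `< small_max`, in `[small_max, large_min]`, and `> large_min`.
#' @export
volume_split <- function(volumes, small_max = 30, large_min = 50) {
  if (inherits(volumes, "cavity_set")) volumes <- volumes$cavities$volume
  stopifnot(small_max > 0, large_min > 0, small_max <= large_min)
  c(n_small = sum(volumes < small_max),
    n_mid = sum(volumes >= small_max & volumes <= large_min),
    n_large = sum(volumes > large_min))
}
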
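#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end comparison.
#'
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param grid_spacing voxel edge length, Angstrom (default 0.6).
#' @param contact_margin lining-residue contact margin, Angstrom.
#' @param min_lining minimum lining residues per cavity (default 3).
#' @param region_bounds OSP class bounds `c(surface|boundary,
#'   boundary|core)`.
#' @param alpha_levels significance levels for directional calls.
#' @param pooling flexibility-index pooling mode.
#' @param min_length,min_identity pair-filter thresholds
#'   (see [filter_pairs()]).
#' @param dot_density OSP surface dots per Angstrom^2.
#' @param radii_set radii table name (see [assign_radii()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(probe_radius = 1.4, grid_spacing = 0.6,
                            contact_margin = 0.5, min_lining = 3L,
                            region_bounds = c(0.250, 0.500),
                            alpha_levels = c(0.1, 0.05, 0.025, 0.01, 0.005),
                            pooling = c("by_residue", "by_cavity"),
                            min_length = 200, min_identity = 35,
                            dot_density = 3, radii_set = "default") {
  pooling <- match.arg(pooling)
  stopifnot(probe_radius > 0, grid_spacing > 0,
            length(region_bounds) == 2L,
            region_bounds[1L] > 0, region_bounds[2L] <= 1,
            region_bounds[1L] < region_bounds[2L])
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 contact_margin = contact_margin, min_lining = min_lining,
                 region_bounds = region_bounds, alpha_levels = alpha_levels,
                 pooling = pooling, min_length = min_length,
                 min_identity = min_identity, dot_density = dot_density,
                 radii_set = radii_set),
            class = "pipeline_config")
}

#' Profile one structure: cavities, OSP, regions, flexibility
#'
#' Runs the single-structure leg of the pipeline: cavity detection,
#' per-residue OSP, per-cavity mean OSP and region label, per-chain B-factor
#' normalization, per-cavity flexibility, and the protein's region frequency
#' vector.
#'
#' @param structure a `protein_structure` (radii need not be assigned yet).
#' @param config a [pipeline_config()].
#' @return a `protein_cavity_profile`: list with `protein_id`,
#'   `n_residues`, `cavity_set` (fully annotated), `residue_osps`,
#'   `normalized`, `freqs`.
#' @export
profile_structure <- function(structure, config = pipeline_config()) {
  if (any(is.na(structure$atoms$vdw_radius))) {
    structure <- assign_radii(structure, config$radii_set)
  }
  grid <- grid_spec(spacing = config$grid_spacing,
                    probe_radius = config$probe_radius)
  cs <- detect_cavities(structure, grid,
                        contact_margin = config$contact_margin,
                        min_lining = config$min_lining)
  osps <- compute_residue_osp(structure, dot_density = config$dot_density)
  cs <- annotate_osp(cs, osps)
  cs <- annotate_region(cs, bounds = config$region_bounds)
  normalized <- normalize_b_factors(structure)
  cs <- annotate_flexibility(cs, normalized)
  structure(list(protein_id = structure$structure_id,
                 n_residues = n_residues(structure),
                 cavity_set = cs, residue_osps = osps,
                 normalized = normalized,
                 freqs = region_frequencies(cs)),
            class = "protein_cavity_profile")
}

#' @export
print.protein_cavity_profile <- function(x, ...) {
  cat("protein_cavity_profile '", x$protein_id, "': ", x$n_residues,
      " residues, ", nrow(x$cavity_set$cavities), " cavities\n", sep = "")
  invisible(x)
}

#' Run the full two-group cavity comparison
#'
#' Orchestrates the whole analysis from a homolog-pair manifest: read and
#' filter pairs, profile every structure, summarize both groups, compare
#' region frequencies with one-tailed t statistics, and split cavity
#' volumes into small/intermediate/large classes. Pairing is preserved: a
#' structure failing to parse aborts the run unless `skip_errors = TRUE`,
#' which drops the whole pair so group sizes stay equal.
#'
#' @param manifest a pair manifest data frame (see [read_pair_manifest()])
#'   or the path to one. Paths in `thermo_file` / `meso_file` are resolved
#'   relative to `base_dir`.
#' @param config a [pipeline_config()].
#' @param base_dir directory the manifest's file paths are relative to.
#' @param out_dir optional output directory; when given, per-protein cavity
#'   tables, frequency tables, group summaries, the region comparison,
#'   the volume split and a JSON report with significance calls and every
#'   parameter are written there (tab-separated and JSON, 4-decimal
#'   rounding; byte-identical on rerun with identical inputs).
#' @param skip_errors drop unparseable pairs instead of aborting.
#' @return a `comparison_report`: list with `profiles_th`, `profiles_me`,
#'   `summary_th`, `summary_me`, `comparison`, `volume_split_th`,
#'   `volume_split_me`, `config`.
#' @export
run_compare <- function(manifest, config = pipeline_config(),
                        base_dir = ".", out_dir = NULL, skip_errors = FALSE) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- read_pair_manifest(manifest)
  }
  if (all(c("thermo_length", "meso_length") %in% names(manifest))) {
    manifest <- filter_pairs(manifest, config$min_length, config$min_identity)
  }
  if (!nrow(manifest)) stop("no pairs left to analyze", call. = FALSE)

  profiles_th <- list(); profiles_me <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pair <- tryCatch({
      th <- read_structure(file.path(base_dir, row$thermo_file),
                           chain = row$thermo_chain)
      me <- read_structure(file.path(base_dir, row$meso_file),
                           chain = row$meso_chain)
      list(th = profile_structure(th, config),
           me = profile_structure(me, config))
    }, error = function(e) {
      if (skip_errors) {
        warning("dropping pair ", i, " (", row$thermo_file, " / ",
                row$meso_file, "): ", conditionMessage(e), call. = FALSE)
        NULL
      } else {
        stop("pair ", i, " (", row$thermo_file, " / ", row$meso_file, "): ",
             conditionMessage(e), call. = FALSE)
      }
    })
    if (!is.null(pair)) {
      profiles_th[[length(profiles_th) + 1L]] <- pair$th
      profiles_me[[length(profiles_me) + 1L]] <- pair$me
    }
  }
  if (!length(profiles_th)) stop("every pair failed", call. = FALSE)

  summary_th <- build_group_summary(profiles_th, "thermophilic")
  summary_me <- build_group_summary(profiles_me, "mesophilic")
  comparison <- compare_groups(summary_th, summary_me, config$alpha_levels)
  vs_th <- volume_split(do.call(c, lapply(profiles_th,
                                          function(p) p$cavity_set$cavities$volume)))
  vs_me <- volume_split(do.call(c, lapply(profiles_me,
                                          function(p) p$cavity_set$cavities$volume)))
  report <- structure(list(profiles_th = profiles_th, profiles_me = profiles_me,
                           summary_th = summary_th, summary_me = summary_me,
                           comparison = comparison,
                           volume_split_th = vs_th, volume_split_me = vs_me,
                           config = config),
                      class = "comparison_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report: ", length(x$profiles_th), " pairs\n", sep = "")
  print(x$summary_th); print(x$summary_me); print(x$comparison)
  invisible(x)
}

# per-protein cavity table across a group, 4-decimal rounding for output
.group_cavity_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    cav <- p$cavity_set$cavities
    if (!nrow(cav)) return(NULL)
    data.frame(protein_id = p$protein_id, cav,
               lining_residues = vapply(p$cavity_set$lining, paste,
                                        character(1), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Write a comparison report bundle to disk
#'
#' Emits `cavities_<group>.tsv`, `frequencies_<group>.tsv`,
#' `comparison.tsv`, `volume_split.tsv`, and `report.json` (group
#' summaries, significance calls at every level, and the full parameter
#' set) under `out_dir`. Floating-point values are printed to 4 decimals.
#'
#' @param report a `comparison_report` from [run_compare()].
#' @param out_dir output directory, created if absent.
#' @return invisibly the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 4))
    df
  }
  files <- character(0)
  for (g in c("th", "me")) {
    profs <- report[[paste0("profiles_", g)]]
    tag <- if (g == "th") "thermo" else "meso"
    cav <- .group_cavity_table(profs)
    f <- file.path(out_dir, paste0("cavities_", tag, ".tsv"))
    utils::write.table(fmt(cav), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    fr <- do.call(rbind, lapply(profs, `[[`, "freqs"))
    f <- file.path(out_dir, paste0("frequencies_", tag, ".tsv"))
    utils::write.table(fmt(fr), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "comparison.tsv")
  utils::write.table(fmt(report$comparison$table), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  vs <- data.frame(group = c("thermophilic", "mesophilic"),
                   rbind(report$volume_split_th, report$volume_split_me))
  f <- file.path(out_dir, "volume_split.tsv")
  utils::write.table(vs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  summarize <- function(s) {
    list(group_name = s$group_name, n_proteins = s$n_proteins,
         n_cavities_total = s$n_cavities_total,
         n_residues_total = s$n_residues_total,
         cavities_per_protein = round(s$cavities_per_protein, 4),
         cavities_per_residue = round(s$cavities_per_residue, 4),
         mean_volume = round(s$mean_volume, 4),
         mean_area = round(s$mean_area, 4),
         mean_freq = round(s$mean_freq, 4), sd_freq = round(s$sd_freq, 4),
         flexibility_by_residue = round(s$flexibility_by_residue, 4),
         flexibility_by_cavity = round(s$flexibility_by_cavity, 4))
  }
  calls <- report$comparison$calls
  json <- list(
    thermophilic = summarize(report$summary_th),
    mesophilic = summarize(report$summary_me),
    t = stats::setNames(round(report$comparison$table$t, 4),
                        report$comparison$table$region),
    df = report$comparison$df,
    calls = stats::setNames(lapply(rownames(calls), function(r)
      as.list(calls[r, ])), rownames(calls)),
    parameters = unclass(report$config),
    package_version = as.character(utils::packageVersion("cavstat"))
  )
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
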
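# Three-letter codes of the 20 standard amino acids; only these participate
# in cavity geometry (no HETATM, waters, nucleic acids).
.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Element-keyed van der Waals radii (Angstrom). Values follow common
# surface-calculation practice; unknown elements fall back to `.default`.
.radii_tables <- list(
  default = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, .default = 1.70)
)

#' Residue identifiers of a structure's atoms
#'
#' Builds the `"chain:resno[ins]"` identifier used throughout the package to
#' key residues (lining lists, OSP tables, normalized B tables).
#'
#' @param structure a `protein_structure`.
#' @return character vector, one entry per atom.
#' @export
residue_ids <- function(structure) {
  a <- structure$atoms
  paste0(a$chain, ":", a$resno, ifelse(a$ins == "", "", a$ins))
}

#' Read a protein structure from PDB-format text
#'
#' Parses fixed-column ATOM records (via bio3d), keeps standard amino acids
#' only, drops HETATM records, waters, and hydrogens, and resolves alternate
#' locations by keeping the highest-occupancy altloc (ties broken by file
#' order).
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines
#'   (a single string with embedded newlines also works).
#' @param chain chain identifier to select, or `"all"` (default) for every
#'   chain.
#' @param structure_id identifier stored on the result; defaults to the file
#'   basename (or `"structure"` for in-memory text), plus the chain.
#' @return a `protein_structure`: a list with `structure_id` and `atoms`, a
#'   data frame with one row per heavy atom (`serial`, `name`, `element`,
#'   `resid`, `chain`, `resno`, `ins`, `x`, `y`, `z`, `b`, `occ`,
#'   `vdw_radius` -- `NA` until [assign_radii()] -- and `is_calpha`).
#' @seealso [assign_radii()], [write_pdb()]
#' @export
read_structure <- function(pdb, chain = "all", structure_id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    }
  } else {
    lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(structure_id)) structure_id <- "structure"
  }
  parsed <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB input: ", conditionMessage(e),
                             call. = FALSE)
  )
  at <- parsed$atom
  at$row <- seq_len(nrow(at))
  at <- at[at$type == "ATOM" & at$resid %in% .standard_aa, , drop = FALSE]
  if (!identical(chain, "all")) {
    at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("no ATOM records for chain selector '", chain, "'", call. = FALSE)
  }
  # element symbol: trust column 77-78 when present, else derive from the name
  ele <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  miss <- ele == ""
  if (any(miss)) {
    guess <- toupper(substr(trimws(at$elety[miss]), 1L, 1L))
    guess[grepl("^[0-9]", trimws(at$elety[miss]))] <- "H"
    ele[miss] <- guess
  }
  at$element <- ele
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no heavy atoms for chain selector '", chain, "'", call. = FALSE)
  }
  # altloc resolution: highest occupancy wins, ties to first in file
  at$ins2 <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, at$ins2, trimws(at$elety), sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, at$row)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$ins2, trimws(at$elety),
                             sep = "|")), , drop = FALSE]
  at <- at[order(at$row), , drop = FALSE]

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = at$element,
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    ins = at$ins2,
    x = at$x, y = at$y, z = at$z,
    b = ifelse(is.na(at$b), 0, at$b),
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms$vdw_radius <- NA_real_
  atoms$is_calpha <- atoms$name == "CA"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in PDB input", call. = FALSE)
  }
  new_protein_structure(atoms, paste0(structure_id,
                                      if (!identical(chain, "all")) paste0("_", chain) else ""))
}

new_protein_structure <- function(atoms, structure_id) {
  stopifnot(nrow(atoms) > 0L)
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat("protein_structure '", x$structure_id, "': ",
      length(unique(paste(a$chain, a$resno, a$ins))), " residues, ",
      nrow(a), " heavy atoms, chains: ",
      paste(unique(a$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Assign van der Waals radii to every atom
#'
#' @param structure a `protein_structure`.
#' @param radii_set name of a bundled radii table; currently `"default"`
#'   (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, fallback 1.70 Angstrom).
#' @return the structure with `atoms$vdw_radius` filled. Unknown elements get
#'   the table's fallback radius with a warning.
#' @export
assign_radii <- function(structure, radii_set = "default") {
  if (!radii_set %in% names(.radii_tables)) {
    stop("unknown radii set '", radii_set, "'", call. = FALSE)
  }
  tab <- .radii_tables[[radii_set]]
  ele <- structure$atoms$element
  r <- unname(tab[ele])
  unk <- is.na(r)
  if (any(unk)) {
    warning("unknown element(s) ", paste(unique(ele[unk]), collapse = ", "),
            "; using default radius ", tab[[".default"]], " A", call. = FALSE)
    r[unk] <- tab[[".default"]]
  }
  structure$atoms$vdw_radius <- r
  structure
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-column ATOM records that round-trip through
#' [read_structure()] (coordinates to 3 decimals, B factors to 2).
#'
#' @param structure a `protein_structure`.
#' @param file optional path; when `NULL` the PDB text is returned as a
#'   character vector of lines.
#' @return invisibly the lines written (or the lines themselves if
#'   `file = NULL`).
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atoms
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
    stop("coordinates overflow fixed PDB columns", call. = FALSE)
  }
  out <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = out,
    eleno = a$serial, elety = a$name, resid = a$resid, chain = a$chain,
    resno = a$resno, insert = ifelse(a$ins == "", NA, a$ins),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    o = a$occ, b = a$b, elesy = a$element
  )
  lines <- readLines(out)
  if (is.null(file)) unlink(out)
  invisible(lines)
}

#' Read a thermophilic/mesophilic pair manifest
#'
#' The manifest is a comma- or tab-separated table with columns
#' `thermo_file`, `thermo_chain`, `meso_file`, `meso_chain`,
#' `identity_percent`, and optionally `thermo_length` / `meso_length`.
#'
#' @param path manifest file.
#' @return data frame of pairs, one row per homolog pair.
#' @export
read_pair_manifest <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("thermo_file", "thermo_chain", "meso_file", "meso_chain",
            "identity_percent")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Filter homolog pairs by size and sequence identity
#'
#' Keeps pairs where both members have at least `min_length` residues and the
#' pair's sequence identity is at least `min_identity` percent; small or
#' weakly homologous pairs are dropped. Order is preserved and the filter is
#' idempotent.
#'
#' @param pairs data frame with `thermo_length`, `meso_length`,
#'   `identity_percent` columns (identity is manifest metadata, not computed
#'   here).
#' @param min_length minimum residue count per member (default 200).
#' @param min_identity minimum percent identity (default 35).
#' @return the retained rows of `pairs`.
#' @export
filter_pairs <- function(pairs, min_length = 200, min_identity = 35) {
  stopifnot(all(c("thermo_length", "meso_length", "identity_percent") %in%
                  names(pairs)))
  if (any(pairs$identity_percent < 0 | pairs$identity_percent > 100)) {
    stop("identity_percent outside [0, 100]", call. = FALSE)
  }
  keep <- pairs$thermo_length >= min_length &
    pairs$meso_length >= min_length &
    pairs$identity_percent >= min_identity
  pairs[keep, , drop = FALSE]
}

# number of distinct residues in a structure
n_residues <- function(structure) {
  length(unique(residue_ids(structure)))
}
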
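# Shared fixtures, all generated in code.

# Hollow shell with a single central void of free radius 4.0 A.
# Frozen oracle values for this exact fixture (seed-deterministic):
#   analytic probe-swept volume  4/3*pi*4^3 = 268.083 A^3
#   brute-force fine-grid flood fill at 0.2 A spacing = 267.608 A^3
shell_fixture <- function() {
  generate_structure(
    synthetic_structure_spec(shell_radii = c(2.0, 3.8, 5.7, 7.4),
                             void_centers = list(c(0, 0, 0)),
                             void_free_radii = 4.0, seed = 7),
    "shell")
}
SHELL_ANALYTIC_VOLUME <- 4 / 3 * pi * 4.0^3
SHELL_FINE_GRID_VOLUME <- 267.608

# compact close-packed cluster with no interior gap for a 1.4 A probe
solid_fixture <- function() {
  generate_structure(
    synthetic_structure_spec(shell_radii = c(0, 2.2, 4.2, 6.2), seed = 2),
    "solid")
}

# two disjoint voids separated by a solid wall
two_void_fixture <- function() {
  generate_structure(
    synthetic_structure_spec(
      shell_radii = c(0, 2.0, 3.6, 5.2, 6.8, 8.4, 10.0),
      void_centers = list(c(-3.5, 0, 0), c(3.5, 0, 0)),
      void_free_radii = c(2.2, 2.2), seed = 3),
    "twovoid")
}

# hand-written fixed-column PDB text: 3 residues on chain A plus records
# that must be filtered (HETATM ligand, water, hydrogen) and an altloc pair
pdb_text_fixture <- function() {
  c(
    "HEADER    TEST",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 14.00           C",
    "ATOM      4  CA  GLY A   2       3.800   2.000   1.000  1.00 20.00           C",
    "ATOM      5  HA  GLY A   2       4.100   2.300   1.200  1.00 20.00           H",
    "ATOM      6  CA AVAL A   3       6.000   3.000   2.000  0.40 30.00           C",
    "ATOM      7  CA BVAL A   3       6.100   3.000   2.000  0.60 31.00           C",
    "ATOM      8  CB  VAL A   3       6.500   4.400   2.000  1.00 32.00           C",
    "HETATM    9  O   HOH A 101      10.000  10.000  10.000  1.00 40.00           O",
    "HETATM   10 ZN    ZN A 102      12.000  12.000  12.000  1.00 15.00          ZN",
    "END"
  )
}

# minimal structure built directly from coordinates: one single-atom
# pseudo-residue per row, radii assigned, all C
atoms_structure <- function(xyz, b = NULL, id = "toy", radius = 1.7) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(b)) b <- seq(10, by = 5, length.out = n)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resid = "ALA",
    chain = "A", resno = seq_len(n), ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = b, occ = 1,
    vdw_radius = radius, is_calpha = TRUE, stringsAsFactors = FALSE)
  structure(list(structure_id = id, atoms = atoms),
            class = "protein_structure")
}
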
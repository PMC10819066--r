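# cavstat

Cavity location and flexibility statistics for protein thermostability
comparisons.

## What it does, and for whom

Interior cavities — empty spaces inside a folded protein that a 1.4 Å water
probe cannot reach from bulk solvent — influence both stability and
function. A recurring question in protein engineering is whether
thermophilic proteins and their mesophilic homologs place their cavities
differently in the fold (surface, boundary layer, or packed core) and
whether cavity-lining residues differ in flexibility. cavstat is for
structural bioinformaticians running exactly that comparison: it turns a
set of PDB structures plus a homolog-pair manifest into per-cavity
geometry, burial classification, normalized flexibility, and group-level
one-tailed t statistics.

The pipeline:

1. **Cavity detection** — a voxel center is probe-placeable iff it lies at
   least `r_vdw + r_probe` from every atom center; probe-placeable voxels
   6-connected to the box boundary are bulk solvent, the remaining
   components are interior cavities, and each cavity's volume is the
   probe-swept void (voxels within `r_probe` of a cavity voxel, outside
   all van der Waals spheres). Cavities keep at least 3 lining residues.
2. **Burial classification** — per-residue occluded surface packing (OSP):
   surface dots on each atom's van der Waals sphere cast normal rays,
   occluded within one water diameter (2.8 Å) at distance `L` with weight
   `1 − L/2.8`. A cavity's mean lining OSP maps to surface `[0, 0.250)`,
   boundary `[0.250, 0.500)`, or core `[0.500, 1]`.
3. **Flexibility** — per-chain z-scores of Cα B factors,
   `B' = (B − <B>)/σ`; cavity flexibility is the mean `B'` of lining
   residues, and region flexibility indices pool lining residues per
   region across a group.
4. **Group statistics** — per-protein region frequencies (summing to 1)
   are compared between groups with
   `t = (X_Th − X_Me) / sqrt(S²_Th/N_Th + S²_Me/N_Me)`,
   read one-tailed at `df = N_Th + N_Me − 2` against fixed critical levels
   (1.282 / 1.645 / 1.960 / 2.326 / 2.576 at α = 0.1 … 0.005).

A seeded synthetic-structure generator (concentric pseudo-atom shells with
carved voids of known geometry, plus a two-group frequency/flexibility
cohort sampler) makes every stage testable with no downloads.

## Worked example

Generate a hollow pseudo-protein with a central void of free radius
4.0 Å, detect and annotate its cavity:

```r
library(cavstat)

spec <- synthetic_structure_spec(shell_radii = c(2.0, 3.8, 5.7, 7.4),
                                 void_centers = list(c(0, 0, 0)),
                                 void_free_radii = 4.0, seed = 7)
st <- generate_structure(spec, "shell")$structure

cs <- detect_cavities(st, grid_spec(spacing = 0.4))
cs <- annotate_region(annotate_osp(cs, compute_residue_osp(st)))
cs <- annotate_flexibility(cs, normalize_b_factors(st))
cs$cavities[, c("volume", "surface_area", "n_lining", "mean_osp", "region")]
#>    volume surface_area n_lining mean_osp  region
#> 1 255.552     189.0133      121 0.069693 surface
```

The detected volume (255.6 ų at 0.4 Å spacing) approximates the analytic
probe-swept volume of the carved void, 4/3·π·4³ = 268.1 ų, within the
grid tolerance; an independent brute-force flood fill at 0.2 Å spacing
gives 267.6 ų, which `detect_cavities` reproduces exactly at the same
spacing. The 121 lining residues are the innermost wall shell; their mean
OSP of 0.07 classifies this thin-walled synthetic shell as a surface
cavity.

The statistical layer runs directly from a printed group-summary table
(means, SDs, and group sizes per region), with no structures needed:

```r
tab <- read.delim(system.file("extdata", "region_frequency_summary.tsv",
                              package = "cavstat"))
ttest_from_summary(tab)[, c("region", "t", "df")]
#>     region          t df
#> 1  surface -0.1295298 38
#> 2 boundary -1.7624549 38
#> 3     core  1.8388336 38
```

A negative t favors the mesophilic group (more boundary cavities), a
positive t the thermophilic group (more core cavities); at the one-tailed
0.05 level (|t| > 1.645) both are significant, while the surface region is
not.

For a full two-group run, `run_compare()` takes a manifest
(`thermo_file`, `thermo_chain`, `meso_file`, `meso_chain`,
`identity_percent`, optional lengths for filtering) and writes per-protein
cavity tables, group summaries, the region comparison, and a JSON report.

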
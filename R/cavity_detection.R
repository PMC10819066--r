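#' Grid specification for probe-based cavity detection
#'
#' @param spacing voxel edge length in Angstrom (default 0.6). Must be
#'   smaller than the probe radius or the grid cannot resolve the probe.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param padding margin beyond the atom bounding box, in Angstrom; default
#'   (`NULL`) is `2 * (probe_radius + max vdw radius)`, enough for bulk
#'   solvent to surround the structure.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(spacing = 0.6, probe_radius = 1.4, padding = NULL) {
  stopifnot(spacing > 0, probe_radius > 0)
  if (spacing >= probe_radius) {
    stop("grid spacing (", spacing, " A) must be smaller than the probe radius (",
         probe_radius, " A)", call. = FALSE)
  }
  structure(list(spacing = spacing, probe_radius = probe_radius,
                 padding = padding), class = "grid_spec")
}

# mark voxels whose center lies within `radius[i]` of atom center i.
# axes ax/ay/az are the grid coordinates; returns a logical vector over the
# nx*ny*nz linear index.
.mark_spheres <- function(ax, ay, az, cx, cy, cz, radius) {
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  blocked <- logical(nx * ny * nz)
  for (i in seq_along(cx)) {
    R <- radius[i]
    ix <- which(abs(ax - cx[i]) <= R)
    iy <- which(abs(ay - cy[i]) <= R)
    iz <- which(abs(az - cz[i]) <= R)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((ax[ix] - cx[i])^2, (ay[iy] - cy[i])^2, "+"),
                (az[iz] - cz[i])^2, "+")
    sel <- which(d2 <= R * R, arr.ind = TRUE)
    if (nrow(sel)) {
      lin <- ix[sel[, 1L]] + nx * (iy[sel[, 2L]] - 1L) +
        nx * ny * (iz[sel[, 3L]] - 1L)
      blocked[lin] <- TRUE
    }
  }
  blocked
}

# 6-connected flood fill over `open` voxels starting from `seeds` (linear
# indices); returns a logical "visited" vector. Vectorized frontier BFS.
.flood_fill <- function(open, seeds, nx, ny, nz) {
  visited <- logical(length(open))
  frontier <- seeds[open[seeds]]
  visited[frontier] <- TRUE
  nxy <- nx * ny
  while (length(frontier)) {
    idx0 <- frontier - 1L
    ix <- idx0 %% nx
    iy <- (idx0 %/% nx) %% ny
    iz <- idx0 %/% nxy
    nb <- c(frontier[ix > 0L] - 1L,
            frontier[ix < nx - 1L] + 1L,
            frontier[iy > 0L] - nx,
            frontier[iy < ny - 1L] + nx,
            frontier[iz > 0L] - nxy,
            frontier[iz < nz - 1L] + nxy)
    nb <- unique(nb)
    nb <- nb[open[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# linear indices of all voxels on the 6 faces of the grid box
.boundary_voxels <- function(nx, ny, nz) {
  nxy <- nx * ny
  face_xy <- as.vector(outer(seq_len(nx), (seq_len(ny) - 1L) * nx, "+"))
  face_xz <- as.vector(outer(seq_len(nx), (seq_len(nz) - 1L) * nxy, "+"))
  face_yz <- as.vector(outer((seq_len(ny) - 1L) * nx + 1L,
                             (seq_len(nz) - 1L) * nxy, "+"))
  unique(c(face_xy, face_xy + (nz - 1L) * nxy,
           face_xz, face_xz + (ny - 1L) * nx,
           face_yz, face_yz + nx - 1L))
}

#' Surface area of a voxel set
#'
#' Area of the boundary between the given voxels and everything else,
#' counted as exposed voxel faces times `spacing^2`. A grid approximation of
#' the true surface.
#'
#' @param voxels linear indices of the voxel set.
#' @param dims integer vector `c(nx, ny, nz)`.
#' @param spacing voxel edge length, Angstrom.
#' @return area in Angstrom^2.
#' @export
voxel_surface_area <- function(voxels, dims, spacing) {
  if (!length(voxels)) return(0)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nxy <- nx * ny
  inset <- logical(nx * ny * nz)
  inset[voxels] <- TRUE
  idx0 <- voxels - 1L
  ix <- idx0 %% nx
  iy <- (idx0 %/% nx) %% ny
  iz <- idx0 %/% nxy
  faces <- 0L
  count_exposed <- function(ok, off) {
    # neighbor outside the grid counts as exposed
    sum(!ok) + sum(!inset[voxels[ok] + off])
  }
  faces <- faces + count_exposed(ix > 0L, -1L)
  faces <- faces + count_exposed(ix < nx - 1L, +1L)
  faces <- faces + count_exposed(iy > 0L, -nx)
  faces <- faces + count_exposed(iy < ny - 1L, +nx)
  faces <- faces + count_exposed(iz > 0L, -nxy)
  faces <- faces + count_exposed(iz < nz - 1L, +nxy)
  faces * spacing^2
}

#' Detect interior cavities with a solvent probe on a uniform grid
#'
#' A voxel center is probe-placeable iff it lies at least
#' `vdw_radius + probe_radius` from every atom center. Probe-placeable
#' voxels 6-connected to the box boundary are bulk solvent; the remaining
#' probe-placeable connected components are interior cavities. Each cavity's
#' void volume is the probe-swept region: voxels within `probe_radius` of
#' any cavity voxel center and outside all atom van der Waals spheres.
#'
#' The reported `surface_area` is the exposed voxel-face area of the void
#' set (see [voxel_surface_area()]) scaled by 2/3, the standard correction
#' for the systematic 3/2 overestimate of axis-aligned face counting
#' relative to a smooth surface of isotropic orientation.
#'
#' Components are discarded unless they have at least `min_voxels`
#' probe-center voxels and at least `min_lining` lining residues (a residue
#' lines a cavity iff one of its heavy atoms is within
#' `vdw_radius + probe_radius + contact_margin` of a cavity voxel center).
#'
#' @param structure a `protein_structure` with radii assigned
#'   (see [assign_radii()]).
#' @param grid a [grid_spec()].
#' @param contact_margin lining-residue contact margin, Angstrom
#'   (default 0.5).
#' @param min_lining minimum number of lining residues per cavity
#'   (default 3).
#' @param min_voxels minimum probe-center component size in voxels
#'   (default 3); removes grid noise.
#' @return a `cavity_set`: list with `cavities` (data frame: `cavity_id`,
#'   `voxel_count`, `volume`, `surface_area`, `n_lining`, plus `mean_osp`,
#'   `region`, `flexibility` columns filled by later stages), `lining` (list
#'   of residue-id vectors), `voxels` / `void_voxels` (linear indices),
#'   `grid` (axes, dims, spacing), and `structure_id`.
#' @export
detect_cavities <- function(structure, grid = grid_spec(),
                            contact_margin = 0.5, min_lining = 3L,
                            min_voxels = 3L) {
  a <- structure$atoms
  if (nrow(a) < 4L) stop("structure has fewer than 4 atoms", call. = FALSE)
  if (any(is.na(a$vdw_radius))) {
    stop("radii not assigned; call assign_radii() first", call. = FALSE)
  }
  h <- grid$spacing
  probe <- grid$probe_radius
  if (h >= probe) {
    stop("grid spacing must be smaller than the probe radius", call. = FALSE)
  }
  pad <- if (is.null(grid$padding)) 2 * (probe + max(a$vdw_radius)) else grid$padding

  ax <- seq(min(a$x) - pad, max(a$x) + pad + h, by = h)
  ay <- seq(min(a$y) - pad, max(a$y) + pad + h, by = h)
  az <- seq(min(a$z) - pad, max(a$z) + pad + h, by = h)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  dims <- c(nx, ny, nz)

  blocked <- .mark_spheres(ax, ay, az, a$x, a$y, a$z, a$vdw_radius + probe)
  open <- !blocked
  solvent <- .flood_fill(open, .boundary_voxels(nx, ny, nz), nx, ny, nz)
  interior <- open & !solvent
  cavity_open <- which(interior)
  if (!length(cavity_open)) {
    return(.empty_cavity_set(structure$structure_id, ax, ay, az, h, probe))
  }

  # connected components of the interior probe-placeable voxels
  comps <- list()
  remaining <- interior
  while (any(remaining)) {
    seed <- which.max(remaining)
    comp <- .flood_fill(remaining, seed, nx, ny, nz)
    comps[[length(comps) + 1L]] <- which(comp)
    remaining <- remaining & !comp
  }

  vdw_blocked <- .mark_spheres(ax, ay, az, a$x, a$y, a$z, a$vdw_radius)

  # spherical dilation offsets for the probe-swept volume
  m <- floor(probe / h)
  og <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  og <- og[(og$dx^2 + og$dy^2 + og$dz^2) * h * h <= probe * probe, , drop = FALSE]
  offs <- as.integer(og$dx + nx * og$dy + nx * ny * og$dz)

  nxy <- nx * ny
  res <- list()
  for (comp in comps) {
    if (length(comp) < min_voxels) next
    lining <- .lining_residues(comp, a, ax, ay, az, nx, nxy, probe,
                               contact_margin)
    if (length(lining) < min_lining) next
    # dilate; offsets cannot leave the grid because padding >= probe
    void <- unique(as.vector(outer(comp, offs, "+")))
    void <- void[void >= 1L & void <= nx * ny * nz]
    void <- void[!vdw_blocked[void]]
    res[[length(res) + 1L]] <- list(
      voxels = comp, void_voxels = void, lining = lining,
      volume = length(void) * h^3,
      # 2/3 corrects the systematic 3/2 overestimate of axis-aligned
      # face counting (exact in expectation for isotropic surfaces)
      surface_area = voxel_surface_area(void, dims, h) * 2 / 3
    )
  }

  if (!length(res)) {
    return(.empty_cavity_set(structure$structure_id, ax, ay, az, h, probe))
  }
  cav <- data.frame(
    cavity_id = seq_along(res),
    voxel_count = vapply(res, function(r) length(r$void_voxels), integer(1)),
    volume = vapply(res, `[[`, numeric(1), "volume"),
    surface_area = vapply(res, `[[`, numeric(1), "surface_area"),
    n_lining = vapply(res, function(r) length(r$lining), integer(1)),
    mean_osp = NA_real_, region = NA_character_, flexibility = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(
    cavities = cav,
    lining = lapply(res, `[[`, "lining"),
    voxels = lapply(res, `[[`, "voxels"),
    void_voxels = lapply(res, `[[`, "void_voxels"),
    grid = list(ax = ax, ay = ay, az = az, dims = dims, spacing = h,
                probe_radius = probe),
    structure_id = structure$structure_id
  ), class = "cavity_set")
}

.empty_cavity_set <- function(id, ax, ay, az, h, probe) {
  structure(list(
    cavities = data.frame(cavity_id = integer(0), voxel_count = integer(0),
                          volume = numeric(0), surface_area = numeric(0),
                          n_lining = integer(0), mean_osp = numeric(0),
                          region = character(0), flexibility = numeric(0),
                          stringsAsFactors = FALSE),
    lining = list(), voxels = list(), void_voxels = list(),
    grid = list(ax = ax, ay = ay, az = az,
                dims = c(length(ax), length(ay), length(az)),
                spacing = h, probe_radius = probe),
    structure_id = id
  ), class = "cavity_set")
}

# residues with a heavy atom within (vdw + probe + margin) of any
# probe-center voxel of the component
.lining_residues <- function(comp, atoms, ax, ay, az, nx, nxy, probe, margin) {
  idx0 <- comp - 1L
  vx <- ax[(idx0 %% nx) + 1L]
  vy <- ay[((idx0 %/% nx) %% (nxy %/% nx)) + 1L]
  vz <- az[(idx0 %/% nxy) + 1L]
  cut <- atoms$vdw_radius + probe + margin
  # prefilter atoms by component bounding box
  cand <- which(atoms$x >= min(vx) - cut & atoms$x <= max(vx) + cut &
                  atoms$y >= min(vy) - cut & atoms$y <= max(vy) + cut &
                  atoms$z >= min(vz) - cut & atoms$z <= max(vz) + cut)
  if (!length(cand)) return(character(0))
  hit <- vapply(cand, function(i) {
    d2 <- (vx - atoms$x[i])^2 + (vy - atoms$y[i])^2 + (vz - atoms$z[i])^2
    any(d2 <= cut[i]^2)
  }, logical(1))
  ids <- paste0(atoms$chain[cand], ":", atoms$resno[cand],
                ifelse(atoms$ins[cand] == "", "", atoms$ins[cand]))
  sort(unique(ids[hit]))
}

#' Lining residues of a detected cavity
#'
#' Recomputes the lining set of one cavity under a chosen contact margin: a
#' residue lines the cavity iff any heavy atom center is within
#' `vdw_radius + probe_radius + contact_margin` of a cavity voxel center.
#' Monotone in the margin.
#'
#' @param cavity_set result of [detect_cavities()].
#' @param structure the same structure the cavities were detected on.
#' @param cavity_id which cavity.
#' @param contact_margin margin in Angstrom (default 0.5).
#' @return sorted character vector of residue identifiers.
#' @export
lining_residues <- function(cavity_set, structure, cavity_id,
                            contact_margin = 0.5) {
  g <- cavity_set$grid
  comp <- cavity_set$voxels[[cavity_id]]
  .lining_residues(comp, structure$atoms, g$ax, g$ay, g$az,
                   g$dims[1L], g$dims[1L] * g$dims[2L],
                   g$probe_radius, contact_margin)
}

#' @export
print.cavity_set <- function(x, ...) {
  cat("cavity_set for '", x$structure_id, "': ", nrow(x$cavities),
      " cavities (spacing ", x$grid$spacing, " A, probe ",
      x$grid$probe_radius, " A)\n", sep = "")
  if (nrow(x$cavities)) print(x$cavities, row.names = FALSE)
  invisible(x)
}
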
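# Independent brute-force oracles, implemented with different algorithms
# than the package (dense arrays + repeated-sweep relaxation instead of
# frontier BFS; plain loops instead of vectorized ray batches).

# Brute-force grid void finder. Returns list(n_cavities, volumes,
# atom_volume, box_volume). Flood fill by repeated neighbor sweeps over a
# 3-D logical array until a fixed point; components by seeded re-sweeps.
oracle_voids <- function(structure, spacing, probe = 1.4) {
  a <- structure$atoms
  pad <- 2 * (probe + max(a$vdw_radius))
  ax <- seq(min(a$x) - pad, max(a$x) + pad + spacing, by = spacing)
  ay <- seq(min(a$y) - pad, max(a$y) + pad + spacing, by = spacing)
  az <- seq(min(a$z) - pad, max(a$z) + pad + spacing, by = spacing)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  dist_mask <- function(extra) {
    m <- array(FALSE, c(nx, ny, nz))
    for (i in seq_len(nrow(a))) {
      R <- a$vdw_radius[i] + extra
      d2 <- outer(outer((ax - a$x[i])^2, (ay - a$y[i])^2, "+"),
                  (az - a$z[i])^2, "+")
      m <- m | (d2 <= R * R)
    }
    m
  }
  blocked <- dist_mask(probe)
  vdw <- dist_mask(0)
  open <- !blocked

  sweep_fill <- function(seed_mask, domain) {
    vis <- seed_mask & domain
    repeat {
      grown <- vis
      grown[-1, , ] <- grown[-1, , ] | vis[-nx, , ]
      grown[-nx, , ] <- grown[-nx, , ] | vis[-1, , ]
      grown[, -1, ] <- grown[, -1, ] | vis[, -ny, ]
      grown[, -ny, ] <- grown[, -ny, ] | vis[, -1, ]
      grown[, , -1] <- grown[, , -1] | vis[, , -nz]
      grown[, , -nz] <- grown[, , -nz] | vis[, , -1]
      grown <- grown & domain
      if (identical(grown, vis)) return(vis)
      vis <- grown
    }
  }
  edge <- array(FALSE, c(nx, ny, nz))
  edge[c(1, nx), , ] <- TRUE; edge[, c(1, ny), ] <- TRUE
  edge[, , c(1, nz)] <- TRUE
  solvent <- sweep_fill(edge, open)
  interior <- open & !solvent

  volumes <- numeric(0)
  remaining <- interior
  m <- floor(probe / spacing)
  ball <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  ball <- ball[(ball$dx^2 + ball$dy^2 + ball$dz^2) * spacing^2 <= probe^2, ]
  while (any(remaining)) {
    seed <- array(FALSE, c(nx, ny, nz))
    seed[which(remaining)[1]] <- TRUE
    comp <- sweep_fill(seed, remaining)
    idx <- which(comp, arr.ind = TRUE)
    void <- array(FALSE, c(nx, ny, nz))
    for (r in seq_len(nrow(ball))) {
      sh <- cbind(idx[, 1] + ball$dx[r], idx[, 2] + ball$dy[r],
                  idx[, 3] + ball$dz[r])
      ok <- sh[, 1] >= 1 & sh[, 1] <= nx & sh[, 2] >= 1 & sh[, 2] <= ny &
        sh[, 3] >= 1 & sh[, 3] <= nz
      void[sh[ok, , drop = FALSE]] <- TRUE
    }
    void <- void & !vdw
    volumes <- c(volumes, sum(void) * spacing^3)
    remaining <- remaining & !comp
  }
  list(n_cavities = length(volumes), volumes = volumes,
       atom_volume = sum(vdw) * spacing^3,
       box_volume = nx * ny * nz * spacing^3)
}

# Brute-force occluded-surface value for a set of single-atom residues,
# plain per-dot loops at arbitrary density. Returns OSP per atom index.
oracle_osp <- function(xyz, radii, dot_density, ray_limit = 2.8) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  osp <- numeric(n)
  for (i in seq_len(n)) {
    nd <- max(12L, round(dot_density * 4 * pi * radii[i]^2))
    u <- cavstat:::fibonacci_sphere(nd)
    wsum <- 0; kept <- 0L
    for (d in seq_len(nd)) {
      p <- xyz[i, ] + radii[i] * u[d, ]
      buried <- FALSE
      best <- Inf
      for (j in seq_len(n)) {
        if (j == i) next
        mv <- xyz[j, ] - p
        m2 <- sum(mv * mv)
        if (m2 < radii[j]^2) { buried <- TRUE; break }
        bq <- sum(mv * u[d, ])
        disc <- bq * bq - (m2 - radii[j]^2)
        if (disc >= 0) {
          t1 <- bq - sqrt(disc)
          if (t1 > 0 && t1 <= ray_limit) best <- min(best, t1)
        }
      }
      if (!buried) {
        kept <- kept + 1L
        if (is.finite(best)) wsum <- wsum + (1 - best / ray_limit)
      }
    }
    osp[i] <- if (kept > 0) min(1, max(0, wsum / kept)) else NA_real_
  }
  osp
}
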
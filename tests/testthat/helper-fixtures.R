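# Fixtures are generated in code: analytic volumes and lattice meshes with
# known geometry, used as oracles throughout the suite.

# binary-ish sphere volume (value `val` inside radius r, 0 outside)
mk_sphere_volume <- function(r, vox, val = 500, units = "vBMD") {
  n <- ceiling(2 * (r + 4 * vox) / vox)
  g <- (0:(n - 1)) * vox - (r + 4 * vox)
  arr <- array(0, c(n, n, n))
  arr[outer(g^2, outer(g^2, g^2, "+"), "+") < r^2] <- val
  density_volume(arr, vox, origin = rep(-(r + 4 * vox), 3), units = units)
}

# sphere with a cylindrical channel of radius chan_r drilled along z
mk_drilled_sphere_volume <- function(r, vox, chan_r, val = 500) {
  vol <- mk_sphere_volume(r, vox, val)
  n <- dim(vol$values)[1]
  g <- (0:(n - 1)) * vox + vol$origin[1]
  xy2 <- outer(g^2, g^2, "+")
  vol$values[array(rep(xy2 < chan_r^2, n), dim(vol$values))] <- 0
  vol
}

# closed lattice-of-revolution mesh: two pole vertices plus nz rings of nt
# points, radius given by radius_fun(z); same topology family as the phantom
mk_lattice_mesh <- function(radius_fun, length, nz = 80, nt = 32) {
  z <- seq(0, length, length.out = nz + 2)[2:(nz + 1)]
  r <- radius_fun(z)
  th <- 2 * pi * (0:(nt - 1)) / nt
  verts <- rbind(c(0, 0, 0), c(0, 0, length),
                 do.call(rbind, lapply(seq_len(nz), function(i)
                   cbind(r[i] * cos(th), r[i] * sin(th), z[i]))))
  ridx <- function(rr, j) 2L + (rr - 1L) * nt + ((j - 1L) %% nt) + 1L
  tris <- matrix(0L, 2L * (nrow(verts) - 2L), 3L)
  t <- 0L
  for (j in seq_len(nt)) {
    t <- t + 1L; tris[t, ] <- c(1L, ridx(1L, j + 1L), ridx(1L, j))
  }
  for (rr in seq_len(nz - 1L)) for (j in seq_len(nt)) {
    t <- t + 1L; tris[t, ] <- c(ridx(rr, j), ridx(rr, j + 1L), ridx(rr + 1L, j + 1L))
    t <- t + 1L; tris[t, ] <- c(ridx(rr, j), ridx(rr + 1L, j + 1L), ridx(rr + 1L, j))
  }
  for (j in seq_len(nt)) {
    t <- t + 1L; tris[t, ] <- c(2L, ridx(nz, j), ridx(nz, j + 1L))
  }
  labeled_mesh(verts, tris)
}

# unit-sphere-like mesh of controllable resolution
mk_sphere_mesh <- function(r = 1, nz = 60, nt = 32) {
  mk_lattice_mesh(function(z) sqrt(pmax(r^2 - (z - r)^2, 0)), 2 * r, nz, nt)
}

# independent trilinear oracle: direct 8-corner formula, one point at a time
trilinear_oracle <- function(vol, p) {
  g <- (p - vol$origin) / vol$voxel_size
  i <- floor(g)
  f <- g - i
  s <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    s <- s + w * vol$values[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1]
  }
  s
}

# direct voxel-masking probe oracle: mean over interior voxels whose centres
# lie inside the cylinder between entry and exit
cylinder_voxel_oracle <- function(vol, entry, exit, radius) {
  idx <- which(attr(vol, "inside"))
  ijk <- arrayInd(idx, dim(vol$values)) - 1L
  pts <- sweep(ijk * vol$voxel_size, 2, vol$origin, "+")
  d <- exit - entry
  L <- sqrt(sum(d^2))
  d <- d / L
  t <- as.vector(sweep(pts, 2, entry) %*% d)
  perp2 <- rowSums(sweep(pts, 2, entry)^2) - t^2
  sel <- t >= 0 & t <= L & perp2 <= radius^2
  mean(vol$values[idx[sel]])
}

# small corresponded phantom population, reused by shape/density tests
phantom_homology <- function(n, mode_sds = NULL, seed = 1,
                             points_per_segment = 10,
                             zones = NULL, voxel_size = 0.3,
                             n_theta = 32, n_rings = 40) {
  args <- list(n, seed = seed, zones = zones, voxel_size = voxel_size,
               n_theta = n_theta, n_rings = n_rings)
  if (!is.null(mode_sds)) args$mode_sds <- mode_sds
  pop <- do.call(generate_population, args)
  specs <- lapply(pop$specimens, function(s)
    list(mesh = s$mesh, landmarks = s$landmarks))
  ref <- select_reference(lapply(specs, function(s)
    resample_segments(s$landmarks, points_per_segment)))
  hom <- establish_homology(specs[[ref]], specs,
                            points_per_segment = points_per_segment)
  list(pop = pop, specs = specs, ref = ref, hom = hom)
}

rigid_rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
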
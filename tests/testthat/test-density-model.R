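test_that("trilinear sampling is exact at nodes and matches the 8-corner oracle", {
  set.seed(5)
  vol <- density_volume(array(runif(512), c(8, 8, 8)), 1, units = "vBMD")
  # voxel-centre exactness
  expect_identical(trilinear_sample(vol, matrix(c(3, 4, 5), 1)),
                   vol$values[4, 5, 6])
  # cell centre equals the mean of the 8 corners
  expect_equal(trilinear_sample(vol, matrix(c(2.5, 3.5, 4.5), 1)),
               mean(vol$values[3:4, 4:5, 5:6]))
  pts <- matrix(runif(150) * 6.9, 50, 3)
  expect_lt(max(abs(trilinear_sample(vol, pts) -
                    apply(pts, 1, trilinear_oracle, vol = vol))), 1e-12)
  # linear fields are reproduced exactly
  g <- 0:7
  lin <- outer(g, outer(2 * g, -0.5 * g, "+"), "+")
  lv <- density_volume(array(lin, c(8, 8, 8)), 1, units = "vBMD")
  f <- function(p) p[, 1] + 2 * p[, 2] - 0.5 * p[, 3]
  expect_lt(max(abs(trilinear_sample(lv, pts) - f(pts))), 1e-12)
  # outside the voxel-centre hull -> NA sentinel
  expect_true(is.na(trilinear_sample(vol, matrix(c(-1, 3, 3), 1))))
})

test_that("masked trilinear sampling renormalizes over valid corners", {
  vol <- density_volume(array(10, c(4, 4, 4)), 1, units = "vBMD")
  msk <- array(TRUE, c(4, 4, 4))
  msk[1, , ] <- FALSE
  vol$values[1, , ] <- 0
  # plain sampling blends toward the zeroed slab; masked sampling does not
  p <- matrix(c(0.25, 2, 2), 1)
  expect_lt(trilinear_sample(vol, p), 10)
  expect_equal(trilinear_sample(vol, p, mask = msk), 10)
  # fully masked neighbourhoods return NA
  expect_true(is.na(trilinear_sample(vol, matrix(c(0, 2, 2), 1),
                                     mask = array(FALSE, c(4, 4, 4)))))
})

test_that("reference grid classification matches parity and volume oracles", {
  # unit cube in generic position (slightly rotated so no grid node falls
  # exactly on a face; the grid lattice is anchored to the bounding box)
  R <- rigid_rotation_z(4) %*%
    matrix(c(1, 0, 0, 0, cos(0.05), sin(0.05), 0, -sin(0.05), cos(0.05)), 3, 3)
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  cube <- labeled_mesh(
    corners %*% R,
    rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
          c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
          c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)))
  g <- build_reference_grid(cube, 0.25)
  # brute-force parity oracle: nodes strictly inside the back-rotated cube
  idx <- which(array(TRUE, g$dim))
  nodes <- sweep((arrayInd(idx, g$dim) - 1) * g$spacing, 2, g$origin, "+")
  back <- nodes %*% t(R)
  oracle_inside <- apply(back, 1, function(p) all(p > 0) && all(p < 1))
  expect_identical(sum(g$inside), sum(oracle_inside))
  expect_identical(as.vector(g$inside), unname(oracle_inside))
  # sphere volume from inside-node count
  sp <- mk_sphere_mesh(5, nz = 80, nt = 48)
  gs <- build_reference_grid(sp, 0.25)
  expect_lt(abs(gs$n_inside * 0.25^3 / (4 / 3 * pi * 125) - 1), 0.03)
  # translation equivariance: the mask is mesh-relative
  sp2 <- labeled_mesh(sweep(sp$vertices, 2, c(3.2, -1.7, 9.4), "+"),
                      sp$triangles, sp$region)
  gs2 <- build_reference_grid(sp2, 0.25)
  expect_identical(gs2$inside, gs$inside)
  expect_error(build_reference_grid(sp, -1), "> 0")
})

make_constant_population <- function(values, n_theta = 16, n_rings = 12) {
  ph <- generate_phantom_mesh(phantom_params(), n_theta, n_rings)
  vols <- lapply(values, function(c0) {
    zp <- zone_profile(peripheral_mean = c0 + 2e-9,
                       intermediate_means = c(medial = c0 + 1e-9,
                                              proximal = c0 + 1e-9,
                                              distal = c0 + 1e-9,
                                              lateral = c0 + 1e-9),
                       centre_mean = c0, noise_sd = 0)
    generate_phantom_volume(ph$mesh, zp, voxel_size = 0.5, seed = 1)
  })
  hom <- structure(list(triangulation = ph$mesh$triangles,
                        region = ph$mesh$region,
                        vertices = rep(list(ph$mesh$vertices), length(values))),
                   class = "homologous_mesh_set")
  grid <- build_reference_grid(ph$mesh, 0.5)
  list(grid = grid, hom = hom, vols = vols, mesh = ph$mesh)
}

test_that("averaging constant-interior specimens recovers the constants", {
  cp <- make_constant_population(c(300, 300))
  mod <- build_averaged_model(cp$grid, cp$hom, cp$vols,
                              mean_vertices = cp$mesh$vertices,
                              n_controls = 100)
  vals <- mod$mean_vbmd[mod$inside & mod$n_count == 2]
  expect_lt(max(abs(vals - 300)), 1e-6)
  # two different constants average linearly
  cp2 <- make_constant_population(c(200, 400))
  mod2 <- build_averaged_model(cp2$grid, cp2$hom, cp2$vols,
                               mean_vertices = cp2$mesh$vertices,
                               n_controls = 100)
  vals2 <- mod2$mean_vbmd[mod2$inside & mod2$n_count == 2]
  expect_lt(max(abs(vals2 - 300)), 1e-6)
})

test_that("averaged model is permutation-invariant and linear in the fields", {
  cp <- make_constant_population(c(200, 400))
  mod_ab <- build_averaged_model(cp$grid, cp$hom, cp$vols,
                                 mean_vertices = cp$mesh$vertices,
                                 n_controls = 100)
  mod_ba <- build_averaged_model(cp$grid, cp$hom, rev(cp$vols),
                                 mean_vertices = cp$mesh$vertices,
                                 n_controls = 100)
  expect_equal(mod_ab$mean_vbmd, mod_ba$mean_vbmd)
  vols2 <- lapply(cp$vols, function(v) { v$values <- 2 * v$values; v })
  mod2 <- build_averaged_model(cp$grid, cp$hom, vols2,
                               mean_vertices = cp$mesh$vertices,
                               n_controls = 100)
  expect_equal(mod2$mean_vbmd, 2 * mod_ab$mean_vbmd, tolerance = 1e-12)
})

test_that("zone segmentation matches analytic shells and partitions exactly", {
  sp <- mk_sphere_mesh(10, nz = 100, nt = 64)
  grid <- build_reference_grid(sp, 0.4)
  mod <- structure(list(origin = grid$origin, spacing = grid$spacing,
                        dim = grid$dim, inside = grid$inside,
                        mean_vbmd = array(1, grid$dim), n_specimens = 1),
                   class = "averaged_density_model")
  mod <- segment_zones(mod, sp, peripheral_depth = 2, centre_start_depth = 5)
  zs <- zone_stats(mod)
  shell <- function(r0, r1) 4 / 3 * pi * (r1^3 - r0^3)
  expect_equal(zs$volume_mm3[zs$zone == "peripheral"], shell(8, 10),
               tolerance = 0.05 * shell(8, 10))
  expect_equal(sum(zs$volume_mm3[grepl("intermediate", zs$zone)]), shell(5, 8),
               tolerance = 0.05 * shell(5, 8))
  expect_equal(zs$volume_mm3[zs$zone == "centre"], shell(0, 5),
               tolerance = 0.05 * shell(0, 5))
  # exact partition of interior nodes and exact volume conservation
  expect_identical(sum(zs$n_nodes), sum(grid$inside))
  expect_equal(sum(zs$volume_mm3), sum(grid$inside) * grid$spacing^3,
               tolerance = 1e-9)
  # an over-deep centre start empties the centre zone with a warning
  expect_warning(segment_zones(mod, sp, peripheral_depth = 2,
                               centre_start_depth = 12), "empty")
  expect_error(segment_zones(mod, sp, peripheral_depth = 3,
                             centre_start_depth = 2), "peripheral_depth")
})

test_that("zone statistics on a constant model have zero spread", {
  cp <- make_constant_population(c(250, 250))
  mod <- build_averaged_model(cp$grid, cp$hom, cp$vols,
                              mean_vertices = cp$mesh$vertices,
                              n_controls = 100)
  mod <- segment_zones(mod, cp$mesh, peripheral_depth = 1,
                       centre_start_depth = 3)
  zs <- zone_stats(mod)
  nz <- zs[zs$n_nodes > 0 & !is.na(zs$mean), ]
  expect_true(all(abs(nz$mean - 250) < 1e-6))
  expect_true(all(nz$sd < 1e-6))
})

test_that("probing a constant field returns the constant at every station", {
  cv <- density_volume(array(100, c(10, 10, 10)), 1, units = "vBMD")
  pr <- probe_pathway(cv, c(1, 1, 1), c(8, 8, 8), diameter = 2)
  expect_true(all(abs(pr$profile$mean_vbmd - 100) < 1e-9))
  expect_equal(pr$summary$mean, 100)
  # per-station means lie within the station sample range by construction
  expect_true(all(pr$profile$mean_vbmd >= pr$summary$min - 1e-12))
  expect_error(probe_pathway(cv, c(1, 1, 1), c(1, 1, 1)), "differ")
  expect_error(probe_pathway(cv, c(50, 50, 50), c(60, 60, 60)), "outside")
})

test_that("line-mode probing reproduces a linear ramp exactly", {
  g <- 0:9
  ramp <- density_volume(array(outer(g, outer(0 * g, 0 * g, "+"), "+"),
                               c(10, 10, 10)), 1, units = "vBMD")
  pr <- probe_pathway(ramp, c(1, 4, 4), c(8, 4, 4), n_stations = 15,
                      mode = "line")
  expect_lt(max(abs(pr$profile$mean_vbmd -
                    seq(1, 8, length.out = 15))), 1e-9)
})

test_that("probe profiles are invariant under a lattice rotation of volume and path", {
  ph <- generate_phantom_mesh(phantom_params(), n_theta = 16, n_rings = 12)
  vol <- generate_phantom_volume(ph$mesh, zone_profile(noise_sd = 0),
                                 voxel_size = 0.5, seed = 1)
  # rotate volume and path 90 degrees about z: (x,y,z) -> (-y,x,z)
  d <- dim(vol$values)
  rot_vals <- aperm(vol$values, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  rot <- density_volume(rot_vals, vol$voxel_size,
                        origin = c(-(vol$origin[2] + (d[2] - 1) * vol$voxel_size),
                                   vol$origin[1], vol$origin[3]),
                        units = "vBMD")
  attr(rot, "inside") <- array(aperm(attr(vol, "inside"),
                                     c(2, 1, 3))[d[2]:1, , ], dim(rot_vals))
  rotp <- function(p) c(-p[2], p[1], p[3])
  e <- c(0, 0, 2); x <- c(0, 0, 22)
  p1 <- probe_pathway(vol, e, x, diameter = 3, n_stations = 20)
  p2 <- probe_pathway(rot, rotp(e), rotp(x), diameter = 3, n_stations = 20)
  expect_equal(p2$summary$mean, p1$summary$mean, tolerance = 1e-6)
})

test_that("peripheral pathways carry more bone mineral than central ones", {
  ph <- generate_phantom_mesh(phantom_params())
  vol <- generate_phantom_volume(ph$mesh, zone_profile(noise_sd = 0),
                                 voxel_size = 0.3, seed = 1)
  paths <- carposhape:::default_probe_paths(ph$mesh, margin_depth = 0.5)
  pc <- probe_pathway(vol, paths$central$entry, paths$central$exit, diameter = 3)
  pp <- probe_pathway(vol, paths$peripheral$entry, paths$peripheral$exit,
                      diameter = 3)
  expect_gt(pp$summary$mean, pc$summary$mean)
  # both within 2% of the direct voxel-masking oracle
  oc <- cylinder_voxel_oracle(vol, paths$central$entry, paths$central$exit, 1.5)
  op <- cylinder_voxel_oracle(vol, paths$peripheral$entry,
                              paths$peripheral$exit, 1.5)
  expect_lt(abs(pc$summary$mean / oc - 1), 0.02)
  expect_lt(abs(pp$summary$mean / op - 1), 0.02)
})

test_that("phantom population density recovery: machinery is exact for a homogeneous population", {
  zones <- zone_profile(noise_sd = 0)
  ph <- phantom_homology(3, c(length = 0), seed = 5, zones = zones,
                         voxel_size = 0.4, n_theta = 16, n_rings = 16)
  al <- procrustes_align(ph$hom)
  mean_mesh <- labeled_mesh(al$mean_vertices, al$triangulation, al$region)
  grid <- build_reference_grid(mean_mesh, 0.4)
  mod <- build_averaged_model(grid, ph$hom,
                              lapply(ph$pop$specimens, `[[`, "volume"),
                              mean_vertices = al$mean_vertices,
                              n_controls = 200)
  mod <- segment_zones(mod, mean_mesh)
  zs <- zone_stats(mod)
  gen <- c(zones$peripheral_mean,
           zones$intermediate_means[c("medial", "proximal", "distal", "lateral")],
           zones$centre_mean)
  expect_lt(max(abs(zs$mean / gen - 1)), 0.02)
})
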
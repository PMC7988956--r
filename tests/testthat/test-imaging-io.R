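test_that("non-osseous clamping zeroes negative HU and nothing else", {
  v <- density_volume(array(c(-100, 0, 250, rep(1, 5)), c(2, 2, 2)), 1)
  out <- clamp_nonosseous(v)
  expect_identical(out$values[1:3], c(0, 0, 250))
  allneg <- clamp_nonosseous(density_volume(array(-1, c(3, 3, 3)), 1))
  expect_identical(sum(allneg$values), 0)
  nonneg <- density_volume(array(5, c(2, 2, 2)), 1)
  expect_identical(clamp_nonosseous(nonneg)$values, nonneg$values)
  vb <- density_volume(array(1, c(2, 2, 2)), 1, units = "vBMD")
  expect_error(clamp_nonosseous(vb), "HU")
})

test_that("HU to vBMD calibration is the stated affine map", {
  v <- density_volume(array(c(100, 200, 0, 0, 0, 0, 0, 0), c(2, 2, 2)), 1,
                      calibration = c(slope = 0.5, intercept = 10))
  out <- hu_to_vbmd(v)
  expect_identical(out$units, "vBMD")
  expect_equal(out$values[1:2], c(60, 110))
  expect_equal(out$values[3], 10)  # 0 HU maps to the intercept
  ident <- hu_to_vbmd(density_volume(array(7, c(2, 2, 2)), 1,
                                     calibration = c(slope = 1, intercept = 0)))
  expect_equal(as.vector(ident$values), rep(7, 8))
  nocal <- density_volume(array(1, c(2, 2, 2)), 1)
  expect_error(hu_to_vbmd(nocal), "calibration")
  # processing order: clamping acts on HU before calibration, so a positive
  # intercept bounds the calibrated background from below
  neg <- density_volume(array(c(-50, 80, rep(0, 6)), c(2, 2, 2)), 1,
                        calibration = c(slope = 0.5, intercept = 10))
  expect_gte(min(hu_to_vbmd(clamp_nonosseous(neg))$values), 10)
})

test_that("mirroring is an involution that preserves geometry and chirality", {
  ph <- generate_phantom_mesh(phantom_params())
  m <- ph$mesh
  expect_identical(mirror_to_right(m, "right"), m)
  twice <- mirror_to_right(mirror_to_right(m, "left"), "left")
  expect_equal(twice$vertices, m$vertices)
  expect_identical(twice$triangles, m$triangles)
  # signed-volume oracle: reflection plus winding flip keeps volume positive
  mir <- mirror_to_right(m, "left")
  expect_equal(mesh_volume(mir), mesh_volume(m), tolerance = 1e-9)
  # single-vertex check about the x = 0 plane
  tri <- labeled_mesh(rbind(c(3, 1, 2), c(4, 0, 0), c(3, 2, 0), c(5, 1, 1)),
                      rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3)))
  expect_equal(mirror_to_right(tri, "left", plane_x = 0)$vertices[1, ],
               c(-3, 1, 2))
  # inter-landmark distances are preserved exactly
  hm <- do.call(rbind, ph$landmarks$homologous)
  hm_m <- hm
  hm_m[, 1] <- -hm_m[, 1]
  expect_equal(as.matrix(dist(hm_m)), as.matrix(dist(hm)), tolerance = 1e-12)
  # volumes: mirroring twice restores the array exactly
  v <- generate_phantom_volume(ph$mesh, zone_profile(noise_sd = 0),
                               voxel_size = 0.6, seed = 1)
  expect_identical(mirror_to_right(mirror_to_right(v, "left"), "left")$values,
                   v$values)
})

test_that("volumes round-trip through MHD and NIfTI", {
  v <- density_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), 0.3,
                      origin = c(-1, 2, 0.5),
                      calibration = c(slope = 0.7, intercept = 3))
  d <- withr::local_tempdir()
  write_volume(v, file.path(d, "v.mhd"))
  r <- read_volume(file.path(d, "v.mhd"))
  expect_identical(r$values, v$values)
  expect_identical(r$origin, v$origin)
  expect_identical(r$calibration, v$calibration)
  expect_identical(r$units, "HU")
  write_volume(v, file.path(d, "v.nii.gz"))
  rn <- read_volume(file.path(d, "v.nii.gz"))
  expect_equal(array(as.numeric(rn$values), dim(rn$values)), v$values,
               tolerance = 1e-6)
  expect_equal(rn$voxel_size, 0.3, tolerance = 1e-6)
})

test_that("meshes and landmarks round-trip through PLY and JSON", {
  ph <- generate_phantom_mesh(phantom_params(), n_theta = 16, n_rings = 12)
  d <- withr::local_tempdir()
  write_ply(ph$mesh, file.path(d, "m.ply"))
  r <- read_ply(file.path(d, "m.ply"))
  expect_identical(r$triangles, ph$mesh$triangles)
  expect_identical(r$region, ph$mesh$region)
  expect_equal(r$vertices, ph$mesh$vertices, tolerance = 1e-8)
  write_landmarks(ph$landmarks, file.path(d, "lm.json"))
  lr <- read_landmarks(file.path(d, "lm.json"))
  expect_identical(names(lr$homologous), names(ph$landmarks$homologous))
  expect_equal(do.call(rbind, lr$homologous),
               do.call(rbind, ph$landmarks$homologous))
  expect_equal(lr$segments[[2]]$points, ph$landmarks$segments[[2]]$points,
               ignore_attr = TRUE)
  expect_identical(lr$segments[[2]]$from, "proximal_pole")
})

test_that("threshold segmentation recovers an analytic sphere surface", {
  vol <- mk_sphere_volume(8, 0.25)
  m <- segment_to_mesh(vol, 250)
  expect_true(is_closed_mesh(m))
  expect_identical(mesh_genus(m), 0L)
  expect_lt(abs(mesh_area(m) / (4 * pi * 64) - 1), 0.03)
  expect_true(all(m$region == "bone"))
})

test_that("segmentation rejects empty thresholds and keeps the largest blob", {
  vol <- mk_sphere_volume(5, 0.4)
  expect_error(segment_to_mesh(vol, 600), "threshold")
  # add a second, smaller blob: only the larger one is meshed
  n <- dim(vol$values)[1]
  g <- (0:(n - 1)) * 0.4 + vol$origin[1]
  small <- outer((g - 7)^2, outer(g^2, g^2, "+"), "+") < 1.5^2
  vol$values[small] <- 500
  m <- segment_to_mesh(vol, 250)
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 125) - 1), 0.05)
})

test_that("segmented volume converges to the analytic volume with resolution", {
  true_v <- 4 / 3 * pi * 5^3
  err <- vapply(c(0.5, 0.25), function(vox)
    abs(mesh_volume(segment_to_mesh(mk_sphere_volume(5, vox), 250)) - true_v),
    numeric(1))
  expect_lt(err[2], err[1])
})

test_that("morphological closing removes narrow channels and reports wide ones", {
  dm <- segment_to_mesh(mk_drilled_sphere_volume(8, 0.125, 0.25), 250)
  expect_identical(mesh_genus(dm), 1L)
  cl <- close_foramina(dm, max_hole_diameter = 1)
  expect_identical(mesh_genus(cl), 0L)
  expect_null(attr(cl, "unclosed_genus"))
  wide <- segment_to_mesh(mk_drilled_sphere_volume(8, 0.125, 1), 250)
  expect_warning(cl2 <- close_foramina(wide, max_hole_diameter = 1), "remain")
  expect_identical(attr(cl2, "unclosed_genus"), mesh_genus(cl2))
  expect_gt(mesh_genus(cl2), 0L)
})

test_that("closing a hole-free mesh is a near identity", {
  sp <- segment_to_mesh(mk_sphere_volume(8, 0.25), 250)
  cl <- close_foramina(sp, max_hole_diameter = 1)
  expect_true(is_closed_mesh(cl))
  expect_identical(mesh_genus(cl), 0L)
  expect_lt(abs(mesh_volume(cl) - mesh_volume(sp)) / mesh_volume(sp), 0.005)
})
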
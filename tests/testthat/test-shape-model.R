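make_two_copy_set <- function() {
  ph <- generate_phantom_mesh(phantom_params(), n_theta = 16, n_rings = 16)
  v <- ph$mesh$vertices
  R <- rigid_rotation_z(30)
  structure(list(triangulation = ph$mesh$triangles, region = ph$mesh$region,
                 vertices = list(v, sweep(v %*% R, 2, c(5, -3, 2), "+"))),
            class = "homologous_mesh_set")
}

test_that("GPA removes rigid motions between identical shapes", {
  hs <- make_two_copy_set()
  al <- procrustes_align(hs)
  rmsd <- sqrt(mean((al$vertices[[1]] - al$vertices[[2]])^2))
  expect_lt(rmsd, 1e-6)
  expect_true(al$converged)
  # mean equals the (centred) shape
  expect_equal(al$mean_vertices, al$vertices[[1]], tolerance = 1e-6)
})

test_that("GPA preserves centroid size exactly and is idempotent", {
  ph <- phantom_homology(8, c(length = 5, dorsal_width = 1.25), seed = 17)
  before <- vapply(ph$hom$vertices, centroid_size, numeric(1))
  al <- procrustes_align(ph$hom)
  after <- vapply(al$vertices, centroid_size, numeric(1))
  expect_lt(max(abs(before - after)), 1e-9)
  # mean is centred at the origin
  expect_lt(max(abs(colMeans(al$mean_vertices))), 1e-9)
  # realigning an aligned set moves nothing
  al2 <- procrustes_align(al)
  expect_lt(max(abs(al2$vertices[[3]] - al$vertices[[3]])), 1e-8)
})

test_that("PCA recovers a single latent length mode", {
  ph <- phantom_homology(15, c(length = 5), seed = 3)
  model <- fit_shape_pca(procrustes_align(ph$hom))
  expect_gt(model$variance_fractions[1], 0.95)
  expect_gt(abs(cor(model$scores[, 1], ph$pop$params_table$length)), 0.99)
})

test_that("PCA model is orthonormal, normalized and lossless", {
  ph <- phantom_homology(8, c(length = 5, dorsal_width = 1.25,
                              bend_angle = 4), seed = 19)
  al <- procrustes_align(ph$hom)
  model <- fit_shape_pca(al)
  expect_equal(sum(model$variance_fractions), 1, tolerance = 1e-9)
  G <- t(model$modes) %*% model$modes
  expect_lt(max(abs(G - diag(ncol(model$modes)))), 1e-8)
  # full reconstruction of every training specimen
  for (i in seq_along(al$vertices))
    expect_lt(max(abs(reconstruct_specimen(model, i) - al$vertices[[i]])), 1e-6)
})

test_that("identical shapes give a degenerate zero-variance model", {
  ph <- phantom_homology(4, c(length = 0), seed = 2, points_per_segment = 6,
                         n_theta = 16, n_rings = 12)
  model <- fit_shape_pca(procrustes_align(ph$hom))
  expect_true(model$degenerate)
  expect_lt(sum(model$mode_variances), 1e-12)
})

test_that("shape synthesis is linear about the mean", {
  ph <- phantom_homology(10, c(length = 5), seed = 23)
  model <- fit_shape_pca(procrustes_align(ph$hom))
  expect_equal(synthesize_shape(model, 1, 0)$vertices, model$mean_vertices)
  up <- synthesize_shape(model, 1, 2)$vertices - model$mean_vertices
  dn <- synthesize_shape(model, 1, -2)$vertices - model$mean_vertices
  expect_equal(up, -dn)
  # +/- 2 SD length contrast matches 4 latent SDs of length
  len <- function(v) {
    ax <- principal_axes(v)
    diff(range(sweep(v, 2, ax$centre) %*% ax$axes[, 1]))
  }
  contrast <- len(synthesize_shape(model, 1, 2)$vertices) -
              len(synthesize_shape(model, 1, -2)$vertices)
  expect_equal(contrast, 4 * sd(ph$pop$params_table$length), tolerance = 0.05)
  expect_error(synthesize_shape(model, ncol(model$modes) + 1, 1), "mode")
})

test_that("morphometrics match analytic oracles on canonical solids", {
  # cylinder with a cosine waist necking from radius 5 to 4 at mid-length
  cyl <- mk_lattice_mesh(function(z) 5 - 0.5 * (1 + cos(2 * pi * (z / 26 - 0.5))),
                         26, nz = 150, nt = 48)
  mm <- measure_morphometrics(cyl)
  expect_equal(mm$length, 26, tolerance = 1e-6)
  expect_equal(mm$waist_diameters[1], 8, tolerance = 0.01 * 8)
  expect_equal(mm$waist_diameters[2], 8, tolerance = 0.01 * 8)
  # unit sphere: total area within 2% of 4 pi, waist diameters near 2
  sp <- mk_sphere_mesh(1, nz = 80, nt = 48)
  ms <- measure_morphometrics(sp)
  expect_lt(abs(ms$total_area / (4 * pi) - 1), 0.02)
  expect_equal(ms$waist_diameters, c(2, 2), tolerance = 0.02)
  expect_equal(ms$total_area, sum(ms$region_areas), tolerance = 1e-6)
})

test_that("morphometrics are invariant under mirroring", {
  ph <- generate_phantom_mesh(phantom_params())
  m1 <- measure_morphometrics(ph$mesh)
  m2 <- measure_morphometrics(mirror_to_right(ph$mesh, "left"))
  for (f in c("length", "waist_area", "total_area", "dorsal_width"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-9)
  expect_equal(m1$waist_diameters, m2$waist_diameters, tolerance = 1e-9)
  expect_equal(m1$region_areas, m2$region_areas, tolerance = 1e-9)
})

test_that("waist diameters are bounded by pole-level diameters", {
  ph <- generate_phantom_mesh(phantom_params(bend_angle = 0))
  mm <- measure_morphometrics(ph$mesh)
  # lobe diameters exceed the waist diameters by construction
  expect_lt(mm$waist_diameters[1],
            2 * max(phantom_params()$proximal_radius,
                    phantom_params()$distal_radius) + 1e-9)
  expect_gt(mm$waist_diameters[2], 0)
})

test_that("population statistics match hand values and a streaming oracle", {
  s <- population_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_match(s$formatted, "2.0 ± 1.0 \\(1.0-3.0\\)")
  expect_equal(population_stats(rep(4, 6))$sd, 0)
  # Welford streaming oracle on 1000 random values
  set.seed(8)
  x <- rnorm(1000, 50, 9)
  n <- 0; mu <- 0; m2 <- 0
  for (v in x) {
    n <- n + 1
    d <- v - mu
    mu <- mu + d / n
    m2 <- m2 + d * (v - mu)
  }
  s2 <- population_stats(x)
  expect_equal(s2$mean, mu, tolerance = 1e-10)
  expect_equal(s2$sd, sqrt(m2 / (n - 1)), tolerance = 1e-10)
})

test_that("mean-model descriptors differ from means of per-specimen descriptors", {
  ph <- phantom_homology(8, c(length = 5, dorsal_width = 1.25), seed = 29)
  al <- procrustes_align(ph$hom)
  model <- fit_shape_pca(al)
  mean_mesh <- synthesize_shape(model, 1, 0)
  # path 1: measure the mean model once
  mean_model_area <- measure_morphometrics(mean_mesh)$total_area
  # path 2: average the per-specimen measurements
  per_spec <- vapply(seq_along(al$vertices), function(i)
    measure_morphometrics(homologous_mesh(al, i))$total_area, numeric(1))
  expect_false(isTRUE(all.equal(mean_model_area, mean(per_spec),
                                tolerance = 1e-6)))
  # on a size-varying population the mean of areas exceeds the mean model's
  # area (area is convex in scale)
  expect_gt(mean(per_spec), mean_model_area)
})
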
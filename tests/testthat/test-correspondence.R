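test_that("segment resampling yields equidistant points with exact endpoints", {
  lm <- landmark_set(list(a = c(0, 0, 0), b = c(10, 0, 0)),
                     list(list(name = "s", from = "a", to = "b",
                               points = rbind(c(0, 0, 0), c(10, 0, 0)))))
  out <- resample_segments(lm, 5)
  expect_equal(out$segments[[1]]$points[, 1], c(0, 2.5, 5, 7.5, 10))
  # arc-length walk oracle: bent polyline of length 7, middle point at 3.5
  lm2 <- landmark_set(list(a = c(0, 0, 0), b = c(3, 4, 0)),
                      list(list(name = "s", from = "a", to = "b",
                                points = rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))))
  out2 <- resample_segments(lm2, 3)
  expect_equal(out2$segments[[1]]$points[2, ], c(3, 0.5, 0))
  expect_equal(out2$segments[[1]]$points[c(1, 3), ], rbind(c(0, 0, 0), c(3, 4, 0)))
  # idempotence on an already-equidistant segment
  out3 <- resample_segments(out, 5)
  expect_equal(out3$segments[[1]]$points, out$segments[[1]]$points,
               tolerance = 1e-9)
  zl <- landmark_set(list(a = c(0, 0, 0), b = c(0, 0, 0)),
                     list(list(name = "z", from = "a", to = "b",
                               points = rbind(c(0, 0, 0), c(0, 0, 0)))))
  expect_error(resample_segments(zl, 3), "zero-length")
  expect_error(resample_segments(lm, 1), ">= 2")
})

test_that("TPS interpolates controls, reproduces affine maps, matches a dense-solve oracle", {
  set.seed(4)
  S <- matrix(runif(24) * 10, 8, 3)
  Tg <- S + matrix(rnorm(24), 8, 3)
  tp <- fit_tps(S, Tg)
  expect_lt(max(abs(apply_tps(tp, S) - Tg)), 1e-8)
  # side conditions: weights sum to zero with zero first moments
  expect_lt(max(abs(t(cbind(1, S)) %*% tp$weights)), 1e-8)
  # identity and pure translation are recovered with zero kernel weights
  tid <- fit_tps(S, S)
  expect_lt(max(abs(tid$weights)), 1e-10)
  expect_equal(unname(tid$affine), unname(rbind(0, diag(3))),
               tolerance = 1e-9, ignore_attr = TRUE)
  tt <- fit_tps(S, sweep(S, 2, c(1, -2, 3), "+"))
  expect_lt(max(abs(tt$weights)), 1e-10)
  q <- matrix(runif(15) * 10, 5, 3)
  expect_equal(apply_tps(tt, q), sweep(q, 2, c(1, -2, 3), "+"),
               tolerance = 1e-8)
  # independently coded dense linear solve, evaluated at random queries
  oracle_tps <- function(S, Tg, P) {
    k <- nrow(S)
    K <- matrix(0, k, k)
    for (i in 1:k) for (j in 1:k)
      K[i, j] <- sqrt(sum((S[i, ] - S[j, ])^2))
    A <- rbind(cbind(K, 1, S), cbind(rbind(rep(1, k), t(S)), matrix(0, 4, 4)))
    sol <- solve(A, rbind(Tg, matrix(0, 4, 3)))
    w <- sol[1:k, ]
    aff <- sol[(k + 1):(k + 4), ]
    t(apply(P, 1, function(p) {
      u <- sqrt(colSums((t(S) - p)^2))
      as.vector(c(1, p) %*% aff + u %*% w)
    }))
  }
  Q <- matrix(runif(60) * 12 - 1, 20, 3)
  expect_lt(max(abs(apply_tps(tp, Q) - oracle_tps(S, Tg, Q))), 1e-6)
})

test_that("TPS rejects degenerate control configurations", {
  flat <- cbind(matrix(runif(16), 8, 2), 0)
  expect_error(fit_tps(flat, flat + 1), "coplanar")
  S <- matrix(runif(24), 8, 3)
  S[2, ] <- S[1, ]
  expect_error(fit_tps(S, S), "duplicated")
  expect_error(fit_tps(S[1:3, ], S[1:3, ]), "at least 4")
})

test_that("self-correspondence returns the reference vertices", {
  ph <- generate_phantom_mesh(phantom_params(), n_theta = 16, n_rings = 16)
  ref <- list(mesh = ph$mesh, landmarks = ph$landmarks)
  hom <- establish_homology(ref, list(ref), points_per_segment = 8)
  expect_lt(max(abs(hom$vertices[[1]] - ph$mesh$vertices)), 1e-6)
  expect_lt(hom$residuals$mean_residual[1], 1e-8)
})

test_that("correspondence is exact under a rigid motion of the target", {
  ph <- generate_phantom_mesh(phantom_params(), n_theta = 16, n_rings = 16)
  R <- rigid_rotation_z(37)
  tvec <- c(4, -2, 8)
  rot_mesh <- labeled_mesh(sweep(ph$mesh$vertices %*% R, 2, tvec, "+"),
                           ph$mesh$triangles, ph$mesh$region)
  rot_lm <- ph$landmarks
  rot_lm$homologous <- lapply(rot_lm$homologous, function(p)
    as.vector(p %*% R) + tvec)
  rot_lm$segments <- lapply(rot_lm$segments, function(s) {
    s$points <- sweep(s$points %*% R, 2, tvec, "+")
    s
  })
  hom <- establish_homology(list(mesh = ph$mesh, landmarks = ph$landmarks),
                            list(list(mesh = rot_mesh, landmarks = rot_lm)),
                            points_per_segment = 8)
  expected <- sweep(ph$mesh$vertices %*% R, 2, tvec, "+")
  expect_lt(max(abs(hom$vertices[[1]] - expected)), 1e-3)
})

test_that("corresponded meshes preserve region area fractions and total area", {
  ph <- phantom_homology(5, c(length = 4, distal_radius = 0.5), seed = 21)
  hom <- transfer_cartilage_regions(ph$specs[[ph$ref]]$mesh$region, ph$hom)
  for (i in seq_along(ph$specs)) {
    own <- region_areas(ph$specs[[i]]$mesh)
    corr <- region_areas(homologous_mesh(hom, i))
    # area fractions against the target phantom's own analytic labels
    # (within 5 percentage points per region)
    expect_lt(max(abs(corr / sum(corr) - own / sum(own))), 0.05)
    # total corresponded area tracks the target's own segmented-mesh area
    expect_lt(abs(sum(corr) / sum(own) - 1), 0.02)
  }
})

test_that("cartilage label transfer shares triangle labels but not areas", {
  ph <- phantom_homology(4, c(length = 5), seed = 13)
  hom <- transfer_cartilage_regions(ph$specs[[ph$ref]]$mesh$region, ph$hom)
  # identical label composition in triangle counts (shared triangulation)
  expect_identical(hom$region, ph$specs[[ph$ref]]$mesh$region)
  tab <- hom$region_area_table
  # longer specimens have a larger absolute radius-facet area
  lens <- ph$pop$params_table$length
  expect_gt(cor(lens, tab$cartilage_radius), 0.9)
  # all-bone reference labels propagate unchanged
  hom2 <- transfer_cartilage_regions(rep("bone", nrow(ph$hom$triangulation)),
                                     ph$hom)
  expect_true(all(hom2$region == "bone"))
  expect_error(transfer_cartilage_regions(
    rep(NA_character_, nrow(ph$hom$triangulation)), ph$hom), "[Uu]nlabel")
})

test_that("reference selection picks the most central specimen", {
  pop <- generate_population(5, mode_sds = c(length = 3), seed = 31)
  lms <- lapply(pop$specimens, function(s) resample_segments(s$landmarks, 8))
  ref <- select_reference(lms)
  lens <- pop$params_table$length
  # the selected specimen should be nearer the median length than the extremes
  expect_lt(abs(lens[ref] - median(lens)),
            max(abs(lens - median(lens))))
})
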
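#' Generative parameters of a scaphoid phantom
#'
#' The phantom family is a two-lobed solid of revolution: proximal and distal
#' lobes of given radii joined through a circular waist, flattened on the
#' dorsal side and bent about the waist. These six geometric parameters are
#' the independent generative modes of the synthetic population; defaults are
#' chosen to give a 26 mm bone with waist and dorsal-surface dimensions in
#' the anatomical range.
#'
#' @param length pole-to-pole axial length (mm).
#' @param proximal_radius,distal_radius lobe radii (mm).
#' @param waist_radius radius of the circular waist (mm); must be smaller
#'   than both lobe radii so a waist exists.
#' @param waist_axial_position waist position as a fraction of length, in
#'   (0, 1).
#' @param dorsal_width height of the dorsal flattening plane above the long
#'   axis (mm); the surface is clamped at `y = dorsal_width / 2`.
#' @param bend_angle bending of the distal lobe about the waist (degrees).
#' @param seed integer recorded with the specimen.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(length = 26, proximal_radius = 6,
                           distal_radius = 7, waist_radius = 5.2,
                           waist_axial_position = 0.5, dorsal_width = 6.5,
                           bend_angle = 15, seed = 1L) {
  p <- list(length = length, proximal_radius = proximal_radius,
            distal_radius = distal_radius, waist_radius = waist_radius,
            waist_axial_position = waist_axial_position,
            dorsal_width = dorsal_width, bend_angle = bend_angle,
            seed = as.integer(seed))
  for (f in c("length", "proximal_radius", "distal_radius", "waist_radius",
              "dorsal_width"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop("invalid phantom_params: ", f, " must be strictly positive")
  if (p$waist_radius >= min(p$proximal_radius, p$distal_radius))
    stop("invalid phantom_params: waist_radius must be < min(proximal_radius, distal_radius) so a waist exists")
  if (p$waist_axial_position <= 0 || p$waist_axial_position >= 1)
    stop("invalid phantom_params: waist_axial_position must lie in (0, 1)")
  structure(p, class = "phantom_params")
}

# axial radius profile r(z) of the unbent solid of revolution:
# elliptical pole caps peaking at the lobe centres, cosine blends into the
# waist, C1-smooth with the minimum exactly waist_radius at the waist.
phantom_profile <- function(params, z) {
  L <- params$length
  zw <- params$waist_axial_position * L
  z1 <- zw / 2
  z2 <- (zw + L) / 2
  rp <- params$proximal_radius
  rd <- params$distal_radius
  rw <- params$waist_radius
  r <- numeric(length(z))
  a <- z <= z1
  r[a] <- rp * sqrt(pmax(0, 1 - ((z1 - z[a]) / z1)^2))
  b <- z > z1 & z <= zw
  r[b] <- rw + (rp - rw) * (1 + cos(pi * (z[b] - z1) / (zw - z1))) / 2
  cc <- z > zw & z <= z2
  r[cc] <- rw + (rd - rw) * (1 - cos(pi * (z[cc] - zw) / (z2 - zw))) / 2
  d <- z > z2
  r[d] <- rd * sqrt(pmax(0, 1 - ((z[d] - z2) / (L - z2))^2))
  r
}

# progressive bend of the distal part about the x axis through the waist:
# rotation angle ramps linearly from 0 at the waist to bend_angle at the
# distal pole, keeping the mesh continuous.
phantom_bend <- function(points, params) {
  L <- params$length
  zw <- params$waist_axial_position * L
  ang <- params$bend_angle * pi / 180
  s <- pmin(pmax((points[, 3] - zw) / (L - zw), 0), 1)
  phi <- ang * s
  y <- points[, 2]
  z <- points[, 3] - zw
  points[, 2] <- y * cos(phi) - z * sin(phi)
  points[, 3] <- y * sin(phi) + z * cos(phi) + zw
  points
}

# position of a surface point at unbent axial coordinate z and angle theta
# (theta = 0 lateral +x, 90 dorsal +y, 180 medial, 270 volar), with dorsal
# flattening and bend applied.
phantom_surface_point <- function(params, z, theta) {
  r <- phantom_profile(params, z)
  x <- r * cos(theta)
  y <- pmin(r * sin(theta), params$dorsal_width / 2)
  phantom_bend(cbind(x, y, z), params)
}

#' Generate a scaphoid phantom mesh with analytic landmarks
#'
#' Builds a closed genus-zero triangulation of the two-lobed, waisted,
#' dorsally flattened and bent solid described by [phantom_params], places
#' homologous landmarks and segment polylines at analytically defined surface
#' points (pole tips, waist extrema, the four surface meridians), labels the
#' triangles with five surface regions (four cartilage facets and the dorsal
#' rough surface), and records the generative parameters.
#'
#' The triangulation is a pole-fan / ring-strip lattice: `n_theta` angular
#' samples on rings placed along the axis (rings always include the waist
#' and both lobe equators), plus the two pole vertices, giving
#' `T = 2 V - 4` triangles.
#'
#' @param params a [phantom_params].
#' @param n_theta angular resolution; a multiple of 8 at least 16, so the
#'   cardinal and diagonal meridians lie on the vertex lattice.
#' @param n_rings approximate number of axial rings; at least 8.
#' @return list with `mesh` (a [labeled_mesh]), `landmarks` (a
#'   [landmark_set]) and `params`.
#' @export
generate_phantom_mesh <- function(params, n_theta = 32, n_rings = 40) {
  stopifnot(inherits(params, "phantom_params"))
  if (n_theta < 16 || n_theta %% 8 != 0)
    stop("n_theta must be a multiple of 8, >= 16")
  if (n_rings < 8) stop("n_rings must be >= 8")
  L <- params$length
  zw <- params$waist_axial_position * L
  z1 <- zw / 2
  z2 <- (zw + L) / 2
  # ring stations: uniform within the four profile segments, boundaries kept
  zb <- c(0, z1, zw, z2, L)
  zs <- unlist(lapply(1:4, function(s) {
    k <- max(3, round(n_rings * (zb[s + 1] - zb[s]) / L))
    seq(zb[s], zb[s + 1], length.out = k + 1)
  }))
  zs <- sort(unique(zs))
  zs <- zs[zs > 0 & zs < L]
  m <- length(zs)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta

  ring_xy <- function(z) {
    r <- phantom_profile(params, z)
    cbind(r * cos(theta), pmin(r * sin(theta), params$dorsal_width / 2),
          rep(z, n_theta))
  }
  verts <- rbind(c(0, 0, 0), c(0, 0, L),
                 do.call(rbind, lapply(zs, ring_xy)))
  zparam <- c(0, L, rep(zs, each = n_theta))
  thparam <- c(NA, NA, rep(theta, m))
  verts <- phantom_bend(verts, params)

  ridx <- function(r, j) 2L + (r - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  tris <- matrix(0L, 2L * (nrow(verts) - 2L), 3L)
  t <- 0L
  for (j in seq_len(n_theta)) {          # proximal pole fan (outward: -z)
    t <- t + 1L
    tris[t, ] <- c(1L, ridx(1L, j + 1L), ridx(1L, j))
  }
  for (r in seq_len(m - 1L)) {
    for (j in seq_len(n_theta)) {
      a <- ridx(r, j); b <- ridx(r, j + 1L)
      cc <- ridx(r + 1L, j); d <- ridx(r + 1L, j + 1L)
      t <- t + 1L; tris[t, ] <- c(a, b, d)
      t <- t + 1L; tris[t, ] <- c(a, d, cc)
    }
  }
  for (j in seq_len(n_theta)) {          # distal pole fan (outward: +z)
    t <- t + 1L
    tris[t, ] <- c(2L, ridx(m, j), ridx(m, j + 1L))
  }

  # region labels from unbent parametric coordinates of triangle centroids
  tz <- matrix(zparam[tris], ncol = 3)
  tth <- matrix(thparam[tris], ncol = 3)
  cz <- rowMeans(tz)
  cth <- atan2(rowMeans(sin(tth), na.rm = TRUE), rowMeans(cos(tth), na.rm = TRUE)) %% (2 * pi)
  deg <- cth * 180 / pi
  region <- ifelse(cz <= z1, "cartilage_radius",
            ifelse(cz >= z2, "cartilage_trapezium_trapezoid",
            ifelse(deg >= 45 & deg < 135, "bone",
            ifelse(deg >= 135 & deg < 270, "cartilage_capitate",
                   "cartilage_lunate"))))
  mesh <- labeled_mesh(verts, tris, region)

  # analytic landmarks (exact mesh-lattice points)
  sp <- function(z, th) as.numeric(phantom_surface_point(params, z, th))
  hom <- list(
    proximal_pole = c(0, 0, 0),
    distal_pole = as.numeric(phantom_bend(matrix(c(0, 0, L), 1), params)),
    waist_lateral = sp(zw, 0), waist_dorsal = sp(zw, pi / 2),
    waist_medial = sp(zw, pi), waist_volar = sp(zw, 3 * pi / 2),
    proximal_peak_volar = sp(z1, 3 * pi / 2),
    distal_peak_volar = sp(z2, 3 * pi / 2))
  meridian <- function(th) {
    pts <- phantom_surface_point(params, zs, rep(th, m))
    rbind(hom$proximal_pole, pts, hom$distal_pole)
  }
  segs <- list(
    list(name = "lateral_meridian", from = "proximal_pole", to = "distal_pole",
         points = meridian(0)),
    list(name = "dorsal_meridian", from = "proximal_pole", to = "distal_pole",
         points = meridian(pi / 2)),
    list(name = "medial_meridian", from = "proximal_pole", to = "distal_pole",
         points = meridian(pi)),
    list(name = "volar_meridian", from = "proximal_pole", to = "distal_pole",
         points = meridian(3 * pi / 2)))
  loop_ring <- function(z) phantom_surface_point(params, rep(z, n_theta), theta)
  strip_edge <- function(th) phantom_surface_point(params, zs[zs >= z1 & zs <= z2],
                                                   rep(th, sum(zs >= z1 & zs <= z2)))
  regs <- list(
    list(name = "cartilage_radius", loop = loop_ring(z1)),
    list(name = "cartilage_trapezium_trapezoid", loop = loop_ring(z2)),
    list(name = "bone", loop = rbind(strip_edge(pi / 4),
                                     strip_edge(3 * pi / 4)[rev(seq_len(sum(zs >= z1 & zs <= z2))), ])))
  list(mesh = mesh, landmarks = landmark_set(hom, segs, regs), params = params)
}

#' Concentric density-zone profile of the phantom
#'
#' Three concentric zones: a high-density peripheral shell (cortical and
#' subchondral bone), an intermediate shell with four angular/axial
#' subregions, and a low-density trabecular centre. Default zone means are
#' the population values reported for the scaphoid (peripheral
#' 549.4 mg HA/cm^3, intermediate 346.5-389.1, centre 225.6).
#'
#' @param peripheral_mean,centre_mean zone means (mg HA/cm^3).
#' @param intermediate_means named numeric vector of the four intermediate
#'   subregion means: `medial`, `proximal`, `distal`, `lateral`.
#' @param noise_sd additive Gaussian noise SD (mg HA/cm^3); values are
#'   clamped at 0.
#' @param peripheral_thickness,intermediate_thickness shell depths (mm).
#' @return an object of class `zone_profile`.
#' @export
zone_profile <- function(peripheral_mean = 549.4,
                         intermediate_means = c(medial = 376.2,
                                                proximal = 379.0,
                                                distal = 346.5,
                                                lateral = 389.1),
                         centre_mean = 225.6, noise_sd = 60,
                         peripheral_thickness = 1.0,
                         intermediate_thickness = 2.0) {
  if (!all(c("medial", "proximal", "distal", "lateral") %in%
           names(intermediate_means)))
    stop("intermediate_means needs medial, proximal, distal, lateral")
  if (!(peripheral_mean > max(intermediate_means) &&
        min(intermediate_means) > centre_mean))
    stop("zone ordering violated: need peripheral_mean > every intermediate mean > centre_mean")
  if (peripheral_thickness <= 0 || intermediate_thickness <= 0)
    stop("zone thicknesses must be strictly positive")
  structure(list(peripheral_mean = peripheral_mean,
                 intermediate_means = intermediate_means,
                 centre_mean = centre_mean, noise_sd = noise_sd,
                 peripheral_thickness = peripheral_thickness,
                 intermediate_thickness = intermediate_thickness),
            class = "zone_profile")
}

# zone code per point: depth to surface + axial thirds / angular halves.
# codes: 1 peripheral, 2 int_medial, 3 int_proximal, 4 int_distal,
# 5 int_lateral, 6 centre
zone_codes <- c("peripheral", "intermediate_medial", "intermediate_proximal",
                "intermediate_distal", "intermediate_lateral", "centre")

assign_zone_codes <- function(points, depth, axes, axis_range,
                              peripheral_depth, centre_start_depth) {
  code <- integer(nrow(points))
  code[depth <= peripheral_depth] <- 1L
  deep <- depth >= centre_start_depth
  code[deep] <- 6L
  mid <- code == 0L
  if (any(mid)) {
    ctr <- sweep(points[mid, , drop = FALSE], 2, axes$centre, "-")
    frac <- (ctr %*% axes$axes[, 1] - axis_range[1]) / diff(axis_range)
    side <- ctr %*% axes$axes[, 2]
    sub <- ifelse(frac < 1 / 3, 3L, ifelse(frac > 2 / 3, 4L,
                  ifelse(side >= 0, 5L, 2L)))
    code[mid] <- sub
  }
  code
}

#' Rasterize a phantom mesh into a zoned density volume
#'
#' Voxels outside the mesh are 0. Interior voxels are assigned to the
#' concentric zones by their depth below the surface (peripheral shell,
#' intermediate shell with four subregions chosen by axial thirds and
#' angular halves about the long axis, trabecular centre) and drawn from
#' `Normal(zone mean, noise_sd)`, clamped at 0. The volume carries the known
#' HU/vBMD calibration so the calibration path of the pipeline is exercised:
#' with `units = "HU"` values are stored as `HU = (vBMD - intercept)/slope`.
#'
#' @param mesh a closed [labeled_mesh], e.g. from [generate_phantom_mesh].
#' @param zones a [zone_profile].
#' @param voxel_size isotropic voxel size (mm); a warning is issued when it
#'   exceeds the peripheral shell thickness (zones unresolvable).
#' @param seed integer seed for the voxel noise.
#' @param units store as calibrated `"vBMD"` or raw `"HU"`.
#' @param calibration linear calibration used for the HU representation.
#' @return a [density_volume] with attributes `inside` (logical array),
#'   `zone_labels` (integer array, 0 = outside, codes 1-6 as in
#'   `zone_codes`) and `zone_profile`.
#' @export
generate_phantom_volume <- function(mesh, zones = zone_profile(),
                                    voxel_size = 0.3, seed = 1L,
                                    units = c("vBMD", "HU"),
                                    calibration = c(slope = 0.7, intercept = 0)) {
  units <- match.arg(units)
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (voxel_size > zones$peripheral_thickness)
    warning("voxel_size exceeds peripheral_thickness: zones unresolvable")
  bb <- apply(mesh$vertices, 2, range)
  margin <- 2 * voxel_size
  origin <- bb[1, ] - margin
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * margin) / voxel_size)) + 1L
  inside <- .cpp_voxelize_mesh(mesh$vertices, mesh$triangles, origin,
                               voxel_size, dims)
  idx <- which(inside)
  ijk <- arrayInd(idx, dims) - 1L
  pts <- sweep(ijk * voxel_size, 2, origin, "+")
  depth <- .cpp_mesh_nearest(mesh$vertices, mesh$triangles, pts)$distance
  axes <- principal_axes(mesh$vertices)
  vr <- range(sweep(mesh$vertices, 2, axes$centre, "-") %*% axes$axes[, 1])
  code <- assign_zone_codes(pts, depth, axes, vr,
                            zones$peripheral_thickness,
                            zones$peripheral_thickness + zones$intermediate_thickness)
  mu <- c(zones$peripheral_mean,
          zones$intermediate_means[["medial"]],
          zones$intermediate_means[["proximal"]],
          zones$intermediate_means[["distal"]],
          zones$intermediate_means[["lateral"]],
          zones$centre_mean)[code]
  set.seed(seed)
  vals <- if (zones$noise_sd > 0) pmax(0, rnorm(length(mu), mu, zones$noise_sd)) else mu
  arr <- array(0, dim = dims)
  arr[idx] <- vals
  zl <- array(0L, dim = dims)
  zl[idx] <- code
  if (units == "HU")
    arr <- (arr - calibration[["intercept"]]) / calibration[["slope"]]
  vol <- density_volume(arr, voxel_size, origin = origin, units = units,
                        calibration = calibration)
  attr(vol, "inside") <- inside
  attr(vol, "zone_labels") <- zl
  attr(vol, "zone_profile") <- zones
  vol
}

#' Generate a phantom population with known latent parameters
#'
#' Draws per-specimen [phantom_params] from independent normal distributions
#' around the default means, builds each mesh and landmark set, and returns
#' the latent parameter table for downstream recovery experiments. Draws
#' violating the geometric invariants are deterministically clamped into the
#' valid range. Fully reproducible from `seed`.
#'
#' @param n number of specimens, >= 3 (PCA needs at least 3 shapes).
#' @param mode_sds named numeric vector of per-parameter SDs; parameters not
#'   named get SD 0. Defaults emulate the anatomical spread (length SD 5 mm,
#'   dorsal width SD 1.25 mm, ...).
#' @param seed integer seed.
#' @param zones optional [zone_profile]; when supplied, a density volume is
#'   generated per specimen.
#' @param n_theta,n_rings,voxel_size,units mesh / volume resolution settings
#'   passed through to the generators.
#' @return list with `specimens` (each `list(mesh, landmarks, params,
#'   volume)`) and `params_table` (data.frame of the latent parameters).
#' @export
generate_population <- function(n, mode_sds = c(length = 5,
                                                proximal_radius = 0.6,
                                                distal_radius = 0.6,
                                                waist_radius = 0.5,
                                                waist_axial_position = 0.04,
                                                dorsal_width = 1.25,
                                                bend_angle = 4),
                                seed = 1L, zones = NULL, n_theta = 32,
                                n_rings = 40, voxel_size = 0.3,
                                units = "vBMD") {
  if (n < 3) stop("n must be >= 3: PCA needs at least 3 shapes for 2 modes")
  base <- phantom_params()
  parnames <- c("length", "proximal_radius", "distal_radius", "waist_radius",
                "waist_axial_position", "dorsal_width", "bend_angle")
  sds <- setNames(rep(0, length(parnames)), parnames)
  sds[names(mode_sds)] <- mode_sds
  set.seed(seed)
  draws <- matrix(rnorm(n * length(parnames)), n, length(parnames),
                  dimnames = list(NULL, parnames))
  tab <- sweep(draws, 2, sds, "*")
  tab <- sweep(tab, 2, unlist(base[parnames]), "+")
  # deterministic clamping into the valid parameter region
  for (f in c("length", "proximal_radius", "distal_radius", "dorsal_width"))
    tab[, f] <- pmax(tab[, f], 0.2 * unlist(base[[f]]))
  tab[, "waist_axial_position"] <- pmin(pmax(tab[, "waist_axial_position"], 0.15), 0.85)
  tab[, "waist_radius"] <- pmin(pmax(tab[, "waist_radius"], 0.5),
                                0.92 * pmin(tab[, "proximal_radius"],
                                            tab[, "distal_radius"]))
  specimens <- lapply(seq_len(n), function(i) {
    p <- do.call(phantom_params, c(as.list(tab[i, ]), list(seed = seed + i)))
    spec <- generate_phantom_mesh(p, n_theta = n_theta, n_rings = n_rings)
    if (!is.null(zones))
      spec$volume <- generate_phantom_volume(spec$mesh, zones,
                                             voxel_size = voxel_size,
                                             seed = seed + i, units = units)
    spec
  })
  list(specimens = specimens,
       params_table = data.frame(specimen = seq_len(n), tab))
}
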
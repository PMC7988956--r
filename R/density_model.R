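#' Isotropic reference grid inside the mean shape
#'
#' Axis-aligned grid of the given spacing covering the mean mesh bounding
#' box (plus one spacing of margin); nodes are classified inside/outside by
#' ray-parity against the closed mean mesh. The inside nodes are the support
#' of the averaged bone-density model.
#'
#' @param mean_mesh closed [labeled_mesh] of the mean shape.
#' @param spacing isotropic node spacing (mm), > 0.
#' @return an object of class `reference_grid`: `origin`, `spacing`, `dim`,
#'   `inside` (logical array), `n_inside`.
#' @export
build_reference_grid <- function(mean_mesh, spacing) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  bb <- apply(mean_mesh$vertices, 2, range)
  origin <- bb[1, ] - spacing
  dims <- as.integer(ceiling((bb[2, ] - bb[1, ] + 2 * spacing) / spacing)) + 1L
  inside <- .cpp_voxelize_mesh(mean_mesh$vertices, mean_mesh$triangles,
                               origin, spacing, dims)
  dim(inside) <- dims
  structure(list(origin = origin, spacing = spacing, dim = dims,
                 inside = inside, n_inside = sum(inside)),
            class = "reference_grid")
}

# coordinates (mm) of grid nodes for the given linear indices
grid_node_coords <- function(grid, idx) {
  ijk <- arrayInd(idx, grid$dim) - 1L
  sweep(ijk * grid$spacing, 2, grid$origin, "+")
}

#' Build the 3D averaged bone-density model
#'
#' For each specimen a thin-plate spline is fitted from a uniform subsample
#' of the mean shape's homologous surface vertices to the specimen's
#' corresponding vertices (in its native volume frame); every inside grid
#' node is warped into the specimen and trilinearly sampled from its
#' calibrated vBMD volume. The per-node population mean over specimens is
#' the averaged model. Sampling is partial-volume aware: corners outside the
#' specimen's bone mask get zero interpolation weight, and nodes that map
#' outside a specimen's volume are excluded from its average (recorded in
#' the per-node specimen count).
#'
#' @param grid a `reference_grid` built inside the mean shape.
#' @param homology a `homologous_mesh_set` with per-specimen vertices in the
#'   same frame as the corresponding `volumes`.
#' @param volumes list of [density_volume]s (units vBMD), one per specimen.
#' @param mean_vertices V x 3 mean-shape vertices in the grid frame; default
#'   is the non-scaling Procrustes mean of `homology`.
#' @param n_controls number of TPS control vertices (uniform subsample).
#' @param lambda TPS regularization.
#' @param mask_mode `"auto"` uses each volume's `inside` attribute when
#'   present, else `values > 0`; `"none"` disables masked sampling.
#' @param flag_threshold specimens with a larger fraction of unmappable
#'   nodes are flagged.
#' @return an object of class `averaged_density_model`: grid geometry plus
#'   `mean_vbmd` (array, `NA` outside), `n_count` (array of per-node
#'   specimen counts), `n_specimens`, `unmappable` (per-specimen fraction),
#'   `flagged`.
#' @export
build_averaged_model <- function(grid, homology, volumes,
                                 mean_vertices = NULL, n_controls = 300,
                                 lambda = 0, mask_mode = c("auto", "none"),
                                 flag_threshold = 0.05) {
  mask_mode <- match.arg(mask_mode)
  n <- length(volumes)
  if (length(homology$vertices) != n)
    stop("homology and volumes must cover the same specimens")
  for (v in volumes)
    if (v$units != "vBMD") stop("volumes must be calibrated to vBMD")
  if (is.null(mean_vertices))
    mean_vertices <- procrustes_align(homology)$mean_vertices
  V <- nrow(mean_vertices)
  ctrl <- unique(round(seq(1, V, length.out = min(n_controls, V))))
  idx <- which(grid$inside)
  nodes <- grid_node_coords(grid, idx)
  acc <- numeric(length(idx))
  cnt <- integer(length(idx))
  unmappable <- numeric(n)
  for (s in seq_len(n)) {
    tps <- fit_tps(mean_vertices[ctrl, , drop = FALSE],
                   homology$vertices[[s]][ctrl, , drop = FALSE],
                   lambda = lambda)
    warped <- apply_tps(tps, nodes)
    msk <- if (mask_mode == "none") NULL
           else if (!is.null(attr(volumes[[s]], "inside"))) attr(volumes[[s]], "inside")
           else volumes[[s]]$values > 0
    vals <- trilinear_sample(volumes[[s]], warped, mask = msk)
    ok <- !is.na(vals)
    unmappable[s] <- mean(!ok)
    acc[ok] <- acc[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  mean_arr <- array(NA_real_, grid$dim)
  mean_arr[idx] <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  cnt_arr <- array(0L, grid$dim)
  cnt_arr[idx] <- cnt
  flagged <- unmappable > flag_threshold
  if (any(flagged))
    warning("specimens with > ", 100 * flag_threshold,
            "% unmappable nodes: ", paste(which(flagged), collapse = ", "))
  structure(list(origin = grid$origin, spacing = grid$spacing,
                 dim = grid$dim, inside = grid$inside,
                 mean_vbmd = mean_arr, n_count = cnt_arr,
                 n_specimens = n, unmappable = unmappable,
                 flagged = flagged),
            class = "averaged_density_model")
}

#' @export
print.averaged_density_model <- function(x, ...) {
  cat(sprintf("averaged_density_model: %d x %d x %d grid at %.3g mm, %d inside nodes, %d specimens\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, sum(x$inside),
              x$n_specimens))
  invisible(x)
}

#' Segment the concentric density zones of the averaged model
#'
#' Every inside node is labelled by its depth below the mean surface:
#' `depth <= peripheral_depth` is the peripheral zone, `depth >=
#' centre_start_depth` the centre zone, and the band between is the
#' intermediate zone, subdivided into proximal-pole and distal-pole
#' subregions (outer axial thirds along the long axis) and medial / lateral
#' subregions (angular halves of the middle third about the second principal
#' axis).
#'
#' @param model an `averaged_density_model`.
#' @param mean_mesh the closed mean mesh the grid was built in.
#' @param peripheral_depth,centre_start_depth zone boundary depths (mm),
#'   `0 < peripheral_depth < centre_start_depth`.
#' @param axes optional precomputed [principal_axes] of the mean mesh.
#' @return the model with `zone_labels` (integer array; 0 outside, 1
#'   peripheral, 2 intermediate medial, 3 intermediate proximal, 4
#'   intermediate distal, 5 intermediate lateral, 6 centre) and
#'   `zone_names`.
#' @export
segment_zones <- function(model, mean_mesh, peripheral_depth = 1.0,
                          centre_start_depth = 3.0, axes = NULL) {
  if (peripheral_depth <= 0 || centre_start_depth <= peripheral_depth)
    stop("need 0 < peripheral_depth < centre_start_depth")
  idx <- which(model$inside)
  nodes <- grid_node_coords(model, idx)
  depth <- .cpp_mesh_nearest(mean_mesh$vertices, mean_mesh$triangles, nodes)$distance
  if (is.null(axes)) axes <- principal_axes(mean_mesh$vertices)
  vr <- range(sweep(mean_mesh$vertices, 2, axes$centre, "-") %*% axes$axes[, 1])
  code <- assign_zone_codes(nodes, depth, axes, vr, peripheral_depth,
                            centre_start_depth)
  if (!any(code == 6L))
    warning("centre zone is empty: centre_start_depth exceeds the maximal interior depth")
  zl <- array(0L, model$dim)
  zl[idx] <- code
  model$zone_labels <- zl
  model$zone_names <- zone_codes
  model
}

#' Zone descriptive statistics of the averaged model
#'
#' Per-zone node counts, volume (node count times node volume, mm^3) and
#' descriptive vBMD statistics, in the mean +/- SD (min-max) layout of the
#' population tables. Empty zones appear as zero-volume rows rather than
#' raising an error.
#'
#' @param model an `averaged_density_model` after [segment_zones].
#' @param digits digits for the formatted column.
#' @return data.frame with one row per zone.
#' @export
zone_stats <- function(model, digits = 1) {
  if (is.null(model$zone_labels)) stop("run segment_zones first")
  vv <- model$spacing^3
  out <- do.call(rbind, lapply(seq_along(zone_codes), function(z) {
    sel <- model$zone_labels == z
    vals <- model$mean_vbmd[sel]
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      return(data.frame(zone = zone_codes[z], n_nodes = sum(sel),
                        volume_mm3 = sum(sel) * vv, mean = NA_real_,
                        sd = NA_real_, min = NA_real_, max = NA_real_,
                        formatted = "empty"))
    data.frame(zone = zone_codes[z], n_nodes = sum(sel),
               volume_mm3 = sum(sel) * vv, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               min = min(vals), max = max(vals),
               formatted = sprintf(
                 paste0("%.", digits, "f ± %.", digits, "f (%.", digits,
                        "f-%.", digits, "f)"),
                 mean(vals), if (length(vals) > 1) stats::sd(vals) else 0,
                 min(vals), max(vals)))
  }))
  rownames(out) <- NULL
  out
}

#' Averaged model as a sampleable density volume
#'
#' Converts the averaged model into a [density_volume] (uncovered and
#' outside nodes set to 0) carrying an `inside` mask of the covered nodes,
#' so that [trilinear_sample] and [probe_pathway] treat the exterior as
#' background.
#'
#' @param model an `averaged_density_model`.
#' @return a [density_volume] with attribute `inside`.
#' @export
as_density_volume <- function(model) {
  vals <- model$mean_vbmd
  msk <- model$inside & !is.na(vals)
  vals[is.na(vals)] <- 0
  vol <- density_volume(vals, model$spacing, origin = model$origin,
                        units = "vBMD")
  attr(vol, "inside") <- msk
  vol
}

#' Virtually probe a cylindrical screw pathway
#'
#' Samples the density field along the segment from `entry` to `exit` at
#' equally spaced stations; at each station the field is trilinearly
#' interpolated on a disk of the given diameter perpendicular to the path (a
#' regular polar pattern: centre plus `n_rings` rings of `n_spokes` points)
#' and averaged. `mode = "line"` ignores the diameter and samples the axis
#' only. Samples outside the volume or its tissue mask are excluded; a path
#' with no valid samples at any station is rejected.
#'
#' @param x a [density_volume] or `averaged_density_model`.
#' @param entry,exit path endpoints (mm).
#' @param diameter probe diameter (mm), > 0.
#' @param n_stations number of stations along the path.
#' @param n_rings,n_spokes polar disk sampling density.
#' @param mode `"disk"` (default) or `"line"`.
#' @return an object of class `probe_profile`: `profile` data.frame
#'   (station, arc_length, mean_vbmd, n_samples), `summary` (path mean /
#'   min / max over stations), `entry`, `exit`, `diameter`.
#' @export
probe_pathway <- function(x, entry, exit, diameter = 3, n_stations = 100,
                          n_rings = 3, n_spokes = 8,
                          mode = c("disk", "line")) {
  mode <- match.arg(mode)
  if (inherits(x, "averaged_density_model")) x <- as_density_volume(x)
  entry <- as.numeric(entry)
  exit <- as.numeric(exit)
  if (all(entry == exit)) stop("entry and exit must differ")
  if (diameter <= 0) stop("diameter must be > 0")
  d <- exit - entry
  len <- sqrt(sum(d^2))
  d <- d / len
  u <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  offsets <- matrix(0, 1, 2)
  if (mode == "disk") {
    for (r in seq_len(n_rings)) {
      ang <- 2 * pi * (seq_len(n_spokes) - 1) / n_spokes
      offsets <- rbind(offsets,
                       cbind(cos(ang), sin(ang)) * (diameter / 2) * r / n_rings)
    }
  }
  arc <- seq(0, len, length.out = n_stations)
  msk <- attr(x, "inside")
  prof <- t(vapply(arc, function(a) {
    ctr <- entry + a * d
    pts <- sweep(offsets[, 1, drop = FALSE] %*% rbind(u) +
                 offsets[, 2, drop = FALSE] %*% rbind(v), 2, ctr, "+")
    vals <- trilinear_sample(x, pts, mask = msk)
    c(mean(vals, na.rm = TRUE), sum(!is.na(vals)))
  }, numeric(2)))
  mean_vbmd <- ifelse(prof[, 2] > 0, prof[, 1], NA_real_)
  if (all(is.na(mean_vbmd)))
    stop("path entirely outside the volume")
  structure(list(profile = data.frame(station = seq_len(n_stations),
                                      arc_length = arc,
                                      mean_vbmd = mean_vbmd,
                                      n_samples = as.integer(prof[, 2])),
                 summary = list(mean = mean(mean_vbmd, na.rm = TRUE),
                                min = min(mean_vbmd, na.rm = TRUE),
                                max = max(mean_vbmd, na.rm = TRUE)),
                 entry = entry, exit = exit, diameter = diameter,
                 mode = mode),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("probe_profile: %.1f mm path, %.1f mm diameter (%s), vBMD mean %.1f (min %.1f, max %.1f)\n",
              max(x$profile$arc_length), x$diameter, x$mode,
              x$summary$mean, x$summary$min, x$summary$max))
  invisible(x)
}
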
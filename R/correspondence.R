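#' Select the reference specimen for correspondence
#'
#' The representative specimen is the one whose landmark configuration
#' minimizes the summed pairwise Procrustes distance (translation + rotation
#' removed, no scaling) to all other specimens.
#'
#' @param landmark_sets list of [landmark_set] objects with identical
#'   structure (after [resample_segments]).
#' @return integer index of the selected reference.
#' @export
select_reference <- function(landmark_sets) {
  ctrls <- lapply(landmark_sets, landmark_controls)
  n <- length(ctrls)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- procrustes_distance(ctrls[[i]], ctrls[[j]])
  }
  which.min(rowSums(D))
}

# rigid (non-scaling) Procrustes RMS distance between two configurations
procrustes_distance <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  R <- kabsch_rotation(A, B)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

# optimal proper rotation R (det +1) minimizing ||A R - B||_F
kabsch_rotation <- function(A, B) {
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Establish vertex-wise homology across specimens
#'
#' The reference mesh is warped to every target with a thin-plate-spline
#' transformation whose controls are the full equidistant landmark sets
#' (homologous plus resampled segment landmarks), then each warped vertex is
#' projected to the nearest point on the target surface so all vertices lie
#' exactly on the segmented surface. Every output specimen shares the
#' reference triangulation and its per-triangle region labels, which is what
#' makes surface points anatomically homologous across the population.
#'
#' @param reference `list(mesh, landmarks)` for the reference specimen.
#' @param targets list of `list(mesh, landmarks)` for all specimens to
#'   correspond (typically including the reference itself).
#' @param points_per_segment segment resampling resolution (see
#'   [resample_segments]).
#' @param lambda TPS regularization (0 = pure interpolation).
#' @param project project warped vertices onto the target surface
#'   (recommended; disable for diagnostics of the raw warp).
#' @param flag_tolerance mean projection residual (mm) above which a
#'   specimen is flagged; default half the mean edge length of the reference.
#' @return an object of class `homologous_mesh_set`: `triangulation`,
#'   `region`, `vertices` (list of V x 3 per specimen), `reference` (index or
#'   name), `residuals` (per-specimen mean/max projection residual),
#'   `flagged` (logical).
#' @export
establish_homology <- function(reference, targets, points_per_segment = 10,
                               lambda = 0, project = TRUE,
                               flag_tolerance = NULL) {
  ref_lm <- resample_segments(reference$landmarks, points_per_segment)
  ref_ctrl <- landmark_controls(ref_lm)
  refv <- reference$mesh$vertices
  if (is.null(flag_tolerance)) {
    ed <- refv[reference$mesh$triangles[, 1], ] - refv[reference$mesh$triangles[, 2], ]
    flag_tolerance <- 0.5 * mean(sqrt(rowSums(ed^2)))
  }
  res <- lapply(targets, function(tg) {
    tg_lm <- resample_segments(tg$landmarks, points_per_segment)
    tg_ctrl <- landmark_controls(tg_lm)
    if (nrow(tg_ctrl) != nrow(ref_ctrl) ||
        !identical(rownames(tg_ctrl), rownames(ref_ctrl)))
      stop("landmark sets do not share names/counts after resampling")
    warped <- apply_tps(fit_tps(ref_ctrl, tg_ctrl, lambda = lambda), refv)
    if (project) {
      pr <- project_to_mesh(tg$mesh, warped)
      list(vertices = pr$point, mean_resid = mean(pr$distance),
           max_resid = max(pr$distance))
    } else {
      list(vertices = warped, mean_resid = 0, max_resid = 0)
    }
  })
  resid <- data.frame(specimen = seq_along(targets),
                      mean_residual = vapply(res, `[[`, numeric(1), "mean_resid"),
                      max_residual = vapply(res, `[[`, numeric(1), "max_resid"))
  structure(list(triangulation = reference$mesh$triangles,
                 region = reference$mesh$region,
                 vertices = lapply(res, `[[`, "vertices"),
                 reference = reference,
                 residuals = resid,
                 flagged = resid$mean_residual > flag_tolerance,
                 flag_tolerance = flag_tolerance),
            class = "homologous_mesh_set")
}

#' @export
print.homologous_mesh_set <- function(x, ...) {
  cat(sprintf("homologous_mesh_set: %d specimens, %d shared vertices, %d triangles\n",
              length(x$vertices), nrow(x$vertices[[1]]), nrow(x$triangulation)))
  if (any(x$flagged))
    cat("flagged specimens (projection residual above tolerance):",
        paste(which(x$flagged), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one specimen of a homologous set as a mesh
#'
#' @param homology a `homologous_mesh_set`.
#' @param i specimen index.
#' @return a [labeled_mesh] with the shared triangulation and labels.
#' @export
homologous_mesh <- function(homology, i) {
  labeled_mesh(homology$vertices[[i]], homology$triangulation, homology$region)
}

#' Transfer cartilage region labels across the homologous set
#'
#' Each specimen inherits the shared per-triangle labels of the reference
#' (identical triangle counts by construction); per-specimen region areas are
#' computed from the specimen's own vertex geometry.
#'
#' @param reference_labels character vector of per-triangle labels (usually
#'   the reference mesh labels already carried by `homology`).
#' @param homology a `homologous_mesh_set`.
#' @return `homology` with `region` set and a `region_area_table` data.frame
#'   (one row per specimen, one column per region, mm^2).
#' @export
transfer_cartilage_regions <- function(reference_labels, homology) {
  if (length(reference_labels) != nrow(homology$triangulation))
    stop("labels must cover all triangles")
  if (anyNA(reference_labels)) stop("unlabeled triangles in reference labels")
  homology$region <- as.character(reference_labels)
  areas <- t(vapply(seq_along(homology$vertices), function(i)
    region_areas(homologous_mesh(homology, i)),
    region_areas(homologous_mesh(homology, 1))))
  homology$region_area_table <- data.frame(specimen = seq_along(homology$vertices),
                                           areas, check.names = FALSE)
  homology
}
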
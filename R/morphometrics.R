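#' Planar cross-section of a closed mesh
#'
#' Intersects the mesh with the plane through `point` with unit `normal` and
#' returns the section's enclosed area (via the line integral of the
#' consistently oriented intersection segments) together with the section
#' points, used by the waist search.
#'
#' @param mesh a closed [labeled_mesh] with outward orientation.
#' @param point a point on the plane.
#' @param normal plane normal (normalized internally).
#' @return list with `area` (mm^2) and `points` (n x 2 in-plane coordinates).
#' @export
cross_section <- function(mesh, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  d <- as.vector(sweep(v, 2, point) %*% normal)
  tr <- mesh$triangles
  s <- matrix(d[tr], ncol = 3)
  crossing <- which(rowSums(s > 0) %in% c(1L, 2L))
  # in-plane orthonormal basis
  u1 <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- u1 - sum(u1 * normal) * normal
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(normal[2] * u1[3] - normal[3] * u1[2],
          normal[3] * u1[1] - normal[1] * u1[3],
          normal[1] * u1[2] - normal[2] * u1[1])
  area2 <- 0
  pts <- matrix(0, 0, 2)
  for (t in crossing) {
    vi <- tr[t, ]
    dv <- d[vi]
    pos <- vi[dv > 0]
    neg <- vi[dv <= 0]
    if (length(pos) == 0 || length(neg) == 0) next
    # two edge intersection points
    ipts <- matrix(0, 2, 3)
    k <- 0
    for (a in pos) for (b in neg) {
      k <- k + 1
      lam <- d[a] / (d[a] - d[b])
      if (k <= 2) ipts[k, ] <- v[a, ] + lam * (v[b, ] - v[a, ])
    }
    if (k != 2) next
    # orient the segment along cross(triangle normal, plane normal)
    e1 <- v[vi[2], ] - v[vi[1], ]
    e2 <- v[vi[3], ] - v[vi[1], ]
    tn <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    dir <- c(tn[2] * normal[3] - tn[3] * normal[2],
             tn[3] * normal[1] - tn[1] * normal[3],
             tn[1] * normal[2] - tn[2] * normal[1])
    if (sum((ipts[2, ] - ipts[1, ]) * dir) < 0) ipts <- ipts[2:1, ]
    p1 <- c(sum((ipts[1, ] - point) * u1), sum((ipts[1, ] - point) * u2))
    p2 <- c(sum((ipts[2, ] - point) * u1), sum((ipts[2, ] - point) * u2))
    area2 <- area2 + (p1[1] * p2[2] - p2[1] * p1[2])
    pts <- rbind(pts, p1, p2)
  }
  list(area = abs(area2) / 2, points = pts)
}

#' Morphometric descriptors of a scaphoid surface model
#'
#' Computes the descriptors used for the population tables: total length
#' (extent along the long axis), the two orthogonal waist diameters at the
#' minimal cross-section (searched over a band of stations around
#' mid-length), the mean width of the dorsal rough surface strip, the
#' per-region surface areas and the total surface area.
#'
#' The long axis defaults to the first principal axis of the vertex cloud.
#' The waist is the station with minimal cross-section area among
#' `n_stations` equally spaced planes covering the central `waist_band`
#' fraction of the length; its first diameter is the maximal in-plane
#' point-pair extent, the second the extent perpendicular to the first.
#' Dorsal width is the mean, over stations along the strip, of the strip's
#' extent perpendicular to the long axis within the strip plane.
#'
#' @param mesh a closed [labeled_mesh].
#' @param axis optional unit long axis (3-vector).
#' @param waist_band central fraction of the length scanned for the waist.
#' @param n_stations number of waist-search stations.
#' @return an object of class `morphometrics`: list with `length`,
#'   `waist_diameters` (ordered pair, mm), `waist_area`, `waist_position`
#'   (fraction of length), `dorsal_width`, `region_areas`, `total_area`.
#' @export
measure_morphometrics <- function(mesh, axis = NULL, waist_band = 0.6,
                                  n_stations = 100) {
  if (!is_closed_mesh(mesh)) stop("measure_morphometrics needs a closed mesh")
  ax <- principal_axes(mesh$vertices)
  if (is.null(axis)) axis <- ax$axes[, 1]
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.vector(sweep(mesh$vertices, 2, ax$centre) %*% axis)
  len <- max(proj) - min(proj)
  lo <- min(proj) + (1 - waist_band) / 2 * len
  stations <- seq(lo, lo + waist_band * len, length.out = n_stations)
  areas <- numeric(n_stations)
  secs <- vector("list", n_stations)
  for (i in seq_len(n_stations)) {
    cs <- cross_section(mesh, ax$centre + stations[i] * axis, axis)
    areas[i] <- cs$area
    secs[[i]] <- cs$points
  }
  # the waist is a local narrowing: take the smallest interior local minimum
  # of the area profile; shapes without one (e.g. a sphere, where sections
  # only shrink toward the band edges) fall back to the mid-length station
  n <- length(areas)
  locmin <- which(areas[2:(n - 1)] <= areas[1:(n - 2)] &
                  areas[2:(n - 1)] <= areas[3:n]) + 1L
  wi <- if (length(locmin)) locmin[which.min(areas[locmin])]
        else which.min(abs(stations - (max(proj) + min(proj)) / 2))
  wp <- secs[[wi]]
  if (nrow(wp) >= 2) {
    dmat <- as.matrix(stats::dist(wp))
    mx <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    dir1 <- wp[mx[2], ] - wp[mx[1], ]
    dir1 <- dir1 / sqrt(sum(dir1^2))
    d1 <- diff(range(wp %*% dir1))
    dir2 <- c(-dir1[2], dir1[1])
    d2 <- diff(range(wp %*% dir2))
  } else d1 <- d2 <- NA_real_
  # dorsal strip width
  bone <- mesh$region == "bone"
  dorsal_width <- NA_real_
  if (any(bone) && !all(bone)) {
    sv <- unique(as.vector(mesh$triangles[bone, ]))
    strip <- mesh$vertices[sv, , drop = FALSE]
    # strip-plane width direction: perpendicular to the long axis and to the
    # mean strip normal
    a <- mesh$vertices[mesh$triangles[bone, 2], , drop = FALSE] -
         mesh$vertices[mesh$triangles[bone, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$triangles[bone, 3], , drop = FALSE] -
         mesh$vertices[mesh$triangles[bone, 1], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nbar <- colSums(nrm)
    nbar <- nbar / sqrt(sum(nbar^2))
    wdir <- c(nbar[2] * axis[3] - nbar[3] * axis[2],
              nbar[3] * axis[1] - nbar[1] * axis[3],
              nbar[1] * axis[2] - nbar[2] * axis[1])
    wdir <- wdir / sqrt(sum(wdir^2))
    sproj <- as.vector(sweep(strip, 2, ax$centre) %*% axis)
    r <- range(sproj)
    r <- r + c(0.1, -0.1) * diff(r)           # trim strip tips
    st <- seq(r[1], r[2], length.out = 9)
    bw <- diff(r) / 8
    widths <- vapply(st, function(s) {
      sel <- abs(sproj - s) <= bw
      if (sum(sel) < 2) return(NA_real_)
      diff(range(strip[sel, , drop = FALSE] %*% wdir))
    }, numeric(1))
    dorsal_width <- mean(widths, na.rm = TRUE)
  }
  ra <- region_areas(mesh)
  structure(list(length = len,
                 waist_diameters = sort(c(d1, d2), decreasing = TRUE),
                 waist_area = areas[wi],
                 waist_position = (stations[wi] - min(proj)) / len,
                 dorsal_width = dorsal_width,
                 region_areas = ra, total_area = sum(ra)),
            class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("length %.2f mm, waist %.2f x %.2f mm (area %.1f mm^2 at %.0f%%), dorsal width %s, total area %.1f mm^2\n",
              x$length, x$waist_diameters[1], x$waist_diameters[2],
              x$waist_area, 100 * x$waist_position,
              ifelse(is.na(x$dorsal_width), "n/a",
                     sprintf("%.2f mm", x$dorsal_width)), x$total_area))
  invisible(x)
}

#' Descriptive population statistics in mean +/- SD (min-max) layout
#'
#' @param values numeric vector (n >= 2) or a data.frame of per-specimen
#'   descriptor columns.
#' @param digits digits for the formatted string.
#' @return for a vector, a one-row data.frame with `mean`, `sd`, `min`,
#'   `max`, `n` and `formatted`; for a data.frame, one row per column.
#' @export
population_stats <- function(values, digits = 1) {
  if (is.data.frame(values)) {
    out <- do.call(rbind, lapply(names(values), function(nm) {
      r <- population_stats(values[[nm]], digits = digits)
      cbind(descriptor = nm, r)
    }))
    rownames(out) <- NULL
    return(out)
  }
  values <- as.numeric(values)
  data.frame(mean = mean(values), sd = stats::sd(values),
             min = min(values), max = max(values), n = length(values),
             formatted = sprintf(
               paste0("%.", digits, "f ± %.", digits, "f (%.", digits,
                      "f-%.", digits, "f)"),
               mean(values), stats::sd(values), min(values), max(values)))
}
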
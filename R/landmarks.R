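#' Landmark set: homologous points, segment polylines, region boundaries
#'
#' Named anatomical (homologous) landmarks, ordered segment-landmark
#' polylines connecting pairs of homologous landmarks along sharp edges and
#' curvatures, and region boundary loops delimiting the cartilage facets and
#' the dorsal rough surface.
#'
#' @param homologous named list of length-3 numeric vectors (mm), or a
#'   3-column matrix with rownames.
#' @param segments list of `list(name, from, to, points)` where `from`/`to`
#'   name homologous landmarks and `points` is the full ordered polyline
#'   (n x 3, first and last rows equal to the flanking homologous landmarks).
#' @param regions list of `list(name, loop)` with `loop` an ordered n x 3
#'   boundary polygon.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(homologous, segments = list(), regions = list()) {
  if (is.matrix(homologous)) {
    nm <- rownames(homologous)
    homologous <- lapply(seq_len(nrow(homologous)), function(i) homologous[i, ])
    names(homologous) <- nm
  }
  if (is.null(names(homologous)) || any(names(homologous) == ""))
    stop("homologous landmarks must be named")
  homologous <- lapply(homologous, as.numeric)
  for (s in segments) {
    if (!all(c("name", "from", "to", "points") %in% names(s)))
      stop("each segment needs name, from, to, points")
    if (nrow(s$points) < 2) stop("segment polylines need >= 2 points")
  }
  structure(list(homologous = homologous, segments = segments,
                 regions = regions), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d homologous, %d segments, %d region loops\n",
              length(x$homologous), length(x$segments), length(x$regions)))
  invisible(x)
}

#' Resample segment landmarks to equidistant points
#'
#' Every segment polyline is replaced by `points_per_segment` points at equal
#' arc-length spacing along the piecewise-linear polyline; the endpoints (the
#' flanking homologous landmarks) are preserved exactly. After resampling all
#' specimens carry identical landmark counts and orderings, which is what
#' makes the segment landmarks usable as thin-plate-spline controls.
#'
#' @param landmarks a [landmark_set].
#' @param points_per_segment integer >= 2, number of points per segment
#'   including both endpoints.
#' @return the resampled [landmark_set].
#' @export
resample_segments <- function(landmarks, points_per_segment) {
  if (points_per_segment < 2) stop("points_per_segment must be >= 2")
  landmarks$segments <- lapply(landmarks$segments, function(s) {
    p <- as.matrix(s$points)
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (sum(seg) <= 0) stop("zero-length segment: ", s$name)
    arc <- c(0, cumsum(seg))
    tgt <- seq(0, arc[length(arc)], length.out = points_per_segment)
    out <- cbind(stats::approx(arc, p[, 1], xout = tgt)$y,
                 stats::approx(arc, p[, 2], xout = tgt)$y,
                 stats::approx(arc, p[, 3], xout = tgt)$y)
    out[1, ] <- p[1, ]
    out[points_per_segment, ] <- p[nrow(p), ]
    s$points <- out
    s
  })
  landmarks
}

#' Thin-plate-spline control matrix of a landmark set
#'
#' Stacks the homologous landmarks (in name order) and the interior segment
#' points (in segment order) into one k x 3 matrix; segment endpoints are
#' dropped as they duplicate homologous landmarks. Specimens resampled to the
#' same `points_per_segment` yield row-wise corresponding control matrices.
#'
#' @param landmarks a [landmark_set].
#' @return numeric k x 3 matrix with rownames.
#' @export
landmark_controls <- function(landmarks) {
  nm <- sort(names(landmarks$homologous))
  hom <- do.call(rbind, landmarks$homologous[nm])
  segs <- lapply(landmarks$segments, function(s) {
    p <- as.matrix(s$points)
    p[-c(1, nrow(p)), , drop = FALSE]
  })
  segnames <- unlist(lapply(landmarks$segments, function(s)
    paste0(s$name, "_", seq_len(nrow(s$points) - 2))))
  out <- rbind(hom, do.call(rbind, segs))
  rownames(out) <- c(nm, segnames)
  out
}

#' Write / read landmark sets as JSON
#'
#' The on-disk dialect is
#' `{"homologous": [{name, xyz}], "segments": [{name, from, to, points}],`
#' `"regions": [{name, loop}]}`.
#'
#' @param landmarks a [landmark_set].
#' @param path file path.
#' @return `read_landmarks` returns a [landmark_set].
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- list(
    homologous = lapply(names(landmarks$homologous), function(n)
      list(name = n, xyz = landmarks$homologous[[n]])),
    segments = lapply(landmarks$segments, function(s)
      list(name = s$name, from = s$from, to = s$to,
           points = unname(as.matrix(s$points)))),
    regions = lapply(landmarks$regions, function(r)
      list(name = r$name, loop = unname(as.matrix(r$loop)))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  hom <- lapply(seq_len(nrow(obj$homologous)), function(i)
    as.numeric(obj$homologous$xyz[[i]]))
  names(hom) <- obj$homologous$name
  segs <- if (length(obj$segments)) lapply(seq_len(nrow(obj$segments)), function(i)
    list(name = obj$segments$name[i], from = obj$segments$from[i],
         to = obj$segments$to[i], points = obj$segments$points[[i]]))
    else list()
  regs <- if (length(obj$regions)) lapply(seq_len(nrow(obj$regions)), function(i)
    list(name = obj$regions$name[i], loop = obj$regions$loop[[i]]))
    else list()
  landmark_set(hom, segs, regs)
}
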
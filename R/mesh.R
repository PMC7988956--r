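#' Triangulated surface mesh with per-triangle region labels
#'
#' The surface container used throughout the pipeline: a closed triangulated
#' surface in millimetre coordinates, each triangle carrying one of the five
#' anatomical region labels (`bone` for the dorsal rough surface plus four
#' articular cartilage facets).
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates (mm).
#' @param triangles integer T x 3 matrix of 1-based vertex indices.
#' @param region character vector of length T with region labels, or `NULL`
#'   for all-`"bone"`.
#' @return an object of class `labeled_mesh` with elements `vertices`,
#'   `triangles`, `region`.
#' @export
labeled_mesh <- function(vertices, triangles, region = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be a T x 3 matrix")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  if (is.null(region)) region <- rep("bone", nrow(triangles))
  if (length(region) != nrow(triangles))
    stop("region must have one label per triangle")
  structure(list(vertices = vertices, triangles = triangles,
                 region = as.character(region)),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh: %d vertices, %d triangles, regions: %s\n",
              nrow(x$vertices), nrow(x$triangles),
              paste(names(table(x$region)), collapse = ", ")))
  invisible(x)
}

# unique undirected edges as a 2-column matrix of sorted index pairs
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(3, 1), drop = FALSE])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  list(key = key, unique = unique(key))
}

#' Closedness, Euler characteristic and genus of a mesh
#'
#' A mesh is closed (watertight) when every edge is shared by exactly two
#' triangles. For a closed surface the Euler characteristic
#' `V - E + T = 2 - 2g` gives the genus `g`; a closed genus-0 triangulation
#' satisfies `T = 2 V - 4`.
#'
#' @param mesh a [labeled_mesh].
#' @return `is_closed_mesh`: logical; `euler_characteristic`: integer;
#'   `mesh_genus`: integer (NA for open meshes).
#' @export
is_closed_mesh <- function(mesh) {
  ed <- mesh_edges(mesh)
  all(tabulate(match(ed$key, ed$unique)) == 2L)
}

#' @rdname is_closed_mesh
#' @export
euler_characteristic <- function(mesh) {
  ed <- mesh_edges(mesh)
  nrow(mesh$vertices) - length(ed$unique) + nrow(mesh$triangles)
}

#' @rdname is_closed_mesh
#' @export
mesh_genus <- function(mesh) {
  if (!is_closed_mesh(mesh)) return(NA_integer_)
  as.integer((2L - euler_characteristic(mesh)) / 2L)
}

#' Triangle areas, total surface area and enclosed volume
#'
#' Surface area is the sum of triangle areas; the enclosed volume uses the
#' divergence theorem on the signed tetrahedra spanned by each triangle and
#' the origin, so it is positive for consistently outward-oriented closed
#' meshes.
#'
#' @param mesh a [labeled_mesh].
#' @return `triangle_areas`: numeric vector (mm^2); `mesh_area`: total mm^2;
#'   `mesh_volume`: signed volume (mm^3).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname triangle_areas
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' @rdname triangle_areas
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Surface area per region label
#'
#' @param mesh a [labeled_mesh].
#' @return named numeric vector of summed triangle areas (mm^2) per label.
#' @export
region_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  vapply(split(ta, mesh$region), sum, numeric(1))
}

#' Point-in-mesh and nearest-point queries
#'
#' `points_in_mesh` classifies points by ray-crossing parity against a closed
#' mesh. `project_to_mesh` returns, for each query point, the nearest point
#' on the mesh surface, its distance and the 1-based face index (ties broken
#' by the lowest face index encountered in the spatial search).
#'
#' @param mesh a [labeled_mesh] (closed for `points_in_mesh`).
#' @param points numeric n x 3 matrix.
#' @return `points_in_mesh`: logical vector; `project_to_mesh`: list with
#'   `distance`, `point` (n x 3), `face`.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- matrix(as.double(points), ncol = 3)
  .cpp_points_in_mesh(mesh$vertices, mesh$triangles, points)
}

#' @rdname points_in_mesh
#' @export
project_to_mesh <- function(mesh, points) {
  points <- matrix(as.double(points), ncol = 3)
  .cpp_mesh_nearest(mesh$vertices, mesh$triangles, points)
}

#' Principal axes of a point cloud with a deterministic sign convention
#'
#' Eigenvectors of the coordinate covariance, ordered by decreasing
#' eigenvalue. Each axis is oriented so that its largest-magnitude component
#' is positive, which makes axis directions reproducible across runs and
#' comparable between the phantom generator and the zone segmentation.
#'
#' @param points numeric n x 3 matrix.
#' @return list with `axes` (3 x 3, columns = axes), `centre` (length-3),
#'   `sdev` (length-3 standard deviations along the axes).
#' @export
principal_axes <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  e <- eigen(stats::cov(points), symmetric = TRUE)
  ax <- e$vectors
  for (i in 1:3) {
    m <- which.max(abs(ax[, i]))
    if (ax[m, i] < 0) ax[, i] <- -ax[, i]
  }
  list(axes = ax, centre = ctr, sdev = sqrt(pmax(e$values, 0)))
}

#' Write / read a labelled mesh as ASCII PLY
#'
#' Standard PLY with an extra per-face integer property `region_id`; the
#' id-to-name mapping is stored in header comments so labels round-trip.
#'
#' @param mesh a [labeled_mesh].
#' @param path file path.
#' @return `read_ply` returns a [labeled_mesh]; `write_ply` returns `path`
#'   invisibly.
#' @export
write_ply <- function(mesh, path) {
  lev <- sort(unique(mesh$region))
  id <- match(mesh$region, lev) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("comment region", seq_along(lev) - 1L, lev),
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices",
    "property int region_id",
    "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L, id),
             con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hend <- which(lines == "end_header")[1]
  if (is.na(hend)) stop("not an ASCII PLY file: ", path)
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  regc <- grep("^comment region ", header, value = TRUE)
  lev <- character(0)
  if (length(regc)) {
    parts <- strsplit(regc, " ")
    ids <- vapply(parts, function(p) as.integer(p[3]), integer(1))
    lev[ids + 1L] <- vapply(parts, function(p) p[4], character(1))
  }
  vl <- lines[hend + seq_len(nv)]
  verts <- matrix(as.numeric(unlist(strsplit(vl, " "), use.names = FALSE)),
                  ncol = 3, byrow = TRUE)
  fl <- lines[hend + nv + seq_len(nf)]
  fm <- matrix(as.integer(unlist(strsplit(fl, " "), use.names = FALSE)),
               ncol = 5, byrow = TRUE)
  region <- if (length(lev)) lev[fm[, 5] + 1L] else NULL
  labeled_mesh(verts, fm[, 2:4] + 1L, region)
}
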
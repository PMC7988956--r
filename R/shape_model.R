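#' Non-scaling generalized Procrustes alignment
#'
#' Iterative superimposition of the corresponded shapes: each shape is
#' optimally translated and rotated (proper rotations only, determinant +1,
#' so anatomical chirality is preserved; no scaling, so size stays in the
#' model and the PCA captures joint size-and-shape, i.e. form) onto the
#' current mean; the mean is recomputed and re-centred until it moves less
#' than `tol`. Centroid size of every shape is preserved exactly.
#'
#' @param homology a `homologous_mesh_set` (>= 2 specimens).
#' @param tol convergence tolerance on the RMS mean-shape change (mm); the
#'   tight default makes alignment idempotent to numerical precision.
#' @param max_iter iteration cap.
#' @return the input set with aligned `vertices`, plus `mean_vertices`,
#'   `iterations` and `converged`.
#' @export
procrustes_align <- function(homology, tol = 1e-10, max_iter = 200) {
  shapes <- homology$vertices
  if (length(shapes) < 2) stop("need at least 2 shapes")
  nv <- vapply(shapes, nrow, integer(1))
  if (length(unique(nv)) != 1) stop("topology mismatch: unequal vertex counts")
  shapes <- lapply(shapes, function(s) scale(s, scale = FALSE))
  # initializing with the arithmetic mean (not an arbitrary specimen) keeps
  # the orientation gauge of an already-aligned set, making re-alignment a
  # no-op
  mean_shape <- scale(Reduce(`+`, shapes) / length(shapes), scale = FALSE)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    # convergence is judged on the largest per-shape movement, not only the
    # mean: individual rotations can still drift while their average cancels
    delta <- 0
    shapes <- lapply(shapes, function(s) {
      s2 <- s %*% kabsch_rotation(s, mean_shape)
      delta <<- max(delta, sqrt(mean((s2 - s)^2)))
      s2
    })
    new_mean <- scale(Reduce(`+`, shapes) / length(shapes), scale = FALSE)
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  homology$vertices <- lapply(shapes, function(s) {
    attr(s, "scaled:center") <- NULL
    s
  })
  attr(mean_shape, "scaled:center") <- NULL
  homology$mean_vertices <- mean_shape
  homology$iterations <- iterations
  homology$converged <- converged
  homology
}

#' Centroid size of a configuration
#'
#' Root-sum-of-squares distance of the vertices from their centroid; the
#' quantity preserved by a non-scaling Procrustes fit.
#'
#' @param vertices V x 3 matrix.
#' @return numeric scalar (mm).
#' @export
centroid_size <- function(vertices) {
  sqrt(sum(scale(vertices, scale = FALSE)^2))
}

#' Principal component analysis of the aligned shapes
#'
#' Eigendecomposition of the vertex-coordinate covariance (divisor N - 1)
#' about the mean shape, computed through the SVD of the centred data
#' matrix. Modes are sorted by decreasing variance and orthonormal; scores
#' are the projections of the centred specimens onto the modes, so every
#' training specimen is reconstructed exactly from all modes. Mode signs are
#' fixed by a documented convention: each mode is oriented so that its
#' displacement field elongates the shape along the mean's long axis (or,
#' when that projection is negligible, along the second axis).
#'
#' @param aligned a `homologous_mesh_set` after [procrustes_align].
#' @param n_modes maximum number of modes to retain (truncated with a notice
#'   when fewer non-degenerate modes exist).
#' @return an object of class `shape_model`: `mean_vertices`,
#'   `triangulation`, `region`, `modes` (3V x M orthonormal columns),
#'   `mode_variances` (mm^2), `variance_fractions` (sums to 1), `scores`
#'   (N x M, mm), `n_specimens`, `degenerate` flag.
#' @export
fit_shape_pca <- function(aligned, n_modes = Inf) {
  if (is.null(aligned$mean_vertices))
    stop("run procrustes_align before fit_shape_pca")
  shapes <- aligned$vertices
  n <- length(shapes)
  if (n < 3) stop("PCA needs at least 3 shapes")
  X <- t(vapply(shapes, as.vector, numeric(length(shapes[[1]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  total_var <- sum(sv$d^2) / (n - 1)
  degenerate <- total_var <= 1e-24
  keep <- seq_len(min(n - 1, length(sv$d)))
  if (is.finite(n_modes) && length(keep) > n_modes) {
    keep <- head(keep, n_modes)
  } else if (is.finite(n_modes) && length(keep) < n_modes && !degenerate) {
    message("only ", length(keep), " modes available (",
            n_modes, " requested)")
  }
  modes <- sv$v[, keep, drop = FALSE]
  variances <- sv$d[keep]^2 / (n - 1)
  scores <- Xc %*% modes
  V <- nrow(aligned$mean_vertices)
  axes <- principal_axes(aligned$mean_vertices)
  a <- axes$axes[, 1]
  pos1 <- as.vector(sweep(aligned$mean_vertices, 2, axes$centre) %*% a)
  pos2 <- as.vector(sweep(aligned$mean_vertices, 2, axes$centre) %*% axes$axes[, 2])
  for (m in seq_along(keep)) {
    fld <- matrix(modes[, m], V, 3)
    proj <- sum((fld %*% a) * pos1)
    if (abs(proj) < 1e-9) proj <- sum((fld %*% axes$axes[, 2]) * pos2)
    if (proj < 0) {
      modes[, m] <- -modes[, m]
      scores[, m] <- -scores[, m]
    }
  }
  structure(list(mean_vertices = matrix(colMeans(X), V, 3),
                 triangulation = aligned$triangulation,
                 region = aligned$region,
                 modes = modes, mode_variances = variances,
                 variance_fractions = if (degenerate) rep(0, length(variances))
                                      else variances / total_var,
                 scores = scores, n_specimens = n,
                 degenerate = degenerate),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d specimens, %d vertices, %d modes\n",
              x$n_specimens, nrow(x$mean_vertices), ncol(x$modes)))
  if (x$degenerate) cat("degenerate model: total variance is zero\n")
  else cat("variance fractions:",
           paste(sprintf("%.1f%%", 100 * head(x$variance_fractions, 5)),
                 collapse = ", "),
           if (length(x$variance_fractions) > 5) "..." else "", "\n")
  invisible(x)
}

#' Synthesize a shape at k standard deviations along one mode
#'
#' `vertices = mean + k_sd * sqrt(mode_variance) * mode`, sharing the model
#' triangulation and region labels; `k_sd = 0` returns the mean mesh.
#'
#' @param model a `shape_model`.
#' @param mode 1-based mode index.
#' @param k_sd displacement in mode standard deviations (e.g. -2, 0, +2).
#' @return a [labeled_mesh].
#' @export
synthesize_shape <- function(model, mode = 1, k_sd = 0) {
  if (mode > ncol(model$modes)) stop("mode index exceeds available modes")
  V <- nrow(model$mean_vertices)
  disp <- matrix(model$modes[, mode], V, 3) * k_sd * sqrt(model$mode_variances[mode])
  labeled_mesh(model$mean_vertices + disp, model$triangulation, model$region)
}

#' Reconstruct a training specimen from the model
#'
#' @param model a `shape_model`.
#' @param i specimen index.
#' @param n_modes number of leading modes to use (default all).
#' @return V x 3 matrix of reconstructed aligned vertices.
#' @export
reconstruct_specimen <- function(model, i, n_modes = ncol(model$modes)) {
  V <- nrow(model$mean_vertices)
  use <- seq_len(n_modes)
  model$mean_vertices +
    matrix(model$modes[, use, drop = FALSE] %*% model$scores[i, use], V, 3)
}
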
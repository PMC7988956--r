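#' Fit a 3D thin-plate-spline transformation
#'
#' Interpolating (or, for `lambda > 0`, regularized) thin-plate spline from
#' `source` control points to `target` points, with the 3D biharmonic kernel
#' `U(r) = r`. The transform is the minimizer of bending energy subject to
#' mapping controls to targets; its kernel weights satisfy the standard side
#' conditions (zero sum and zero first moments), which makes the spline
#' reproduce affine maps exactly with zero kernel weights.
#'
#' @param source,target k x 3 matrices of corresponding control points (mm);
#'   `k >= 4`, not coplanar.
#' @param lambda regularization >= 0; 0 (the default) interpolates exactly.
#' @return an object of class `tps_transform` with `control_source`,
#'   `control_target`, `affine` (4 x 3: intercept row then linear map) and
#'   `weights` (k x 3).
#' @export
fit_tps <- function(source, target, lambda = 0) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  k <- nrow(source)
  if (k < 4) stop("TPS needs at least 4 control points")
  if (nrow(target) != k) stop("source and target must have equal rows")
  if (anyDuplicated(source))
    stop("duplicated control points: TPS system is singular")
  sv <- svd(scale(source, scale = FALSE))$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("coplanar control points: affine part is ill-conditioned (singular values ",
         paste(signif(sv, 3), collapse = ", "), ")")
  # solve in centred, scaled coordinates for conditioning; the U(r) = r
  # kernel is homogeneous, so weights transfer to the original frame and
  # only the affine part needs unscaling
  ctr <- colMeans(source)
  sc <- mean(sqrt(rowSums(sweep(source, 2, ctr)^2)))
  if (sc <= 0) sc <- 1
  Sn <- sweep(source, 2, ctr) / sc
  Tn <- sweep(target, 2, ctr) / sc
  K <- as.matrix(stats::dist(Sn))
  P <- cbind(1, Sn)
  A <- rbind(cbind(K + diag(lambda / sc, k), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Tn, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  sol <- sol + solve(A, rhs - A %*% sol)   # one step of iterative refinement
  w <- sol[seq_len(k), , drop = FALSE]
  an <- sol[k + 1:4, , drop = FALSE]
  B <- an[2:4, , drop = FALSE]                       # linear part (frame-free)
  intercept <- ctr + sc * an[1, ] - as.vector(ctr %*% B)
  affine <- rbind(intercept, B)
  dimnames(affine) <- NULL
  dimnames(w) <- NULL
  structure(list(control_source = source, control_target = target,
                 weights = w, affine = affine, lambda = lambda),
            class = "tps_transform")
}

#' Apply a thin-plate-spline transformation to points
#'
#' Evaluates `f(x) = c + B x + sum_i w_i U(|x - s_i|)` for each query point;
#' deterministic, memory-bounded by chunked evaluation of the kernel matrix.
#'
#' @param transform a `tps_transform` from [fit_tps].
#' @param points n x 3 matrix.
#' @param chunk number of points per kernel-matrix block.
#' @return n x 3 matrix of warped points.
#' @export
apply_tps <- function(transform, points, chunk = 20000L) {
  points <- matrix(as.double(points), ncol = 3)
  n <- nrow(points)
  out <- matrix(0, n, 3)
  S <- transform$control_source
  k <- nrow(S)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    p <- points[idx, , drop = FALSE]
    # distances by direct differencing (cancellation-free near controls)
    U <- matrix(0, nrow(p), k)
    for (j in seq_len(k))
      U[, j] <- sqrt((p[, 1] - S[j, 1])^2 + (p[, 2] - S[j, 2])^2 +
                     (p[, 3] - S[j, 3])^2)
    out[idx, ] <- cbind(1, p) %*% transform$affine + U %*% transform$weights
  }
  out
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("tps_transform: %d controls, lambda = %g\n",
              nrow(x$control_source), x$lambda))
  invisible(x)
}
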
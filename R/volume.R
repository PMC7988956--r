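#' Calibrated 3D density volume
#'
#' Isotropic voxel grid of CT attenuation (HU) or calibrated volumetric bone
#' mineral density (vBMD, mg HA/cm^3). Voxel `(i,j,k)` (0-based) is centred
#' at `origin + c(i,j,k) * voxel_size`; meshes and volumes share this
#' millimetre frame.
#'
#' @param values 3D numeric array.
#' @param voxel_size isotropic voxel edge length (mm), > 0.
#' @param origin length-3 position (mm) of the centre of voxel (0,0,0).
#' @param units `"HU"` or `"vBMD"`.
#' @param calibration named vector `c(slope =, intercept =)` of the linear
#'   HU to vBMD machine calibration (mg HA/cm^3 per HU and mg HA/cm^3), or
#'   `NULL` when unknown.
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size, origin = c(0, 0, 0),
                           units = c("HU", "vBMD"), calibration = NULL) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.null(calibration)) {
    calibration <- c(slope = unname(calibration["slope"]),
                     intercept = unname(calibration["intercept"]))
    if (any(is.na(calibration))) stop("calibration needs slope and intercept")
  }
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), units = units,
                 calibration = calibration),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("density_volume: %s voxels at %.4g mm, units %s, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = " x "), x$voxel_size, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Clamp non-osseous attenuation to zero
#'
#' Voxels with attenuation below 0 HU (soft tissue, air, embedding medium)
#' are set to 0 HU before density calibration; all other voxels and the
#' volume metadata are unchanged. Defined on HU-mode volumes only.
#'
#' @param volume a [density_volume] with `units == "HU"`.
#' @return the clamped [density_volume].
#' @export
clamp_nonosseous <- function(volume) {
  if (volume$units != "HU")
    stop("clamp_nonosseous is defined on HU volumes; got units = ", volume$units)
  volume$values[volume$values < 0] <- 0
  volume
}

#' Convert HU to volumetric bone mineral density
#'
#' Applies the linear machine calibration `vBMD = slope * HU + intercept`
#' elementwise and relabels the volume as vBMD (mg HA/cm^3).
#'
#' @param volume a [density_volume] with `units == "HU"` and a calibration.
#' @return the calibrated [density_volume] with `units == "vBMD"`.
#' @export
hu_to_vbmd <- function(volume) {
  if (volume$units != "HU")
    stop("hu_to_vbmd expects an HU volume; got units = ", volume$units)
  if (is.null(volume$calibration))
    stop("volume has no HU to vBMD calibration")
  volume$values <- volume$calibration["slope"] * volume$values +
    volume$calibration["intercept"]
  dimnames(volume$values) <- NULL
  attr(volume$values, "names") <- NULL
  volume$units <- "vBMD"
  volume
}

#' Mirror left-sided specimens to right
#'
#' Left-handed inputs are reflected across the sagittal mid-plane of the
#' object (the plane `x = x_mid` of its bounding box); right-handed inputs
#' are returned unchanged. For meshes the triangle winding is re-flipped so
#' outward normals are preserved; for volumes the voxel lattice maps onto
#' itself, so mirroring is an exact involution in both cases.
#'
#' @param x a [density_volume] or [labeled_mesh].
#' @param handedness `"left"` or `"right"`.
#' @param plane_x for meshes, the reflection plane `x = plane_x`; defaults to
#'   the bounding-box mid-plane. Volumes always reflect across their own
#'   lattice mid-plane so voxel centres map onto voxel centres.
#' @return an object of the same class as `x`.
#' @export
mirror_to_right <- function(x, handedness = c("right", "left"), plane_x = NULL) {
  handedness <- match.arg(handedness)
  if (handedness == "right") return(x)
  UseMethod("mirror_to_right")
}

#' @export
mirror_to_right.density_volume <- function(x, handedness = c("right", "left"),
                                           plane_x = NULL) {
  x$values <- x$values[dim(x$values)[1]:1, , , drop = FALSE]
  x
}

#' @export
mirror_to_right.labeled_mesh <- function(x, handedness = c("right", "left"),
                                         plane_x = NULL) {
  if (is.null(plane_x))
    plane_x <- (min(x$vertices[, 1]) + max(x$vertices[, 1])) / 2
  x$vertices[, 1] <- 2 * plane_x - x$vertices[, 1]
  x$triangles <- x$triangles[, c(1, 3, 2), drop = FALSE]
  x
}

#' Trilinear interpolation of a density volume
#'
#' Standard trilinear interpolation over the eight voxel centres surrounding
#' each query point. Points outside the voxel-centre hull return `NA` (the
#' sentinel excluded from all averages downstream). When a logical `mask`
#' (same dimensions as the volume) is supplied, masked-out corners receive
#' zero weight and the remaining weights are renormalised; this is the
#' partial-volume-aware mode used when sampling near the bone surface, where
#' plain interpolation would blend bone with background. A point whose eight
#' corners are all masked out returns `NA`.
#'
#' @param volume a [density_volume].
#' @param points numeric n x 3 matrix of query points (mm).
#' @param mask optional logical array, `TRUE` where voxels carry valid tissue
#'   values.
#' @return numeric vector of length n.
#' @export
trilinear_sample <- function(volume, points, mask = NULL) {
  points <- matrix(as.double(points), ncol = 3)
  d <- dim(volume$values)
  g <- sweep(points, 2, volume$origin, "-") / volume$voxel_size
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(points))
  if (!any(ok)) return(out)
  gi <- g[ok, , drop = FALSE]
  i0 <- pmin(floor(gi), matrix(rep(d - 2L, each = nrow(gi)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- gi - i0
  n <- nrow(gi)
  vals <- matrix(0, n, 8)
  wts <- matrix(0, n, 8)
  corner <- expand.grid(0:1, 0:1, 0:1)
  for (c8 in 1:8) {
    ci <- i0[, 1] + corner[c8, 1]
    cj <- i0[, 2] + corner[c8, 2]
    ck <- i0[, 3] + corner[c8, 3]
    lin <- 1 + ci + d[1] * (cj + d[2] * ck)
    vals[, c8] <- volume$values[lin]
    w <- (if (corner[c8, 1] == 1) f[, 1] else 1 - f[, 1]) *
         (if (corner[c8, 2] == 1) f[, 2] else 1 - f[, 2]) *
         (if (corner[c8, 3] == 1) f[, 3] else 1 - f[, 3])
    if (!is.null(mask)) w <- w * as.numeric(mask[lin])
    wts[, c8] <- w
  }
  tot <- rowSums(wts)
  res <- rowSums(vals * wts) / tot
  res[tot <= 0] <- NA_real_
  out[ok] <- res
  out
}

#' Read and write density volumes (NIfTI and MHD/RAW)
#'
#' `write_volume`/`read_volume` dispatch on the file extension: `.nii` /
#' `.nii.gz` go through RNifti; `.mhd` uses a MetaImage text header next to a
#' little-endian float64 `.raw` file (a plain-text-plus-binary pair that
#' round-trips values exactly). Units and calibration are stored in the MHD
#' header; NIfTI files reload as HU with no calibration unless supplied.
#'
#' @param volume a [density_volume].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @param units,calibration metadata to attach when reading formats that do
#'   not carry them.
#' @return `read_volume` returns a [density_volume].
#' @export
write_volume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- rep(volume$voxel_size, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mhd$", path)) {
    rawpath <- sub("\\.mhd$", ".raw", path)
    cal <- volume$calibration
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             paste("DimSize =", paste(dim(volume$values), collapse = " ")),
             paste("ElementSpacing =", paste(rep(volume$voxel_size, 3), collapse = " ")),
             paste("Offset =", paste(volume$origin, collapse = " ")),
             "ElementType = MET_DOUBLE",
             paste("Units =", volume$units),
             if (!is.null(cal)) paste("CalibrationSlope =", cal["slope"]),
             if (!is.null(cal)) paste("CalibrationIntercept =", cal["intercept"]),
             paste("ElementDataFile =", basename(rawpath)))
    writeLines(hdr, path)
    con <- file(rawpath, "wb")
    writeBin(as.vector(volume$values), con, size = 8, endian = "little")
    close(con)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, units = "HU", calibration = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vox <- RNifti::pixdim(img)[1]
    density_volume(array(as.numeric(img), dim = dim(img)), vox,
                   units = units, calibration = calibration)
  } else if (grepl("\\.mhd$", path)) {
    hdr <- readLines(path)
    getv <- function(key) {
      ln <- grep(paste0("^", key, " ="), hdr, value = TRUE)
      if (!length(ln)) return(NULL)
      strsplit(sub(paste0(key, " = "), "", ln[1]), " ")[[1]]
    }
    dims <- as.integer(getv("DimSize"))
    vox <- as.numeric(getv("ElementSpacing"))[1]
    org <- as.numeric(getv("Offset"))
    u <- getv("Units")
    sl <- getv("CalibrationSlope")
    ic <- getv("CalibrationIntercept")
    cal <- if (!is.null(sl)) c(slope = as.numeric(sl), intercept = as.numeric(ic))
    rawpath <- file.path(dirname(path), getv("ElementDataFile"))
    con <- file(rawpath, "rb")
    vals <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
    close(con)
    density_volume(array(vals, dim = dims), vox, origin = org,
                   units = if (!is.null(u)) u else units,
                   calibration = if (!is.null(cal)) cal else calibration)
  } else stop("unsupported volume format: ", path)
}
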
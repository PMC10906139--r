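#' Image volume on a regular isotropic grid
#'
#' Lightweight container for a 3D scalar field (an ADC map, in
#' mm^2/s x 10^-3 or as a ratio to healthy-tissue ADC, or a dimensionless
#' normalized cell density) sampled on a regular voxel grid. World
#' coordinates follow \code{origin + (index - 1) * spacing} with 1-based
#' voxel indices.
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing voxel edge length(s) in mm; a scalar (isotropic) or a
#'   length-3 vector.
#' @param origin physical position of the first voxel centre, mm (length 3).
#' @return An object of class \code{"image_volume"}: a list with elements
#'   \code{data}, \code{spacing} and \code{origin}.
#' @examples
#' v <- image_volume(array(1, c(4, 4, 4)), spacing = 2)
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  stop_if(!is.array(data) || length(dim(data)) != 3L,
          "'data' must be a 3D array")
  stop_if(!all(is.finite(data)), "'data' must be finite")
  stop_if(!is.numeric(spacing) || !length(spacing) %in% c(1L, 3L) ||
            any(!is.finite(spacing)) || any(spacing <= 0),
          "'spacing' must be positive (scalar or length 3)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stop_if(length(origin) != 3L || any(!is.finite(origin)),
          "'origin' must be a finite length-3 vector")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing %s mm, values [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Resample a volume to an isotropic grid
#'
#' Resamples a scalar volume to isotropic voxels of edge \code{target_spacing}
#' by trilinear interpolation (\code{method = "linear"}), or by
#' nearest-neighbour lookup for binary masks (\code{method = "nearest"}).
#' The output grid keeps the input origin and covers the same physical
#' extent.
#'
#' @param vol an [image_volume()] (possibly anisotropic).
#' @param target_spacing desired isotropic voxel edge, mm (> 0).
#' @param method \code{"linear"} for scalar maps, \code{"nearest"} for masks.
#' @return An [image_volume()] with isotropic spacing \code{target_spacing}.
#' @export
resample_isotropic <- function(vol, target_spacing,
                               method = c("linear", "nearest")) {
  stop_if(!inherits(vol, "image_volume"), "'vol' must be an image_volume")
  check_scalar(target_spacing, "target_spacing", positive = TRUE)
  method <- match.arg(method)
  d <- dim(vol$data)
  sp <- vol$spacing
  if (all(abs(sp - target_spacing) < 1e-12))
    return(vol)
  # keep first and last voxel centres inside the original extent
  nd <- pmax(1L, as.integer(floor((d - 1) * sp / target_spacing + 1e-9)) + 1L)
  ax <- lapply(1:3, function(k) (seq_len(nd[k]) - 1) * target_spacing / sp[k] + 1)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  vals <- if (method == "nearest") {
    i <- pmin(pmax(round(g$x), 1), d[1])
    j <- pmin(pmax(round(g$y), 1), d[2])
    k <- pmin(pmax(round(g$z), 1), d[3])
    vol$data[cbind(i, j, k)]
  } else {
    trilinear(vol$data, g$x, g$y, g$z)
  }
  out <- array(vals, nd)
  if (method == "nearest" && is.logical(vol$data)) out <- array(out > 0, nd)
  image_volume(out, target_spacing, vol$origin)
}

# trilinear gather at fractional (1-based) voxel coordinates
trilinear <- function(a, x, y, z) {
  d <- dim(a)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0[d[1] == 1L] <- 1
  y0 <- pmin(floor(y), max(d[2] - 1L, 1L))
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L))
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- function(i, j, k) a[cbind(i, j, k)]
  (1 - fx) * (1 - fy) * (1 - fz) * v(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * v(x1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * v(x0, y1, z0) +
    fx * fy * (1 - fz) * v(x1, y1, z0) +
    (1 - fx) * (1 - fy) * fz * v(x0, y0, z1) +
    fx * (1 - fy) * fz * v(x1, y0, z1) +
    (1 - fx) * fy * fz * v(x0, y1, z1) +
    fx * fy * fz * v(x1, y1, z1)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the isotropic voxel spacing.
#' Masks are stored as 0/1 integer volumes.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @param vol an [image_volume()] or a 3D array (for masks, logical).
#' @param spacing voxel spacing in mm used when \code{vol} is a bare array.
#' @return \code{read_nifti_volume()} returns an [image_volume()];
#'   \code{write_nifti_volume()} returns \code{path} invisibly.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp)
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "image_volume")) {
    data <- vol$data
    spacing <- vol$spacing
  } else {
    data <- vol
    if (is.null(spacing)) spacing <- 1
  }
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(spacing, length.out = 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
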
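#' 3D voxel grid with physical geometry
#'
#' A `voxel_grid` is the volumetric carrier used throughout the package for
#' CT images (HU), binary structure masks, and dose distributions (Gy). It
#' couples a 3D array with its physical geometry: the world position of the
#' first voxel centre (`origin`, mm) and the voxel pitch (`spacing`, mm).
#' World coordinates follow the DICOM LPS convention (+x left, +y posterior,
#' +z superior); voxel `(i, j, k)` (1-based array index) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric or logical 3D array.
#' @param spacing numeric length-3, voxel pitch in mm (all > 0).
#' @param origin numeric length-3, world coordinates (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
    d[1], d[2], d[3],
    paste(format(x$spacing), collapse = " x "),
    paste(format(x$origin), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Create a grid with the same geometry but new values
#'
#' @param grid a `voxel_grid` supplying geometry.
#' @param data replacement array (defaults to zeros).
#' @return A `voxel_grid` sharing `grid`'s origin and spacing.
#' @export
grid_like <- function(grid, data = NULL) {
  if (is.null(data)) data <- array(0, dim(grid$data))
  if (!identical(dim(data), dim(grid$data)))
    stop("replacement data must match the grid shape")
  voxel_grid(data, grid$spacing, grid$origin)
}

#' Do two grids share geometry?
#'
#' @param a,b `voxel_grid` objects.
#' @param tol geometric tolerance in mm.
#' @return `TRUE` if shape, spacing and origin agree within `tol`.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Volume of one voxel in cubic centimetres
#'
#' @param grid a `voxel_grid`.
#' @return Voxel volume in cc (1 cc = 1000 mm^3).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' Volume of a binary mask in cubic centimetres
#'
#' @param mask a `voxel_grid` with logical/0-1 values.
#' @return Mask volume in cc, by exhaustive voxel counting.
#' @export
mask_volume_cc <- function(mask) sum(mask$data != 0) * voxel_volume_cc(mask)

#' World coordinates of every voxel centre
#'
#' @param grid a `voxel_grid`.
#' @return An `n x 3` matrix of LPS world coordinates (mm), in array order
#'   (first index fastest).
#' @export
voxel_coords <- function(grid) {
  d <- dim(grid$data)
  x <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  cbind(rep(x, times = d[2] * d[3]),
        rep(rep(y, each = d[1]), times = d[3]),
        rep(z, each = d[1] * d[2]))
}

#' Centroid of a mask in world coordinates
#'
#' @param mask a binary `voxel_grid`.
#' @return Length-3 LPS world coordinates (mm) of the mask centroid.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  ijk <- unname(colMeans(idx))
  mask$origin + (ijk - 1) * mask$spacing
}

#' Resample a grid onto a target geometry
#'
#' Trilinear (`"linear"`, for continuous fields such as dose and CT) or
#' nearest-neighbour (`"nearest"`, for label masks) interpolation of `src`
#' at the voxel centres of `target`. Points outside `src` receive `fill`.
#'
#' @param src source `voxel_grid`.
#' @param target `voxel_grid` (or list with `spacing`, `origin` and `dim`)
#'   defining the output geometry.
#' @param method `"linear"` or `"nearest"`.
#' @param fill value assigned outside the source volume.
#' @return A `voxel_grid` on the target geometry.
#' @export
resample_grid <- function(src, target, method = c("linear", "nearest"),
                          fill = 0) {
  method <- match.arg(method)
  tdim <- if (is_voxel_grid(target)) dim(target$data) else target$dim
  tsp <- target$spacing
  tor <- target$origin
  pts_x <- tor[1] + (seq_len(tdim[1]) - 1) * tsp[1]
  pts_y <- tor[2] + (seq_len(tdim[2]) - 1) * tsp[2]
  pts_z <- tor[3] + (seq_len(tdim[3]) - 1) * tsp[3]
  vals <- interp_grid_at(src, pts_x, pts_y, pts_z, method = method,
                         fill = fill)
  voxel_grid(array(vals, tdim), tsp, tor)
}

# Interpolate src at the tensor-product points (pts_x x pts_y x pts_z),
# returned in array order. Continuous voxel coordinate: u = (w - origin)/sp.
interp_grid_at <- function(src, pts_x, pts_y, pts_z,
                           method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(src$data)
  nx <- length(pts_x); ny <- length(pts_y); nz <- length(pts_z)
  ux <- (pts_x - src$origin[1]) / src$spacing[1]  # 0-based continuous index
  uy <- (pts_y - src$origin[2]) / src$spacing[2]
  uz <- (pts_z - src$origin[3]) / src$spacing[3]
  expand <- function(vx, vy, vz) {
    list(x = rep(vx, times = ny * nz),
         y = rep(rep(vy, each = nx), times = nz),
         z = rep(vz, each = nx * ny))
  }
  if (method == "nearest") {
    ix <- round(ux); iy <- round(uy); iz <- round(uz)
    e <- expand(ix, iy, iz)
    ok <- e$x >= 0 & e$x <= d[1] - 1 & e$y >= 0 & e$y <= d[2] - 1 &
      e$z >= 0 & e$z <= d[3] - 1
    out <- rep(fill, nx * ny * nz)
    lin <- 1 + e$x[ok] + d[1] * (e$y[ok] + d[2] * e$z[ok])
    out[ok] <- src$data[lin]
    return(out)
  }
  # trilinear
  fx <- floor(ux); fy <- floor(uy); fz <- floor(uz)
  wx <- ux - fx; wy <- uy - fy; wz <- uz - fz
  e0 <- expand(fx, fy, fz)
  ew <- expand(wx, wy, wz)
  inside <- e0$x >= -1 + 1e-9 & e0$x <= d[1] - 1 & e0$y >= -1 + 1e-9 &
    e0$y <= d[2] - 1 & e0$z >= -1 + 1e-9 & e0$z <= d[3] - 1
  # strictly: need corners fx..fx+1 within [0, d-1]; points exactly on the
  # far face (w = 0) are fine. Treat anything whose 8-corner stencil leaves
  # the volume as outside.
  lo_ok <- e0$x >= 0 & e0$y >= 0 & e0$z >= 0
  hi_ok <- (e0$x + (ew$x > 0)) <= d[1] - 1 &
    (e0$y + (ew$y > 0)) <= d[2] - 1 &
    (e0$z + (ew$z > 0)) <= d[3] - 1
  ok <- inside & lo_ok & hi_ok
  out <- rep(fill, nx * ny * nz)
  if (!any(ok)) return(out)
  x0 <- e0$x[ok]; y0 <- e0$y[ok]; z0 <- e0$z[ok]
  tx <- ew$x[ok]; ty <- ew$y[ok]; tz <- ew$z[ok]
  sx <- d[1]; sxy <- d[1] * d[2]
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  v <- src$data
  at <- function(xi, yi, zi) v[1 + xi + sx * yi + sxy * zi]
  c000 <- at(x0, y0, z0); c100 <- at(x1, y0, z0)
  c010 <- at(x0, y1, z0); c110 <- at(x1, y1, z0)
  c001 <- at(x0, y0, z1); c101 <- at(x1, y0, z1)
  c011 <- at(x0, y1, z1); c111 <- at(x1, y1, z1)
  out[ok] <-
    (1 - tz) * ((1 - ty) * ((1 - tx) * c000 + tx * c100) +
                  ty * ((1 - tx) * c010 + tx * c110)) +
    tz * ((1 - ty) * ((1 - tx) * c001 + tx * c101) +
            ty * ((1 - tx) * c011 + tx * c111))
  out
}

#' Write a voxel grid to NIfTI
#'
#' The grid's spacing is stored in the NIfTI pixdim and the origin in the
#' sform translation (LPS is converted to the NIfTI RAS convention).
#'
#' @param grid a `voxel_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_grid_nifti <- function(grid, path) {
  img <- RNifti::asNifti(grid$data)
  # LPS -> RAS: flip signs of x and y in the affine
  aff <- diag(c(-grid$spacing[1], -grid$spacing[2], grid$spacing[3], 1))
  aff[1:3, 4] <- c(-grid$origin[1], -grid$origin[2], grid$origin[3])
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel grid from NIfTI
#'
#' @param path path to a NIfTI file written by [write_grid_nifti()] (or any
#'   axis-aligned NIfTI volume).
#' @return A `voxel_grid` in LPS world coordinates.
#' @export
read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin_ras <- aff[1:3, 4]
  origin <- c(-origin_ras[1], -origin_ras[2], origin_ras[3])
  voxel_grid(array(as.numeric(img), dim(img)[1:3]), spacing, origin)
}
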
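#' Build the microscope-frame query grid
#'
#' Constructs the axis-aligned lattice of 3D query points in the microscope
#' frame. The imaging plane carries one point per image pixel (point counts
#' and spacing equal the image size and pixel size), while the number of
#' points along the viewing direction (`n_z`, the depth samples) is a free
#' hyperparameter whose spacing is chosen so the z extent of the grid equals
#' the x/y extent. Points sit at pixel centers and the box center is the
#' physical origin, so coordinates are in Angstrom and symmetric about zero.
#'
#' @param n_pixels Number of pixels per image side (>= 2).
#' @param pixel_size Pixel size in Angstrom (> 0).
#' @param n_z Number of depth samples along the viewing direction (>= 1).
#' @return An object of class `cf_grid` with elements `n_x`, `n_y`, `n_z`,
#'   `spacing_x`, `spacing_y`, `spacing_z`, `pixel_size`, `extent` (physical
#'   box side in Angstrom), `points` (|G| x 3 matrix, Angstrom), and
#'   `index_map` (|G| x 3 integer matrix of 0-based (a, b, c) lattice
#'   indices; (a, b) is the target pixel, pose-independent).
#' @examples
#' g <- build_grid(16, 1.5, 8)
#' nrow(g$points)  # 16 * 16 * 8
#' @export
build_grid <- function(n_pixels, pixel_size, n_z) {
  if (n_pixels < 2) stop("`n_pixels` must be >= 2")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (n_z < 1) stop("`n_z` must be >= 1")
  n_pixels <- as.integer(n_pixels)
  n_z <- as.integer(n_z)

  extent <- n_pixels * pixel_size
  # pixel i center at (i - n/2 + 0.5) * spacing; same rule on every axis
  ax_xy <- (seq_len(n_pixels) - 1 - n_pixels / 2 + 0.5) * pixel_size
  spacing_z <- extent / n_z
  ax_z <- (seq_len(n_z) - 1 - n_z / 2 + 0.5) * spacing_z

  idx <- as.matrix(expand.grid(a = 0:(n_pixels - 1), b = 0:(n_pixels - 1),
                               c = 0:(n_z - 1)))
  points <- cbind(ax_xy[idx[, 1] + 1], ax_xy[idx[, 2] + 1], ax_z[idx[, 3] + 1])
  colnames(points) <- c("x", "y", "z")

  structure(list(
    n_x = n_pixels, n_y = n_pixels, n_z = n_z,
    spacing_x = pixel_size, spacing_y = pixel_size, spacing_z = spacing_z,
    pixel_size = pixel_size, extent = extent,
    points = points, index_map = idx
  ), class = "cf_grid")
}

#' @export
print.cf_grid <- function(x, ...) {
  cat(sprintf("<cf_grid> %d x %d x %d points, pixel %.3g A, extent %.3g A, |G| = %d\n",
              x$n_x, x$n_y, x$n_z, x$pixel_size, x$extent, nrow(x$points)))
  invisible(x)
}

#' Construct a particle pose
#'
#' A pose is a rigid-body rotation `R` in SO(3) plus an in-plane translation
#' `(t_x, t_y)` in Angstrom relating the specimen's canonical frame to the
#' particle image.
#'
#' @param R 3x3 rotation matrix (orthogonal, det +1, checked to 1e-6).
#' @param t_x,t_y In-plane translation in Angstrom.
#' @return A `cf_pose` object.
#' @export
pose <- function(R = diag(3), t_x = 0, t_y = 0) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("`R` must be 3x3")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6)
    stop("`R` is not orthogonal within 1e-6")
  if (abs(det(R) - 1) > 1e-6)
    stop("`R` must have determinant 1 within 1e-6")
  structure(list(R = R, t_x = t_x, t_y = t_y), class = "cf_pose")
}

#' Pose from RELION ZYZ Euler angles
#'
#' Builds the rotation matrix from the RELION convention Euler angles
#' (rot, tilt, psi) in degrees: `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @param t_x,t_y In-plane translation in Angstrom.
#' @return A `cf_pose` object.
#' @export
pose_from_euler <- function(rot, tilt, psi, t_x = 0, t_y = 0) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  pose(rz(psi) %*% ry(tilt) %*% rz(rot), t_x, t_y)
}

#' Euler angles (degrees) of a pose's rotation, RELION ZYZ convention
#'
#' Inverse of [pose_from_euler()] up to the usual gimbal ambiguity at
#' tilt = 0 or 180 degrees (rot is set to 0 there).
#'
#' @param p A `cf_pose`.
#' @return Named numeric vector `c(rot, tilt, psi)`.
#' @export
pose_to_euler <- function(p) {
  R <- p$R
  tilt <- acos(max(-1, min(1, R[3, 3])))
  if (sin(tilt) > 1e-8) {
    rot <- atan2(R[3, 2], -R[3, 1])
    psi <- atan2(R[2, 3], R[1, 3])
  } else {
    rot <- 0
    psi <- atan2(R[2, 1], R[1, 1]) * sign(R[3, 3])
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

#' Apply a pose to the grid points
#'
#' Queries of the canonical density at a posed particle's grid follow the
#' rotated-grid formulation: each microscope-frame point p is mapped to
#' `R^-1 p + (-t_x, -t_y, 0)`, so the density itself stays in a fixed
#' canonical frame. The grid-index-to-pixel association (`index_map`) is
#' pose-independent and untouched.
#'
#' @param grid A `cf_grid`.
#' @param p A `cf_pose`.
#' @return |G| x 3 matrix of posed coordinates (Angstrom, canonical frame).
#' @export
pose_grid <- function(grid, p) {
  stopifnot(inherits(grid, "cf_grid"), inherits(p, "cf_pose"))
  pts <- grid$points %*% p$R  # points %*% R == t(R^-1 %*% t(points)) for R in SO(3)
  pts[, 1] <- pts[, 1] - p$t_x
  pts[, 2] <- pts[, 2] - p$t_y
  pts
}

#' Jitter query points with uniform noise
#'
#' Perturbs every coordinate component by an independent draw from
#' Uniform(-J/2, J/2) (one draw per component, |G| x 3 in total). In
#' expectation this is a convolution of the queried field with a width-J
#' top-hat per axis, i.e. a sinc low-pass filter in Fourier space, and acts
#' as the pipeline's real-space regularizer. `J = 0` is the identity.
#'
#' @param points K x 3 matrix of coordinates (Angstrom).
#' @param J Jitter width in Angstrom (>= 0).
#' @param seed Optional integer; when given, draws use a local RNG state so
#'   the call is reproducible without disturbing the global stream.
#' @return K x 3 matrix of jittered coordinates.
#' @export
jitter_points <- function(points, J, seed = NULL) {
  if (J < 0) stop("`J` must be >= 0")
  if (J == 0) return(points)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  points + matrix(stats::runif(length(points), -J / 2, J / 2),
                  nrow = nrow(points))
}

#' Mask volume container
#'
#' Wraps a non-negative voxel array on a regular lattice (typically read
#' from an MRC file) together with its voxel spacing, physical origin offset
#' of the box center, and the threshold used to binarize it.
#'
#' @param data 3D numeric array of mask values.
#' @param spacing Voxel spacing in Angstrom.
#' @param origin Physical coordinate (Angstrom, length 3) of the box center;
#'   default c(0,0,0), i.e. the mask box is centered like the query grid.
#' @param cutoff Threshold above which a point is inside the mask
#'   (default 0).
#' @return A `cf_mask` object.
#' @export
mask_volume <- function(data, spacing, origin = c(0, 0, 0), cutoff = 0) {
  stopifnot(length(dim(data)) == 3, spacing > 0)
  if (any(data < 0)) stop("mask values must be non-negative")
  structure(list(data = data, spacing = spacing, origin = origin,
                 cutoff = cutoff), class = "cf_mask")
}

#' Interpolate a mask at arbitrary points
#'
#' Trilinear interpolation of the (soft) mask at physical coordinates,
#' edge-extended outside the mask box.
#'
#' @param mask A `cf_mask`.
#' @param points K x 3 matrix, Angstrom.
#' @return Numeric vector of K interpolated mask values.
#' @export
interpolate_mask <- function(mask, points) {
  d <- dim(mask$data)
  ext <- d * mask$spacing
  u <- sweep(points, 2, mask$origin)
  u <- sweep(u, 2, ext, "/") + 0.5
  as.numeric(cpp_trilinear(u, as.numeric(mask$data), as.integer(c(d, 1L)),
                           1L))
}

#' Restrict a grid to points inside a mask
#'
#' The mask is trilinearly interpolated at the grid points; points whose
#' interpolated value exceeds the mask's cutoff are retained. The returned
#' grid records the surviving point indices in `$kept` so the sparse
#' projection map can drop the matching columns. Thresholding here is the
#' only binarization point: soft masks are accepted as-is.
#'
#' @param grid A `cf_grid` (possibly already restricted).
#' @param mask A `cf_mask`.
#' @return A `cf_grid` whose `points`/`index_map` contain only surviving
#'   points, with `$kept` giving their indices into the *original* full
#'   lattice.
#' @export
subset_by_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "cf_grid"), inherits(mask, "cf_mask"))
  vals <- interpolate_mask(mask, grid$points)
  keep <- vals > mask$cutoff
  if (!any(keep))
    stop(sprintf("mask with cutoff %g retains no grid points", mask$cutoff))
  out <- grid
  out$points <- grid$points[keep, , drop = FALSE]
  out$index_map <- grid$index_map[keep, , drop = FALSE]
  prev <- if (is.null(grid$kept)) seq_len(nrow(grid$points)) else grid$kept
  out$kept <- prev[keep]
  out
}

# Affine map from physical Angstrom coordinates (box centered at origin,
# side `extent`) to the unit cube the field parametrizations consume.
# Owned by the fields module conceptually; shared here for reuse.
normalize_points <- function(points, extent) {
  points / extent + 0.5
}
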
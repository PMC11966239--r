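#' Build the fixed sparse 3D-to-2D projection map
#'
#' Orthogonal projection along the viewing axis is a fixed linear map from
#' grid points to pixels: grid index (a, b, c) contributes to pixel
#' (i, j) = (a, b) regardless of pose, so the n^2 x |G| binary matrix `M` is
#' built once per (grid, mask) pair. Every column holds exactly one 1; under
#' masking the dropped points' columns are simply absent.
#'
#' @param grid A `cf_grid` (possibly mask-restricted).
#' @return A `cf_projection` object with the sparse matrix `M`
#'   (`Matrix::sparseMatrix`, n^2 rows, |G| columns) and the image side `n`.
#' @export
build_projection_map <- function(grid) {
  stopifnot(inherits(grid, "cf_grid"))
  n <- grid$n_x
  pix <- grid$index_map[, 1] + n * grid$index_map[, 2] + 1L
  M <- Matrix::sparseMatrix(i = pix, j = seq_len(nrow(grid$index_map)),
                            x = 1, dims = c(n * n, nrow(grid$index_map)))
  structure(list(M = M, n = n), class = "cf_projection")
}

#' Project field samples to an image
#'
#' `image = reshape(M %*% vec(densities))`: a sparse-matrix multiplication,
#' linear (hence trivially differentiable) in the densities. Mass is
#' conserved exactly: `sum(image) == sum(densities)`.
#'
#' @param densities Numeric vector of |G| field samples (column order of M).
#' @param proj A `cf_projection` from [build_projection_map()].
#' @return n x n numeric matrix.
#' @export
project_densities <- function(densities, proj) {
  if (length(densities) != ncol(proj$M))
    stop(sprintf("expected %d densities, got %d", ncol(proj$M),
                 length(densities)))
  matrix(as.numeric(proj$M %*% densities), proj$n, proj$n)
}

# adjoint (gradient) of project_densities
project_backward <- function(dimage, proj) {
  as.numeric(Matrix::crossprod(proj$M, as.numeric(dimage)))
}

#' Imaging (CTF) parameters
#'
#' The standard parametric phase-contrast CTF: accelerating voltage,
#' spherical aberration, amplitude contrast, astigmatic defocus and an
#' optional phase shift and B-factor envelope.
#'
#' @param voltage Accelerating voltage in kV (default 300).
#' @param cs Spherical aberration in mm (default 2.7).
#' @param amplitude_contrast Amplitude contrast fraction (default 0.1).
#' @param defocus_u,defocus_v Defocus along the major/minor astigmatism axes
#'   in Angstrom (underfocus positive); `defocus_u >= defocus_v` by
#'   convention.
#' @param astigmatism_angle Azimuth of the major axis in degrees.
#' @param phase_shift Additional phase shift in degrees (phase plate).
#' @param pixel_size Pixel size in Angstrom.
#' @param bfactor Optional envelope B-factor in Angstrom^2 (0 = none).
#' @return A `cf_ctf` object.
#' @export
imaging_params <- function(voltage = 300, cs = 2.7, amplitude_contrast = 0.1,
                           defocus_u = 15000, defocus_v = defocus_u,
                           astigmatism_angle = 0, phase_shift = 0,
                           pixel_size = 1, bfactor = 0) {
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(list(voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 defocus_u = defocus_u, defocus_v = defocus_v,
                 astigmatism_angle = astigmatism_angle,
                 phase_shift = phase_shift, pixel_size = pixel_size,
                 bfactor = bfactor), class = "cf_ctf")
}

# relativistic electron wavelength in Angstrom, voltage in kV
electron_wavelength <- function(voltage_kv) {
  V <- voltage_kv * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

fft_freqs <- function(n, d) {
  c(0:(ceiling(n / 2) - 1), -floor(n / 2):-1) / (n * d)
}

#' Evaluate the CTF on the discrete frequency lattice
#'
#' RELION/CTFFIND sign convention:
#' `CTF(g) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with aberration phase
#' `chi = pi lambda g^2 dF(theta) - pi/2 Cs lambda^3 g^4 + phase_shift` and
#' astigmatic defocus
#' `dF(theta) = (dU + dV)/2 + (dU - dV)/2 cos(2 (theta - alpha))`.
#' The lattice uses the unshifted FFT layout (DC at [1, 1]).
#'
#' @param ctf A `cf_ctf`.
#' @param n Image side in pixels.
#' @return n x n real matrix of CTF values.
#' @export
ctf_evaluate <- function(ctf, n) {
  lambda <- electron_wavelength(ctf$voltage)
  f <- fft_freqs(n, ctf$pixel_size)
  fx <- matrix(f, n, n)
  fy <- matrix(f, n, n, byrow = TRUE)
  g2 <- fx^2 + fy^2
  theta <- atan2(fy, fx)
  alpha <- ctf$astigmatism_angle * pi / 180
  df <- (ctf$defocus_u + ctf$defocus_v) / 2 +
    (ctf$defocus_u - ctf$defocus_v) / 2 * cos(2 * (theta - alpha))
  cs_A <- ctf$cs * 1e7  # mm -> Angstrom
  chi <- pi * lambda * g2 * df - pi / 2 * cs_A * lambda^3 * g2^2 +
    ctf$phase_shift * pi / 180
  A <- ctf$amplitude_contrast
  out <- -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
  if (ctf$bfactor > 0) out <- out * exp(-ctf$bfactor * g2 / 4)
  out
}

#' Apply the CTF to an image
#'
#' Discrete convolution with the point-spread function, implemented as an
#' element-wise multiplication by the CTF in Fourier space. The operator is
#' linear and (being real and even on the lattice) self-adjoint, so it is
#' its own gradient operator.
#'
#' @param image n x n real matrix.
#' @param ctf A `cf_ctf`, or a precomputed n x n CTF matrix from
#'   [ctf_evaluate()].
#' @return n x n real matrix.
#' @export
apply_ctf <- function(image, ctf) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("`image` must be a square matrix")
  H <- if (inherits(ctf, "cf_ctf")) ctf_evaluate(ctf, nrow(image)) else ctf
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / length(image)
}

#' Render the predicted image of one particle
#'
#' The full differentiable forward model: grid points are posed
#' (`R^-1 p - t`), jittered, optionally bent by a per-image deformation
#' field, queried into the scalar field, projected by the fixed sparse map
#' and CTF-corrupted.
#'
#' @param field A `cf_field`.
#' @param grid A `cf_grid` (box size must match the CTF's implied image
#'   side through `proj`).
#' @param p A `cf_pose`.
#' @param ctf A `cf_ctf` or precomputed CTF matrix (or `NULL` to skip).
#' @param J Jitter width in Angstrom (default 0).
#' @param jitter_seed Optional seed for the jitter draws.
#' @param vf Optional canonical vector field array `(nF, nF, nF, 3)`
#'   (Angstrom displacements) to bend the query points, as produced by
#'   [predict_field()].
#' @param proj Optional precomputed `cf_projection` (cached by the caller);
#'   built from `grid` when `NULL`.
#' @return n x n predicted image.
#' @export
render_particle <- function(field, grid, p, ctf = NULL, J = 0,
                            jitter_seed = NULL, vf = NULL, proj = NULL) {
  if (is.null(proj)) proj <- build_projection_map(grid)
  pts <- pose_grid(grid, p)
  if (J > 0) pts <- jitter_points(pts, J, seed = jitter_seed)
  if (!is.null(vf)) pts <- bend_points(pts, vf, field$extent)
  dens <- query_field(field, pts)
  img <- project_densities(dens, proj)
  if (!is.null(ctf)) img <- apply_ctf(img, ctf)
  img
}
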
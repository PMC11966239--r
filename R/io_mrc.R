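# Minimal MRC2014 reader/writer (mode 2, float32, little-endian), enough
# for volumes, masks and particle stacks (.mrcs: nz = number of images).

#' Write a volume or image stack to an MRC/MRCS file
#'
#' @param data 3D numeric array (a volume, or a stack with the third
#'   dimension indexing images) or a 2D matrix (written as nz = 1).
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom, stored in the cell header.
#' @param is_stack Mark the file as an image stack (MRCS); affects only
#'   the ispg header word (0 for stacks/images, 1 for volumes).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_size = 1, is_stack = FALSE) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 3)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2: float32
  wi(c(0, 0, 0))                          # nxstart nystart nzstart
  wi(d)                                   # mx my mz
  wf(d * pixel_size)                      # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1, 2, 3))                          # mapc mapr maps
  wf(c(min(data), max(data), mean(data))) # dmin dmax dmean
  wi(if (is_stack) 0 else 1)              # ispg
  wi(0)                                   # nsymbt
  wi(rep(0, 25))                          # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(data))                     # rms
  wi(0)                                   # nlabl
  writeBin(raw(800), con)                 # labels
  wf(as.numeric(data))
  invisible(path)
}

#' Read an MRC/MRCS file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16);
#' the header pixel size (cell length / sample count) is honored.
#'
#' @param path Input path.
#' @return List with `data` (3D array), `pixel_size` (Angstrom), and the
#'   raw header fields `nx`, `ny`, `nz`, `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)          # nxstart..
  mx <- ri(3)
  cella <- rf(3)
  seek(con, 1024)
  nvox <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2,
                             endian = "little")),
    "2" = rf(nvox),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  ps <- if (mx[1] > 0 && cella[1] > 0) cella[1] / mx[1] else 1
  list(data = array(data, dim = d), pixel_size = ps,
       nx = d[1], ny = d[2], nz = d[3], mode = mode)
}

#' Read a mask volume from an MRC file
#'
#' @param path MRC file of non-negative float voxels.
#' @param cutoff Threshold for [subset_by_mask()] (default 0).
#' @return A `cf_mask`.
#' @export
read_mask_mrc <- function(path, cutoff = 0) {
  m <- read_mrc(path)
  mask_volume(m$data, spacing = m$pixel_size, cutoff = cutoff)
}
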
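# MRC2014 volume I/O (mode 2, float32, little endian)
#
# Header layout follows the MRC2014 standard. Cell dimensions are stored in
# Angstrom as the format prescribes; this package works in nm and converts at
# the boundary (1 nm = 10 A). Only mode 2 is supported: synthetic volumes and
# averages are float data, and refusing other modes is safer than guessing.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 volume
#'
#' @param path file path
#' @return a [volume()] with voxel size in nm
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < MRC_HEADER_BYTES) stop("not an MRC file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")        # nxstart
  readBin(con, "integer", 3, size = 4, endian = "little")        # mx my mz
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")        # cellb
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")        # dmin dmax dmean
  readBin(con, "integer", 2, size = 4, endian = "little")        # ispg nsymbt
  readBin(con, "raw", 100)                                       # extra
  orig <- readBin(con, "numeric", 3, size = 4, endian = "little")
  map <- rawToChar(readBin(con, "raw", 4))
  if (map != "MAP ") stop("not an MRC2014 file (missing MAP magic): ", path)
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2 float32)")
  if (any(mapcrs != 1:3)) stop("unsupported MRC axis order (mapc/mapr/maps must be 1,2,3)")
  readBin(con, "raw", 4)                                         # machst
  readBin(con, "numeric", 1, size = 4, endian = "little")        # rms
  readBin(con, "integer", 1, size = 4, endian = "little")        # nlabl
  readBin(con, "raw", 800)
  n <- prod(nxyz)
  expected <- MRC_HEADER_BYTES + 4 * n
  if (sz < expected) stop("truncated MRC data section: ", path)
  dat <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (length(dat) < n) stop("truncated MRC data section: ", path)
  vox <- cella[1] / nxyz[1] / 10                                 # A -> nm
  volume(array(dat, dim = nxyz), voxel_size = vox, origin = orig / 10)
}

#' Write an MRC2014 volume
#'
#' @param vol a [volume()]
#' @param path output path
#' @param invert_contrast multiply densities by -1 on output (cryo-EM density
#'   convention); the in-memory convention is protein-positive
#' @return `path`, invisibly
#' @export
write_mrc <- function(vol, path, invert_contrast = FALSE) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  dat <- as.numeric(vol$data)
  if (invert_contrast) dat <- -dat
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                              # nx ny nz
  wi(2)                              # mode 2 float32
  wi(c(0, 0, 0))                     # nxstart
  wi(d)                              # mx my mz
  wf(d * vol$voxel_size * 10)        # cella, Angstrom
  wf(c(90, 90, 90))                  # cellb
  wi(1:3)                            # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))
  wi(c(1, 0))                        # ispg, nsymbt
  writeBin(raw(100), con)            # extra
  wf(vol$origin * 10)                # origin, Angstrom
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little endian
  wf(sd(dat))
  wi(0)                              # nlabl
  writeBin(raw(800), con)
  writeBin(dat, con, size = 4, endian = "little")
  invisible(path)
}
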
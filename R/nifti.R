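# Minimal NIfTI-1 reader/writer for integer label volumes.
#
# Only the single-file ".nii"/".nii.gz" variant (magic "n+1") is handled.
# The 348-byte header is parsed with explicit byte offsets; endianness is
# detected from sizeof_hdr. Labels are categorical, so scl_slope/scl_inter
# rescaling is rejected rather than applied.

NIFTI_HDR_SIZE <- 348L

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

read_bin_at <- function(raw, offset, what, n, size, signed = TRUE, endian = "little") {
  readBin(raw[(offset + 1L):(offset + n * size)], what = what, n = n,
          size = size, signed = signed, endian = endian)
}

parse_nifti_header <- function(raw) {
  stopifnot(length(raw) >= NIFTI_HDR_SIZE)
  endian <- "little"
  sizeof_hdr <- read_bin_at(raw, 0L, "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- read_bin_at(raw, 0L, "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic '", magic, "')")
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")

  dim        <- read_bin_at(raw, 40L, "integer", 8L, 2L, endian = endian)
  datatype   <- read_bin_at(raw, 70L, "integer", 1L, 2L, endian = endian)
  pixdim     <- read_bin_at(raw, 76L, "double", 8L, 4L, endian = endian)
  vox_offset <- read_bin_at(raw, 108L, "double", 1L, 4L, endian = endian)
  scl_slope  <- read_bin_at(raw, 112L, "double", 1L, 4L, endian = endian)
  scl_inter  <- read_bin_at(raw, 116L, "double", 1L, 4L, endian = endian)
  qform_code <- read_bin_at(raw, 252L, "integer", 1L, 2L, endian = endian)
  sform_code <- read_bin_at(raw, 254L, "integer", 1L, 2L, endian = endian)
  quatern    <- read_bin_at(raw, 256L, "double", 3L, 4L, endian = endian)
  qoffset    <- read_bin_at(raw, 268L, "double", 3L, 4L, endian = endian)
  srow       <- matrix(read_bin_at(raw, 280L, "double", 12L, 4L, endian = endian),
                       nrow = 3, byrow = TRUE)
  list(endian = endian, dim = dim, datatype = datatype, pixdim = pixdim,
       vox_offset = vox_offset, scl_slope = scl_slope, scl_inter = scl_inter,
       qform_code = qform_code, sform_code = sform_code,
       quatern = quatern, qoffset = qoffset, srow = srow)
}

quaternion_to_rotation <- function(b, c, d) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(0, a2))
  matrix(c(a * a + b * b - c * c - d * d, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a * a + d * d - b * b - c * c),
         nrow = 3, byrow = TRUE)
}

nifti_affine <- function(hdr) {
  if (hdr$sform_code > 0) {
    aff <- rbind(hdr$srow, c(0, 0, 0, 1))
  } else if (hdr$qform_code > 0) {
    R <- quaternion_to_rotation(hdr$quatern[1], hdr$quatern[2], hdr$quatern[3])
    qfac <- hdr$pixdim[1]
    if (qfac == 0) qfac <- 1
    S <- diag(c(hdr$pixdim[2], hdr$pixdim[3], qfac * hdr$pixdim[4]))
    aff <- rbind(cbind(R %*% S, hdr$qoffset), c(0, 0, 0, 1))
  } else {
    aff <- diag(c(hdr$pixdim[2:4], 1))
  }
  unname(aff)
}

read_nifti_raw <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (length(chunk) == 0L) break
    chunks[[length(chunks) + 1L]] <- chunk
  }
  do.call(c, chunks)
}

# Returns list(header, data) with data an integer array in x,y,z order.
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_nifti_raw(path)
  hdr <- parse_nifti_header(raw)

  ndim <- hdr$dim[1]
  if (ndim < 1L || ndim > 7L) stop("corrupt NIfTI header (dim[0] = ", ndim, ")")
  dims <- hdr$dim[2:(1 + ndim)]
  if (ndim > 3L && any(dims[4:ndim] > 1L))
    stop("4D+ NIfTI input is not supported; supply one 3D label volume per study")
  dims3 <- c(dims[seq_len(min(3L, ndim))], rep(1L, max(0L, 3L - ndim)))

  dt <- nifti_datatypes[[as.character(hdr$datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", hdr$datatype,
         " (labels must be integer or integral float)")
  if (!(hdr$scl_slope %in% c(0, 1)) || !(hdr$scl_inter %in% c(0)))
    stop("scl_slope/scl_inter rescaling is not supported for label volumes")

  nvox <- prod(dims3)
  off <- as.integer(round(hdr$vox_offset))
  vals <- read_bin_at(raw, off, dt$what, as.integer(nvox), dt$size,
                      signed = dt$signed, endian = hdr$endian)
  if (dt$what == "double") {
    if (any(vals != round(vals)))
      stop("non-integer voxel values: not a label volume")
    vals <- as.integer(round(vals))
  }
  if (anyNA(vals)) stop("failed to decode voxel data")
  data <- array(as.integer(vals), dim = dims3)
  list(header = hdr, data = data, affine = nifti_affine(hdr),
       spacing = abs(hdr$pixdim[2:4]))
}

float32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
int16   <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
int32   <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# Writes a 3D integer array as single-file NIfTI-1 (int16 or int32), sform only.
write_nifti <- function(data, affine, spacing, path) {
  stopifnot(length(dim(data)) == 3L)
  use_int32 <- max(data) > 32767L
  datatype <- if (use_int32) 8L else 4L
  bitpix <- if (use_int32) 32L else 16L

  hdr <- raw(NIFTI_HDR_SIZE)
  put <- function(hdr, offset, bytes) {
    hdr[(offset + 1L):(offset + length(bytes))] <- bytes
    hdr
  }
  hdr <- put(hdr, 0L, int32(348L))
  hdr <- put(hdr, 40L, int16(c(3L, dim(data), 1L, 1L, 1L, 1L)))
  hdr <- put(hdr, 70L, int16(datatype))
  hdr <- put(hdr, 72L, int16(bitpix))
  hdr <- put(hdr, 76L, float32(c(1, spacing, 0, 0, 0, 0)))
  hdr <- put(hdr, 108L, float32(352))            # vox_offset
  hdr <- put(hdr, 112L, float32(c(1, 0)))        # scl_slope, scl_inter
  hdr <- put(hdr, 123L, as.raw(10L))             # xyzt_units: mm
  hdr <- put(hdr, 252L, int16(c(0L, 2L)))        # qform_code 0, sform_code 2
  hdr <- put(hdr, 280L, float32(as.numeric(t(affine[1:3, ]))))
  hdr <- put(hdr, 344L, c(charToRaw("n+1"), as.raw(0L)))

  body <- if (use_int32) int32(as.vector(data)) else int16(as.vector(data))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                         # extension flag (none)
  writeBin(body, con)
  invisible(path)
}
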
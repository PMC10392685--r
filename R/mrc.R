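# Minimal MRC2014 volume I/O (mode 2, 32-bit float, little endian).
# Tomographic volumes and masks travel in this format; no R package on
# CRAN/Bioconductor reads MRC, so the fixed 1024-byte header is handled
# directly.

#' Write a LAC volume as an MRC file
#'
#' Mode-2 (float32) MRC2014 with the voxel size recorded in the cell
#' dimensions (Angstrom).
#'
#' @param volume A [lac_volume()] (or plain 3D array with `voxel_nm`).
#' @param path Output path.
#' @param voxel_nm Voxel width, nm (taken from the volume if available).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path, voxel_nm = NULL) {
  if (inherits(volume, "lac_volume")) {
    arr <- volume$data; voxel_nm <- volume$voxel_nm
  } else {
    arr <- volume
    if (is.null(voxel_nm)) stop("voxel_nm required for a plain array")
  }
  d <- dim(arr)
  stopifnot(length(d) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2 = float32
  wi(c(0, 0, 0))             # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * voxel_nm * 10)      # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(arr), max(arr), mean(arr)))
  wi(c(0, 0))                # ispg nsymbt
  writeBin(raw(100), con)    # extra
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little endian
  wf(stats::sd(arr))
  wi(1)                      # nlabl
  lab <- sprintf("%-80s", "isgtomo simulated LAC volume")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeBin(raw(80 * 9), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Supports mode 2 (float32) and mode 1 (int16) little-endian files, which
#' covers simulated and experimental water-window tomograms.  Truncated
#' files raise an error naming the offending byte offset.
#'
#' @param path MRC file path.
#' @return A [lac_volume()]; voxel width is derived from the cell
#'   dimensions.
#' @export
read_mrc <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) {
    stop("MRC file '", path, "' truncated: header needs 1024 bytes, file has ",
         ifelse(is.na(sz), 0, sz))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)                       # nstart
  m <- ri(3)                  # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(2)  # cellb, map order, stats, ispg/nsymbt
  nsymbt <- 0
  seek(con, 1024 + nsymbt)
  if (any(d <= 0) || any(d > 1e5)) stop("implausible MRC dimensions: ",
                                        paste(d, collapse = "x"))
  bytes_per <- switch(as.character(mode), `1` = 2L, `2` = 4L,
                      stop("unsupported MRC mode ", mode))
  need <- 1024 + nsymbt + prod(as.numeric(d)) * bytes_per
  if (sz < need) {
    stop("MRC file '", path, "' truncated at byte ", sz, ": expected ", need,
         " bytes for ", paste(d, collapse = "x"), " mode-", mode, " data")
  }
  vals <- if (mode == 2L) {
    readBin(con, "numeric", prod(d), size = 4, endian = "little")
  } else {
    readBin(con, "integer", prod(d), size = 2, endian = "little", signed = TRUE)
  }
  arr <- array(vals, dim = d)
  voxel_nm <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] / 10 else 1
  lac_volume(pmax(arr, 0), voxel_nm)
}

#' Write a binary mask as MRC
#'
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_nm Voxel width, nm.
#' @return `path`, invisibly.
#' @export
write_mask_mrc <- function(mask, path, voxel_nm = 37.42) {
  write_mrc(array(as.numeric(mask), dim = dim(mask)), path, voxel_nm = voxel_nm)
}

#' Read a binary mask from MRC
#'
#' @param path MRC path (0/1 values).
#' @return Logical array.
#' @export
read_mask_mrc <- function(path) {
  vol <- read_mrc(path)
  vol$data > 0.5
}
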
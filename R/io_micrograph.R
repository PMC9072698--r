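# Micrograph I/O.  MRC (CCP-EM standard, modes 0/1/2/6) is read and
# written natively — 1024-byte header, little-endian, y axis flipped to
# image (row-down) convention on read and restored on write.  PNG and TIFF
# go through the png and tiff packages; their [0,1] samples are scaled to
# gray levels 0-255.

mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       mx = ints[8], cella_x = cella[1])
}

read_mrc <- function(path, section = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- mrc_read_header(con)
  if (hd$nx < 1 || hd$ny < 1 || hd$nz < 1 ||
      !hd$mode %in% c(0L, 1L, 2L, 6L))
    stop("corrupt or unsupported MRC header in ", path)
  if (hd$nz > 1 && is.null(section))
    stop(sprintf("%s is a %d-section MRC stack: pass an explicit section",
                 path, hd$nz))
  section <- if (is.null(section)) 1L else as.integer(section)
  if (section < 1 || section > hd$nz) stop("section out of range")
  seek(con, 1024)
  npx <- hd$nx * hd$ny
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(hd$mode)]
  if (section > 1) seek(con, 1024 + (section - 1) * npx * bytes_per)
  d <- switch(as.character(hd$mode),
    `0` = as.numeric(readBin(con, "integer", n = npx, size = 1,
                             signed = TRUE, endian = "little")),
    `1` = as.numeric(readBin(con, "integer", n = npx, size = 2,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, "numeric", n = npx, size = 4, endian = "little"),
    `6` = as.numeric(readBin(con, "integer", n = npx, size = 2,
                             signed = FALSE, endian = "little")))
  if (length(d) != npx) stop("truncated MRC data in ", path)
  # x is the fast axis; MRC row 1 is the bottom row -> flip to image order
  img <- t(matrix(d, nrow = hd$nx, ncol = hd$ny))[hd$ny:1, , drop = FALSE]
  ps <- if (hd$mx > 0 && is.finite(hd$cella_x) && hd$cella_x > 0)
    hd$cella_x / hd$mx else NA_real_
  micrograph(img, pixel_size = ps, source_path = path)
}

write_mrc <- function(m, path) {
  px <- m$pixels
  ny <- nrow(px); nx <- ncol(px)
  con <- file(path, "wb")
  on.exit(close(con))
  ps <- if (is.na(m$pixel_size)) 0 else m$pixel_size
  writeBin(as.integer(c(nx, ny, 1L, 2L, 0L, 0L, 0L, nx, ny, 1L)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(ps * nx, ps * ny, 1, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(px), max(px), mean(px))), con, size = 4,
           endian = "little")
  writeBin(as.integer(rep(0L, 30)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # little-endian stamp
  writeBin(as.numeric(stats::sd(as.vector(px))), con, size = 4,
           endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little")   # nlabl
  writeBin(raw(800), con)                                      # labels
  flip <- px[ny:1, , drop = FALSE]
  writeBin(as.numeric(t(flip)), con, size = 4, endian = "little")
  invisible(path)
}

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read a micrograph from MRC, PNG or TIFF
#'
#' @param path File with extension `.mrc`, `.mrcs`, `.png`, `.tif` or
#'   `.tiff`.
#' @param section 1-based section index, required for multi-section MRC
#'   stacks.
#' @return A [micrograph] (row-major image orientation; MRC y axis flipped
#'   to image convention; pixel size from the MRC header when present).
#'   PNG/TIFF samples are scaled to gray levels 0-255.
#' @export
read_micrograph <- function(path, section = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- file_ext(path)
  if (ext %in% c("mrc", "mrcs")) return(read_mrc(path, section))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
  } else stop("unsupported micrograph format: .", ext)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  micrograph(a * 255, source_path = path)
}

#' Write a micrograph to MRC, PNG or TIFF
#'
#' MRC is written as 32-bit float (mode 2) and round-trips exactly for
#' float-representable values; PNG/TIFF are written 8/16-bit from gray
#' levels 0-255 (clamped).
#'
#' @param m A [micrograph].
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  ext <- file_ext(path)
  if (ext %in% c("mrc", "mrcs")) return(invisible(write_mrc(m, path)))
  v <- pmin(pmax(m$pixels / 255, 0), 1)
  if (ext == "png") png::writePNG(v, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(v, path,
                                                      bits.per.sample = 16L)
  else stop("unsupported micrograph format: .", ext)
  invisible(path)
}
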
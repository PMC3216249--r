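# Minimal single-strip 16-bit grayscale TIFF I/O (little-endian, baseline,
# uncompressed). No TIFF library is available in the deployment environment,
# so the few tags needed for a film-scan export are written by hand.

tiff_tags <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offset = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

# write 16-bit unsigned little-endian values as raw bytes
u16_bytes <- function(v) {
  v <- as.integer(round(v))
  if (any(v < 0 | v > 65535)) stop("values outside 16-bit range",
                                   call. = FALSE)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

u16_from_bytes <- function(b) {
  m <- matrix(as.integer(b), nrow = 2)
  m[1, ] + 256L * m[2, ]
}

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Pixel values must already be integers in `[0, 65535]` (see
#' [write_blot_tiff()] for scaled export of simulated film scans). The file
#' is a baseline little-endian TIFF with one strip.
#'
#' @param pixels integer matrix (rows = image rows).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_tiff16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  data <- u16_bytes(as.vector(t(pixels)))  # row-major strip
  ifd_offset <- 8L + length(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  writeBin(data, con)
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  writeBin(as.integer(length(tiff_tags)), con, size = 2, endian = "little")
  entry(tiff_tags["width"], 4L, w)
  entry(tiff_tags["length"], 4L, h)
  entry(tiff_tags["bits"], 3L, 16L)
  entry(tiff_tags["compression"], 3L, 1L)
  entry(tiff_tags["photometric"], 3L, 1L)         # BlackIsZero
  entry(tiff_tags["strip_offset"], 4L, 8L)
  entry(tiff_tags["spp"], 3L, 1L)
  entry(tiff_tags["rows_per_strip"], 4L, h)
  entry(tiff_tags["strip_bytes"], 4L, length(data))
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff16()]
#'
#' Supports single-strip uncompressed little-endian grayscale files.
#'
#' @param path input file.
#' @return integer matrix.
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF is supported", call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  ifd <- u32(4)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- u16(off)
    type <- u16(off + 2)
    val <- if (type == 3L) u16(off + 8) else u32(off + 8)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag) tags[[as.character(tiff_tags[[tag]])]] %||%
    stop(sprintf("missing TIFF tag '%s'", tag), call. = FALSE)
  if (need("compression") != 1L || need("bits") != 16L)
    stop("only uncompressed 16-bit TIFF is supported", call. = FALSE)
  w <- need("width"); h <- need("length")
  so <- need("strip_offset"); sb <- need("strip_bytes")
  v <- u16_from_bytes(raw[so + seq_len(sb)])
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Export a simulated blot image as a 16-bit TIFF
#'
#' Pixel intensities are linearly scaled so the image maximum maps to
#' 65535 (or by an explicit `scale`), clamped at 0, rounded, and written
#' with [write_tiff16()]. Lane metadata and the scale factor are written to
#' a JSON sidecar `<path>.json` so the image can be re-imported for
#' quantification with [read_blot_tiff()].
#'
#' @param image a `blot_image`.
#' @param path output TIFF path.
#' @param scale intensity units per grey level; default maps the image
#'   maximum to 65535.
#' @return the path, invisibly.
#' @export
write_blot_tiff <- function(image, path, scale = NULL) {
  stopifnot(inherits(image, "blot_image"))
  mx <- max(image$pixels)
  scale <- scale %||% (mx / 65535)
  px <- pmin(pmax(round(image$pixels / scale), 0), 65535)
  write_tiff16(px, path)
  sidecar <- list(scale = scale, lanes = image$lanes,
                  config = unclass(image$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a blot image exported by [write_blot_tiff()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` must be present.
#' @return a `blot_image` (without ground truth).
#' @export
read_blot_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- read_tiff16(path) * side$scale
  cfg <- do.call(blot_config, side$config)
  structure(list(pixels = px, lanes = as.data.frame(side$lanes),
                 config = cfg, truth = NULL),
            class = "blot_image")
}
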
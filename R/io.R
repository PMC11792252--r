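# Minimal baseline-TIFF codec for the package's fixed on-disk dialect:
# little-endian, uncompressed, single strip per page, grayscale samples
# that are either 32-bit IEEE floats (phase, intensity, transfer maps) or
# 8-bit unsigned integers (label masks). The installed libtiff wrapper is
# read-only for float data (it cannot WRITE float sample format), hence
# this writer; the reader enforces the dialect so format mistakes fail
# loudly with a message naming the expectation.

TIFF_TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L,
              rows_per_strip = 278L, strip_byte_counts = 279L,
              sample_format = 339L)

write_tag <- function(con, id, type, value) {
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")
  if (type == 3L) {           # SHORT, inline + pad
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {                    # LONG
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write matrices as a multi-page TIFF
#'
#' Writes a list of matrices as an uncompressed little-endian grayscale
#' TIFF, one page per matrix, either as 32-bit IEEE floats (for signed
#' physical quantities such as phase in radians) or as 8-bit unsigned
#' integers (label masks, values 0-255).
#'
#' @param pages a matrix or list of matrices (all the same shape).
#' @param path output file path.
#' @param what \code{"float32"} or \code{"uint8"}.
#' @return \code{path}, invisibly.
#' @export
write_tiff <- function(pages, path, what = c("float32", "uint8")) {
  what <- match.arg(what)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  d <- dim(pages[[1]])
  stopifnot(all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
  bytes_px <- if (what == "float32") 4L else 1L
  n_tags <- length(TIFF_TAG)
  ifd_size <- 2L + n_tags * 12L + 4L
  data_size <- prod(d) * bytes_px
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")  # first IFD offset
  offset <- 8L
  for (k in seq_along(pages)) {
    data_offset <- offset + ifd_size
    writeBin(as.integer(n_tags), con, size = 2, endian = "little")
    write_tag(con, TIFF_TAG["width"], 4L, d[2])
    write_tag(con, TIFF_TAG["length"], 4L, d[1])
    write_tag(con, TIFF_TAG["bits"], 3L, bytes_px * 8L)
    write_tag(con, TIFF_TAG["compression"], 3L, 1L)
    write_tag(con, TIFF_TAG["photometric"], 3L, 1L)
    write_tag(con, TIFF_TAG["strip_offsets"], 4L, data_offset)
    write_tag(con, TIFF_TAG["rows_per_strip"], 4L, d[1])
    write_tag(con, TIFF_TAG["strip_byte_counts"], 4L, data_size)
    write_tag(con, TIFF_TAG["sample_format"], 3L,
              if (what == "float32") 3L else 1L)
    next_ifd <- if (k < length(pages)) data_offset + data_size else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    v <- as.vector(t(pages[[k]]))           # TIFF rows are sequential
    if (what == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      if (any(v < 0 | v > 255)) stop("uint8 pages must hold values in 0..255")
      writeBin(as.raw(as.integer(v)), con)
    }
    offset <- data_offset + data_size
  }
  invisible(path)
}

read_uint <- function(raw, at, n) {
  sum(as.integer(raw[at + seq_len(n) - 1L]) * 256^(seq_len(n) - 1L))
}

#' Read a multi-page TIFF written in the package dialect
#'
#' Strict reader for the files \code{\link{write_tiff}} produces
#' (little-endian, uncompressed, single-strip grayscale pages of float32
#' or uint8 samples). Any deviation raises an error naming the expected
#' property.
#'
#' @param path TIFF file path.
#' @param what expected sample type, \code{"float32"} or \code{"uint8"}.
#' @return List of matrices (numeric for float32, integer for uint8).
#' @export
read_tiff <- function(path, what = c("float32", "uint8")) {
  what <- match.arg(what)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" ||
      read_uint(raw, 3L, 2L) != 42L)
    stop("expected a little-endian TIFF file")
  exp_bits <- if (what == "float32") 32L else 8L
  exp_fmt <- if (what == "float32") 3L else 1L
  pages <- list()
  ifd <- read_uint(raw, 5L, 4L)
  while (ifd != 0L) {
    n_tags <- read_uint(raw, ifd + 1L, 2L)
    tags <- list()
    for (k in seq_len(n_tags)) {
      at <- ifd + 2L + (k - 1L) * 12L + 1L
      id <- read_uint(raw, at, 2L)
      type <- read_uint(raw, at + 2L, 2L)
      tags[[as.character(id)]] <-
        read_uint(raw, at + 8L, if (type == 3L) 2L else 4L)
    }
    need <- function(id) {
      v <- tags[[as.character(TIFF_TAG[[id]])]]
      if (is.null(v)) stop(sprintf("expected TIFF tag '%s' (%d) present",
                                   id, TIFF_TAG[[id]]))
      v
    }
    if (need("compression") != 1L) stop("expected uncompressed TIFF data")
    bits <- need("bits")
    fmt <- need("sample_format")
    if (bits != exp_bits || fmt != exp_fmt)
      stop(sprintf(
        "expected %s samples (%d bits, sample format %d); found %d bits, format %d",
        what, exp_bits, exp_fmt, bits, fmt))
    w <- need("width"); h <- need("length")
    off <- need("strip_offsets")
    nbytes <- need("strip_byte_counts")
    if (nbytes != w * h * bits / 8L)
      stop("expected a single full-image strip")
    if (what == "float32") {
      v <- readBin(raw[off + seq_len(nbytes)], "numeric", n = w * h,
                   size = 4, endian = "little")
      pages[[length(pages) + 1L]] <- matrix(v, h, w, byrow = TRUE)
    } else {
      v <- as.integer(raw[off + seq_len(nbytes)])
      pages[[length(pages) + 1L]] <- matrix(v, h, w, byrow = TRUE)
    }
    ifd <- read_uint(raw, ifd + 2L + n_tags * 12L + 1L, 4L)
  }
  if (length(pages) == 0) stop("TIFF contains no pages")
  pages
}

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) {
    warning(sprintf("sidecar %s is missing; provenance will be empty", sc))
    return(NULL)
  }
  jsonlite::fromJSON(sc, simplifyVector = TRUE)
}

#' Write / read a four-arm raw frame set
#'
#' Frames are stored as a 4-page float32 TIFF in fixed arm order
#' (+x, -x, +y, -y) with a JSON sidecar (\code{<path>.json}) carrying the
#' exposure metadata. Reading a file with any other page count is an
#' error; a missing sidecar is tolerated with a warning.
#'
#' @param fs a \code{qobm_frames} object.
#' @param path TIFF path.
#' @return \code{write_frames}: the path, invisibly. \code{read_frames}:
#'   a \code{qobm_frames} object.
#' @export
write_frames <- function(fs, path) {
  stopifnot(inherits(fs, "qobm_frames"))
  write_tiff(fs$frames[qobm_arms], path, "float32")
  write_sidecar(list(kind = "qobm_frames", arm_order = qobm_arms,
                     exposure = fs$exposure), path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- read_tiff(path, "float32")
  if (length(pages) != 4)
    stop(sprintf("expected 4 pages (+x, -x, +y, -y), found %d",
                 length(pages)))
  sc <- read_sidecar(path)
  structure(list(frames = stats::setNames(pages, qobm_arms),
                 exposure = if (is.null(sc)) list() else sc$exposure),
            class = "qobm_frames")
}

#' Write / read a reconstructed phase image
#'
#' Single-page float32 TIFF (radians) with a JSON sidecar recording the
#' regularization and provenance.
#'
#' @param pi_img a \code{qobm_phase} object.
#' @param path TIFF path.
#' @return \code{write_phase}: the path, invisibly; \code{read_phase}: a
#'   \code{qobm_phase}.
#' @export
write_phase <- function(pi_img, path) {
  stopifnot(inherits(pi_img, "qobm_phase"))
  write_tiff(pi_img$phase, path, "float32")
  write_sidecar(list(kind = "qobm_phase", units = "radians",
                     alpha = pi_img$alpha,
                     provenance = pi_img$provenance), path)
  invisible(path)
}

#' @rdname write_phase
#' @export
read_phase <- function(path) {
  pages <- read_tiff(path, "float32")
  if (length(pages) != 1)
    stop(sprintf("expected 1 phase page, found %d", length(pages)))
  sc <- read_sidecar(path)
  structure(list(phase = pages[[1]],
                 alpha = if (is.null(sc)) NA_real_ else sc$alpha,
                 provenance = if (is.null(sc)) list() else sc$provenance),
            class = "qobm_phase")
}

#' Write / read a label mask
#'
#' Single-page uint8 TIFF holding the category labels
#' (0 background, 1 nucleus, 2 inclusion).
#'
#' @param labels integer matrix.
#' @param path TIFF path.
#' @return \code{write_labels}: the path, invisibly; \code{read_labels}:
#'   an integer matrix.
#' @export
write_labels <- function(labels, path) {
  write_tiff(labels, path, "uint8")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- read_tiff(path, "uint8")
  if (length(pages) != 1)
    stop(sprintf("expected 1 label page, found %d", length(pages)))
  pages[[1]]
}

#' Write / read a tissue phantom
#'
#' A phantom is stored as \code{<prefix>.tif} (2 float32 pages: phase then
#' absorption), \code{<prefix>_labels.tif} (uint8) and
#' \code{<prefix>.tif.json} (metadata).
#'
#' @param ph a \code{qobm_phantom}.
#' @param prefix path prefix (no extension).
#' @return \code{write_phantom}: the prefix, invisibly;
#'   \code{read_phantom}: a \code{qobm_phantom}.
#' @export
write_phantom <- function(ph, prefix) {
  stopifnot(inherits(ph, "qobm_phantom"))
  path <- paste0(prefix, ".tif")
  write_tiff(list(ph$phase, ph$absorption), path, "float32")
  write_labels(ph$labels, paste0(prefix, "_labels.tif"))
  meta <- ph$meta
  meta$kind <- "qobm_phantom"
  write_sidecar(meta, path)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  path <- paste0(prefix, ".tif")
  pages <- read_tiff(path, "float32")
  if (length(pages) != 2)
    stop(sprintf("expected 2 pages (phase, absorption), found %d",
                 length(pages)))
  labels <- read_labels(paste0(prefix, "_labels.tif"))
  sc <- read_sidecar(path)
  structure(list(phase = pages[[1]], absorption = pages[[2]],
                 labels = labels,
                 meta = if (is.null(sc)) list() else sc),
            class = "qobm_phantom")
}

#' Export transfer functions for inspection
#'
#' Writes a WOTF pair as a 4-page float32 TIFF: Re and Im of the
#' amplitude-contrast function, then Re and Im of the phase-contrast
#' function, with the background scalar in the sidecar.
#'
#' @param tf a \code{\link{compute_wotf}} result.
#' @param path TIFF path.
#' @return The path, invisibly.
#' @export
write_wotf <- function(tf, path) {
  stopifnot(inherits(tf, "qobm_wotf"))
  write_tiff(list(Re(tf$H_abs), Im(tf$H_abs), Re(tf$H_ph), Im(tf$H_ph)),
             path, "float32")
  write_sidecar(list(kind = "qobm_wotf", pages = c(
    "Re(H_abs)", "Im(H_abs)", "Re(H_ph)", "Im(H_ph)"),
    B = tf$B, source_label = tf$source_label), path)
  invisible(path)
}
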
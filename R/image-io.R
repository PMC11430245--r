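#' @include cone-layer.R
NULL

## netpbm token reader: whitespace-separated ASCII tokens, '#' comments,
## positioned just past the single whitespace byte that ends the header.
readPNMTokens <- function(con, n) {
  toks <- character(0)
  while (length(toks) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated netpbm header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      toks <- c(toks, tok)
    }
  }
  as.integer(toks)
}

#' Read an image file as an 8-bit RGB raster
#'
#' Reads PNG, binary PPM (P6) or binary PGM (P5). PNG input must be 8 bits
#' per channel (16-bit files are rejected rather than rescaled); grayscale
#' PGM/PNG is expanded to R = G = B with a warning, matching
#' [rgbToConePlanes()]'s ingest contract.
#'
#' @param path file path; format chosen by magic number / extension.
#' @return an h x w x 3 array of integer values in \[0, 255\].
#' @seealso [writeImage()], [generateFixture()]
#' @export
readImage <- function(path) {
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 8 &&
      all(magic[1:4] == as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8L)
      stop(sprintf("format error: PNG bit depth %d, only 8-bit input accepted",
                   info$bit.depth), call. = FALSE)
    img <- round(img * 255)
    if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
      return(img[, , 1:3, drop = FALSE])     # drop alpha if present
    }
    if (length(dim(img)) == 3L) img <- img[, , 1]
    warning("grayscale input: replicating the single channel into R = G = B")
    return(array(rep(img, 3L), dim = c(dim(img), 3L)))
  }
  m2 <- rawToChar(magic[1:2])
  if (!m2 %in% c("P5", "P6"))
    stop("format error: unsupported image format (need PNG, P6 PPM or P5 PGM)",
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 2L, useBytes = TRUE)
  hdr <- readPNMTokens(con, 3L)
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  if (maxval > 255L)
    stop(sprintf("format error: maxval %d, only 8-bit input accepted", maxval),
         call. = FALSE)
  nch <- if (m2 == "P6") 3L else 1L
  bytes <- readBin(con, "integer", n = w * h * nch, size = 1L, signed = FALSE)
  if (length(bytes) < w * h * nch)
    stop("truncated netpbm pixel data", call. = FALSE)
  if (nch == 3L) {
    # interleaved RGB in raster order -> h x w x 3
    px <- array(as.numeric(bytes), dim = c(3L, w, h))
    return(aperm(px, c(3L, 2L, 1L)))
  }
  g <- t(matrix(as.numeric(bytes), nrow = w, ncol = h))
  warning("grayscale input: replicating the single channel into R = G = B")
  array(rep(g, 3L), dim = c(h, w, 3L))
}

#' Write an 8-bit RGB raster
#'
#' Writes binary PPM (P6) or PNG, chosen by file extension.
#'
#' @param image an h x w x 3 array of values in \[0, 255\].
#' @param path output path ending in `.ppm` or `.png`.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  image <- assertRGB8(image)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image / 255, path)
    return(invisible(path))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  px <- as.integer(aperm(image, c(3L, 2L, 1L)))   # interleave RGB, raster order
  writeBin(as.raw(px), con)
  invisible(path)
}

#' Write a signed response map as 16-bit offset PGM
#'
#' Channel maps are signed reals in \[-255, 255\]; PGM stores unsigned
#' integers, so values are encoded as `round(value) + 32768` in a 16-bit
#' (maxval 65535, big-endian) PGM. Decode with `stored - 32768`.
#'
#' @param map signed numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readPGM16()] for the inverse.
#' @export
writePGM16 <- function(map, path) {
  stored <- round(map) + 32768
  if (any(stored < 0) || any(stored > 65535))
    stop("map values out of the representable offset range", call. = FALSE)
  h <- nrow(map); w <- ncol(map)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", w, h), con, eos = NULL)
  v <- as.integer(t(stored))
  writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  invisible(path)
}

#' Read a 16-bit offset PGM back into a signed map
#'
#' @param path a file written by [writePGM16()].
#' @return a signed numeric matrix (`stored - 32768`).
#' @export
readPGM16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 2L, useBytes = TRUE) != "P5")
    stop("format error: not a P5 PGM", call. = FALSE)
  hdr <- readPNMTokens(con, 3L)
  w <- hdr[1]; h <- hdr[2]
  if (hdr[3] != 65535L)
    stop("format error: expected 16-bit (maxval 65535) PGM", call. = FALSE)
  b <- readBin(con, "integer", n = 2L * w * h, size = 1L, signed = FALSE)
  v <- b[c(TRUE, FALSE)] * 256L + b[c(FALSE, TRUE)]
  t(matrix(v, nrow = w, ncol = h)) - 32768
}
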
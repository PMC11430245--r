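#' @include AllClasses.R AllGenerics.R
NULL

## RGB rasters are h x w x 3 numeric arrays holding 8-bit values (0..255),
## rows = image rows, raster-scan order = row by row, left to right.

assertRGB8 <- function(image) {
  if (is.matrix(image)) {
    warning("grayscale input: replicating the single channel into R = G = B")
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("format error: input is not a 2-D raster with a channel axis",
         call. = FALSE)
  if (dim(image)[3] != 3L)
    stop(sprintf("format error: expected 3 channels, got %d", dim(image)[3]),
         call. = FALSE)
  if (anyNA(image) || any(image < 0) || any(image > 255))
    stop("format error: channel values outside the 8-bit range [0, 255]",
         call. = FALSE)
  if (any(image != round(image)))
    stop("format error: channel values are not 8-bit integers", call. = FALSE)
  image
}

#' Map an RGB raster to L/M/S cone planes
#'
#' The photoreceptor layer: each pixel's (R, G, B) byte triple is mapped to
#' (L, M, S) cone responses. The default identity mapping reads the channels
#' straight through (L = R, M = G, S = B), the convention under which the
#' opponent channels are defined; a colorimetric 3x3 RGB-to-LMS matrix may be
#' supplied instead, with results clipped back to \[0, 255\].
#'
#' Grayscale matrices are accepted with a warning by replicating the single
#' channel; 16-bit or out-of-range input is rejected, not rescaled.
#'
#' @param image an h x w x 3 array of 8-bit values (see [readImage()],
#'   [generateFixture()]), or an h x w matrix (grayscale).
#' @param mapping 3x3 real matrix applied to the (R, G, B) column vector;
#'   default identity.
#' @return a [ConePlanes-class] object.
#' @examples
#' img <- generateFixture("uniform", 4, value = c(10, 20, 30))
#' cones <- rgbToConePlanes(img)
#' conePlane(cones, "S")[1, 1]   # 30
#' @export
rgbToConePlanes <- function(image, mapping = diag(3)) {
  image <- assertRGB8(image)
  mapping <- as.matrix(mapping)
  if (!identical(dim(mapping), c(3L, 3L)))
    stop("mapping must be a 3x3 matrix", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- matrix(as.numeric(image), nrow = h * w, ncol = 3L)
  lms <- rgb %*% t(mapping)
  lms <- pmin(pmax(lms, 0), 255)
  new("ConePlanes",
      L = matrix(lms[, 1], h, w),
      M = matrix(lms[, 2], h, w),
      S = matrix(lms[, 3], h, w))
}

#' Generate a seeded synthetic test image
#'
#' Deterministic synthetic RGB rasters standing in for camera input: uniform
#' color fields, a filled disc on a contrasting background (the classic
#' opponent-channel probe, e.g. a blue disc on yellow), a bipartite half-plane
#' edge, and seeded uniform random noise. The generator is a pure function of
#' its arguments; the caller's random-number state is left untouched.
#'
#' @param kind one of `"uniform"`, `"disc"`, `"bipartite"`, `"random"`.
#' @param size image side length in pixels (square output).
#' @param value RGB triple for `"uniform"`.
#' @param fg,bg foreground/background RGB triples for `"disc"` and
#'   `"bipartite"` (fg fills the disc / left half).
#' @param radius disc radius in pixels (must be <= size/2); the disc is
#'   centered on the image center pixel.
#' @param orientation `"vertical"` (left/right split) or `"horizontal"`
#'   for `"bipartite"`.
#' @param seed integer seed, required for `"random"`.
#' @return an h x w x 3 array of 8-bit values.
#' @examples
#' disc <- generateFixture("disc", 33, fg = c(0, 0, 255),
#'                         bg = c(255, 255, 0), radius = 8)
#' disc[17, 17, ]   # 0 0 255 at the center
#' @export
generateFixture <- function(kind, size,
                            value = c(128, 128, 128),
                            fg = c(255, 255, 255), bg = c(0, 0, 0),
                            radius = floor(size / 4),
                            orientation = c("vertical", "horizontal"),
                            seed = NULL) {
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  plane3 <- function(trip, mask = NULL, other = NULL) {
    a <- array(0, dim = c(size, size, 3L))
    for (k in 1:3) {
      p <- matrix(trip[k], size, size)
      if (!is.null(mask)) p[!mask] <- other[k]
      a[, , k] <- p
    }
    a
  }
  switch(match.arg(kind, c("uniform", "disc", "bipartite", "random")),
    uniform = plane3(checkByte(value)),
    disc = {
      if (radius > size / 2)
        stop("disc radius must be <= size/2", call. = FALSE)
      ctr <- (size + 1) / 2
      d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
      plane3(checkByte(fg), mask = d2 <= radius^2, other = checkByte(bg))
    },
    bipartite = {
      orientation <- match.arg(orientation)
      half <- col(matrix(0, size, size)) <= size / 2
      if (orientation == "horizontal") half <- t(half)
      plane3(checkByte(fg), mask = half, other = checkByte(bg))
    },
    random = {
      if (is.null(seed)) stop("seed is required for kind 'random'", call. = FALSE)
      withPrivateRNG(seed, {
        array(sample.int(256L, size * size * 3L, replace = TRUE) - 1L,
              dim = c(size, size, 3L))
      })
    }
  )
}

checkByte <- function(x) {
  if (length(x) != 3L || any(x < 0) || any(x > 255) || any(x != round(x)))
    stop("colors must be RGB triples of bytes in [0, 255]", call. = FALSE)
  as.numeric(x)
}

# run expr under a private seeded RNG stream, restoring the caller's state
withPrivateRNG <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @rdname conePlane
#' @export
setMethod("conePlane", "ConePlanes", function(x, which) {
  which <- match.arg(which, c("L", "M", "S"))
  slot(x, which)
})

#' @rdname imageWidth
#' @export
setMethod("imageWidth", "ConePlanes", function(x) ncol(x@L))

#' @rdname imageWidth
#' @export
setMethod("imageHeight", "ConePlanes", function(x) nrow(x@L))

setMethod("show", "ConePlanes", function(object) {
  cat(sprintf("ConePlanes: %d x %d pixels (L/M/S)\n",
              imageHeight(object), imageWidth(object)))
  for (nm in c("L", "M", "S")) {
    v <- slot(object, nm)
    cat(sprintf("  %s: range [%g, %g], mean %.2f\n",
                nm, min(v), max(v), mean(v)))
  }
})
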
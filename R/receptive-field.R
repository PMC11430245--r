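#' @include AllClasses.R AllGenerics.R
NULL

offsetGrid <- function(size) {
  r <- (size - 1L) / 2L
  o <- seq.int(-r, r)
  list(x = matrix(o, size, size, byrow = TRUE),
       y = matrix(o, size, size),
       r2 = outer(o^2, o^2, `+`))
}

#' Normalized Gaussian weight grid
#'
#' Isotropic Gaussian weights exp(-(x^2 + y^2) / (2 sigma^2)) over the
#' integer offset grid of an odd-sized square window, renormalized to sum to
#' one. This is the radial profile from which both the center and surround
#' regions of a receptive field draw their weights.
#'
#' @param size odd window side length >= 1.
#' @param sigma Gaussian width in pixels, > 0.
#' @return a size x size matrix summing to 1.
#' @examples
#' gaussianWeights(1, 2)        # [[1]]
#' gaussianWeights(3, 1e6)      # ~ 1/9 everywhere (flat limit)
#' @export
gaussianWeights <- function(size, sigma) {
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L || size %% 2L == 0L)
    stop("size must be a single odd integer >= 1", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  g <- exp(-offsetGrid(size)$r2 / (2 * sigma^2))
  g / sum(g)
}

#' Build a center-surround receptive field
#'
#' Constructs a [ReceptiveField-class]: the center is the disc of offsets
#' with x^2 + y^2 <= centerRadius^2, the surround its complement on the
#' grid (default `"disjoint"` style); each region carries Gaussian weights
#' of its own width, renormalized to unit sum within the region so that the
#' opponent response to uniform input is exactly zero. `style =
#' "overlapping"` instead builds the classical overlapping
#' difference-of-Gaussians, both Gaussians spanning the full grid.
#'
#' Defaults when sigmas are omitted: `sigmaCenter = centerRadius / 2`
#' (floored at 0.25 so a single-pixel center stays well defined -- its
#' normalized weight is 1 regardless) and `sigmaSurround = size / 3`.
#'
#' @param size odd side length >= 3 (disjoint style needs a nonempty
#'   surround).
#' @param sigmaCenter,sigmaSurround Gaussian widths; must satisfy
#'   `sigmaSurround > sigmaCenter`.
#' @param centerRadius center disc radius in pixels, `0 <= centerRadius <
#'   size/2 * sqrt(2)`; the default 0.5 makes the center a single pixel,
#'   the midget-cell wiring of the foveal pathway.
#' @param style `"disjoint"` or `"overlapping"`.
#' @return a [ReceptiveField-class] object.
#' @examples
#' rf <- makeReceptiveField(3)
#' sum(rf@centerWeights)    # 1
#' sum(rf@surroundWeights)  # 1
#' @export
makeReceptiveField <- function(size, sigmaCenter = NULL, sigmaSurround = NULL,
                               centerRadius = 0.5,
                               style = c("disjoint", "overlapping")) {
  size <- as.integer(size)
  style <- match.arg(style)
  if (is.null(sigmaCenter)) sigmaCenter <- max(centerRadius / 2, 0.25)
  if (is.null(sigmaSurround)) sigmaSurround <- size / 3
  if (sigmaSurround <= sigmaCenter)
    stop("sigmaSurround must exceed sigmaCenter", call. = FALSE)
  if (centerRadius < 0 || centerRadius >= size / 2 * sqrt(2))
    stop("centerRadius must lie in [0, size/2 * sqrt(2))", call. = FALSE)
  og <- offsetGrid(size)
  if (style == "disjoint") {
    cm <- og$r2 <= centerRadius^2
    sm <- !cm
  } else {
    cm <- sm <- matrix(TRUE, size, size)
  }
  if (!any(cm)) stop("configuration error: empty center region", call. = FALSE)
  if (!any(sm)) stop("configuration error: empty surround region", call. = FALSE)
  regionWeights <- function(mask, sigma) {
    w <- exp(-og$r2 / (2 * sigma^2))
    w[!mask] <- 0
    w / sum(w)
  }
  new("ReceptiveField",
      size = size, sigmaCenter = sigmaCenter, sigmaSurround = sigmaSurround,
      centerRadius = centerRadius, style = style,
      centerMask = cm, surroundMask = sm,
      centerWeights = regionWeights(cm, sigmaCenter),
      surroundWeights = regionWeights(sm, sigmaSurround))
}

#' @rdname combinedKernel
#' @export
setMethod("combinedKernel", "ReceptiveField",
          function(field) field@centerWeights - field@surroundWeights)

distinctFromGrid <- function(weights, r2, tol) {
  key <- sort(unique(as.vector(r2)))
  idx <- matrix(match(as.vector(r2), key), nrow(r2), ncol(r2))
  # integrity: equal radius must mean equal weight
  for (k in seq_along(key)) {
    w <- weights[idx == k]
    if (diff(range(w)) > tol)
      stop("integrity error: weights differ at equal radius beyond tolerance",
           call. = FALSE)
  }
  list(count = length(key), radii2 = key, indexMap = idx)
}

#' @rdname distinctWeightCount
#' @details Radial symmetry lets the datapath store one weight per distinct
#'   squared radius instead of one per grid cell -- three stored weights
#'   suffice for a 3x3 field (radii^2 in 0, 1, 2), six for 5x5. The index
#'   map reconstructs the full grid exactly from the stored slots. The count
#'   is taken on the combined center - surround kernel; an integrity error is
#'   raised if weights at equal radius differ beyond `tol`.
#' @export
setMethod("distinctWeightCount", "ReceptiveField", function(field, tol = 1e-12) {
  distinctFromGrid(combinedKernel(field), offsetGrid(field@size)$r2, tol)
})

#' @rdname distinctWeightCount
#' @export
setMethod("distinctWeightCount", "matrix", function(field, tol = 1e-12) {
  if (nrow(field) != ncol(field) || nrow(field) %% 2L == 0L)
    stop("weight grid must be square with odd size", call. = FALSE)
  distinctFromGrid(field, offsetGrid(nrow(field))$r2, tol)
})

shiftScheduleOf <- function(num) {
  a <- abs(num)
  e <- integer(0)
  k <- 0L
  while (a > 0) {
    if (a %% 2L == 1L) e <- c(e, k)
    a <- a %/% 2L
    k <- k + 1L
  }
  e
}

#' @rdname quantizeToShifts
#' @export
setMethod("quantizeToShifts", "numeric", function(x, fractionBits) {
  f <- as.integer(fractionBits)
  if (length(f) != 1L || is.na(f) || f < 1L || f > 24L)
    stop("fractionBits must be in [1, 24]", call. = FALSE)
  num <- as.integer(round(x * 2^f))    # round half to even: bias-free
  new("ShiftWeightSet", fractionBits = f, weights = as.numeric(x),
      numerators = num, shifts = lapply(num, shiftScheduleOf))
})

#' @rdname quantizeToShifts
#' @export
setMethod("quantizeToShifts", "ReceptiveField", function(x, fractionBits) {
  dist <- function(grid) {
    d <- distinctFromGrid(grid, offsetGrid(x@size)$r2, 1e-12)
    grid[match(seq_len(d$count), d$indexMap)]
  }
  list(center = quantizeToShifts(dist(x@centerWeights), fractionBits),
       surround = quantizeToShifts(dist(x@surroundWeights), fractionBits),
       combined = quantizeToShifts(dist(combinedKernel(x)), fractionBits))
})

#' @rdname quantizedValues
#' @export
setMethod("quantizedValues", "ShiftWeightSet",
          function(x) x@numerators / 2^x@fractionBits)

setMethod("show", "ReceptiveField", function(object) {
  cat(sprintf(
    "ReceptiveField: %dx%d (%s), centerRadius %.2g, sigmas %.3g / %.3g\n",
    object@size, object@size, object@style, object@centerRadius,
    object@sigmaCenter, object@sigmaSurround))
  cat(sprintf("  center %d px, surround %d px, %d distinct radial weights\n",
              sum(object@centerMask), sum(object@surroundMask),
              distinctWeightCount(object)$count))
})

setMethod("show", "ShiftWeightSet", function(object) {
  cat(sprintf("ShiftWeightSet: %d weights at %d fraction bits\n",
              length(object@weights), object@fractionBits))
  err <- max(abs(quantizedValues(object) - object@weights), 0)
  cat(sprintf("  max |quantization error| %.3g (bound %.3g)\n",
              err, 2^(-object@fractionBits - 1)))
})

#' Serialize / restore a receptive-field configuration
#'
#' `rfConfig()` captures the constructor arguments of a field;
#' `rfFromConfig()` rebuilds the field from such a list (e.g. read from the
#' YAML run configuration).
#'
#' @param field a [ReceptiveField-class].
#' @param config a named list with entries `size`, `sigmaCenter`,
#'   `sigmaSurround`, `centerRadius`, `style`.
#' @return `rfConfig()` a named list; `rfFromConfig()` a ReceptiveField.
#' @export
rfConfig <- function(field) {
  list(size = field@size, sigmaCenter = field@sigmaCenter,
       sigmaSurround = field@sigmaSurround,
       centerRadius = field@centerRadius, style = field@style)
}

#' @rdname rfConfig
#' @export
rfFromConfig <- function(config) {
  makeReceptiveField(size = config$size,
                     sigmaCenter = config$sigmaCenter,
                     sigmaSurround = config$sigmaSurround,
                     centerRadius = if (is.null(config$centerRadius)) 0.5
                                    else config$centerRadius,
                     style = if (is.null(config$style)) "disjoint"
                             else config$style)
}
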
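#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ConePlanes: the photoreceptor layer
#'
#' Three aligned intensity planes for the long- (L), medium- (M) and
#' short-wavelength (S) cone mosaics, derived from an RGB raster. Values are
#' stored as reals but are constrained to the 8-bit range \[0, 255\]; with the
#' default identity mapping L, M and S carry the image's R, G and B bytes
#' unchanged.
#'
#' @slot L,M,S numeric matrices of identical dimensions with values in
#'   \[0, 255\]; rows are image rows, columns image columns.
#'
#' @seealso [rgbToConePlanes()], [conePlane()]
#' @export
setClass("ConePlanes",
  representation(L = "matrix", M = "matrix", S = "matrix"),
  validity = function(object) {
    msgs <- character()
    dims <- list(dim(object@L), dim(object@M), dim(object@S))
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      msgs <- c(msgs, "L, M and S planes must share identical dimensions")
    for (nm in c("L", "M", "S")) {
      v <- slot(object, nm)
      if (!is.numeric(v))
        msgs <- c(msgs, sprintf("plane %s must be numeric", nm))
      else if (anyNA(v) || any(v < 0) || any(v > 255))
        msgs <- c(msgs, sprintf("plane %s has values outside [0, 255]", nm))
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' ReceptiveField: a center-surround Gaussian receptive field
#'
#' A square, odd-sized weight grid modelling one ganglion cell's receptive
#' field after Rodieck's difference-of-Gaussians: an excitatory center region
#' and an antagonistic surround ring, each carrying Gaussian weights
#' renormalized to unit sum so that opponent responses vanish on uniform
#' input. In the default `"disjoint"` style the two regions partition the
#' grid (center disc of radius `centerRadius`, surround = complement),
#' mirroring circuit layouts that wire center and surround cells to separate
#' adder inputs; the classical overlapping-DoG variant keeps both Gaussians
#' on the full grid.
#'
#' @slot size odd integer side length in pixels.
#' @slot sigmaCenter,sigmaSurround Gaussian widths (pixels) of the center and
#'   surround profiles; `sigmaSurround > sigmaCenter`.
#' @slot centerRadius radius (pixels) of the center disc on the offset grid.
#' @slot style `"disjoint"` (partitioned regions) or `"overlapping"`
#'   (classical DoG, both masks cover the grid).
#' @slot centerMask,surroundMask logical size-by-size masks.
#' @slot centerWeights,surroundWeights non-negative size-by-size weight
#'   grids, each summing to 1 over its mask and zero off it.
#'
#' @seealso [makeReceptiveField()], [gaussianWeights()],
#'   [distinctWeightCount()], [combinedKernel()]
#' @export
setClass("ReceptiveField",
  representation(
    size = "integer", sigmaCenter = "numeric", sigmaSurround = "numeric",
    centerRadius = "numeric", style = "character",
    centerMask = "matrix", surroundMask = "matrix",
    centerWeights = "matrix", surroundWeights = "matrix"
  ),
  validity = function(object) {
    msgs <- character()
    s <- object@size
    if (length(s) != 1L || s < 1L || s %% 2L == 0L)
      msgs <- c(msgs, "size must be a single odd integer >= 1")
    if (object@sigmaCenter <= 0 || object@sigmaSurround <= 0)
      msgs <- c(msgs, "sigmas must be positive")
    grids <- list(object@centerMask, object@surroundMask,
                  object@centerWeights, object@surroundWeights)
    if (!all(vapply(grids, function(g) identical(dim(g), c(s, s)), logical(1))))
      msgs <- c(msgs, "masks and weights must be size x size")
    else {
      cm <- object@centerMask; sm <- object@surroundMask
      if (object@style == "disjoint") {
        if (any(cm & sm)) msgs <- c(msgs, "center and surround masks overlap")
        if (!all(cm | sm)) msgs <- c(msgs, "masks must cover the grid")
      }
      tol <- 1e-12
      if (abs(sum(object@centerWeights[cm]) - 1) > tol)
        msgs <- c(msgs, "center weights must sum to 1 over the center mask")
      if (abs(sum(object@surroundWeights[sm]) - 1) > tol)
        msgs <- c(msgs, "surround weights must sum to 1 over the surround mask")
      if (any(object@centerWeights[!cm] != 0) ||
          any(object@surroundWeights[!sm] != 0))
        msgs <- c(msgs, "weights must be zero off their mask")
      if (any(object@centerWeights < 0) || any(object@surroundWeights < 0))
        msgs <- c(msgs, "weights must be non-negative")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' ShiftWeightSet: shift-add quantized weights
#'
#' Fixed-point representation of a weight vector for a multiplier-free
#' datapath: each weight w is rounded to a signed integer numerator over
#' 2^fractionBits, and the numerator is decomposed into its set bits so that
#' multiplication becomes a sum of arithmetic shifts. The quantization error
#' per weight is bounded by 2^-(fractionBits+1).
#'
#' @slot fractionBits integer f in \[1, 24\].
#' @slot weights the original real weights.
#' @slot numerators signed integer numerators round(w * 2^f).
#' @slot shifts list of integer vectors; entry i holds the exponents e such
#'   that numerators\[i\] = sign * sum(2^e). Shifting the multiplicand by
#'   (e - f) bit positions and summing reproduces the product.
#'
#' @seealso [quantizeToShifts()], [quantizedValues()]
#' @export
setClass("ShiftWeightSet",
  representation(fractionBits = "integer", weights = "numeric",
                 numerators = "integer", shifts = "list"),
  validity = function(object) {
    msgs <- character()
    f <- object@fractionBits
    if (length(f) != 1L || f < 1L || f > 24L)
      msgs <- c(msgs, "fractionBits must be a single integer in [1, 24]")
    n <- length(object@weights)
    if (length(object@numerators) != n || length(object@shifts) != n)
      msgs <- c(msgs, "weights, numerators and shifts must be aligned")
    else if (n > 0) {
      recon <- vapply(seq_len(n), function(i) {
        e <- object@shifts[[i]]
        sign(object@numerators[i]) * sum(2^e)
      }, numeric(1))
      recon[object@numerators == 0L] <- 0
      if (!isTRUE(all.equal(recon, as.numeric(object@numerators),
                            tolerance = 0)))
        msgs <- c(msgs, "shift schedule does not reproduce the numerators")
      err <- abs(object@numerators / 2^f - object@weights)
      if (any(err > 2^(-f - 1) + 1e-15))
        msgs <- c(msgs, "quantization error exceeds 2^-(f+1)")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' ChannelMap: one opponent pathway's response map
#'
#' A signed response map for a single opponent channel (K, M or P) in the
#' image frame, together with a validity mask combining border validity (the
#' receptive-field window must fit inside the image) and retinal-region
#' gating (M inside the fovea, P outside, K everywhere). The map is zero and
#' flagged invalid outside the mask.
#'
#' @slot channel one of "K", "M", "P".
#' @slot map signed numeric matrix, image-sized.
#' @slot validMask logical matrix of the same dimensions.
#'
#' @seealso [channelMaps()]
#' @export
setClass("ChannelMap",
  representation(channel = "character", map = "matrix", validMask = "matrix"),
  validity = function(object) {
    msgs <- character()
    if (!(length(object@channel) == 1L && object@channel %in% c("K", "M", "P")))
      msgs <- c(msgs, "channel must be one of 'K', 'M', 'P'")
    if (!identical(dim(object@map), dim(object@validMask)))
      msgs <- c(msgs, "map and validMask dimensions differ")
    else if (any(object@map[!object@validMask] != 0))
      msgs <- c(msgs, "map must be zero outside validMask")
    if (length(msgs)) msgs else TRUE
  }
)

#' RetinalGeometry: fixation, fovea and eccentricity layout
#'
#' Spatial layout tying image pixels to visual angle: the fixation point, the
#' pixels-per-degree scale, the foveal half-angle (default 2.5 degrees, i.e.
#' a 5-degree full fovea) and a non-decreasing eccentricity-to-receptive-
#' field-size profile. The default profile is linear, size = a + b * ecc,
#' snapped up to the nearest odd integer; a tabulated (ecc, size) profile may
#' be supplied instead and is interpolated piecewise-linearly.
#'
#' @slot fixation numeric (x, y) in pixel coordinates (x = column, y = row).
#' @slot pixelsPerDegree pixels per degree of visual angle (> 0).
#' @slot foveaHalfAngle foveal half-angle in degrees (> 0).
#' @slot viewingDistance optional viewing distance in mm (NULL if unknown).
#' @slot rfIntercept,rfSlope intercept a (pixels) and slope b (pixels per
#'   degree) of the linear receptive-field-size profile.
#' @slot profileTable optional two-column matrix (ecc_deg, size) overriding
#'   the linear profile; sizes must be non-decreasing in eccentricity.
#'
#' @seealso [retinalGeometry()], [foveaExtent()], [eccentricityDeg()],
#'   [foveaMask()], [rfSizeAt()]
#' @export
setClass("RetinalGeometry",
  representation(
    fixation = "numeric", pixelsPerDegree = "numeric",
    foveaHalfAngle = "numeric", viewingDistance = "numericOrNULL",
    rfIntercept = "numeric", rfSlope = "numeric",
    profileTable = "matrixOrNULL"
  ),
  validity = function(object) {
    msgs <- character()
    if (length(object@fixation) != 2L || anyNA(object@fixation))
      msgs <- c(msgs, "fixation must be a finite (x, y) pair")
    if (object@pixelsPerDegree <= 0)
      msgs <- c(msgs, "pixelsPerDegree must be > 0")
    if (object@foveaHalfAngle <= 0)
      msgs <- c(msgs, "foveaHalfAngle must be > 0")
    if (object@rfSlope < 0)
      msgs <- c(msgs, "rfSlope must be non-negative (profile is non-decreasing)")
    pt <- object@profileTable
    if (!is.null(pt)) {
      if (ncol(pt) != 2L || nrow(pt) < 1L)
        msgs <- c(msgs, "profileTable must have columns (ecc, size)")
      else if (is.unsorted(pt[, 1]) || is.unsorted(pt[, 2]))
        msgs <- c(msgs, "profileTable must be non-decreasing in both columns")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' DatapathReport: datapath structure and resource accounting
#'
#' Accounting record for the emulated hardware datapath: stage counts of the
#' vector-product unit (one parallel multiply level followed by a balanced
#' binary adder tree, versus a sequential multiply-accumulate chain),
#' streaming latency, and LUT-equivalent resource totals with and without
#' sharing of the red-green computational primitive.
#'
#' Slots not applicable to the operation that produced the report are NA.
#'
#' @slot mode `"sequential"` or `"parallel_tree"` (NA for resource reports).
#' @slot n vector length of the dot product.
#' @slot multiplyLevels,adderLevels,criticalPath stage counts; for the
#'   parallel tree criticalPath = 1 + ceiling(log2(n)), for the sequential
#'   chain criticalPath = n + 1.
#' @slot latency streaming latency in ingested pixels until the first valid
#'   output (NA outside streaming mode).
#' @slot unitCosts named numeric map unit -> LUT-equivalent cost.
#' @slot withSharing,withoutSharing resource totals.
#' @slot savingsPercent 100 * (withoutSharing - withSharing) / withoutSharing.
#'
#' @seealso [vectorProductTree()], [resourceReport()], [streamConvolve()]
#' @export
setClass("DatapathReport",
  representation(
    mode = "character", n = "integer",
    multiplyLevels = "integer", adderLevels = "integer",
    criticalPath = "integer", latency = "integer",
    unitCosts = "numeric", withSharing = "numeric",
    withoutSharing = "numeric", savingsPercent = "numeric"
  ),
  prototype(
    mode = NA_character_, n = NA_integer_,
    multiplyLevels = NA_integer_, adderLevels = NA_integer_,
    criticalPath = NA_integer_, latency = NA_integer_,
    unitCosts = numeric(0), withSharing = NA_real_,
    withoutSharing = NA_real_, savingsPercent = NA_real_
  ),
  validity = function(object) {
    msgs <- character()
    if (!is.na(object@mode) &&
        !object@mode %in% c("sequential", "parallel_tree", "stream"))
      msgs <- c(msgs, "mode must be 'sequential', 'parallel_tree' or 'stream'")
    n <- object@n; cp <- object@criticalPath
    if (!is.na(n) && !is.na(cp) && !is.na(object@mode)) {
      if (object@mode == "parallel_tree" &&
          cp != 1L + as.integer(ceiling(log2(max(n, 1L)))))
        msgs <- c(msgs, "parallel_tree criticalPath must be 1 + ceiling(log2(n))")
      if (object@mode == "sequential" && cp != n + 1L)
        msgs <- c(msgs, "sequential criticalPath must be n + 1")
    }
    ws <- object@withSharing; wo <- object@withoutSharing
    if (!is.na(ws) && !is.na(wo)) {
      expect <- if (wo > 0) 100 * (wo - ws) / wo else 0
      if (!isTRUE(all.equal(object@savingsPercent, expect)))
        msgs <- c(msgs, "savingsPercent inconsistent with totals")
    }
    if (length(msgs)) msgs else TRUE
  }
)
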
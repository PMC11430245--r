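#' @include AllClasses.R
NULL

#' Extract one cone plane
#'
#' @param x a [ConePlanes-class] object.
#' @param which `"L"`, `"M"` or `"S"`.
#' @return a numeric matrix (rows = image rows).
#' @export
setGeneric("conePlane", function(x, which) standardGeneric("conePlane"))

#' Image dimensions of a retinal object
#'
#' `imageWidth()` and `imageHeight()` return the pixel dimensions of the
#' underlying image frame.
#'
#' @param x a [ConePlanes-class] or [ChannelMap-class] object.
#' @return a single integer.
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))

#' @rdname imageWidth
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))

#' Count the distinct stored weights of a radially symmetric field
#'
#' @param field a [ReceptiveField-class] object (or a numeric weight matrix).
#' @param tol tolerance for the radial-symmetry integrity check.
#' @return a list with `count` (number of distinct squared radii, i.e. stored
#'   weight slots), `radii2` (the sorted distinct squared radii) and
#'   `indexMap` (size-by-size integer matrix mapping each offset to its slot).
#' @export
setGeneric("distinctWeightCount",
           function(field, tol = 1e-12) standardGeneric("distinctWeightCount"))

#' Quantize weights to shift-add fixed point
#'
#' Rounds each weight to a signed numerator over `2^fractionBits`
#' (round-half-to-even) and records the numerator's set bits, the schedule of
#' arithmetic shifts that replaces the multiplier in the datapath.
#'
#' @param x a numeric vector of weights, or a [ReceptiveField-class] (then
#'   the center kernel, surround kernel and signed combined kernel
#'   center - surround are each quantized).
#' @param fractionBits integer in \[1, 24\].
#' @return for numeric input a [ShiftWeightSet-class]; for a receptive field
#'   a named list of three ShiftWeightSets (`center`, `surround`,
#'   `combined`), each over the field's distinct radial weights.
#' @export
setGeneric("quantizeToShifts",
           function(x, fractionBits) standardGeneric("quantizeToShifts"))

#' Quantized values of a ShiftWeightSet
#'
#' @param x a [ShiftWeightSet-class].
#' @return numeric vector `numerators / 2^fractionBits`.
#' @export
setGeneric("quantizedValues", function(x) standardGeneric("quantizedValues"))

#' Signed combined difference-of-Gaussians kernel
#'
#' @param field a [ReceptiveField-class].
#' @return the size-by-size matrix `centerWeights - surroundWeights`; applied
#'   to a uniform patch it responds 0 by construction.
#' @export
setGeneric("combinedKernel", function(field) standardGeneric("combinedKernel"))

#' Channel accessors
#'
#' @param x a [ChannelMap-class].
#' @return `channelName()` the channel label; `responseMap()` the signed map;
#'   `validMask()` the logical validity mask.
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname channelName
#' @export
setGeneric("responseMap", function(x) standardGeneric("responseMap"))

#' @rdname channelName
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
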
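#' @include receptive-field.R geometry.R
NULL

## Region sums are evaluated in deviation form about the window's center
## sample: because both regions have unit gain, X_cen - Y_per equals
## sum(cw * (X - x0)) - sum(sw * (Y - y0)) + (x0 - y0) in exact arithmetic,
## and the deviation form makes the cancellation on uniform input exact in
## floating point as well (every product is exactly zero). Offset invariance
## is likewise exact for integer-valued planes.

patchCheck <- function(patch, field) {
  s <- field@size
  if (!is.matrix(patch) || !identical(dim(patch), c(s, s)))
    stop(sprintf("shape error: patch must be %d x %d", s, s), call. = FALSE)
}

centerValue <- function(patch, field) patch[(field@size + 1L) / 2L,
                                            (field@size + 1L) / 2L]

regionDev <- function(weights, patch, ref) sum(weights * (patch - ref))

#' Center-minus-surround computational primitive
#'
#' The reusable opponent unit from which all three channels are assembled:
#' `(X_cen - Y_per) / 2`, where X_cen is the center-region weighted sum of
#' one cone plane and Y_per the surround-region weighted sum of another.
#' The four primitives of the datapath are this operation on the plane pairs
#' (L,M) i.e. R-G, (S,M) B-G, (S,L) B-R and (M,L) G-R.
#'
#' @param centerPatch,surroundPatch size x size patches of the two cone
#'   planes, aligned with the field.
#' @param field a [ReceptiveField-class].
#' @return a signed scalar response.
#' @examples
#' rf <- makeReceptiveField(3)
#' primitiveResponse(matrix(255, 3, 3), matrix(0, 3, 3), rf)   # 127.5
#' @export
primitiveResponse <- function(centerPatch, surroundPatch, field) {
  patchCheck(centerPatch, field); patchCheck(surroundPatch, field)
  x0 <- centerValue(centerPatch, field); y0 <- centerValue(surroundPatch, field)
  (regionDev(field@centerWeights, centerPatch, x0) -
   regionDev(field@surroundWeights, surroundPatch, y0) + (x0 - y0)) / 2
}

#' Koniocellular blue-yellow opponent response
#'
#' The K pathway pits the S-cone center against a yellow surround (the mean
#' of the L and M surrounds): direct form `S_cen - (M_per + L_per) / 2`,
#' or equivalently the sum of the B-G and B-R primitives
#' `(S_cen - M_per)/2 + (S_cen - L_per)/2`. The two forms are algebraically
#' identical; both are available so the decomposition used for primitive
#' sharing can be checked against the direct definition.
#'
#' @param L,M,S size x size cone-plane patches.
#' @param field a [ReceptiveField-class].
#' @param form `"direct"`, `"primitive"` or `"both"` (returns a named
#'   vector of the two).
#' @return signed scalar response (or length-2 vector for `"both"`).
#' @export
kResponse <- function(L, M, S, field, form = c("direct", "primitive", "both")) {
  form <- match.arg(form)
  for (p in list(L, M, S)) patchCheck(p, field)
  l0 <- centerValue(L, field); m0 <- centerValue(M, field)
  s0 <- centerValue(S, field)
  cw <- field@centerWeights; sw <- field@surroundWeights
  direct <- function() {
    regionDev(cw, S, s0) -
      (regionDev(sw, M, m0) + regionDev(sw, L, l0)) / 2 +
      (s0 - (m0 + l0) / 2)
  }
  primitive <- function() {
    primitiveResponse(S, M, field) + primitiveResponse(S, L, field)
  }
  switch(form,
         direct = direct(),
         primitive = primitive(),
         both = c(direct = direct(), primitive = primitive()))
}

#' Midget red-green opponent response (M pathway)
#'
#' The foveal two-color channel: red center against green surround,
#' `(L_cen - M_per) / 2` -- a single application of the R-G primitive.
#'
#' @inheritParams kResponse
#' @return signed scalar response.
#' @export
mResponse <- function(L, M, field) primitiveResponse(L, M, field)

#' Homochromatic opponent response (P pathway)
#'
#' The peripheral luminance-type channel: both center and surround draw on
#' the same cone classes, `(L_cen - L_per)/2 + (M_cen - M_per)/2`
#' (homochromatic form), which equals the primitive decomposition
#' `(L_cen - M_per)/2 + (M_cen - L_per)/2` (R-G plus G-R).
#'
#' @inheritParams kResponse
#' @param form `"homochromatic"`, `"primitive"` or `"both"`.
#' @return signed scalar response (or length-2 vector for `"both"`).
#' @export
pResponse <- function(L, M, field,
                      form = c("homochromatic", "primitive", "both")) {
  form <- match.arg(form)
  patchCheck(L, field); patchCheck(M, field)
  homo <- function() {
    l0 <- centerValue(L, field); m0 <- centerValue(M, field)
    cw <- field@centerWeights; sw <- field@surroundWeights
    (regionDev(cw, L, l0) - regionDev(sw, L, l0)) / 2 +
      (regionDev(cw, M, m0) - regionDev(sw, M, m0)) / 2
  }
  primitive <- function() {
    primitiveResponse(L, M, field) + primitiveResponse(M, L, field)
  }
  switch(form,
         homochromatic = homo(),
         primitive = primitive(),
         both = c(homochromatic = homo(), primitive = primitive()))
}

## quantize a field's region weights to fractionBits (round half to even);
## returns a plain list usable in place of the S4 slots
fieldWeights <- function(field, fractionBits = NULL) {
  cw <- field@centerWeights; sw <- field@surroundWeights
  if (!is.null(fractionBits)) {
    f <- as.integer(fractionBits)
    cw <- round(cw * 2^f) / 2^f
    sw <- round(sw * 2^f) / 2^f
  }
  list(size = field@size, centerWeights = cw, surroundWeights = sw)
}

## per-window channel evaluators over plain weight lists (deviation form,
## same arithmetic as the exported patch functions)
windowResponse <- function(channel, wts, wL, wM, wS) {
  s <- wts$size; c0 <- (s + 1L) / 2L
  cw <- wts$centerWeights; sw <- wts$surroundWeights
  if (channel == "K") {
    l0 <- wL[c0, c0]; m0 <- wM[c0, c0]; s0 <- wS[c0, c0]
    sum(cw * (wS - s0)) -
      (sum(sw * (wM - m0)) + sum(sw * (wL - l0))) / 2 +
      (s0 - (m0 + l0) / 2)
  } else if (channel == "M") {
    l0 <- wL[c0, c0]; m0 <- wM[c0, c0]
    (sum(cw * (wL - l0)) - sum(sw * (wM - m0)) + (l0 - m0)) / 2
  } else {
    l0 <- wL[c0, c0]; m0 <- wM[c0, c0]
    (sum(cw * (wL - l0)) - sum(sw * (wL - l0))) / 2 +
      (sum(cw * (wM - m0)) - sum(sw * (wM - m0))) / 2
  }
}

#' Default peripheral receptive field for a given size
#'
#' The field used by the P pathway at eccentricities where the geometry
#' profile requests `size` pixels: center disc radius 0.5 for a 3x3 field
#' (single-pixel center, as in the fovea) growing as `(size - 1)/4` for
#' larger fields.
#'
#' @param size odd field size.
#' @return a [ReceptiveField-class].
#' @export
defaultFieldFor <- function(size) {
  makeReceptiveField(size,
                     centerRadius = if (size <= 3L) 0.5 else (size - 1) / 4)
}

#' Compute region-gated K, M and P channel maps
#'
#' Runs the three opponent pathways over a full image: the K blue-yellow map
#' everywhere, the M red-green map only inside the fovea, and the P
#' homochromatic map only outside it, with the P receptive-field size growing
#' with eccentricity along the geometry profile. A pixel is valid when its
#' channel's receptive-field window fits inside the image and the pixel lies
#' in the channel's retinal region; maps are zero elsewhere.
#'
#' The `"stream"` engine delivers windows through the raster-scan line-buffer
#' emulation ([streamConvolve()]'s machinery) and produces maps bit-identical
#' to the `"batch"` engine, which slices windows directly.
#'
#' @param cones a [ConePlanes-class].
#' @param geometry a [RetinalGeometry-class].
#' @param fields optional list with entries `K`, `M` ([ReceptiveField-class],
#'   default 3x3 single-pixel-center fields) and `P` (a function
#'   size -> ReceptiveField, default [defaultFieldFor()]).
#' @param engine `"batch"` or `"stream"`.
#' @param fractionBits optional integer: quantize all region weights to
#'   shift-add fixed point with this many fraction bits before evaluation.
#' @return named list of three [ChannelMap-class] objects (`K`, `M`, `P`).
#' @export
channelMaps <- function(cones, geometry, fields = list(),
                        engine = c("batch", "stream"), fractionBits = NULL) {
  stopifnot(is(cones, "ConePlanes"), is(geometry, "RetinalGeometry"))
  engine <- match.arg(engine)
  h <- imageHeight(cones); w <- imageWidth(cones)
  kField <- if (!is.null(fields$K)) fields$K else makeReceptiveField(3L)
  mField <- if (!is.null(fields$M)) fields$M else makeReceptiveField(3L)
  pFieldFor <- if (!is.null(fields$P)) fields$P else defaultFieldFor
  if (min(h, w) < max(kField@size, mField@size))
    stop("image smaller than the receptive field", call. = FALSE)

  fov <- foveaMask(geometry, c(h, w))
  if (!any(fov))
    warning("fovea mask is empty: M channel map has no valid pixels")

  L <- cones@L; M <- cones@M; S <- cones@S

  evalMap <- function(channel, field, centers) {
    wts <- fieldWeights(field, fractionBits)
    out <- matrix(0, h, w)
    r <- (wts$size - 1L) / 2L
    fits <- matrix(FALSE, h, w)
    if (h >= wts$size && w >= wts$size)
      fits[(r + 1L):(h - r), (r + 1L):(w - r)] <- TRUE
    sel <- centers & fits
    if (any(sel)) {
      if (engine == "batch") {
        for (idx in which(sel)) {
          i <- (idx - 1L) %% h + 1L; j <- (idx - 1L) %/% h + 1L
          ri <- (i - r):(i + r); cj <- (j - r):(j + r)
          out[i, j] <- windowResponse(channel, wts,
                                      L[ri, cj], M[ri, cj], S[ri, cj])
        }
      } else {
        streamWindows3(L, M, S, wts$size, function(i, j, wL, wM, wS) {
          if (sel[i, j])
            out[i, j] <<- windowResponse(channel, wts, wL, wM, wS)
        })
      }
    }
    new("ChannelMap", channel = channel, map = out, validMask = sel)
  }

  kMap <- evalMap("K", kField, matrix(TRUE, h, w))
  mMap <- evalMap("M", mField, fov)

  # P: eccentricity-dependent field size outside the fovea
  ecc <- eccentricityGrid(geometry, c(h, w))
  sizes <- matrix(rfSizeAt(as.vector(ecc), geometry), h, w)
  pOut <- matrix(0, h, w)
  pMask <- matrix(FALSE, h, w)
  for (s in sort(unique(sizes[!fov]))) {
    if (min(h, w) < s) next
    part <- evalMap("P", pFieldFor(s), !fov & sizes == s)
    pOut <- pOut + part@map
    pMask <- pMask | part@validMask
  }
  pMap <- new("ChannelMap", channel = "P", map = pOut, validMask = pMask)

  list(K = kMap, M = mMap, P = pMap)
}

#' @rdname channelName
#' @export
setMethod("channelName", "ChannelMap", function(x) x@channel)

#' @rdname channelName
#' @export
setMethod("responseMap", "ChannelMap", function(x) x@map)

#' @rdname channelName
#' @export
setMethod("validMask", "ChannelMap", function(x) x@validMask)

#' @rdname imageWidth
#' @export
setMethod("imageWidth", "ChannelMap", function(x) ncol(x@map))

#' @rdname imageWidth
#' @export
setMethod("imageHeight", "ChannelMap", function(x) nrow(x@map))

setMethod("show", "ChannelMap", function(object) {
  v <- object@map[object@validMask]
  cat(sprintf("ChannelMap %s: %d x %d, %d valid pixels\n",
              object@channel, nrow(object@map), ncol(object@map),
              sum(object@validMask)))
  if (length(v))
    cat(sprintf("  range [%.3f, %.3f], mean %.4f\n", min(v), max(v), mean(v)))
})

#' Summary statistics of channel maps
#'
#' @param maps the list returned by [channelMaps()].
#' @return a data.frame with one row per channel: valid pixel count, min,
#'   max and mean response over the valid region.
#' @export
channelSummary <- function(maps) {
  do.call(rbind, lapply(maps, function(m) {
    v <- m@map[m@validMask]
    data.frame(channel = m@channel, valid = sum(m@validMask),
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_)
  }))
}
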
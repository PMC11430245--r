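#' @include receptive-field.R
NULL

resolveKernel <- function(field) {
  if (is(field, "ReceptiveField")) combinedKernel(field)
  else if (is.matrix(field) && nrow(field) == ncol(field) &&
           nrow(field) %% 2L == 1L) field
  else stop("field must be a ReceptiveField or an odd square matrix",
            call. = FALSE)
}

## Raster-scan line-buffer window delivery over three planes at once:
## (size-1) line buffers of length width plus a size x size register window
## per plane; the window shifts one column per ingested pixel and is handed
## to `emit(i, j, winL, winM, winS)` (i, j = window-center pixel) once full.
streamWindows3 <- function(L, M, S, size, emit) {
  h <- nrow(L); w <- ncol(L); s <- as.integer(size)
  if (w < s || h < s)
    stop("configuration error: image width smaller than the field",
         call. = FALSE)
  r <- (s - 1L) / 2L
  planes <- list(L, M, S)
  bufs <- lapply(planes, function(p) matrix(0, max(s - 1L, 1L), w))
  wins <- lapply(planes, function(p) matrix(0, s, s))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (k in 1:3) {
        px <- planes[[k]][i, j]
        win <- wins[[k]]
        if (s > 1L) {
          newcol <- c(bufs[[k]][, j], px)
          if (s > 2L) bufs[[k]][1:(s - 2L), j] <- bufs[[k]][2:(s - 1L), j]
          bufs[[k]][s - 1L, j] <- px
          win[, 1:(s - 1L)] <- win[, 2:s]
          win[, s] <- newcol
        } else win[1L, 1L] <- px
        wins[[k]] <- win
      }
      if (i >= s && j >= s)
        emit(i - r, j - r, wins[[1L]], wins[[2L]], wins[[3L]])
    }
  }
  invisible(NULL)
}

#' Streaming line-buffer convolution
#'
#' Emulates the raster-scan hardware delivery of receptive fields: pixels
#' arrive one per cycle in row-major order; `size - 1` line buffers of
#' length `width` plus a size x size register window make the full
#' receptive field readable in parallel each cycle once the window has
#' filled. The first valid response appears after
#' `(size - 1) * width + size` ingested pixels, and the emitted response
#' grid is bit-exactly the valid-region convolution computed by
#' [batchConvolve()] (both evaluate `sum(window * kernel)` over identical
#' windows).
#'
#' @param plane numeric matrix (one cone plane).
#' @param field a [ReceptiveField-class] (its signed combined kernel is
#'   used) or an odd square kernel matrix.
#' @return list with `response` ((h-size+1) x (w-size+1) matrix of window
#'   dot products), `latency` (pixels until first valid output) and
#'   `report` (a [DatapathReport-class] in `"stream"` mode).
#' @export
streamConvolve <- function(plane, field) {
  kernel <- resolveKernel(field)
  s <- nrow(kernel)
  h <- nrow(plane); w <- ncol(plane)
  out <- matrix(NA_real_, h - s + 1L, w - s + 1L)
  streamWindows3(plane, plane, plane, s, function(i, j, wL, wM, wS) {
    r <- (s - 1L) / 2L
    out[i - r, j - r] <<- sum(wL * kernel)
  })
  latency <- (s - 1L) * w + s
  rep <- new("DatapathReport", mode = "stream", n = as.integer(s * s),
             latency = as.integer(latency))
  list(response = out, latency = as.integer(latency), report = rep)
}

#' Direct valid-region convolution
#'
#' Whole-image reference path for the streaming datapath: for every position
#' where the window fits, the response is `sum(window * kernel)`, the same
#' expression (and floating-point summation order) [streamConvolve()]
#' evaluates, so the two are bit-identical.
#'
#' @inheritParams streamConvolve
#' @return (h-size+1) x (w-size+1) response matrix.
#' @export
batchConvolve <- function(plane, field) {
  kernel <- resolveKernel(field)
  s <- nrow(kernel)
  h <- nrow(plane); w <- ncol(plane)
  if (h < s || w < s)
    stop("configuration error: image smaller than the field", call. = FALSE)
  out <- matrix(NA_real_, h - s + 1L, w - s + 1L)
  for (i in seq_len(h - s + 1L))
    for (j in seq_len(w - s + 1L))
      out[i, j] <- sum(plane[i:(i + s - 1L), j:(j + s - 1L)] * kernel)
  out
}

#' Vector product via parallel multiply/adder tree or sequential MAC
#'
#' Computes the dot product of a receptive-field window with its weights the
#' way the datapath does, and reports the critical path. In
#' `"parallel_tree"` mode all n products are formed in one simultaneous
#' multiply level and summed by a balanced binary adder tree:
#' `criticalPath = 1 + ceiling(log2(n))` stages (5 for the 9-dimensional
#' product of a 3x3 field). In `"sequential"` mode a single
#' multiply-accumulate unit takes one multiply stage plus one accumulate
#' stage per element: `criticalPath = n + 1` (10 for n = 9).
#'
#' With a [ShiftWeightSet-class] the multiplies are exact integer shift-adds
#' (values must be integers, e.g. 8-bit pixels); tree and sequential results
#' are then bit-identical, and the accumulator is asserted to stay within
#' exact-integer range.
#'
#' @param values numeric vector of length n.
#' @param weights numeric vector of length n, or a [ShiftWeightSet-class]
#'   of length n.
#' @param mode `"parallel_tree"` or `"sequential"`.
#' @return list with `value` (the dot product) and `report`
#'   (a [DatapathReport-class]).
#' @examples
#' vectorProductTree(rep(1, 9), rep(1, 9))$report@criticalPath    # 5
#' vectorProductTree(rep(1, 9), rep(1, 9), "sequential")$report@criticalPath # 10
#' @export
vectorProductTree <- function(values, weights,
                              mode = c("parallel_tree", "sequential")) {
  mode <- match.arg(mode)
  fixed <- is(weights, "ShiftWeightSet")
  wv <- if (fixed) weights@numerators else weights
  n <- length(values)
  if (length(wv) != n)
    stop("shape error: values and weights lengths differ", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (fixed) {
    if (any(values != round(values)))
      stop("fixed-point mode requires integer values", call. = FALSE)
    # accumulator width f + bits(values) + log2(n) + 1 must fit exactly
    stopifnot(sum(abs(values * as.numeric(wv))) < 2^53)
  }
  products <- values * as.numeric(wv)
  if (mode == "parallel_tree") {
    acc <- products
    adderLevels <- 0L
    while (length(acc) > 1L) {
      m <- length(acc)
      half <- m %/% 2L
      nxt <- acc[seq_len(half) * 2L - 1L] + acc[seq_len(half) * 2L]
      if (m %% 2L == 1L) nxt <- c(nxt, acc[m])
      acc <- nxt
      adderLevels <- adderLevels + 1L
    }
    total <- acc
    multiplyLevels <- 1L
  } else {
    total <- 0
    for (i in seq_len(n)) total <- total + products[i]
    adderLevels <- n
    multiplyLevels <- 1L
  }
  value <- if (fixed) total / 2^weights@fractionBits else total
  cp <- if (mode == "parallel_tree") multiplyLevels + adderLevels
        else n + 1L
  rep <- new("DatapathReport", mode = mode, n = as.integer(n),
             multiplyLevels = multiplyLevels,
             adderLevels = as.integer(adderLevels),
             criticalPath = as.integer(cp))
  list(value = value, report = rep)
}

#' LUT-equivalent resource accounting with primitive sharing
#'
#' Models the resource effect of sharing the red-green computational
#' primitive between the M and P pathways: `withSharing` is the cost of the
#' units actually instantiated; `withoutSharing` adds the cost of the
#' duplicates that sharing avoids; savings are reported as a percentage of
#' the without-sharing total. Unit costs are configuration inputs
#' (synthesis figures, see [defaultUnitCosts()]), not values this software
#' derives.
#'
#' @param unitCosts named numeric vector, unit name -> LUT-equivalent cost.
#' @param instantiatedUnits character vector of unit names actually built.
#' @param sharedUnits character vector of unit names whose duplicate is
#'   avoided by sharing (may repeat, may be empty).
#' @return a [DatapathReport-class] carrying the totals and
#'   `savingsPercent` (round only at the reporting layer).
#' @examples
#' costs <- c(pipeline = 1397, R_G = 313)
#' r <- resourceReport(costs, "pipeline", "R_G")
#' r@withoutSharing          # 1710
#' round(r@savingsPercent)   # 18
#' @export
resourceReport <- function(unitCosts, instantiatedUnits,
                           sharedUnits = character(0)) {
  unknown <- setdiff(c(instantiatedUnits, sharedUnits), names(unitCosts))
  if (length(unknown))
    stop(sprintf("configuration error: unknown unit(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  ws <- sum(unitCosts[instantiatedUnits])
  saved <- if (length(sharedUnits)) sum(unitCosts[sharedUnits]) else 0
  wo <- ws + saved
  sp <- if (wo > 0) 100 * (wo - ws) / wo else 0
  new("DatapathReport", unitCosts = unitCosts,
      withSharing = ws, withoutSharing = wo, savingsPercent = sp)
}

#' Percent decrease between two resource totals
#'
#' @param before,after totals in the same unit; `before > 0`.
#' @return `100 * (before - after) / before`, unrounded.
#' @examples
#' round(percentDecrease(1132, 334), 1)   # 70.5
#' @export
percentDecrease <- function(before, after) {
  if (any(before <= 0)) stop("before must be > 0", call. = FALSE)
  100 * (before - after) / before
}

#' Bundled LUT cost tables
#'
#' Loads the LUT-equivalent unit-cost configuration shipped with the
#' package (`inst/extdata/lut_costs.yaml`). These are published FPGA
#' synthesis figures for the four opponent primitives at 3x3 and 5x5
#' receptive-field sizes, before and after datapath optimization; they are
#' configuration inputs for [resourceReport()], not values this software
#' computes. The file keeps both reported costs for the shared red-green
#' unit (313 in the accounting narrative, 316 in the per-unit table);
#' `rg_shared_cost` selects the one that reproduces the published 1710
#' total.
#'
#' @param path optional alternative YAML file.
#' @return a nested list of cost tables.
#' @export
defaultUnitCosts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lut_costs.yaml", package = "retinaKMP",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

setMethod("show", "DatapathReport", function(object) {
  cat("DatapathReport\n")
  if (!is.na(object@mode)) {
    cat(sprintf("  mode: %s", object@mode))
    if (!is.na(object@n)) cat(sprintf(", n = %d", object@n))
    cat("\n")
  }
  if (!is.na(object@criticalPath))
    cat(sprintf("  critical path: %d stages (%d multiply + %d adder)\n",
                object@criticalPath, object@multiplyLevels,
                object@adderLevels))
  if (!is.na(object@latency))
    cat(sprintf("  streaming latency: %d pixels\n", object@latency))
  if (!is.na(object@withSharing))
    cat(sprintf(
      "  resources: %g with sharing / %g without (%.1f%% saved)\n",
      object@withSharing, object@withoutSharing, object@savingsPercent))
})
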
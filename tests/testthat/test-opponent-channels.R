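test_that("the computational primitive is the half difference of region sums", {
  rf <- makeReceptiveField(3)
  expect_equal(primitiveResponse(matrix(80, 3, 3), matrix(80, 3, 3), rf), 0)
  expect_equal(primitiveResponse(matrix(255, 3, 3), matrix(0, 3, 3), rf), 127.5)

  set.seed(11)
  for (i in 1:25) {
    X <- randomPatch(3); Y <- randomPatch(3)
    oracle <- (bruteWeightedSum(rf@centerWeights, X) -
               bruteWeightedSum(rf@surroundWeights, Y)) / 2
    expect_equal(primitiveResponse(X, Y, rf), oracle, tolerance = 1e-12)
  }
  expect_error(primitiveResponse(matrix(0, 2, 2), matrix(0, 3, 3), rf),
               "shape")
})

test_that("blue-yellow response: direct and primitive decompositions agree", {
  rf <- makeReceptiveField(3)
  u <- matrix(117, 3, 3)
  expect_equal(kResponse(u, u, u, rf), 0)

  S <- matrix(0, 3, 3); S[2, 2] <- 255
  z <- matrix(0, 3, 3)
  expect_equal(kResponse(z, z, S, rf), 255)      # S_cen = 255, surrounds dark

  set.seed(22)
  for (i in 1:50) {
    L <- randomPatch(3); M <- randomPatch(3); S <- randomPatch(3)
    both <- kResponse(L, M, S, rf, form = "both")
    expect_equal(both[["direct"]], both[["primitive"]], tolerance = 1e-12)
    oracle <- bruteWeightedSum(rf@centerWeights, S) -
      (bruteWeightedSum(rf@surroundWeights, M) +
       bruteWeightedSum(rf@surroundWeights, L)) / 2
    expect_equal(both[["direct"]], oracle, tolerance = 1e-12)
  }
})

test_that("red-green midget response is one application of the R-G primitive", {
  rf <- makeReceptiveField(3)
  expect_equal(mResponse(matrix(9, 3, 3), matrix(9, 3, 3), rf), 0)
  expect_equal(mResponse(matrix(255, 3, 3), matrix(0, 3, 3), rf), 127.5)
  set.seed(33)
  L <- randomPatch(3); M <- randomPatch(3)
  expect_identical(mResponse(L, M, rf), primitiveResponse(L, M, rf))
})

test_that("homochromatic response: both algebraic forms agree", {
  rf <- makeReceptiveField(3)
  u <- matrix(64, 3, 3)
  expect_equal(pResponse(u, u, rf), 0)

  # L = M, center value a, surround value b -> a - b
  a <- 200; b <- 30
  P <- matrix(b, 3, 3); P[2, 2] <- a
  expect_equal(pResponse(P, P, rf), a - b)

  set.seed(44)
  for (i in 1:50) {
    L <- randomPatch(3); M <- randomPatch(3)
    both <- pResponse(L, M, rf, form = "both")
    expect_equal(both[["homochromatic"]], both[["primitive"]],
                 tolerance = 1e-12)
  }
})

test_that("channel maps follow the retinal region gating", {
  img <- generateFixture("random", 21, seed = 5)
  cones <- rgbToConePlanes(img)

  # fovea covering the whole image: P has no valid pixels, M fills the frame
  gAll <- retinalGeometry(c(11, 11), pixelsPerDegree = 1, foveaHalfAngle = 50)
  mAll <- channelMaps(cones, gAll)
  expect_false(any(mAll$P@validMask))
  expect_equal(sum(mAll$M@validMask), 19 * 19)   # 3x3 border strip invalid

  # empty fovea: M empty (with a warning), P covers the valid frame
  gNone <- retinalGeometry(c(-90, -90), pixelsPerDegree = 1,
                           foveaHalfAngle = 1e-9, rfSlope = 0)
  expect_warning(mNone <- channelMaps(cones, gNone), "fovea mask is empty")
  expect_false(any(mNone$M@validMask))
  expect_true(all(mNone$P@validMask[2:20, 2:20]))
})

test_that("region masks partition the frame: M and P disjoint, K superset", {
  img <- generateFixture("random", 25, seed = 9)
  cones <- rgbToConePlanes(img)
  g <- retinalGeometry(c(13, 13), pixelsPerDegree = 3, foveaHalfAngle = 2.5)
  maps <- channelMaps(cones, g)
  expect_false(any(maps$M@validMask & maps$P@validMask))
  expect_true(all(maps$K@validMask[maps$M@validMask | maps$P@validMask]))
  # maps are zero and invalid outside their masks
  for (m in maps) expect_true(all(m@map[!m@validMask] == 0))
})

test_that("K map lights up inside a blue disc on a yellow field", {
  img <- generateFixture("disc", 33, fg = c(0, 0, 255), bg = c(255, 255, 0),
                         radius = 8)
  cones <- rgbToConePlanes(img)
  g <- retinalGeometry(c(17, 17), pixelsPerDegree = 10)
  maps <- channelMaps(cones, g)
  K <- maps$K@map
  expect_equal(max(K), 255)
  peak <- which(K == max(K), arr.ind = TRUE)
  d <- sqrt((peak[, 2] - 17)^2 + (peak[, 1] - 17)^2)
  expect_true(all(d <= 8))                        # maxima inside the disc
  expect_lt(K[17, 17 + 10], 0)                    # yellow side of the ring

  # independent check of the full map: batch convolution with region kernels
  rf <- makeReceptiveField(3)
  S <- conePlane(cones, "S"); M <- conePlane(cones, "M")
  L <- conePlane(cones, "L")
  oracle <- bruteConvolve(S, rf@centerWeights) -
    (bruteConvolve(M, rf@surroundWeights) +
     bruteConvolve(L, rf@surroundWeights)) / 2
  expect_equal(K[2:32, 2:32], oracle, tolerance = 1e-9)
})

test_that("uniform images yield exactly zero K, M and P maps", {
  for (v in c(0, 128, 255)) {
    cones <- rgbToConePlanes(generateFixture("uniform", 15,
                                             value = c(v, v, v)))
    g <- retinalGeometry(c(8, 8), pixelsPerDegree = 2)
    maps <- channelMaps(cones, g)
    for (m in maps) expect_identical(max(abs(m@map)), 0)
  }
})

test_that("responses are offset-invariant and linear in the cone planes", {
  rf <- makeReceptiveField(3)
  set.seed(55)
  for (i in 1:20) {
    L <- randomPatch(3); M <- randomPatch(3); S <- randomPatch(3)
    base <- c(kResponse(L, M, S, rf), mResponse(L, M, rf), pResponse(L, M, rf))
    # exact offset invariance for integer shifts of all three planes
    off <- c(kResponse(L + 40, M + 40, S + 40, rf),
             mResponse(L + 40, M + 40, rf), pResponse(L + 40, M + 40, rf))
    expect_identical(off, base)
    # linearity under scaling into [0, 1]
    a <- 0.3
    sc <- c(kResponse(a * L, a * M, a * S, rf), mResponse(a * L, a * M, rf),
            pResponse(a * L, a * M, rf))
    expect_equal(sc, a * base, tolerance = 1e-12)
  }
})

test_that("eccentricity-growing fields enlarge the P pathway's window", {
  img <- generateFixture("random", 41, seed = 12)
  cones <- rgbToConePlanes(img)
  g <- retinalGeometry(c(21, 21), pixelsPerDegree = 2, foveaHalfAngle = 2.5,
                       rfIntercept = 3, rfSlope = 0.5)
  maps <- channelMaps(cones, g)
  # far corner pixels use a larger field than near-fovea P pixels
  eccFar <- eccentricityDeg(c(41, 41), g)
  expect_gt(rfSizeAt(eccFar, g), 3L)
  expect_true(any(maps$P@validMask))
  # a pixel whose enlarged window does not fit the image is invalid
  expect_false(maps$P@validMask[41, 41])
})

test_that("stream and batch engines produce bit-identical channel maps", {
  img <- generateFixture("random", 19, seed = 77)
  cones <- rgbToConePlanes(img)
  g <- retinalGeometry(c(10, 10), pixelsPerDegree = 2)
  mb <- channelMaps(cones, g, engine = "batch")
  ms <- channelMaps(cones, g, engine = "stream")
  for (ch in c("K", "M", "P")) {
    expect_identical(ms[[ch]]@map, mb[[ch]]@map)
    expect_identical(ms[[ch]]@validMask, mb[[ch]]@validMask)
  }
})

test_that("quantized fixed-point weights keep uniform rejection exact", {
  cones <- rgbToConePlanes(generateFixture("uniform", 11,
                                           value = c(99, 99, 99)))
  g <- retinalGeometry(c(6, 6), pixelsPerDegree = 2)
  maps <- channelMaps(cones, g, fractionBits = 8L)
  for (m in maps) expect_identical(max(abs(m@map)), 0)
})
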
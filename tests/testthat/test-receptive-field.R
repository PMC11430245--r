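test_that("gaussian weights normalize, flatten in the wide limit and match a brute-force oracle", {
  expect_identical(gaussianWeights(1, 3.7), matrix(1, 1, 1))

  flat <- gaussianWeights(3, 1e6)
  expect_true(all(abs(flat - 1 / 9) < 1e-9))

  # independent oracle: sum exp(-r^2/2) over the nine offsets, divide
  g <- gaussianWeights(3, 1.0)
  total <- 0
  for (x in -1:1) for (y in -1:1) total <- total + exp(-(x^2 + y^2) / 2)
  expect_equal(g[2, 2], exp(0) / total, tolerance = 1e-14)
  expect_equal(sum(g), 1, tolerance = 1e-12)

  expect_error(gaussianWeights(4, 1), "odd")
  expect_error(gaussianWeights(0, 1), "odd")
  expect_error(gaussianWeights(3, 0), "positive")
})

test_that("center/surround masks partition the grid at the configured radius", {
  rf <- makeReceptiveField(3, centerRadius = 0.5)
  expect_equal(sum(rf@centerMask), 1)           # single central pixel
  expect_equal(sum(rf@surroundMask), 8)
  expect_equal(rf@centerWeights[2, 2], 1)

  # offsets with x^2 + y^2 <= 1.5^2 on the 5x5 grid: 9 center, 16 surround
  rf5 <- makeReceptiveField(5, centerRadius = 1.5)
  expect_equal(sum(rf5@centerMask), 9)
  expect_equal(sum(rf5@surroundMask), 16)
  expect_false(any(rf5@centerMask & rf5@surroundMask))
  expect_true(all(rf5@centerMask | rf5@surroundMask))

  for (rf_i in list(rf, rf5)) {
    expect_equal(sum(rf_i@centerWeights), 1, tolerance = 1e-12)
    expect_equal(sum(rf_i@surroundWeights), 1, tolerance = 1e-12)
  }

  # radius swallowing the whole 3x3 grid leaves no surround
  expect_error(makeReceptiveField(3, centerRadius = 1.5), "empty surround")
  expect_error(makeReceptiveField(3, sigmaCenter = 2, sigmaSurround = 1),
               "exceed")
})

test_that("weights are radially symmetric: equal radius implies equal weight", {
  for (size in c(3L, 5L, 7L)) {
    rf <- makeReceptiveField(size, centerRadius = (size - 1) / 4)
    k <- combinedKernel(rf)
    r <- (size - 1) / 2
    off <- seq(-r, r)
    r2 <- outer(off^2, off^2, `+`)
    for (v in unique(as.vector(r2)))
      expect_lt(diff(range(k[r2 == v])), 1e-15)
  }
})

test_that("distinct weight slots count the distinct squared radii", {
  expect_equal(distinctWeightCount(makeReceptiveField(3))$count, 3)
  expect_equal(distinctWeightCount(matrix(1, 1, 1))$count, 1)
  d5 <- distinctWeightCount(makeReceptiveField(5))
  expect_equal(d5$count, 6)
  expect_equal(d5$radii2, c(0, 1, 2, 4, 5, 8))
})

test_that("slot count matches a brute-force unique count for sizes 1 to 9", {
  expect_equal(distinctWeightCount(matrix(1, 1, 1))$count, 1L)
  for (size in c(3L, 5L, 7L, 9L)) {
    rf <- makeReceptiveField(size, centerRadius = (size - 1) / 4)
    k <- combinedKernel(rf)
    brute <- length(unique(signif(as.vector(k), 12)))
    expect_equal(distinctWeightCount(rf)$count, brute)
  }
})

test_that("stored slots plus index map reconstruct the grid exactly", {
  rf <- makeReceptiveField(7, centerRadius = 1.5)
  k <- combinedKernel(rf)
  d <- distinctWeightCount(rf)
  slots <- k[match(seq_len(d$count), d$indexMap)]
  expect_identical(matrix(slots[d$indexMap], 7, 7), k)
})

test_that("a symmetry violation raises an integrity error", {
  k <- combinedKernel(makeReceptiveField(3))
  k[1, 2] <- k[1, 2] + 1e-6
  expect_error(distinctWeightCount(k), "integrity")
})

test_that("unit-gain regions reject uniform input", {
  for (size in c(3L, 5L, 9L)) {
    rf <- makeReceptiveField(size, centerRadius = (size - 1) / 4)
    for (cst in c(1, 113, 255)) {
      expect_equal(sum(rf@centerWeights) * cst - sum(rf@surroundWeights) * cst,
                   0, tolerance = 1e-12)
    }
  }
})

test_that("dyadic weights quantize exactly and 1/9 hits the rounding bound", {
  q <- quantizeToShifts(0.5, 8L)
  expect_identical(q@numerators, 128L)
  expect_identical(q@shifts[[1]], 7L)            # 2^7 / 2^8 = 2^-1
  expect_identical(quantizedValues(q), 0.5)

  q2 <- quantizeToShifts(0.75, 8L)
  expect_identical(q2@numerators, 192L)
  expect_identical(sort(q2@shifts[[1]]), c(6L, 7L))   # 2^-2 + 2^-1
  expect_identical(quantizedValues(q2), 0.75)

  q3 <- quantizeToShifts(1 / 9, 8L)
  expect_identical(q3@numerators, 28L)           # round(256 / 9)
  expect_identical(quantizedValues(q3), 0.109375)
  expect_lte(abs(quantizedValues(q3) - 1 / 9), 2^-9)
})

test_that("quantization error stays below 2^-(f+1) for random weights", {
  set.seed(1234)
  w <- runif(10000)
  for (f in c(4L, 8L, 12L)) {
    q <- quantizeToShifts(w, f)
    expect_lte(max(abs(quantizedValues(q) - w)), 2^(-f - 1))
    # shift schedules reproduce every numerator as a sum of powers of two
    recon <- vapply(seq_along(w), function(i)
      sign(q@numerators[i]) * sum(2^q@shifts[[i]]), numeric(1))
    recon[q@numerators == 0L] <- 0
    expect_identical(as.integer(recon), q@numerators)
  }
})

test_that("a receptive field quantizes per region and for the signed kernel", {
  rf <- makeReceptiveField(3)
  qs <- quantizeToShifts(rf, 8L)
  expect_named(qs, c("center", "surround", "combined"))
  expect_length(qs$combined@weights, 3)          # one slot per radius
  expect_true(any(qs$combined@numerators < 0))   # surround side is negative
})

test_that("field configurations serialize and rebuild identically", {
  rf <- makeReceptiveField(5, centerRadius = 1.5)
  rf2 <- rfFromConfig(rfConfig(rf))
  expect_equal(rf2@centerWeights, rf@centerWeights)
  expect_equal(rf2@surroundWeights, rf@surroundWeights)
  expect_identical(rf2@style, rf@style)
})

test_that("the overlapping DoG variant spans the full grid in both regions", {
  rf <- makeReceptiveField(5, style = "overlapping", sigmaCenter = 0.8,
                           sigmaSurround = 2)
  expect_true(all(rf@centerMask) && all(rf@surroundMask))
  expect_equal(sum(rf@centerWeights), 1, tolerance = 1e-12)
  expect_equal(sum(rf@surroundWeights), 1, tolerance = 1e-12)
})
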
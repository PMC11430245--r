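# Independent oracles, deliberately written as naive double loops with
# accumulation orders different from the package's evaluation paths.

# plain weighted sum over a patch
bruteWeightedSum <- function(weights, patch) {
  acc <- 0
  for (a in seq_len(nrow(weights)))
    for (b in seq_len(ncol(weights)))
      acc <- acc + weights[a, b] * patch[a, b]
  acc
}

# valid-region convolution by explicit accumulation
bruteConvolve <- function(plane, kernel) {
  s <- nrow(kernel)
  h <- nrow(plane); w <- ncol(plane)
  out <- matrix(0, h - s + 1, w - s + 1)
  for (i in seq_len(h - s + 1))
    for (j in seq_len(w - s + 1)) {
      acc <- 0
      for (a in 1:s)
        for (b in 1:s)
          acc <- acc + plane[i + a - 1, j + b - 1] * kernel[a, b]
      out[i, j] <- acc
    }
  out
}

# depth of a balanced binary adder tree built by explicit construction
bruteTreeDepth <- function(n) {
  if (n == 1) return(0L)
  nodes <- rep(0L, n)              # leaf depths
  while (length(nodes) > 1) {
    nxt <- integer(0)
    while (length(nodes) >= 2) {
      nxt <- c(nxt, max(nodes[1], nodes[2]) + 1L)
      nodes <- nodes[-(1:2)]
    }
    nodes <- c(nxt, nodes)
  }
  nodes
}

# random size x size patch of 8-bit values
randomPatch <- function(size) {
  matrix(sample.int(256L, size * size, replace = TRUE) - 1L, size, size)
}
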
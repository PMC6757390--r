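# Integral array, breakpoint array, block iteration and the wavelet-tree
# reference generator.

test_that("integral array entries follow the per-cell layout", {
  y <- as.numeric(1:12)
  ia <- IntegralArray(y, cellSize = 4)
  # within the cell [8, 12), entry 9 sums positions 9..11
  expect_equal(ia@stats[10, ], c(n = 3, sum = sum(y[10:12]),
                                 sumsq = sum(y[10:12]^2)))
  expect_equal(ia@stats[13, ], c(n = 0, sum = 0, sumsq = 0))
  # cell size 1: entry t is exactly the statistics of y[t]
  ia1 <- IntegralArray(y, cellSize = 1)
  expect_equal(ia1@stats[seq_len(12), 2], y)
  expect_equal(ia1@stats[seq_len(12), 1], rep(1, 12))
  # entry 0 covers the whole first cell
  set.seed(21)
  z <- rnorm(10)
  iaz <- IntegralArray(z, cellSize = 4)
  expect_equal(iaz@stats[1, ], c(n = 4, sum = sum(z[1:4]),
                                 sumsq = sum(z[1:4]^2)))
})

test_that("block statistics queries combine cells as in the worked example", {
  y <- as.numeric(1:12)
  ia <- IntegralArray(y, cellSize = 4)
  v <- ia@stats
  expect_equal(queryStats(ia, 3, 10), v[4, ] + v[5, ] + v[9, ] - v[11, ])
  expect_equal(queryStats(ia, 3, 10)[["sum"]], sum(y[4:10]))
  for (t in 0:11)
    expect_equal(queryStats(ia, t, t + 1)[["sum"]], y[t + 1])
  expect_error(queryStats(ia, 5, 5), "s < e")
  expect_error(queryStats(ia, -1, 5), "s < e")
  expect_error(queryStats(ia, 0, 13), "s < e")
})

test_that("queries equal direct summation for random blocks and cell sizes", {
  set.seed(22)
  for (cs in c(1, 3, 4, 16)) {
    y <- rnorm(137)
    ia <- IntegralArray(y, cellSize = cs)
    for (rep in 1:125) {
      s <- sample(0:136, 1)
      e <- s + sample.int(137 - s, 1)
      got <- queryStats(ia, s, e)
      expect_equal(got[["n"]], e - s)
      expect_equal(got[["sum"]], sum(y[(s + 1):e]), tolerance = 1e-9)
      expect_equal(got[["sumsq"]], sum(y[(s + 1):e]^2), tolerance = 1e-9)
    }
  }
})

test_that("large-array queries stay accurate with the default cell size", {
  set.seed(23)
  T <- 1e7
  y <- rnorm(T)
  ia <- IntegralArray(y)      # c = 65536
  for (rep in 1:30) {
    len <- sample(c(1, 2, 5, 100, 10000, 1000000), 1)
    s <- sample.int(T - len, 1)
    got <- queryStats(ia, s, s + len)
    want <- sum(y[(s + 1):(s + len)])   # long-double accumulation
    want2 <- sum(y[(s + 1):(s + len)]^2)
    expect_lt(abs(got[["sum"]] - want), 1e-8 * max(1, abs(want)))
    expect_lt(abs(got[["sumsq"]] - want2), 1e-8 * max(1, want2))
  }
})

test_that("breakpoint array jumps match the by-definition stretches", {
  w <- structure(c(Inf, 1, 3, 2), role = "boundary")
  expect_equal(BreakpointArray(w, maxJump = 10)@jumps, c(4L, 1L, 2L, 1L))
  expect_equal(BreakpointArray(w, maxJump = 1)@jumps, rep(1L, 4))
  dec <- structure(c(Inf, 9, 8, 7, 6, 5), role = "boundary")
  expect_equal(BreakpointArray(dec, maxJump = 100)@jumps, 6:1)
  set.seed(24)
  for (rep in 1:50) {
    T <- sample.int(120, 1) + 1
    w <- c(Inf, runif(T - 1))
    m <- sample(c(1, 2, 7, 200), 1)
    bpa <- BreakpointArray(structure(w, role = "boundary"), maxJump = m)
    expect_equal(as.numeric(bpa@jumps), bruteJumps(w, m))
    # validity: all weights inside a stretch are strictly below its head
    for (t in seq_len(T)) {
      j <- bpa@jumps[t]
      if (j > 1) expect_true(all(w[t] > w[(t + 1):(t + j - 1)]))
    }
  }
})

test_that("pointer chasing finds the same boundary as a linear scan", {
  set.seed(25)
  for (rep in 1:50) {
    T <- sample.int(150, 1) + 1L
    w <- c(Inf, runif(T - 1L))
    bpa <- BreakpointArray(structure(w, role = "boundary"),
                           maxJump = sample(c(3, 64, 200), 1))
    for (k in 1:10) {
      from <- sample(0:T, 1)
      lambda <- runif(1)
      expect_identical(nextBreakpoint(bpa, from, lambda),
                       scanNextBoundary(w, from, lambda))
    }
    expect_identical(nextBreakpoint(bpa, 1L, 0), 1L)  # lambda = 0: everywhere
    expect_identical(nextBreakpoint(bpa, 1L, 2), T)   # above all finite weights
  }
})

test_that("the two-spike configuration yields 5 compressive blocks", {
  y <- fig2Signal()
  bpa <- BreakpointArray(breakpointWeights(y))
  ia <- IntegralArray(y)
  blocks <- iterBlocks(bpa, ia, lambda = 1)
  expect_equal(nrow(blocks), 5L)
  expect_equal(blocks$start, c(0L, 1L, 2L, 14L, 15L))
  expect_equal(blocks$end, c(1L, 2L, 14L, 15L, 16L))
})

test_that("block boundaries equal the thresholded weight set", {
  set.seed(26)
  for (rep in 1:25) {
    y <- rnorm(sample.int(200, 1) + 1)
    w <- breakpointWeights(y)
    bpa <- BreakpointArray(w)
    ia <- IntegralArray(y, cellSize = 8)
    for (k in 1:2) {
      lambda <- runif(1, 0, 3)
      blocks <- iterBlocks(bpa, ia, lambda)
      expect_equal(blocks$start, which(w >= lambda) - 1L)
      expect_equal(blocks$end, c(blocks$start[-1], length(y)))
      expect_equal(blocks$n, blocks$end - blocks$start)
    }
    blocks0 <- iterBlocks(bpa, ia, 0)
    expect_equal(nrow(blocks0), length(y))       # singletons at lambda = 0
  }
})

test_that("a block generator reaches exactly 2T - 1 distinct blocks", {
  set.seed(27)
  T <- 64L
  for (rep in 1:5) {
    w <- c(Inf, runif(T - 1L))                  # unique finite entries
    y <- rnorm(T)
    bpa <- BreakpointArray(structure(w, role = "boundary"))
    ia <- IntegralArray(y, cellSize = 16)
    seen <- character(0)
    for (lambda in c(2, sort(unique(w[is.finite(w)]), decreasing = TRUE))) {
      b <- iterBlocks(bpa, ia, lambda)
      seen <- union(seen, paste(b$start, b$end))
    }
    expect_length(seen, 2L * T - 1L)
  }
})

test_that("expected deque size at the end of construction is about ln T", {
  # the construction deque holds the running right-to-left maxima, so its
  # expected size after the last push is the harmonic number H_T for
  # randomly ordered distinct weights (and the expected size is largest
  # there); the maximum over the pass is recorded too but exceeds H_T
  set.seed(28)
  T <- 10000L
  fin <- replicate(200, {
    w <- sample(runif(T))
    BreakpointArray(w, maxJump = 65536L)@finalQueueLength
  })
  H <- sum(1 / seq_len(T))
  se <- sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - H), 3 * se)
})

test_that("wavelet-tree generator reproduces the 8-block reference structure", {
  y <- fig2Signal()
  wt <- waveletTreeBlocks(y, lambda = 1)
  expect_equal(nrow(wt), 8L)
  # compressive boundaries plus the subtree-pruning boundaries
  expect_equal(wt$start, sort(union(c(0, 1, 2, 14, 15), c(2, 4, 8, 12, 14))))
  expect_equal(wt$n, wt$end - wt$start)
})

test_that("wavelet tree degenerates to singletons below all coefficients", {
  set.seed(29)
  y <- rnorm(32)
  wt <- waveletTreeBlocks(y, lambda = 0)
  expect_equal(nrow(wt), 32L)
  expect_equal(wt$sum, y, tolerance = 1e-12)
})

test_that("breakpoint-array boundaries are a subset of wavelet-tree boundaries", {
  set.seed(30)
  for (rep in 1:200) {
    y <- rnorm(sample.int(130, 1) + 1)
    lambda <- runif(1, 0, 3)
    bpa <- BreakpointArray(breakpointWeights(y))
    ia <- IntegralArray(y, cellSize = 32)
    comp <- iterBlocks(bpa, ia, lambda)$start
    tree <- waveletTreeBlocks(y, lambda)$start
    expect_true(all(comp %in% tree))
  }
})
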
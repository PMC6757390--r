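# Gaussian block likelihoods, compressed forward-backward sampling, conjugate
# parameter updates and the full Gibbs loop.

test_that("block log-likelihood equals the summed per-position density", {
  expect_equal(blockLogLik(c(n = 1, sum = 2, sumsq = 4), mu = 2, sigma2 = 1),
               -0.5 * log(2 * pi))
  expect_equal(blockLogLik(c(n = 2, sum = 0, sumsq = 2), mu = 0, sigma2 = 1),
               -log(2 * pi) - 1)
  set.seed(41)
  for (rep in 1:50) {
    yb <- rnorm(sample.int(30, 1), sd = 3)
    mu <- runif(1, -2, 2); s2 <- runif(1, 0.1, 4)
    st <- c(n = length(yb), sum = sum(yb), sumsq = sum(yb^2))
    expect_equal(blockLogLik(st, mu, s2),
                 sum(dnorm(yb, mu, sqrt(s2), log = TRUE)), tolerance = 1e-9)
  }
  expect_error(blockLogLik(c(n = 1, sum = 0, sumsq = 0), 0, 0), "positive")
})

test_that("forward variables at singleton blocks equal the dense recursion", {
  set.seed(42)
  for (rep in 1:20) {
    T <- sample.int(64, 1)
    y <- rnorm(T, sd = 2)
    S <- sample(2:4, 1)
    model <- randomModel(S)
    blocks <- iterBlocks(BreakpointArray(breakpointWeights(y)),
                         IntegralArray(y, cellSize = 16), lambda = 0)
    expect_equal(nrow(blocks), T)
    expect_equal(forwardVariables(blocks, model), denseForward(y, model),
                 tolerance = 1e-10)
  }
})

test_that("single-state sampling assigns state 1 everywhere", {
  y <- rnorm(50)
  model <- new("HMMModel", mu = 0, sigma2 = 1, A = matrix(1, 1, 1), pi = 1)
  blocks <- iterBlocks(BreakpointArray(breakpointWeights(y)),
                       IntegralArray(y), lambda = 0.5)
  runs <- forwardBackwardSample(blocks, model)
  expect_true(all(runs$state == 1L))
  expect_equal(sum(runs$length), 50L)
})

test_that("near-deterministic two-block posteriors are sampled as the MAP path", {
  # two far-separated blocks, near-diagonal transitions: the exact posterior
  # over the 4 assignments puts essentially all mass on (1, 2)
  model <- new("HMMModel", mu = c(-5, 5), sigma2 = c(0.25, 0.25),
               A = matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE),
               pi = c(0.5, 0.5))
  y <- c(rep(-5, 8), rep(5, 8))
  blocks <- iterBlocks(BreakpointArray(breakpointWeights(y)),
                       IntegralArray(y), lambda = 1)
  expect_equal(nrow(blocks), 2L)
  # exact enumeration of the four assignments
  lp <- sapply(list(c(1, 1), c(1, 2), c(2, 1), c(2, 2)), function(q) {
    blockLogLik(unlist(blocks[1, 3:5]), model@mu[q[1]], 0.25) +
      blockLogLik(unlist(blocks[2, 3:5]), model@mu[q[2]], 0.25) +
      log(model@pi[q[1]]) + 7 * log(model@A[q[1], q[1]]) +
      log(model@A[q[1], q[2]]) + 7 * log(model@A[q[2], q[2]])
  })
  expect_equal(which.max(lp), 2L)
  set.seed(43)
  hits <- sum(replicate(1000, {
    r <- forwardBackwardSample(blocks, model)
    identical(r$state, c(1L, 2L))
  }))
  expect_gte(hits, 999)
})

test_that("transition counting matches hand counts and conserves totals", {
  cnt <- countTransitions(data.frame(length = c(5, 3), state = c(1, 2)), S = 2)
  expect_equal(cnt$trans, matrix(c(4L, 1L, 0L, 2L), 2, byrow = TRUE))
  expect_equal(cnt$init, c(1L, 0L))
  set.seed(44)
  for (rep in 1:25) {
    S <- sample(2:6, 1)
    runs <- randomRuns(sample(50:300, 1), S)
    runs$state <- runs$state + 1L
    cnt <- countTransitions(runs, S)
    expect_equal(sum(cnt$trans), sum(runs$length) - 1L)
    expect_equal(sum(cnt$init), 1L)
  }
})

test_that("emission sampling concentrates on the conjugate posterior", {
  prior <- new("HMMPrior", mu0 = c(0, 0), nu = c(1, 1), alpha = c(1, 1),
               beta = c(1, 1), transConc = matrix(1, 2, 2), initConc = c(1, 1))
  set.seed(45)
  n <- 1e6
  stats <- rbind(c(n, 3 * n, n * (9 + 0.01)),   # mean 3, sd 0.1
                 c(0, 0, 0))
  em <- sampleEmissions(stats, prior)
  expect_lt(abs(em$mu[1] - 3), 0.01)
  expect_lt(abs(em$sigma2[1] - 0.01), 0.001)
  # empty state draws from the prior, which has infinite-variance tails but
  # a well-defined scale
  expect_true(em$sigma2[2] > 0)
  # prior dominance: huge nu pins the mean at mu0
  priorBig <- new("HMMPrior", mu0 = c(7, 7), nu = c(1e9, 1e9),
                  alpha = c(2, 2), beta = c(1, 1),
                  transConc = matrix(1, 2, 2), initConc = c(1, 1))
  em2 <- sampleEmissions(rbind(c(10, 0, 10), c(0, 0, 0)), priorBig)
  expect_lt(abs(em2$mu[1] - 7), 0.01)
})

test_that("transition sampling follows the Dirichlet posterior", {
  prior <- new("HMMPrior", mu0 = c(0, 0), nu = c(1, 1), alpha = c(1, 1),
               beta = c(1, 1), transConc = matrix(1, 2, 2), initConc = c(1, 1))
  set.seed(46)
  tm <- sampleTransitions(list(trans = matrix(c(1e6, 0, 0, 1e6), 2),
                               init = c(1L, 0L)), prior)
  expect_gt(tm$A[1, 1], 0.999)
  expect_gt(tm$A[2, 2], 0.999)
  expect_equal(rowSums(tm$A), c(1, 1), tolerance = 1e-12)
  expect_equal(sum(tm$pi), 1, tolerance = 1e-12)
})

test_that("compression threshold uses the smallest emission variance", {
  m <- new("HMMModel", mu = c(0, 1), sigma2 = c(4, 1),
           A = matrix(0.5, 2, 2), pi = c(0.5, 0.5))
  expect_equal(compressionThreshold(m, 1000), sqrt(2 * log(1000)),
               tolerance = 1e-12)
  expect_equal(compressionThreshold(m, 1), 0)
  m2 <- new("HMMModel", mu = c(0, 1, 2), sigma2 = c(4, 1, 25),
            A = matrix(1 / 3, 3, 3), pi = rep(1 / 3, 3))
  expect_equal(compressionThreshold(m2, 1000), compressionThreshold(m, 1000))
})

test_that("automatic priors: quantile means and MAD noise estimate", {
  set.seed(47)
  y <- rnorm(100)
  expect_equal(autoHyperparams(y, 1)@mu0, median(y))
  yn <- rnorm(1e5)
  pr <- autoHyperparams(yn, 3)
  expect_lt(abs(sqrt(pr@beta[1]) - 1), 0.1)      # MAD estimate near sigma = 1
  ym <- c(rnorm(3000, -2, 0.05), rnorm(3000, 0, 0.05), rnorm(3000, 2, 0.05))
  pr3 <- autoHyperparams(ym, 3)
  expect_lt(abs(pr3@mu0[1] - -2), 0.15)
  expect_lt(abs(pr3@mu0[3] - 2), 0.15)
  expect_lt(abs(pr3@mu0[2]), 0.15)
  # constant signal falls back to the variance floor
  expect_equal(autoHyperparams(rep(1, 10), 1)@beta, 1e-8)
})

test_that("single-state Gibbs runs put all marginal mass on state 0", {
  set.seed(48)
  fit <- runFBG(rnorm(300), nStates = 1, iterations = 10, burnIn = 5, seed = 2)
  expect_equal(fit@records@R, 10L)
  mt <- marginalsTable(fit)
  expect_true(all(mt$state0 == 10))
  expect_true(all(modalStates(fit@records) == 0L))
})

test_that("the Gibbs sampler recovers a planted segmentation", {
  sim <- genPiecewise(2000, 5, c(-2, 0, 2), 0.3, seed = 11)
  fit <- runFBG(sim$signal, nStates = 3, iterations = 60, burnIn = 60,
                seed = 5)
  modal <- modalStates(fit@records)
  truthMean <- rep(sim$truth$mean, sim$truth$end - sim$truth$start)
  predMean <- fit@postMu[modal + 1L]
  # occupied state means sit near the true levels
  for (s in unique(modal)) {
    lev <- as.numeric(names(sort(table(truthMean[modal == s]),
                                 decreasing = TRUE))[1])
    expect_lt(abs(fit@postMu[s + 1L] - lev), 0.1)
  }
  expect_gt(binaryF1(abs(truthMean) >= 1, abs(predMean) >= 1), 0.95)
})

test_that("lambda trace equals the threshold from the previous sweep's variance", {
  set.seed(49)
  sim <- genPiecewise(500, 3, c(-2, 0, 2), 0.3, seed = 13)
  fit <- runFBG(sim$signal, nStates = 3, iterations = 20, burnIn = 10,
                seed = 3)
  tr <- fit@trace
  T <- 500
  expect_equal(tr$lambda[-1],
               sqrt(2 * log(T)) * sqrt(head(tr$minVariance, -1)),
               tolerance = 1e-12)
  # same weights: a lower threshold can only add boundaries
  ord <- order(tr$lambda)
  expect_true(all(diff(tr$nBlocks[ord]) <= 0))
})

test_that("runs are reproducible from the seed", {
  sim <- genPiecewise(400, 3, c(-2, 0, 2), 0.3, seed = 17)
  f1 <- runFBG(sim$signal, nStates = 3, iterations = 15, burnIn = 10, seed = 9)
  f2 <- runFBG(sim$signal, nStates = 3, iterations = 15, burnIn = 10, seed = 9)
  expect_identical(f1@trace, f2@trace)
  expect_identical(f1@postMu, f2@postMu)
  expect_identical(marginalsTable(f1), marginalsTable(f2))
})
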
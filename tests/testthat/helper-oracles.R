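# Independent oracles used across the suite. All deliberately use direct
# definitions (explicit summation, linear scans, dense matrices) rather than
# the package's compressed paths.

# boundary weights by direct evaluation of the max-over-discontinuities rule,
# from brute-force inner products
oracleBoundaryWeights <- function(y) {
  T <- length(y)
  out <- rep(-Inf, T)
  out[1L] <- Inf
  co <- oracleWaveletCoefficients(y)
  if (nrow(co)) {
    for (i in seq_len(nrow(co))) {
      for (pos in c(co$bPlus[i], co$bCenter[i], co$bMinus[i])) {
        if (pos > 0 && pos < T)
          out[pos + 1L] <- max(out[pos + 1L], abs(co$d[i]))
      }
    }
  }
  # centres of wavelets with incomplete support are Inf
  j <- 1L
  while (2^(j - 1L) < T) {
    half <- 2^(j - 1L)
    bc <- seq(half, T - 1L, by = 2L * half)
    bm <- bc + half
    out[bc[bm > T] + 1L] <- Inf
    j <- j + 1L
  }
  out
}

# smallest t >= from with w[t] >= lambda, by linear scan
scanNextBoundary <- function(w, from, lambda) {
  T <- length(w)
  t <- as.integer(from)
  while (t < T && w[t + 1L] < lambda) t <- t + 1L
  t
}

# maximal capped jump distances by definition (quadratic scan)
bruteJumps <- function(w, m) {
  T <- length(w)
  vapply(seq_len(T), function(t) {
    nxt <- T + 1L
    if (t < T) {
      hit <- which(w[(t + 1L):T] >= w[t])
      if (length(hit)) nxt <- t + hit[1L]
    }
    min(nxt - t, m, T + 1L - t)
  }, numeric(1))
}

# textbook per-position scaled forward recursion (dense, uncompressed)
denseForward <- function(y, model) {
  S <- length(model@mu)
  T <- length(y)
  alpha <- matrix(0, T, S)
  e <- function(t) stats::dnorm(y[t], model@mu, sqrt(model@sigma2))
  a <- model@pi * e(1L)
  alpha[1L, ] <- a / sum(a)
  if (T > 1L) for (t in 2:T) {
    a <- as.vector(alpha[t - 1L, ] %*% model@A) * e(t)
    alpha[t, ] <- a / sum(a)
  }
  alpha
}

# dense T x S count matrix accumulated run by run
denseCountUpdate <- function(mat, runs) {
  pos <- 1L
  for (i in seq_len(nrow(runs))) {
    idx <- pos:(pos + runs$length[i] - 1L)
    mat[idx, runs$state[i] + 1L] <- mat[idx, runs$state[i] + 1L] + 1L
    pos <- pos + runs$length[i]
  }
  mat
}

# random run-length partition of T positions over 0-based states < S
randomRuns <- function(T, S) {
  nb <- sample.int(min(8L, T), 1L)
  bnd <- if (nb > 1L) sort(sample.int(T - 1L, nb - 1L)) else integer(0)
  len <- diff(c(0L, bnd, T))
  data.frame(length = len, state = sample.int(S, length(len), replace = TRUE) - 1L)
}

# binary F-measure of CNV detection: positives are positions with
# |segment mean| >= 1
binaryF1 <- function(truthPos, predPos) {
  tp <- sum(truthPos & predPos)
  if (tp == 0) return(0)
  prec <- tp / sum(predPos)
  rec <- tp / sum(truthPos)
  2 * prec * rec / (prec + rec)
}

# T = 16 configuration in which only the level-1 wavelets at the two ends
# carry signal: |d_{1,0}| = |d_{1,7}| = sqrt(2), every other coefficient 0
fig2Signal <- function() c(1, -1, rep(0, 12), 1, -1)

randomModel <- function(S, muSpread = 3) {
  A <- matrix(stats::rgamma(S * S, 1), S, S)
  A <- A / rowSums(A)
  p <- stats::rgamma(S, 1)
  new("HMMModel", mu = stats::runif(S, -muSpread, muSpread),
      sigma2 = stats::runif(S, 0.2, 2), A = A, pi = p / sum(p))
}
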
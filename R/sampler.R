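# Forward-Backward Gibbs sampling of a Gaussian-emission HMM over compressed
# blocks. Within a block of n positions assigned to state s the emission term
# is the product Gaussian likelihood from the sufficient statistics and the
# n-1 self-transitions contribute A[s,s]^(n-1).

#' Gaussian block log-likelihood from sufficient statistics
#'
#' \eqn{-\frac{n}{2}\ln(2\pi\sigma^2) -
#'   \frac{\mathrm{sumsq} - 2\mu\,\mathrm{sum} + n\mu^2}{2\sigma^2}}, the
#' exact joint log-density of the `n` block values under i.i.d.
#' \eqn{N(\mu, \sigma^2)}.
#'
#' @param stats named numeric `c(n, sum, sumsq)` (from [queryStats()]),
#'   `n >= 1`.
#' @param mu,sigma2 emission mean and variance (`sigma2 > 0`).
#' @return scalar log-likelihood.
#' @export
blockLogLik <- function(stats, mu, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  n <- stats[["n"]]
  if (n < 1) stop("block must contain at least one position", call. = FALSE)
  -(n / 2) * log(2 * pi * sigma2) -
    (stats[["sumsq"]] - 2 * mu * stats[["sum"]] + n * mu^2) / (2 * sigma2)
}

# B x S matrix of block log "emission" terms including the within-block
# self-transition factor A[s,s]^(n-1)
.blockLogEmissions <- function(blocks, model) {
  S <- length(model@mu)
  B <- nrow(blocks)
  n <- blocks$n; sm <- blocks$sum; sq <- blocks$sumsq
  le <- matrix(0, B, S)
  for (s in seq_len(S)) {
    mu <- model@mu[s]; s2 <- model@sigma2[s]
    le[, s] <- -(n / 2) * log(2 * pi * s2) -
      (sq - 2 * mu * sm + n * mu^2) / (2 * s2) +
      (n - 1) * log(model@A[s, s])
  }
  le
}

#' Normalized forward variables over compressed blocks
#'
#' Forward filtering with per-block rescaling:
#' \eqn{\alpha_1(s) \propto \pi_s A_{ss}^{n_1 - 1} e_s(1)} and
#' \eqn{\alpha_k(s) \propto e_s(k) A_{ss}^{n_k - 1}
#'   \sum_{s'} \alpha_{k-1}(s') A_{s's}}, each row normalized to sum 1.
#' With singleton blocks this is exactly the textbook per-position forward
#' recursion.
#'
#' @param blocks block `data.frame` from [iterBlocks()].
#' @param model an [HMMModel-class].
#' @return numeric `nrow(blocks)` x S matrix of normalized forward variables.
#' @export
forwardVariables <- function(blocks, model) {
  S <- length(model@mu)
  B <- nrow(blocks)
  if (B < 1L) stop("empty block sequence", call. = FALSE)
  le <- .blockLogEmissions(blocks, model)
  A <- model@A
  alpha <- matrix(0, B, S)
  a <- model@pi * exp(le[1L, ] - max(le[1L, ]))
  z <- sum(a)
  if (z <= 0 || !is.finite(z))
    stop("forward recursion underflow at block 1 (lambda too small ",
         "or degenerate parameters)", call. = FALSE)
  alpha[1L, ] <- a / z
  if (B > 1L) for (k in 2:B) {
    a <- as.vector(alpha[k - 1L, ] %*% A) * exp(le[k, ] - max(le[k, ]))
    z <- sum(a)
    if (z <= 0 || !is.finite(z))
      stop("forward recursion underflow at block ", k, call. = FALSE)
    alpha[k, ] <- a / z
  }
  alpha
}

#' Sample a state path over compressed blocks
#'
#' Forward filtering over the block sequence with per-block rescaling,
#' followed by backward sampling of one state per block. The forward variables
#' coincide with the textbook per-position recursion when every block is a
#' singleton, so compression at threshold 0 is exact.
#'
#' @param blocks block `data.frame` from [iterBlocks()].
#' @param model an [HMMModel-class].
#' @return `data.frame` with columns `length` (block sizes, summing to `T`)
#'   and `state` (1-based sampled state per block).
#' @export
forwardBackwardSample <- function(blocks, model) {
  S <- length(model@mu)
  B <- nrow(blocks)
  alpha <- forwardVariables(blocks, model)
  A <- model@A
  q <- integer(B)
  q[B] <- sample.int(S, 1L, prob = alpha[B, ])
  if (B > 1L) for (k in (B - 1L):1L) {
    p <- alpha[k, ] * A[, q[k + 1L]]
    q[k] <- sample.int(S, 1L, prob = p)
  }
  data.frame(length = as.integer(round(blocks$n)), state = q)
}

#' Transition and initial-state counts of a sampled path
#'
#' Each run of `length` positions in one state contributes `length - 1`
#' self-transitions; consecutive runs contribute one between-run transition;
#' the first run contributes the single initial-state count. Totals are
#' therefore `T - 1` transitions and 1 initial count.
#'
#' @param runs `data.frame` with `length` and 1-based `state` columns.
#' @param S number of states.
#' @return list with `trans` (S x S integer matrix) and `init` (length-S).
#' @export
countTransitions <- function(runs, S) {
  st <- runs$state
  len <- runs$length
  trans <- matrix(0L, S, S)
  selfc <- vapply(seq_len(S),
                  function(s) sum(len[st == s]) - sum(st == s), numeric(1))
  diag(trans) <- as.integer(selfc)
  if (nrow(runs) > 1L) {
    from <- st[-length(st)]; to <- st[-1L]
    tab <- tabulate((from - 1L) * S + to, nbins = S * S)
    trans <- trans + matrix(tab, S, S, byrow = TRUE)
  }
  init <- integer(S)
  init[st[1L]] <- 1L
  list(trans = trans, init = init)
}

#' Sample emission parameters from the conjugate posterior
#'
#' Per state with aggregated statistics `(n, sum, sumsq)`, the
#' normal-inverse-gamma posterior is
#' \eqn{\nu' = \nu + n}, \eqn{\mu_0' = (\nu\mu_0 + \mathrm{sum})/\nu'},
#' \eqn{\alpha' = \alpha + n/2},
#' \eqn{\beta' = \beta + \frac12(\mathrm{sumsq} - \mathrm{sum}^2/n) +
#'   \frac{\nu n (\mathrm{sum}/n - \mu_0)^2}{2\nu'}};
#' \eqn{\sigma^2 \sim} inverse-gamma\eqn{(\alpha', \beta')} then
#' \eqn{\mu \sim N(\mu_0', \sigma^2/\nu')}. States with no assigned data draw
#' from the prior. Draws are consumed state by state, variance before mean.
#'
#' @param statsByState numeric S x 3 matrix (columns `n`, `sum`, `sumsq`).
#' @param prior an [HMMPrior-class].
#' @return list with numeric vectors `mu` and `sigma2`.
#' @export
sampleEmissions <- function(statsByState, prior) {
  S <- length(prior@mu0)
  mu <- numeric(S); sigma2 <- numeric(S)
  for (s in seq_len(S)) {
    n <- statsByState[s, 1L]
    nu1 <- prior@nu[s] + n
    a1 <- prior@alpha[s] + n / 2
    if (n > 0) {
      sm <- statsByState[s, 2L]; sq <- statsByState[s, 3L]
      ybar <- sm / n
      ss <- max(sq - sm^2 / n, 0)
      m1 <- (prior@nu[s] * prior@mu0[s] + sm) / nu1
      b1 <- prior@beta[s] + ss / 2 +
        prior@nu[s] * n * (ybar - prior@mu0[s])^2 / (2 * nu1)
    } else {
      m1 <- prior@mu0[s]
      b1 <- prior@beta[s]
    }
    sigma2[s] <- 1 / stats::rgamma(1L, shape = a1, rate = b1)
    mu[s] <- stats::rnorm(1L, m1, sqrt(sigma2[s] / nu1))
  }
  list(mu = mu, sigma2 = sigma2)
}

#' Sample transition matrix and initial distribution
#'
#' Each transition row is drawn from
#' Dirichlet(concentration + observed row counts) via normalized gamma
#' variates; likewise the initial distribution. Rows are drawn in state
#' order, then the initial distribution.
#'
#' @param counts list with `trans` and `init` as from [countTransitions()].
#' @param prior an [HMMPrior-class].
#' @return list with `A` (row-stochastic matrix) and `pi`.
#' @export
sampleTransitions <- function(counts, prior) {
  S <- length(prior@initConc)
  A <- matrix(0, S, S)
  for (s in seq_len(S)) {
    g <- stats::rgamma(S, shape = prior@transConc[s, ] + counts$trans[s, ])
    A[s, ] <- g / sum(g)
  }
  g <- stats::rgamma(S, shape = prior@initConc + counts$init)
  list(A = A, pi = g / sum(g))
}

#' Compression threshold from sampled emission parameters
#'
#' The universal threshold computed with the *smallest* sampled emission
#' variance: the most precise state dictates how fine the block structure must
#' be for the regression not to mask real transitions into it.
#'
#' @param model an [HMMModel-class] (or list with element `sigma2`).
#' @param T signal length.
#' @return threshold \eqn{\sqrt{2\ln T}\,\min_s \sigma_s}.
#' @export
compressionThreshold <- function(model, T) {
  s2 <- if (is(model, "HMMModel")) model@sigma2 else model$sigma2
  universalThreshold(T, min(s2))
}

# robust noise variance from successive differences: differences of a
# piecewise-constant signal are pure noise almost everywhere, with variance
# 2 sigma^2; 0.6745 is the normal-consistency constant of the MAD
.madNoiseVariance <- function(y) {
  if (length(y) < 2L) return(1e-8)
  s <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  max(s^2, 1e-8)
}

#' Data-driven prior for the Gaussian HMM
#'
#' Deterministic heuristic: prior state means sit at `S` evenly spaced
#' quantiles of the data between the 0.5th and 99.5th percentiles (the
#' median for `S = 1`), so states are anchored to distinct signal levels;
#' `nu = alpha = 1`; `beta` equals a noise-variance estimate from the median
#' absolute successive difference (robust against the jumps themselves);
#' all Dirichlet concentrations are 1.
#'
#' @param y numeric signal, `length(y) >= S`.
#' @param S number of states.
#' @return an [HMMPrior-class].
#' @export
autoHyperparams <- function(y, S) {
  y <- .checkSignal(y)
  S <- as.integer(S)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  if (length(y) < S) stop("need at least S data points", call. = FALSE)
  probs <- if (S == 1L) 0.5 else seq(0.005, 0.995, length.out = S)
  mu0 <- as.numeric(stats::quantile(y, probs, names = FALSE, type = 7))
  v <- .madNoiseVariance(y)
  new("HMMPrior", mu0 = mu0, nu = rep(1, S), alpha = rep(1, S),
      beta = rep(v, S), transConc = matrix(1, S, S), initConc = rep(1, S))
}

#' Dynamically compressed Forward-Backward Gibbs sampler
#'
#' Builds the Haar breakpoint array and the integral array once, then
#' alternates: (1) regenerate the block sequence at the current compression
#' threshold, (2) sample a state path over the blocks, (3) sample emission and
#' transition parameters from the assignment, (4) set the next threshold to
#' the universal threshold at the smallest sampled emission variance,
#' (5) after burn-in, fold the sampled path into the run-length compressed
#' marginal counts. The first sweep's threshold is bootstrapped from a MAD
#' noise estimate. Fully reproducible given `seed`.
#'
#' @param y numeric signal (e.g. window-averaged differential read depth).
#' @param nStates number of copy-number states (default 8).
#' @param iterations recorded sweeps after burn-in (default 200).
#' @param burnIn discarded initial sweeps (default 1800).
#' @param seed optional integer seed.
#' @param cellSize integral-array cell width.
#' @param maxJump breakpoint-array jump cap.
#' @param recordBurnIn record marginals during burn-in too (default `FALSE`).
#' @param verbose log per-sweep progress (iteration, blocks, lambda) to
#'   standard error every 100 sweeps.
#' @return a [HaarFBGFit-class].
#' @examples
#' sim <- genPiecewise(400, 4, c(-2, 0, 2), 0.3, seed = 1)
#' fit <- runFBG(sim$signal, nStates = 3, iterations = 40, burnIn = 40,
#'               seed = 1)
#' head(callSegments(fit))
#' @export
runFBG <- function(y, nStates = 8L, iterations = 200L, burnIn = 1800L,
                   seed = NULL, cellSize = 65536L, maxJump = 65536L,
                   recordBurnIn = FALSE, verbose = FALSE) {
  y <- .checkSignal(y)
  T <- length(y)
  nStates <- as.integer(nStates)
  iterations <- as.integer(iterations)
  burnIn <- as.integer(burnIn)
  if (nStates < 1L || iterations < 1L || burnIn < 0L)
    stop("need nStates >= 1, iterations >= 1, burnIn >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  bpa <- BreakpointArray(breakpointWeights(y), maxJump = maxJump)
  ia <- IntegralArray(y, cellSize = cellSize)
  prior <- autoHyperparams(y, nStates)
  v0 <- .madNoiseVariance(y)
  model <- new("HMMModel", mu = prior@mu0, sigma2 = rep(v0, nStates),
               A = matrix(1 / nStates, nStates, nStates),
               pi = rep(1 / nStates, nStates))
  lambda <- universalThreshold(T, v0)

  nSweeps <- burnIn + iterations
  records <- MarginalRecords(T)
  muTrace <- matrix(NA_real_, nSweeps, nStates)
  s2Trace <- matrix(NA_real_, nSweeps, nStates)
  trLambda <- numeric(nSweeps)
  trBlocks <- integer(nSweeps)
  trMinVar <- numeric(nSweeps)
  recorded <- logical(nSweeps)

  for (it in seq_len(nSweeps)) {
    blocks <- iterBlocks(bpa, ia, lambda)
    runs <- forwardBackwardSample(blocks, model)
    occ <- rowsum(as.matrix(blocks[, c("n", "sum", "sumsq")]),
                  group = runs$state)
    agg <- matrix(0, nStates, 3L)
    agg[as.integer(rownames(occ)), ] <- occ
    em <- sampleEmissions(agg, prior)
    tm <- sampleTransitions(countTransitions(runs, nStates), prior)
    model <- new("HMMModel", mu = em$mu, sigma2 = em$sigma2,
                 A = tm$A, pi = tm$pi)
    trLambda[it] <- lambda
    trBlocks[it] <- nrow(blocks)
    trMinVar[it] <- min(em$sigma2)
    muTrace[it, ] <- em$mu
    s2Trace[it, ] <- em$sigma2
    lambda <- compressionThreshold(model, T)
    rec <- it > burnIn || recordBurnIn
    recorded[it] <- rec
    if (rec) {
      runs0 <- data.frame(length = runs$length, state = runs$state - 1L)
      records <- addRunLengths(records, runs0)
    }
    if (verbose && it %% 100L == 0L)
      message(sprintf("sweep %d/%d: %d blocks, lambda = %.4g",
                      it, nSweeps, nrow(blocks), trLambda[it]))
  }

  postMu <- colMeans(muTrace[recorded, , drop = FALSE])
  new("HaarFBGFit", records = records,
      trace = data.frame(iteration = seq_len(nSweeps), lambda = trLambda,
                         nBlocks = trBlocks, minVariance = trMinVar,
                         recorded = recorded),
      muTrace = muTrace, sigma2Trace = s2Trace, model = model,
      postMu = postMu, prior = prior,
      config = list(nStates = nStates, iterations = iterations,
                    burnIn = burnIn, seed = seed, cellSize = cellSize,
                    maxJump = maxJump, recordBurnIn = recordBurnIn))
}
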
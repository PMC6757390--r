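#' @import methods
NULL

#' Cell-partitioned integral array of sufficient statistics
#'
#' Stores, for every data position, partial cumulative sums of the Gaussian
#' sufficient statistics \eqn{T(y) = (1, y, y^2)}. Positions are grouped into
#' non-overlapping cells of `cellSize` positions and sums run from high to low
#' indices within each cell, so any block query touches only numbers of
#' bounded magnitude: floating-point cancellation does not grow with the
#' distance from the origin as it would for one global cumulative sum. A zero
#' sentinel row at index `T` lets queries ending at `T` proceed without a
#' special case.
#'
#' @slot stats numeric matrix with `T + 1` rows and columns `n`, `sum`,
#'   `sumsq`; row `t + 1` holds \eqn{\sum_{i=t}^{c_{end}-1} T(y[i])} where
#'   `c_end` is the end of the cell containing `t` (capped at `T`).
#' @slot cellSize integer cell width `c`.
#' @slot T integer number of data positions.
#' @seealso [IntegralArray()], [queryStats()]
#' @export
setClass("IntegralArray",
         representation(stats = "matrix", cellSize = "integer", T = "integer"),
         validity = function(object) {
           if (object@cellSize < 1L) return("cellSize must be >= 1")
           if (nrow(object@stats) != object@T + 1L)
             return("stats must have T + 1 rows (zero sentinel at index T)")
           if (!identical(colnames(object@stats), c("n", "sum", "sumsq")))
             return("stats columns must be n, sum, sumsq")
           if (any(object@stats[object@T + 1L, ] != 0))
             return("sentinel row must be zero")
           TRUE
         })

#' Breakpoint array
#'
#' Boundary weights plus capped jump distances: `jumps[t]` is the length of
#' the *stretch* at `t`, the maximal run (capped at `maxJump`) in which every
#' later weight is strictly below `weights[t]`. Threshold queries follow these
#' jumps, skipping whole stretches whose head is already below the threshold,
#' which takes expected logarithmic time per block for randomly ordered
#' weights.
#'
#' @slot weights numeric boundary weights (entry 0 is `Inf`).
#' @slot jumps integer stretch lengths, all in `[1, maxJump]`.
#' @slot maxJump integer cap `m` on the jump distance.
#' @slot maxQueueLength,finalQueueLength integer: the largest and the final
#'   number of pending indices held by the construction deque (the final
#'   length estimates the expected queue size at the cursor position where it
#'   is largest; see the methods vignette).
#' @seealso [BreakpointArray()], [nextBreakpoint()], [iterBlocks()]
#' @export
setClass("BreakpointArray",
         representation(weights = "numeric", jumps = "integer",
                        maxJump = "integer", maxQueueLength = "integer",
                        finalQueueLength = "integer"),
         validity = function(object) {
           if (length(object@weights) != length(object@jumps))
             return("weights and jumps must have equal length")
           if (object@maxJump < 1L) return("maxJump must be >= 1")
           if (length(object@jumps) &&
               (min(object@jumps) < 1L || max(object@jumps) > object@maxJump))
             return("jumps must lie in [1, maxJump]")
           TRUE
         })

#' Run-length compressed marginal state counts
#'
#' Tallies how often each HMM state was sampled at each data position across
#' recorded Gibbs iterations. Positions are grouped into segments (runs that
#' have always been assigned as one piece so far); each segment stores one
#' signed-integer count encoding (see [decodeSegment()]). Segments split as
#' finer block structures appear, so the final partition refines every
#' recorded iteration's block partition.
#'
#' @slot starts integer 0-based segment start positions (first is 0).
#' @slot lengths integer segment lengths; together the segments tile `[0, T)`.
#' @slot encodings list of integer vectors, one count encoding per segment.
#' @slot T integer number of data positions.
#' @slot R integer number of recorded iterations.
#' @slot sMax integer largest 0-based state label seen (-1 before any).
#' @seealso [MarginalRecords()], [addRunLengths()], [queryCounts()],
#'   [callSegments()]
#' @export
setClass("MarginalRecords",
         representation(starts = "integer", lengths = "integer",
                        encodings = "list", T = "integer", R = "integer",
                        sMax = "integer"),
         validity = function(object) {
           if (object@T < 1L) return("T must be positive")
           if (length(object@starts) != length(object@lengths) ||
               length(object@starts) != length(object@encodings))
             return("starts, lengths and encodings must have equal length")
           if (any(object@lengths < 1L)) return("segment lengths must be positive")
           if (sum(object@lengths) != object@T)
             return("segment lengths must sum to T")
           if (length(object@starts) &&
               !identical(object@starts,
                          c(0L, cumsum(object@lengths)[-length(object@lengths)])))
             return("segments must be ordered, disjoint and gapless")
           TRUE
         })

#' Gaussian-emission HMM parameters
#'
#' @slot mu numeric per-state emission means (signal units).
#' @slot sigma2 numeric per-state emission variances (> 0).
#' @slot A row-stochastic transition matrix.
#' @slot pi initial state distribution.
#' @export
setClass("HMMModel",
         representation(mu = "numeric", sigma2 = "numeric",
                        A = "matrix", pi = "numeric"),
         validity = function(object) {
           S <- length(object@mu)
           if (length(object@sigma2) != S || length(object@pi) != S ||
               !all(dim(object@A) == c(S, S)))
             return("mu, sigma2, pi and A must agree on the number of states")
           if (any(object@sigma2 <= 0)) return("variances must be positive")
           if (any(object@A < 0) || any(object@pi < 0))
             return("probabilities must be non-negative")
           if (any(abs(rowSums(object@A) - 1) > 1e-12))
             return("transition rows must sum to 1")
           if (abs(sum(object@pi) - 1) > 1e-12)
             return("initial distribution must sum to 1")
           TRUE
         })

#' Conjugate prior for the Gaussian HMM
#'
#' Normal-inverse-gamma priors per state on (mean, variance) and Dirichlet
#' priors on each transition row and the initial distribution.
#'
#' @slot mu0,nu,alpha,beta numeric per-state NIG hyperparameters
#'   (`nu`, `alpha`, `beta` > 0).
#' @slot transConc Dirichlet concentration matrix for transition rows.
#' @slot initConc Dirichlet concentration vector for the initial distribution.
#' @export
setClass("HMMPrior",
         representation(mu0 = "numeric", nu = "numeric", alpha = "numeric",
                        beta = "numeric", transConc = "matrix",
                        initConc = "numeric"),
         validity = function(object) {
           S <- length(object@mu0)
           if (length(object@nu) != S || length(object@alpha) != S ||
               length(object@beta) != S || length(object@initConc) != S ||
               !all(dim(object@transConc) == c(S, S)))
             return("hyperparameter dimensions must agree")
           if (any(object@nu <= 0) || any(object@alpha <= 0) ||
               any(object@beta <= 0))
             return("nu, alpha, beta must be positive")
           if (any(object@transConc <= 0) || any(object@initConc <= 0))
             return("Dirichlet concentrations must be positive")
           TRUE
         })

#' Result of a compressed Forward-Backward Gibbs run
#'
#' @slot records [MarginalRecords-class] posterior state counts.
#' @slot trace data.frame with one row per sweep: `iteration`, `lambda`
#'   (compression threshold used), `nBlocks`, `minVariance`, `recorded`.
#' @slot muTrace,sigma2Trace numeric matrices (sweeps x states) of sampled
#'   emission parameters.
#' @slot model final [HMMModel-class].
#' @slot postMu numeric posterior-mean emission means over recorded sweeps.
#' @slot prior the [HMMPrior-class] used.
#' @slot config list of run settings (states, iterations, burnIn, seed, ...).
#' @export
setClass("HaarFBGFit",
         representation(records = "MarginalRecords", trace = "data.frame",
                        muTrace = "matrix", sigma2Trace = "matrix",
                        model = "HMMModel", postMu = "numeric",
                        prior = "HMMPrior", config = "list"))

setMethod("show", "IntegralArray", function(object) {
  cat(sprintf("IntegralArray: %d positions, cell size %d (%d cells)\n",
              object@T, object@cellSize,
              ceiling(object@T / object@cellSize)))
})

setMethod("show", "BreakpointArray", function(object) {
  w <- object@weights
  cat(sprintf(paste0("BreakpointArray: %d positions, max jump %d\n",
                     "  finite weights: %d; construction deque max/final: %d/%d\n"),
              length(w), object@maxJump, sum(is.finite(w)),
              object@maxQueueLength, object@finalQueueLength))
})

setMethod("show", "MarginalRecords", function(object) {
  cat(sprintf(paste0("MarginalRecords: %d positions in %d segments, ",
                     "%d recorded iterations, states 0..%d\n"),
              object@T, length(object@starts), object@R,
              max(object@sMax, 0L)))
})

setMethod("show", "HMMModel", function(object) {
  S <- length(object@mu)
  cat(sprintf("HMMModel with %d states\n  mu:     %s\n  sigma2: %s\n",
              S, paste(signif(object@mu, 4), collapse = " "),
              paste(signif(object@sigma2, 4), collapse = " ")))
})

setMethod("show", "HaarFBGFit", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("HaarFBGFit: T = %d, %d states, %d sweeps ",
                     "(%d recorded)\n  final lambda: %.4g, final blocks: %d\n",
                     "  posterior-mean state means: %s\n"),
              object@records@T, length(object@model@mu), nrow(object@trace),
              object@records@R, utils::tail(object@trace$lambda, 1),
              utils::tail(object@trace$nBlocks, 1),
              paste(signif(object@postMu, 4), collapse = " ")))
})

#' @describeIn IntegralArray-class number of data positions
#' @param x an object
#' @export
setMethod("length", "IntegralArray", function(x) as.integer(x@T))

#' @describeIn BreakpointArray-class number of data positions
#' @param x an object
#' @export
setMethod("length", "BreakpointArray", function(x) length(x@weights))

#' @describeIn MarginalRecords-class number of data positions
#' @param x an object
#' @export
setMethod("length", "MarginalRecords", function(x) as.integer(x@T))
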
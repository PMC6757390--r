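# Discrete Haar wavelet bookkeeping. All data coordinates are 0-based and
# half-open; a wavelet psi_{j,k} (scale j >= 1, shift k >= 0) has value
# +2^{-j/2} on [b+, bc) and -2^{-j/2} on [bc, b-), where
#   b+ = 2^j k,  bc = 2^j (k + 1/2),  b- = 2^j (k + 1).

.checkSignal <- function(y) {
  if (length(y) < 1L)
    stop("signal must contain at least one value", call. = FALSE)
  if (!is.numeric(y) || anyNA(y) || any(!is.finite(y)))
    stop("signal values must be finite numerics", call. = FALSE)
  invisible(as.numeric(y))
}

.weightRole <- function(w) attr(w, "role")

.setWeightRole <- function(w, role) {
  attr(w, "role") <- role
  w
}

#' Maxlet transform of a signal
#'
#' Computes, via the lifting scheme, the absolute Haar detail coefficient
#' \eqn{|\langle \psi_{j,k}, y\rangle|} of every fully supported wavelet and
#' stores it at the wavelet's central discontinuity \eqn{b^\pm_{j,k}}; this is
#' the in-order DFS layout of the wavelet tree. Positions that are the central
#' discontinuity of a wavelet whose support extends past the end of the data
#' receive `Inf` (their magnitude is unknown without padding, so they must act
#' as boundaries at any threshold), as does position 0. The computation
#' overwrites a single working copy of the signal scale by scale; no auxiliary
#' buffer proportional to the data size is allocated.
#'
#' @param y Numeric vector, the signal (finite values, length >= 1).
#' @return Numeric vector of length `length(y)` with attribute
#'   `role = "maxlet"`. Entry at (0-based) position \eqn{2^{j-1}(2k+1)} holds
#'   \eqn{|d_{j,k}|} for fully supported wavelets and `Inf` otherwise.
#' @seealso [haarBoundaryTransform()], [breakpointWeights()],
#'   [oracleWaveletCoefficients()]
#' @examples
#' maxletTransform(c(1, 1, -1, -1))  # Inf 0 2 0
#' @export
maxletTransform <- function(y) {
  w <- .checkSignal(y)
  T <- length(w)
  j <- 1L
  half <- 1L
  while (half < T) {                    # scale j, half = 2^(j-1)
    step <- 2L * half
    bPlus <- seq.int(0L, T - 1L, by = step)
    bCenter <- bPlus + half
    keep <- bCenter < T
    bPlus <- bPlus[keep]
    bCenter <- bCenter[keep]
    full <- bPlus + step <= T           # complete support: b- <= T
    if (any(full)) {
      iL <- bPlus[full] + 1L
      iC <- bCenter[full] + 1L
      cL <- w[iL]
      cR <- w[iC]
      w[iC] <- abs(cL - cR) / sqrt(step)
      w[iL] <- cL + cR                  # scale coefficient for level j
    }
    if (any(!full))
      w[bCenter[!full] + 1L] <- Inf
    half <- step
    j <- j + 1L
  }
  w[1L] <- Inf
  .setWeightRole(w, "maxlet")
}

#' Haar boundary transform
#'
#' Converts a maxlet array into breakpoint weights: for every position
#' \eqn{t > 0} the output is the maximum \eqn{|d_{j,k}|} over all wavelets
#' having *any* of their three discontinuities at \eqn{t}; position 0 is
#' always `Inf` (there is a block boundary before the first position).
#'
#' The maxlet layout makes this a local computation: the wavelets with an edge
#' discontinuity at a level-\eqn{j} central position \eqn{t} are exactly those
#' whose centres sit at \eqn{t \pm 2^{\ell-1}} for \eqn{\ell < j}. Scales are
#' processed top-down so that every read is of a not-yet-updated lower-level
#' entry; each entry is read at most twice, giving linear time in place.
#'
#' @param w Numeric weight vector produced by [maxletTransform()].
#' @return Numeric vector of breakpoint weights with attribute
#'   `role = "boundary"`; entry 0 is `Inf`.
#' @examples
#' haarBoundaryTransform(maxletTransform(c(1, -1, 1, -1)))
#' @export
haarBoundaryTransform <- function(w) {
  if (!identical(.weightRole(w), "maxlet"))
    stop("input must be a maxlet weight vector (see maxletTransform)",
         call. = FALSE)
  T <- length(w)
  if (T == 1L)
    return(.setWeightRole(w, "boundary"))
  J <- 1L
  while (2^J < T) J <- J + 1L        # deepest level whose centres can be < T
  if (J < 2L) {
    w[1L] <- Inf
    return(.setWeightRole(w, "boundary"))
  }
  for (j in seq.int(J, 2L)) {
    half <- 2^(j - 1L)
    centers <- seq.int(half, T - 1L, by = 2L * half)
    centers <- centers[w[centers + 1L] < Inf]      # complete-support nodes only
    if (!length(centers)) next
    acc <- w[centers + 1L]
    for (l in seq_len(j - 1L)) {
      off <- 2^(l - 1L)
      acc <- pmax(acc, w[centers - off + 1L], w[centers + off + 1L])
    }
    w[centers + 1L] <- acc
  }
  w[1L] <- Inf
  .setWeightRole(w, "boundary")
}

#' Haar breakpoint weights of a signal
#'
#' Convenience composition of [maxletTransform()] and
#' [haarBoundaryTransform()]: `breakpointWeights(y)[t+1]` exceeds a threshold
#' `lambda` exactly when the Haar wavelet regression of `y` at threshold
#' `lambda` has a discontinuity between positions `t-1` and `t`.
#'
#' @inheritParams maxletTransform
#' @return Boundary-role weight vector, suitable for [BreakpointArray()].
#' @export
breakpointWeights <- function(y) {
  haarBoundaryTransform(maxletTransform(y))
}

#' Universal threshold
#'
#' \eqn{\lambda_u = \sqrt{2 \ln T}\,\sigma}: the expected maximum absolute
#' deviation of \eqn{T} i.i.d. centred Gaussian variables with variance
#' \eqn{\sigma^2}. Haar coefficients of pure noise fall below this value with
#' high probability, so thresholding at \eqn{\lambda_u} removes them.
#'
#' @param T Positive integer, the signal length.
#' @param variance Non-negative noise variance \eqn{\sigma^2}.
#' @return `sqrt(2 * log(T)) * sqrt(variance)`.
#' @examples
#' universalThreshold(1000, 4)
#' @export
universalThreshold <- function(T, variance) {
  if (length(T) != 1L || is.na(T) || T < 1)
    stop("T must be a positive integer", call. = FALSE)
  if (length(variance) != 1L || is.na(variance) || variance < 0)
    stop("variance must be non-negative", call. = FALSE)
  sqrt(2 * log(T)) * sqrt(variance)
}

#' Brute-force Haar wavelet coefficients
#'
#' Computes every fully supported discrete Haar detail coefficient
#' \eqn{d_{j,k} = \langle \psi_{j,k}, y \rangle} by explicit summation over
#' the wavelet's support, in \eqn{O(T \log T)} time. This deliberately avoids
#' the lifting recursion and serves as the independent oracle for
#' [maxletTransform()] and [haarBoundaryTransform()].
#'
#' @inheritParams maxletTransform
#' @return A `data.frame` with columns `j`, `k`, `bPlus`, `bCenter`, `bMinus`
#'   (0-based positions) and the signed coefficient `d`.
#' @export
oracleWaveletCoefficients <- function(y) {
  y <- .checkSignal(y)
  T <- length(y)
  out <- list()
  j <- 1L
  while (2^j <= T) {
    step <- 2^j
    half <- step / 2
    for (k in 0:(floor(T / step) - 1L)) {
      bp <- k * step
      bc <- bp + half
      bm <- bp + step
      d <- (sum(y[(bp + 1L):bc]) - sum(y[(bc + 1L):bm])) / sqrt(step)
      out[[length(out) + 1L]] <- c(j, k, bp, bc, bm, d)
    }
    j <- j + 1L
  }
  if (!length(out))
    return(data.frame(j = integer(), k = integer(), bPlus = integer(),
                      bCenter = integer(), bMinus = integer(), d = numeric()))
  m <- do.call(rbind, out)
  data.frame(j = as.integer(m[, 1]), k = as.integer(m[, 2]),
             bPlus = as.integer(m[, 3]), bCenter = as.integer(m[, 4]),
             bMinus = as.integer(m[, 5]), d = m[, 6])
}
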
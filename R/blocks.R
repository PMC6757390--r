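# Block generator: breakpoint array (boundaries) + integral array (statistics).
# All coordinates 0-based, half-open.

#' Build an integral array
#'
#' One linear pass computes, within each cell of `cellSize` consecutive
#' positions, the cumulative sufficient statistics from the cell's high end
#' down to each position (the layout that keeps block queries free of
#' long-range floating-point cancellation; see
#' [IntegralArray-class]).
#'
#' @param y numeric signal (finite, length >= 1).
#' @param cellSize positive integer cell width; the default \eqn{2^{16}}
#'   mirrors the 2-byte pointer design of the companion breakpoint array.
#' @return An [IntegralArray-class] object.
#' @examples
#' ia <- IntegralArray(rnorm(100), cellSize = 16)
#' queryStats(ia, 10, 20)
#' @export
IntegralArray <- function(y, cellSize = 65536L) {
  y <- .checkSignal(y)
  cellSize <- as.integer(cellSize)
  if (is.na(cellSize) || cellSize < 1L)
    stop("cellSize must be a positive integer", call. = FALSE)
  T <- length(y)
  stats <- matrix(0, nrow = T + 1L, ncol = 3L,
                  dimnames = list(NULL, c("n", "sum", "sumsq")))
  if (cellSize == 1L) {
    stats[seq_len(T), ] <- cbind(1, y, y * y)
  } else {
    nCells <- ceiling(T / cellSize)
    for (ci in seq_len(nCells)) {
      lo <- (ci - 1L) * cellSize + 1L
      hi <- min(ci * cellSize, T)
      idx <- lo:hi
      ys <- y[idx]
      stats[idx, 1L] <- rev(cumsum(rep(1, length(idx))))
      stats[idx, 2L] <- rev(cumsum(rev(ys)))
      stats[idx, 3L] <- rev(cumsum(rev(ys * ys)))
    }
  }
  new("IntegralArray", stats = stats, cellSize = cellSize, T = T)
}

#' Query block sufficient statistics
#'
#' Returns \eqn{\sum_{t=s}^{e-1} (1, y[t], y[t]^2)} for the half-open block
#' `[s, e)` by adding the entry at `s` and the entries at interior cell
#' starts, and subtracting the entry at `e` iff `e` is not a cell start.
#' Runs in `O(1 + (e - s)/cellSize)` time.
#'
#' @param ia an [IntegralArray-class].
#' @param s,e 0-based half-open block limits, `0 <= s < e <= length(ia)`.
#' @return Named numeric vector `c(n, sum, sumsq)`.
#' @export
queryStats <- function(ia, s, e) {
  stopifnot(is(ia, "IntegralArray"))
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e) ||
      s < 0 || e > ia@T || s >= e)
    stop("require 0 <= s < e <= T", call. = FALSE)
  s <- as.integer(s); e <- as.integer(e)
  cs <- ia@cellSize
  v <- ia@stats
  res <- v[s + 1L, ]
  m0 <- (s %/% cs + 1L) * cs              # first cell start after s
  if (m0 < e) {
    ms <- seq.int(m0, e - 1L, by = cs)
    if (length(ms) == 1L) res <- res + v[ms + 1L, ]
    else res <- res + colSums(v[ms + 1L, , drop = FALSE])
  }
  if (e %% cs != 0L) res <- res - v[e + 1L, ]
  res
}

#' Build a breakpoint array
#'
#' Single left-to-right pass over finalized boundary weights using a deque of
#' pending indices: an index is finalized (its stretch length recorded) when a
#' weight at least as large arrives, or when it falls `maxJump` positions
#' behind the cursor (the cap trades maximality for 2-byte-sized jumps without
#' losing compressivity). Indices still pending at the end stretch to `T`,
#' capped. The deque holds the running right-to-left maxima of the weights, so
#' its expected size at any cursor is at most \eqn{H_T \approx \ln T} for
#' randomly ordered weights; both the maximum and the final queue length are
#' recorded on the returned object.
#'
#' @param weights boundary weight vector from [breakpointWeights()] /
#'   [haarBoundaryTransform()] (entry 0 must be `Inf`), or any numeric vector
#'   of weights for direct use.
#' @param maxJump positive integer jump cap `m` (default \eqn{2^{16}}).
#' @return A [BreakpointArray-class].
#' @examples
#' bpa <- BreakpointArray(breakpointWeights(c(1, 1, -1, -1)), maxJump = 8)
#' @export
BreakpointArray <- function(weights, maxJump = 65536L) {
  maxJump <- as.integer(maxJump)
  if (is.na(maxJump) || maxJump < 1L)
    stop("maxJump must be a positive integer", call. = FALSE)
  role <- .weightRole(weights)
  if (!is.null(role) && role != "boundary")
    stop("weights must be boundary weights, not '", role, "'", call. = FALSE)
  w <- as.numeric(weights)
  T <- length(w)
  if (T < 1L) stop("weights must be non-empty", call. = FALSE)
  jumps <- integer(T)
  dq <- integer(T)
  head <- 1L; tail <- 0L
  maxLen <- 0L
  for (t in seq_len(T)) {
    if (tail >= head && t - dq[head] >= maxJump) {   # front fell m behind
      jumps[dq[head]] <- maxJump
      head <- head + 1L
    }
    wt <- w[t]
    while (tail >= head && w[dq[tail]] <= wt) {      # weight >= back arrives
      jumps[dq[tail]] <- t - dq[tail]
      tail <- tail - 1L
    }
    tail <- tail + 1L
    dq[tail] <- t
    if (tail - head + 1L > maxLen) maxLen <- tail - head + 1L
  }
  finalLen <- tail - head + 1L
  while (tail >= head) {                             # pending stretches run to T
    jumps[dq[head]] <- min(T + 1L - dq[head], maxJump)
    head <- head + 1L
  }
  new("BreakpointArray", weights = w, jumps = jumps, maxJump = maxJump,
      maxQueueLength = maxLen, finalQueueLength = finalLen)
}

#' Next block boundary at or after a position
#'
#' Smallest 0-based `t >= from` with `weights[t] >= lambda`, or `T` if none.
#' Follows jump pointers: a stretch whose head is below the threshold cannot
#' contain a boundary, so whole stretches are skipped (expected `O(log N)`
#' jumps for a block of `N` randomly ordered weights).
#'
#' @param bpa a [BreakpointArray-class].
#' @param from 0-based start position, `0 <= from <= T`.
#' @param lambda threshold.
#' @return 0-based boundary position, or `T`.
#' @export
nextBreakpoint <- function(bpa, from, lambda) {
  stopifnot(is(bpa, "BreakpointArray"))
  T <- length(bpa@weights)
  if (length(from) != 1L || is.na(from) || from < 0 || from > T)
    stop("require 0 <= from <= T", call. = FALSE)
  t <- as.integer(from)
  w <- bpa@weights
  p <- bpa@jumps
  while (t < T && w[t + 1L] < lambda) t <- t + p[t + 1L]
  as.integer(min(t, T))
}

#' Generate the compressed block sequence for a threshold
#'
#' Emits the ordered, gapless blocks of the Haar regression at threshold
#' `lambda`: a boundary sits exactly before every position whose breakpoint
#' weight is `>= lambda` (and nowhere else -- the generator is compressive),
#' and each block carries its sufficient statistics from the integral array.
#'
#' @param bpa a [BreakpointArray-class].
#' @param ia the [IntegralArray-class] built over the same signal.
#' @param lambda compression threshold.
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `n`, `sum`, `sumsq`.
#' @examples
#' y <- c(rep(0, 8), rep(5, 8))
#' iterBlocks(BreakpointArray(breakpointWeights(y)), IntegralArray(y), 3)
#' @export
iterBlocks <- function(bpa, ia, lambda) {
  stopifnot(is(bpa, "BreakpointArray"), is(ia, "IntegralArray"))
  T <- length(bpa@weights)
  if (ia@T != T) stop("structures were built over different signals",
                      call. = FALSE)
  bnd <- integer(256L)
  nb <- 1L
  bnd[1L] <- 0L                                   # sentinel boundary
  t <- nextBreakpoint(bpa, 1L, lambda)
  while (t < T) {
    nb <- nb + 1L
    if (nb > length(bnd)) bnd <- c(bnd, integer(length(bnd)))
    bnd[nb] <- t
    t <- nextBreakpoint(bpa, t + 1L, lambda)
  }
  starts <- bnd[seq_len(nb)]
  ends <- c(starts[-1L], T)
  st <- matrix(0, nrow = nb, ncol = 3L)
  for (i in seq_len(nb)) st[i, ] <- queryStats(ia, starts[i], ends[i])
  data.frame(start = starts, end = ends,
             n = st[, 1L], sum = st[, 2L], sumsq = st[, 3L])
}

#' Wavelet-tree block generator (reference implementation)
#'
#' Reproduces the block structure of the earlier wavelet-tree scheme: the
#' dyadic tree (padded to the next power of two) stores each subtree's
#' maximum absolute coefficient; DFS recurses into any node whose subtree
#' maximum reaches `lambda`, emitting a boundary at its central discontinuity,
#' and nodes whose own coefficient reaches `lambda` additionally emit their
#' left and right edge discontinuities. Wavelets with incomplete support are
#' treated as above any threshold. This generator is *subcompressive* -- it
#' can emit boundaries where the breakpoint weight is below `lambda` -- and is
#' provided as a reference/oracle, not used by the sampler.
#'
#' @param y numeric signal.
#' @param lambda threshold.
#' @return `data.frame` as [iterBlocks()].
#' @export
waveletTreeBlocks <- function(y, lambda) {
  y <- .checkSignal(y)
  T <- length(y)
  S1 <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y * y))
  if (T == 1L) {
    return(data.frame(start = 0L, end = 1L, n = 1, sum = y, sumsq = y * y))
  }
  J <- ceiling(log2(T))
  # per-level |d| (Inf for incomplete support, -Inf past the data) and
  # bottom-up subtree maxima
  d <- vector("list", J)
  s <- vector("list", J)
  for (j in seq_len(J)) {
    nk <- 2^(J - j)
    bp <- 2^j * (0:(nk - 1)); bc <- bp + 2^(j - 1); bm <- bp + 2^j
    dj <- rep(-Inf, nk)
    dj[bp < T & bm > T] <- Inf
    ok <- bm <= T
    dj[ok] <- abs((2 * S1[bc[ok] + 1] - S1[bp[ok] + 1] - S1[bm[ok] + 1]) /
                    sqrt(2^j))
    d[[j]] <- dj
    s[[j]] <- if (j == 1L) dj
              else pmax(dj, s[[j - 1L]][2 * (0:(nk - 1)) + 1],
                        s[[j - 1L]][2 * (0:(nk - 1)) + 2])
  }
  bound <- new.env()
  bound$b <- c(0L)
  visit <- function(j, k) {
    bp <- 2^j * k
    if (bp >= T) return(invisible())
    if (s[[j]][k + 1] < lambda) return(invisible())
    bc <- bp + 2^(j - 1); bm <- bp + 2^j
    if (bc > 0 && bc < T) bound$b <- c(bound$b, bc)
    if (d[[j]][k + 1] >= lambda) {
      if (bp > 0 && bp < T) bound$b <- c(bound$b, bp)
      if (bm < T) bound$b <- c(bound$b, bm)
    }
    if (j > 1L) { visit(j - 1L, 2L * k); visit(j - 1L, 2L * k + 1L) }
    invisible()
  }
  visit(J, 0L)
  starts <- sort(unique(as.integer(bound$b)))
  ends <- c(starts[-1L], T)
  data.frame(start = starts, end = ends,
             n = ends - starts,
             sum = S1[ends + 1L] - S1[starts + 1L],
             sumsq = S2[ends + 1L] - S2[starts + 1L])
}
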
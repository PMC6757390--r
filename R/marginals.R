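# Run-length compressed posterior state counts.
#
# Count encoding for one segment (states are 0-based here, matching the
# signed-integer scheme): reading left to right with current state s
# (initially 0),
#   * a negative entry -n records n observations of state s, then s advances
#     by one;
#   * a positive entry v jumps s to v (runs of zero-count states collapse to
#     this single number); index values must be strictly increasing and
#     strictly greater than the current state (no unnecessary index).
# A literal 0 never appears inside an encoding; it marks segment starts in
# the flattened queue layout.

#' Decode a segment count encoding
#'
#' @param enc integer vector of signed count/index entries.
#' @return named integer vector of per-state counts for states `0..smax`
#'   (names are the 0-based state labels); `integer(0)` for an empty
#'   encoding.
#' @examples
#' decodeSegment(c(-2L, 3L, -8L, -1L, -4L, 9L, -5L))
#' @export
decodeSegment <- function(enc) {
  if (!length(enc)) return(integer(0))
  enc <- as.integer(enc)
  if (anyNA(enc) || any(enc == 0L))
    stop("corrupt encoding: entries must be non-zero integers", call. = FALSE)
  s <- 0L
  cts <- integer(0)
  for (v in enc) {
    if (v > 0L) {
      if (v <= s)
        stop("corrupt encoding: index ", v,
             " not above current state ", s, call. = FALSE)
      s <- v
    } else {
      if (s + 1L > length(cts)) cts <- c(cts, integer(s + 1L - length(cts)))
      cts[s + 1L] <- cts[s + 1L] - v
      s <- s + 1L
    }
  }
  names(cts) <- as.character(seq_along(cts) - 1L)
  cts
}

#' Encode per-state counts
#'
#' Inverse of [decodeSegment()]: produces the canonical (shortest) signed
#' encoding of a non-negative count vector.
#'
#' @param counts integer vector of counts for states `0, 1, 2, ...`.
#' @return integer encoding vector.
#' @export
encodeCounts <- function(counts) {
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  nz <- which(counts > 0L) - 1L            # 0-based states with counts
  if (!length(nz)) return(integer(0))
  enc <- integer(2L * length(nz))
  ne <- 0L
  cur <- 0L
  for (v in nz) {
    if (v > cur) { ne <- ne + 1L; enc[ne] <- v; cur <- v }
    ne <- ne + 1L; enc[ne] <- -counts[v + 1L]
    cur <- cur + 1L
  }
  enc[seq_len(ne)]
}

# add one observation of 0-based state q to an encoding
.incrementEncoding <- function(enc, q) {
  cts <- decodeSegment(enc)
  if (q + 1L > length(cts)) cts <- c(cts, integer(q + 1L - length(cts)))
  cts[q + 1L] <- cts[q + 1L] + 1L
  encodeCounts(cts)
}

#' Create empty marginal records
#'
#' A single segment spanning `[0, T)` with no counts recorded.
#'
#' @param T positive integer number of positions.
#' @return a [MarginalRecords-class].
#' @export
MarginalRecords <- function(T) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be a positive integer", call. = FALSE)
  new("MarginalRecords", starts = 0L, lengths = T, encodings = list(integer(0)),
      T = T, R = 0L, sMax = -1L)
}

#' Fold one sampled state path into the marginal records
#'
#' Merge-walks the segment queue against the run-length encoded path: where a
#' run boundary falls inside a segment the segment is split, and every
#' resulting segment receives one additional count for its run's state. Each
#' segment is visited exactly once (queue discipline), so the cost is
#' `O(#segments + #runs)` plus the encoding updates.
#'
#' @param records a [MarginalRecords-class].
#' @param runs `data.frame` with columns `length` (positive integers summing
#'   to `T`) and `state` (0-based state labels).
#' @return the updated [MarginalRecords-class] (counts for one more
#'   iteration).
#' @export
addRunLengths <- function(records, runs) {
  stopifnot(is(records, "MarginalRecords"))
  len <- as.integer(runs$length)
  st <- as.integer(runs$state)
  if (any(len < 1L) || any(st < 0L))
    stop("runs need positive lengths and non-negative states", call. = FALSE)
  if (sum(len) != records@T)
    stop("run lengths must sum to T = ", records@T, call. = FALSE)

  nOut <- length(records@lengths) + length(len)    # upper bound after splits
  oStart <- integer(nOut); oLen <- integer(nOut); oEnc <- vector("list", nOut)
  no <- 0L
  i <- 1L                      # segment index
  j <- 1L                      # run index
  cur <- 0L                    # current position
  segEnd <- records@lengths[1L]
  runEnd <- len[1L]
  while (cur < records@T) {
    pieceEnd <- min(segEnd, runEnd)
    no <- no + 1L
    oStart[no] <- cur
    oLen[no] <- pieceEnd - cur
    oEnc[[no]] <- .incrementEncoding(records@encodings[[i]], st[j])
    cur <- pieceEnd
    if (cur == segEnd && i < length(records@lengths)) {
      i <- i + 1L
      segEnd <- segEnd + records@lengths[i]
    }
    if (cur == runEnd && j < length(len)) {
      j <- j + 1L
      runEnd <- runEnd + len[j]
    }
  }
  new("MarginalRecords", starts = oStart[seq_len(no)],
      lengths = oLen[seq_len(no)], encodings = oEnc[seq_len(no)],
      T = records@T, R = records@R + 1L,
      sMax = max(records@sMax, max(st)))
}

#' Query marginal counts at a position
#'
#' @param records a [MarginalRecords-class].
#' @param t 0-based position, `0 <= t < T`.
#' @return named integer vector of counts for states `0..sMax` (zero-padded).
#' @export
queryCounts <- function(records, t) {
  stopifnot(is(records, "MarginalRecords"))
  if (length(t) != 1L || is.na(t) || t < 0 || t >= records@T)
    stop("require 0 <= t < T", call. = FALSE)
  i <- findInterval(t, records@starts)
  cts <- decodeSegment(records@encodings[[i]])
  ns <- max(records@sMax + 1L, 0L)
  out <- integer(ns)
  if (length(cts)) out[seq_along(cts)] <- cts
  names(out) <- as.character(seq_len(ns) - 1L)
  out
}

# per-position modal 0-based state (ties -> lower state label)
#' Per-position modal states
#'
#' The most frequently sampled (0-based) state at every position; ties break
#' to the lower state label.
#'
#' @param records a [MarginalRecords-class] with `R >= 1`.
#' @return integer vector of length `T`.
#' @export
modalStates <- function(records) {
  stopifnot(is(records, "MarginalRecords"))
  if (records@R < 1L) stop("no iterations recorded", call. = FALSE)
  modal <- vapply(records@encodings, function(e) {
    cts <- decodeSegment(e)
    which.max(cts) - 1L
  }, integer(1))
  rep(modal, records@lengths)
}

#' Segment calls from marginal records
#'
#' Per segment the modal state is taken (ties to the lower label); adjacent
#' segments sharing a modal state are merged; a merged segment is flagged as
#' a call when the absolute posterior-mean emission mean of its modal state
#' is at least `minAbsMean` (for differential read-depth signals, a state
#' mean of magnitude 1 is the smallest single-copy dosage shift).
#'
#' @param records a [MarginalRecords-class] (or a [HaarFBGFit-class], from
#'   which records and posterior state means are taken).
#' @param stateMeans numeric posterior-mean emission mean per state (index
#'   `s + 1` is 0-based state `s`); unused when `records` is a fit.
#' @param minAbsMean calling threshold on the absolute state mean.
#' @return `data.frame` with 0-based half-open `start`, `end`, 0-based
#'   `state`, `posterior` (length-weighted modal count fraction), `mean`
#'   (the state's posterior-mean emission mean) and logical `called`.
#' @export
callSegments <- function(records, stateMeans = NULL, minAbsMean = 1.0) {
  if (is(records, "HaarFBGFit")) {
    if (is.null(stateMeans)) stateMeans <- records@postMu
    records <- records@records
  }
  stopifnot(is(records, "MarginalRecords"))
  if (records@R < 1L) stop("no iterations recorded", call. = FALSE)
  if (is.null(stateMeans)) stop("stateMeans required", call. = FALSE)
  M <- length(records@lengths)
  modal <- integer(M); frac <- numeric(M)
  for (i in seq_len(M)) {
    cts <- decodeSegment(records@encodings[[i]])
    modal[i] <- which.max(cts) - 1L
    frac[i] <- max(cts) / records@R
  }
  r <- rle(modal)
  idx2 <- cumsum(r$lengths)           # last segment index of each merged run
  idx1 <- c(1L, utils::head(idx2, -1L) + 1L)
  n <- length(r$values)
  start <- records@starts[idx1]
  end <- records@starts[idx2] + records@lengths[idx2]
  post <- vapply(seq_len(n), function(g) {
    sel <- idx1[g]:idx2[g]
    sum(frac[sel] * records@lengths[sel]) / sum(records@lengths[sel])
  }, numeric(1))
  mn <- stateMeans[r$values + 1L]
  data.frame(start = start, end = end, state = r$values,
             posterior = post, mean = mn,
             called = abs(mn) >= minAbsMean)
}
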
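# Track input/output and preprocessing. A "track" is a named list of numeric
# vectors, one per chromosome (plain-text input yields a single element named
# "track"); positions are implicit 0-based indices.

#' Read a coverage/difference track
#'
#' `plain` format is one numeric value per line. `bedGraph` is the standard
#' 4-column format (chrom, start, end, value; 0-based half-open), read via
#' `rtracklayer` and expanded to one value per covered position; gaps are
#' filled with 0, overlapping intervals are an error. `auto` picks bedGraph
#' for `.bedgraph`/`.bg` file extensions and plain otherwise.
#'
#' @param path file path.
#' @param format `"auto"`, `"plain"` or `"bedgraph"`.
#' @return named list of numeric vectors, one per chromosome.
#' @export
readTrack <- function(path, format = c("auto", "plain", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "plain"
  if (format == "plain") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    vals <- suppressWarnings(as.numeric(lines[keep]))
    if (anyNA(vals)) {
      bad <- which(keep)[which(is.na(vals))[1L]]
      stop("parse error in ", path, " at line ", bad, ": '",
           lines[bad], "' is not a number", call. = FALSE)
    }
    if (!length(vals)) stop("empty track: ", path, call. = FALSE)
    return(list(track = vals))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e)
                   stop("parse error in ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  df <- as.data.frame(GenomicRanges::sort(gr))  # 1-based inclusive coords
  out <- list()
  for (chrom in unique(as.character(df$seqnames))) {
    g <- df[df$seqnames == chrom, , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("overlapping intervals for ", chrom, " in ", path, call. = FALSE)
    v <- numeric(max(g$end))
    for (i in seq_len(nrow(g))) v[g$start[i]:g$end[i]] <- g$score[i]
    out[[chrom]] <- v
  }
  out
}

#' Subtract one track from another
#'
#' Elementwise `a - b` per chromosome; chromosome sets and lengths must
#' match. Subtracting the control from the case track removes shared
#' additive coverage bias before segmentation.
#'
#' @param a,b tracks as returned by [readTrack()].
#' @return track of differences.
#' @export
subtractTracks <- function(a, b) {
  if (!identical(sort(names(a)), sort(names(b))))
    stop("tracks cover different chromosomes", call. = FALSE)
  out <- lapply(names(a), function(ch) {
    if (length(a[[ch]]) != length(b[[ch]]))
      stop("track lengths differ for ", ch, call. = FALSE)
    a[[ch]] - b[[ch]]
  })
  names(out) <- names(a)
  out
}

#' Number of windows covering n positions
#'
#' @param n number of positions (may exceed the integer range).
#' @param w window width.
#' @return `ceiling(n / w)`.
#' @examples
#' nWindows(1880703547, 20)
#' @export
nWindows <- function(n, w) {
  if (w < 1) stop("w must be >= 1", call. = FALSE)
  ceiling(as.numeric(n) / as.numeric(w))
}

#' Average a vector over non-overlapping windows
#'
#' The final window may be partial and is averaged over its actual length.
#' Window averaging of low-coverage count differences brings the noise close
#' to Gaussian, which is what the HMM emission model assumes.
#'
#' @param values numeric vector.
#' @param w window width (default 20).
#' @return numeric vector of length `nWindows(length(values), w)`.
#' @examples
#' windowAverage(c(1, 2, 3, 4, 5), 2)  # 1.5 3.5 5
#' @export
windowAverage <- function(values, w = 20L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be >= 1", call. = FALSE)
  if (w == 1L) return(as.numeric(values))
  grp <- (seq_along(values) - 1L) %/% w
  as.numeric(rowsum(as.numeric(values), grp)) / tabulate(grp + 1L)
}

#' Write segment calls as BED5+
#'
#' One row per called segment: chrom, start and end rescaled from window to
#' base coordinates (0-based half-open), the modal state label as name,
#' `round(1000 * posterior)` as score, and the state's posterior-mean
#' emission mean as a sixth column. Rows are ordered by chromosome and start.
#'
#' @param calls `data.frame` from [callSegments()]; an optional `chrom`
#'   column labels chromosomes (default `"track"`).
#' @param path output file.
#' @param window window width used in preprocessing (coordinate scale
#'   factor).
#' @param includeNonCalls write all segments, not only calls (default
#'   `FALSE`).
#' @return invisibly, the number of rows written.
#' @export
writeBedCalls <- function(calls, path, window = 20L, includeNonCalls = FALSE) {
  if (is.null(calls$chrom)) calls$chrom <- rep("track", nrow(calls))
  if (!includeNonCalls) calls <- calls[calls$called, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  w <- as.integer(window)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tstate\tscore\tmean", con)
  if (nrow(calls))
    writeLines(sprintf("%s\t%d\t%d\tstate%d\t%d\t%.6g",
                       calls$chrom, as.integer(calls$start) * w,
                       as.integer(calls$end) * w, calls$state,
                       as.integer(round(1000 * calls$posterior)),
                       calls$mean),
               con)
  invisible(nrow(calls))
}

#' Marginal counts as a table
#'
#' @param records a [MarginalRecords-class] (or [HaarFBGFit-class]).
#' @param nStates optional minimum number of state columns (zero-padded).
#' @return `data.frame` with `start`, `end` and one `state<k>` count column
#'   per state.
#' @export
marginalsTable <- function(records, nStates = NULL) {
  if (is(records, "HaarFBGFit")) {
    if (is.null(nStates)) nStates <- records@config$nStates
    records <- records@records
  }
  stopifnot(is(records, "MarginalRecords"))
  ns <- max(records@sMax + 1L, 1L, nStates)
  m <- t(vapply(records@encodings, function(e) {
    cts <- decodeSegment(e)
    out <- integer(ns)
    if (length(cts)) out[seq_along(cts)] <- cts
    out
  }, integer(ns)))
  df <- data.frame(start = records@starts,
                   end = records@starts + records@lengths)
  m <- matrix(m, nrow = length(records@starts))
  colnames(m) <- paste0("state", seq_len(ns) - 1L)
  cbind(df, as.data.frame(m))
}
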
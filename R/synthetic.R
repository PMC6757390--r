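# Ground-truthed simulators: piecewise-constant Gaussian signals for the
# sampler itself, and a two-track Poisson count simulator emulating the
# differential read-depth pipeline (case minus control, window-averaged).

#' Simulate a piecewise-constant signal with Gaussian noise
#'
#' Segment boundaries are drawn uniformly without replacement, each segment's
#' mean is drawn from `meanLevels`, and i.i.d. centred Gaussian noise of
#' standard deviation `sigma` is added.
#'
#' @param T signal length.
#' @param nSegments number of segments (`1 <= nSegments <= T`).
#' @param meanLevels numeric vector of possible segment means.
#' @param sigma noise standard deviation (`>= 0`).
#' @param seed optional integer seed (bit-reproducible output).
#' @return list with `signal` (numeric length `T`) and `truth`, a
#'   `data.frame` of 0-based half-open segments with columns `start`, `end`,
#'   `mean` and `state` (index into `meanLevels`).
#' @examples
#' sim <- genPiecewise(200, 3, c(-2, 0, 2), 0.3, seed = 42)
#' @export
genPiecewise <- function(T, nSegments, meanLevels, sigma, seed = NULL) {
  T <- as.integer(T)
  nSegments <- as.integer(nSegments)
  if (nSegments < 1L || nSegments > T)
    stop("need 1 <= nSegments <= T", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bnd <- if (nSegments > 1L) sort(sample.int(T - 1L, nSegments - 1L))
         else integer(0)
  start <- c(0L, bnd)
  end <- c(bnd, T)
  state <- sample.int(length(meanLevels), nSegments, replace = TRUE)
  means <- meanLevels[state]
  signal <- rep(means, end - start) + stats::rnorm(T, 0, sigma)
  list(signal = signal,
       truth = data.frame(start = start, end = end, mean = means,
                          state = state),
       sigma = sigma)
}

#' Simulate two-track differential coverage
#'
#' Emulates a multiplexed case/control sequencing experiment: both tracks
#' share a smooth additive coverage bias (a low-frequency sinusoid mixture),
#' the case track's Poisson rate is additionally scaled by copy number, and
#' the differential signal is the window-averaged difference of the two count
#' tracks. Because the bias is additive and shared, it cancels exactly in the
#' rate difference; after averaging over `window` positions the Poisson noise
#' is approximately Gaussian.
#'
#' @param T number of base positions.
#' @param cnvSpec optional `data.frame` with 0-based half-open `start`, `end`
#'   and integer `copy` (case copy number; 2 = neutral) in base coordinates;
#'   `NULL` for no CNVs.
#' @param meanCoverage mean per-position coverage of the diploid state
#'   (default 4, a typical low-coverage WGS design).
#' @param biasAmplitude amplitude of the shared additive bias.
#' @param window averaging window width (default 20).
#' @param seed optional integer seed.
#' @return list with integer `case` and `control` counts, numeric
#'   `caseRate`/`controlRate` (the Poisson rates, bias included), `signal`
#'   (window-averaged difference), `truth` (window-coordinate segments with
#'   the expected differential mean `meanCoverage * (copy - 2) / 2`), and
#'   `window`.
#' @export
genDifferentialCoverage <- function(T, cnvSpec = NULL, meanCoverage = 4,
                                    biasAmplitude = 1, window = 20L,
                                    seed = NULL) {
  T <- as.integer(T)
  if (meanCoverage <= 0) stop("meanCoverage must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- (seq_len(T) - 1) / T
  phase <- stats::runif(2, 0, 2 * pi)
  bias <- biasAmplitude * (sin(2 * pi * 3 * x + phase[1]) +
                             0.5 * sin(2 * pi * 7 * x + phase[2]))
  copy <- rep(2, T)
  if (!is.null(cnvSpec) && nrow(cnvSpec))
    for (i in seq_len(nrow(cnvSpec)))
      copy[(cnvSpec$start[i] + 1L):cnvSpec$end[i]] <- cnvSpec$copy[i]
  controlRate <- pmax(meanCoverage + bias, 0)
  caseRate <- pmax(meanCoverage * copy / 2 + bias, 0)
  ctl <- stats::rpois(T, controlRate)
  cs <- stats::rpois(T, caseRate)
  signal <- windowAverage(cs - ctl, window)
  expDiff <- windowAverage(meanCoverage * (copy - 2) / 2, window)
  r <- rle(expDiff)
  end <- cumsum(r$lengths)
  truth <- data.frame(start = c(0L, utils::head(end, -1L)), end = end,
                      mean = r$values)
  list(case = cs, control = ctl, caseRate = caseRate,
       controlRate = controlRate, signal = signal, truth = truth,
       window = as.integer(window))
}
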
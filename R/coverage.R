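# Split-and-mix bead-coverage statistics.

#' Analytic library coverage
#'
#' Expected fraction of a library of `N` distinct sequences that appears on
#' at least one bead when `B` beads are drawn independently and uniformly
#' with replacement (the split-and-mix occupancy model):
#' `1 - (1 - 1/N)^B`.
#'
#' @param N library size (>= 1).
#' @param B number of beads drawn (>= 0).
#' @return expected covered fraction in \[0, 1\].
#' @examples
#' coverageAnalytic(4096, 13584)  # ~0.9637, the threefold-bead design point
#' @export
coverageAnalytic <- function(N, B) {
  if (length(N) != 1L || !is.finite(N) || N < 1)
    stop("N must be a single value >= 1")
  if (any(B < 0)) stop("B must be >= 0")
  -expm1(B * log1p(-1 / N))
}

#' Monte-Carlo library coverage
#'
#' Simulates repeated bead draws and reports the realized unique-sequence
#' fraction per replicate together with the pooled appearance-frequency
#' histogram. The mean unique fraction converges to [coverageAnalytic()]
#' and the appearance counts to Binomial(B, 1/N).
#'
#' @param N library size.
#' @param B beads per replicate.
#' @param replicates number of Monte-Carlo repetitions.
#' @param seed RNG seed; the full output is reproducible given the seed.
#' @return list with `uniqueFraction` (numeric, one per replicate), `mean`,
#'   `se` (standard error of the mean), `analytic`, and `freqHistogram`
#'   (mean number of sequences with appearance frequency 0, 1, 2, ...).
#' @export
coverageSimulate <- function(N, B, replicates = 200, seed = 1) {
  if (N < 1) stop("N must be >= 1")
  set.seed(seed)
  maxFreq <- 0L
  histAcc <- numeric(0)
  frac <- numeric(replicates)
  for (r in seq_len(replicates)) {
    counts <- tabulate(sample.int(N, B, replace = TRUE), nbins = N)
    frac[r] <- sum(counts > 0L) / N
    h <- tabulate(counts + 1L)          # h[k] = # sequences seen k-1 times
    if (length(h) > maxFreq) {
      histAcc <- c(histAcc, numeric(length(h) - maxFreq))
      maxFreq <- length(h)
    }
    histAcc[seq_along(h)] <- histAcc[seq_along(h)] + h
  }
  list(
    uniqueFraction = frac,
    mean = mean(frac),
    se = stats::sd(frac) / sqrt(replicates),
    analytic = coverageAnalytic(N, B),
    freqHistogram = stats::setNames(histAcc / replicates,
      as.character(seq_len(maxFreq) - 1L))
  )
}
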
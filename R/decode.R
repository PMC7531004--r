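# Constrained de novo decoding: score observed peak lists against the
# theoretical ladders of the (finite) library and return the best-matching
# sequence(s). The search space is always the library, never the full
# 20-residue sequence space.

# Count how many theoretical ions find an observed peak within tol.
# mz must be sorted ascending. Each theoretical ion matches at most the
# single nearest observed peak.
.countMatches <- function(theo, mz, tol) {
  if (!length(mz)) return(0L)
  i <- findInterval(theo, mz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(mz))
  d <- pmin(abs(theo - mz[lo]), abs(mz[hi] - theo))
  sum(d <= tol + 1e-9)
}

# Vectorized variant: theoMat is k x m (k candidates); returns integer k.
.countMatchesMat <- function(theoMat, mz, tol) {
  if (!length(mz)) return(integer(nrow(theoMat)))
  v <- as.vector(t(theoMat))               # row-wise flatten
  i <- findInterval(v, mz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(mz))
  d <- pmin(abs(v - mz[lo]), abs(mz[hi] - v))
  hits <- d <= tol + 1e-9
  as.integer(rowSums(matrix(hits, nrow = nrow(theoMat), byrow = TRUE)))
}

#' Match a theoretical ladder against an observed peak list
#'
#' @param ladder a [FragmentLadder-class].
#' @param peaks a [PeakList-class].
#' @param tolerance matching tolerance in Da (> 0 for continuous modes;
#'   0 allowed for nominal integer ladders).
#' @return list with `matchedIonCount` (0..28 for the 15-mer library) and
#'   `matchedFraction`.
#' @export
matchPeaks <- function(ladder, peaks, tolerance = 0.3) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  theo <- c(ladder@bIons, ladder@yIons)
  cnt <- .countMatches(theo, peaks@mz, tolerance)
  list(matchedIonCount = as.integer(cnt),
       matchedFraction = cnt / length(theo))
}

#' Decode one spectrum against a library
#'
#' Candidate generation first filters the library by precursor mass (when
#' the peak list carries one), then scores the b/y ladders of the surviving
#' candidates against the observed peaks. Status is `"unique"` only when a
#' single candidate attains the top score and reaches
#' `minMatchedFraction`; co-leaders (e.g., members of a parent-mass
#' degeneracy group seen through a precursor-only spectrum) give
#' `"ambiguous"`, and an empty peak list or empty candidate set gives
#' `"no_match"`. Ties are never silently broken.
#'
#' @param peaks a [PeakList-class].
#' @param scheme a [LibraryScheme-class].
#' @param tolerance matching tolerance in Da; default 0 for nominal mode,
#'   0.3 Da otherwise (TOF/TOF-scale accuracy).
#' @param minMatchedFraction minimum matched ion fraction for acceptance.
#' @param mode mass mode of the theoretical ladders.
#' @param ladders optional precomputed [libraryLadders()] result (must match
#'   `scheme` and `mode`); avoids recomputation in batch decoding.
#' @param maxCandidates maximum number of ranked candidates retained in the
#'   result object.
#' @return a [DecodingResult-class].
#' @export
decodeSpectrum <- function(peaks, scheme, tolerance = NULL,
                           minMatchedFraction = 0.5,
                           mode = c("monoisotopic", "average", "nominal"),
                           ladders = NULL, maxCandidates = 10L) {
  mode <- match.arg(mode)
  if (is.null(tolerance))
    tolerance <- if (mode == "nominal") 0 else 0.3
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (is.null(ladders)) ladders <- libraryLadders(scheme, mode)
  stopifnot(identical(ladders$mode, mode))

  emptyRes <- function(nScored = 0L) new("DecodingResult",
    candidates = data.frame(sequence = character(),
      matchedIonCount = integer(), matchedFraction = numeric()),
    status = "no_match", toleranceUsed = tolerance,
    nScored = as.integer(nScored), nLeaders = 0L)

  if (!length(peaks@mz)) return(emptyRes())

  idx <- seq_along(ladders$sequences)
  if (!is.na(peaks@precursorMz)) {
    idx <- which(abs(ladders$parentMH - peaks@precursorMz) <= tolerance + 1e-9)
    if (!length(idx)) return(emptyRes())
  }
  scores <- .countMatchesMat(ladders$ions[idx, , drop = FALSE], peaks@mz,
    tolerance)
  nIons <- ncol(ladders$ions)
  top <- max(scores)
  # rank: score desc, canonical library order for ties
  o <- order(-scores, idx)
  keep <- o[seq_len(min(maxCandidates, length(o)))]
  cand <- data.frame(
    sequence = ladders$sequences[idx[keep]],
    matchedIonCount = scores[keep],
    matchedFraction = scores[keep] / nIons
  )
  leaders <- sum(scores == top)
  status <- if (leaders == 1L && top / nIons >= minMatchedFraction)
    "unique" else "ambiguous"
  new("DecodingResult", candidates = cand, status = status,
    toleranceUsed = tolerance, nScored = length(idx),
    nLeaders = as.integer(leaders))
}

#' Batch-decode spectra
#'
#' Decodes a list of peak lists (e.g., from [readMGF()]) against a library,
#' computing the ladder table once.
#'
#' @param peakLists list of [PeakList-class] objects.
#' @param scheme a [LibraryScheme-class].
#' @inheritParams decodeSpectrum
#' @return data.frame with one row per spectrum: `sourceId`, `status`,
#'   `sequence` (`NA` unless unique), `matchedFraction`, `nCandidates`
#'   (number of co-leading candidates).
#' @export
decodeSpectra <- function(peakLists, scheme, tolerance = NULL,
                          minMatchedFraction = 0.5,
                          mode = c("monoisotopic", "average", "nominal"),
                          ladders = NULL) {
  mode <- match.arg(mode)
  if (is.null(ladders)) ladders <- libraryLadders(scheme, mode)
  rows <- lapply(peakLists, function(pl) {
    res <- decodeSpectrum(pl, scheme, tolerance = tolerance,
      minMatchedFraction = minMatchedFraction, mode = mode,
      ladders = ladders, maxCandidates = 2L)
    cand <- res@candidates
    data.frame(
      sourceId = pl@sourceId,
      status = res@status,
      sequence = if (res@status == "unique") cand$sequence[1] else NA_character_,
      matchedFraction = if (nrow(cand)) cand$matchedFraction[1] else NA_real_,
      nCandidates = res@nLeaders
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
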
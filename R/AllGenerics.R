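#' @rdname LibraryScheme-class
#' @param object,x a \code{LibraryScheme}
#' @export
setGeneric("variablePositions", function(x) standardGeneric("variablePositions"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("parentSequence", function(x) standardGeneric("parentSequence"))

#' @rdname PeakList-class
#' @param x a \code{PeakList}
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))

#' @rdname PeakList-class
#' @export
setGeneric("peakIntensity", function(x) standardGeneric("peakIntensity"))

#' @rdname PeakList-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname FragmentLadder-class
#' @param x a \code{FragmentLadder}
#' @export
setGeneric("bIons", function(x) standardGeneric("bIons"))

#' @rdname FragmentLadder-class
#' @export
setGeneric("yIons", function(x) standardGeneric("yIons"))

#' @rdname FragmentLadder-class
#' @export
setGeneric("parentMH", function(x) standardGeneric("parentMH"))

#' @rdname DecodingResult-class
#' @param x a \code{DecodingResult}
#' @export
setGeneric("decodingStatus", function(x) standardGeneric("decodingStatus"))

#' @rdname DecodingResult-class
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname HillFit-class
#' @param x a \code{HillFit}
#' @export
setGeneric("ec50", function(x) standardGeneric("ec50"))

#' @rdname HillFit-class
#' @export
setGeneric("hillSlope", function(x) standardGeneric("hillSlope"))

setMethod("variablePositions", "LibraryScheme", function(x) x@variablePositions)
setMethod("residueTable", "LibraryScheme", function(x) x@residues)
setMethod("librarySize", "LibraryScheme", function(x) {
  if (length(x@alphabets) == 0L) return(1L)
  as.integer(prod(lengths(x@alphabets)))
})
setMethod("parentSequence", "LibraryScheme", function(x) {
  paste(x@parentCodes, collapse = "")
})

setMethod("peakMz", "PeakList", function(x) x@mz)
setMethod("peakIntensity", "PeakList", function(x) x@intensity)
setMethod("precursorMz", "PeakList", function(x) x@precursorMz)

setMethod("bIons", "FragmentLadder", function(x) x@bIons)
setMethod("yIons", "FragmentLadder", function(x) x@yIons)
setMethod("parentMH", "FragmentLadder", function(x) x@parentMH)

setMethod("decodingStatus", "DecodingResult", function(x) x@status)
setMethod("candidates", "DecodingResult", function(x) x@candidates)

setMethod("ec50", "HillFit", function(x) x@ec50)
setMethod("hillSlope", "HillFit", function(x) x@hillSlope)

setMethod("show", "LibraryScheme", function(object) {
  np <- length(object@positionCodes)
  vp <- object@variablePositions
  cat(sprintf("LibraryScheme '%s': %d positions, %d variable (%s)\n",
    object@schemeId, np, length(vp), paste(vp, collapse = ",")))
  cat(sprintf("  library size: %d; parent: %s\n",
    librarySize(object), parentSequence(object)))
})

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s': %d peaks", object@sourceId, length(object@mz)))
  if (!is.na(object@precursorMz))
    cat(sprintf(", precursor m/z %.4f", object@precursorMz))
  cat("\n")
})

setMethod("show", "FragmentLadder", function(object) {
  cat(sprintf("FragmentLadder (%s) for %s: %d b-ions, %d y-ions, [M+H]+ %.4f\n",
    object@mode, object@sequence, length(object@bIons),
    length(object@yIons), object@parentMH))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: status %s (%d candidates scored, tol %g Da)\n",
    object@status, object@nScored, object@toleranceUsed))
  if (nrow(object@candidates))
    print(utils::head(object@candidates, 3))
})

setMethod("show", "HillFit", function(object) {
  if (object@converged) {
    cat(sprintf(
      "HillFit: EC50 %.4g, slope %.3g, bottom %.3g, top %.3g (RSS %.3g)\n",
      object@ec50, object@hillSlope, object@bottom, object@top, object@rss))
  } else {
    cat("HillFit: not converged (degenerate or insufficient data)\n")
  }
})
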
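# Scheme JSON serialization and FASTA-style sequence IO.

#' Write / read a library scheme as JSON
#'
#' Serializes positions, alphabets, parent sequence, cap deltas and the
#' residue mass table; `readSchemeJSON(writeSchemeJSON(x, p))` reproduces
#' the scheme.
#'
#' @param scheme a [LibraryScheme-class].
#' @param path file path.
#' @return `writeSchemeJSON`: invisibly `path`; `readSchemeJSON`: a
#'   [LibraryScheme-class].
#' @export
writeSchemeJSON <- function(scheme, path) {
  jsonlite::write_json(list(
    schemeId = scheme@schemeId,
    positionCodes = scheme@positionCodes,
    variablePositions = scheme@variablePositions,
    alphabets = scheme@alphabets,
    parentCodes = scheme@parentCodes,
    nTermDelta = as.list(scheme@nTermDelta),
    cTermDelta = as.list(scheme@cTermDelta),
    residues = scheme@residues
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSchemeJSON
#' @export
readSchemeJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- as.data.frame(x$residues)
  res$nominal <- as.integer(res$nominal)
  pos <- as.character(x$positionCodes)
  new("LibraryScheme",
    residues = res,
    positionCodes = pos,
    variablePositions = as.integer(x$variablePositions),
    alphabets = lapply(
      if (is.list(x$alphabets)) x$alphabets
      else apply(x$alphabets, 1, identity, simplify = FALSE),
      as.character),
    parentCodes = as.character(x$parentCodes),
    nTermDelta = unlist(x$nTermDelta)[c("nominal", "average", "monoisotopic")],
    cTermDelta = unlist(x$cTermDelta)[c("nominal", "average", "monoisotopic")],
    schemeId = x$schemeId)
}

#' Write / read sequences as FASTA
#'
#' One record per sequence (e.g., `>bead_00001` followed by the
#' 15-character canonical string), via Biostrings.
#'
#' @param seqs named character vector of canonical sequence strings (names
#'   become record ids; defaults are generated).
#' @param path file path.
#' @return `writeSequencesFASTA`: invisibly `path`; `readSequencesFASTA`: a
#'   named character vector.
#' @export
writeSequencesFASTA <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("bead_%05d", seq_along(seqs))
  bs <- Biostrings::BStringSet(unname(seqs))
  names(bs) <- ids
  Biostrings::writeXStringSet(bs, path)
  invisible(path)
}

#' @rdname writeSequencesFASTA
#' @export
readSequencesFASTA <- function(path) {
  bs <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(bs), names(bs))
}
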
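# Theoretical b/y fragment ladders.
#
# Ion conventions (singly charged, MALDI regime):
#   b_i = sum(residues 1..i) + nTermDelta + proton
#   y_j = sum(residues n-j+1..n) + water + cTermDelta + proton
#   [M+H]+ = sum(all residues) + water + both caps + proton
# In nominal mode the proton is 1 Da, so for the default scheme
# b_i = sum + 28 + 1 and y_j = sum + 61 + 1, and complementarity
# b_i + y_(n-i) = [M+H]+ + proton holds exactly in integers.

# Residue-mass matrix (n x npos) for a batch of sequences.
.residueMassMatrix <- function(seqs, scheme, mode) {
  m <- .codesMatrix(seqs, scheme)
  lut <- .massLookup(scheme, mode)
  matrix(lut[m], nrow = nrow(m))
}

#' Theoretical fragment ladder of one peptide
#'
#' Computes the singly protonated b- and y-ion series of a capped library
#' peptide. b-ions carry the N-terminal cap, y-ions the C-terminal cap, so
#' `b_i + y_(n-i) = parentMH + proton` for every cleavage site.
#'
#' @param seq canonical sequence string.
#' @param scheme a [LibraryScheme-class].
#' @param mode mass mode.
#' @return a [FragmentLadder-class].
#' @export
theoreticalLadder <- function(seq, scheme,
                              mode = c("monoisotopic", "average", "nominal")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1L)
  r <- as.vector(.residueMassMatrix(seq, scheme, mode))
  n <- length(r)
  b <- cumsum(r)[-n] + scheme@nTermDelta[[mode]] + .PROTON[[mode]]
  y <- cumsum(rev(r))[-n] + .WATER[[mode]] + scheme@cTermDelta[[mode]] +
    .PROTON[[mode]]
  mh <- sum(r) + .WATER[[mode]] + scheme@nTermDelta[[mode]] +
    scheme@cTermDelta[[mode]] + .PROTON[[mode]]
  new("FragmentLadder", sequence = seq, bIons = b, yIons = y,
    parentMH = mh, mode = mode)
}

#' Precomputed ladders for a whole library
#'
#' Builds the full ion matrix for every member of a scheme in canonical
#' enumeration order. Used by the decoder so that batch decoding does not
#' recompute ladders per spectrum.
#'
#' @param scheme a [LibraryScheme-class].
#' @param mode mass mode.
#' @return list with `sequences` (canonical order), `ions` (matrix, one row
#'   per sequence: b1..b(n-1), y1..y(n-1)), `parentMH` (numeric vector) and
#'   `mode`.
#' @export
libraryLadders <- function(scheme,
                           mode = c("monoisotopic", "average", "nominal")) {
  mode <- match.arg(mode)
  seqs <- enumerateLibrary(scheme)
  rm <- .residueMassMatrix(seqs, scheme, mode)
  n <- ncol(rm)
  cum <- rm
  for (j in 2:n) cum[, j] <- cum[, j] + cum[, j - 1L]
  total <- cum[, n]
  b <- cum[, -n, drop = FALSE] + scheme@nTermDelta[[mode]] + .PROTON[[mode]]
  # y_j = total - cum[, n-j]
  y <- total - cum[, (n - 1L):1L, drop = FALSE] + .WATER[[mode]] +
    scheme@cTermDelta[[mode]] + .PROTON[[mode]]
  mh <- total + .WATER[[mode]] + scheme@nTermDelta[[mode]] +
    scheme@cTermDelta[[mode]] + .PROTON[[mode]]
  list(sequences = seqs, ions = cbind(b, y), parentMH = mh, mode = mode)
}
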
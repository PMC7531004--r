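# Library scheme construction and mass bookkeeping.

# Residue masses (Da) of the 20 proteinogenic amino-acid residues plus
# Z = d-N-gamma-methylasparagine ("Asm", displayed N'), whose residue mass is
# Asn + CH2. Nominal masses are the monoisotopic masses rounded to integers.
.residueTable <- function() {
  tab <- data.frame(
    code = c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q",
             "K", "E", "M", "H", "F", "R", "Y", "W", "Z"),
    displayName = c("Gly", "Ala", "Ser", "Pro", "Val", "Thr", "Cys", "Leu",
                    "Ile", "Asn", "Asp", "Gln", "Lys", "Glu", "Met", "His",
                    "Phe", "Arg", "Tyr", "Trp", "Asm (N')"),
    monoisotopic = c(57.02146, 71.03711, 87.03203, 97.05276, 99.06841,
                     101.04768, 103.00919, 113.08406, 113.08406, 114.04293,
                     115.02694, 128.05858, 128.09496, 129.04259, 131.04049,
                     137.05891, 147.06841, 156.10111, 163.06333, 186.07931,
                     128.05858),
    average = c(57.0513, 71.0779, 87.0773, 97.1152, 99.1311, 101.1039,
                103.1429, 113.1576, 113.1576, 114.1026, 115.0874, 128.1292,
                128.1723, 129.1155, 131.1961, 137.1393, 147.1739, 156.1857,
                163.1733, 186.2099, 128.1292),
    stringsAsFactors = FALSE
  )
  tab$nominal <- as.integer(round(tab$monoisotopic))
  tab$hbond <- tab$code %in% c("T", "Z")
  tab[, c("code", "displayName", "nominal", "average", "monoisotopic", "hbond")]
}

#' The default gramicidin A library scheme
#'
#' Builds the 15-position gramicidin A scaffold with six variable positions
#' (residue numbers 4, 6, 8, 10, 12 and 14), each drawing from the
#' four-residue alphabet d-Leu (L), d-Val (V), d-Thr (T) and d-Asm (Z,
#' displayed N'), an N-terminal formyl cap and a C-terminal ethanolamide
#' cap. Fixed positions carry the parent residues
#' (Val-Gly-Ala-x-Ala-x-Val-x-Trp-x-Trp-x-Trp-x-Trp). The variable alphabet
#' has pairwise-distinct nominal residue masses (113, 99, 101, 128 Da), the
#' property that makes every library member identifiable from its b/y
#' fragment ladder. Chirality is carried in display names only; residue
#' masses are chirality-independent.
#'
#' @return a [LibraryScheme-class] with 4^6 = 4096 members.
#' @examples
#' sch <- defaultScheme()
#' librarySize(sch)
#' parentSequence(sch)
#' @export
defaultScheme <- function() {
  pos <- c("V", "G", "A", NA, "A", NA, "V", NA, "W", NA, "W", NA, "W", NA, "W")
  vp <- which(is.na(pos))
  alphabet <- c("L", "V", "T", "Z")
  parent <- pos
  parent[vp] <- c("L", "V", "V", "L", "L", "L")
  new("LibraryScheme",
    residues = .residueTable(),
    positionCodes = pos,
    variablePositions = as.integer(vp),
    alphabets = rep(list(alphabet), length(vp)),
    parentCodes = parent,
    nTermDelta = .FORMYL,
    cTermDelta = .ETHANOLAMIDE,
    schemeId = "gramicidinA-4096"
  )
}

# Split canonical strings into a codes matrix (n x positions).
.codesMatrix <- function(seqs, scheme) {
  n <- length(scheme@positionCodes)
  if (any(nchar(seqs) != n))
    stop("sequences must have exactly ", n, " residues")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    ncol = n, byrow = TRUE)
}

#' Validate sequences against a scheme
#'
#' Checks that fixed positions match the scaffold and that variable
#' positions draw only from their alphabet.
#'
#' @param seqs character vector of canonical sequence strings.
#' @param scheme a [LibraryScheme-class].
#' @return invisibly `TRUE`; errors on the first violation.
#' @export
validateSequence <- function(seqs, scheme) {
  m <- .codesMatrix(seqs, scheme)
  vp <- scheme@variablePositions
  fixedIdx <- setdiff(seq_along(scheme@positionCodes), vp)
  for (j in fixedIdx) {
    bad <- m[, j] != scheme@positionCodes[j]
    if (any(bad))
      stop(sprintf("fixed position %d must be '%s' (sequence %d has '%s')",
        j, scheme@positionCodes[j], which(bad)[1], m[which(bad)[1], j]))
  }
  for (k in seq_along(vp)) {
    bad <- !(m[, vp[k]] %in% scheme@alphabets[[k]])
    if (any(bad))
      stop(sprintf("position %d residue '%s' not in alphabet {%s}",
        vp[k], m[which(bad)[1], vp[k]],
        paste(scheme@alphabets[[k]], collapse = ",")))
  }
  invisible(TRUE)
}

# Named residue-mass lookup for one mode; errors on unknown codes.
.massLookup <- function(scheme, mode) {
  mode <- .checkMode(mode)
  stats::setNames(scheme@residues[[mode]], scheme@residues$code)
}

#' Peptide mass
#'
#' Mass of capped library peptides: sum of residue masses plus water plus
#' the N- and C-terminal cap deltas, in the requested mass mode. Nominal
#' mode is pure integer arithmetic.
#'
#' @param seqs character vector of canonical sequence strings.
#' @param scheme a [LibraryScheme-class].
#' @param mode `"nominal"`, `"average"` or `"monoisotopic"`.
#' @return numeric vector of masses in Da.
#' @examples
#' sch <- defaultScheme()
#' round(peptideMass(parentSequence(sch), sch, "average"))  # 1882
#' @export
peptideMass <- function(seqs, scheme, mode = c("monoisotopic", "average", "nominal")) {
  mode <- match.arg(mode)
  m <- .codesMatrix(seqs, scheme)
  lut <- .massLookup(scheme, mode)
  unknown <- setdiff(unique(as.vector(m)), names(lut))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  rs <- matrix(lut[m], nrow = nrow(m))
  rowSums(rs) + .WATER[[mode]] + scheme@nTermDelta[[mode]] +
    scheme@cTermDelta[[mode]]
}

#' Variable-position composition
#'
#' Counts each alphabet residue across the variable positions of each
#' sequence and the number of hydrogen-bond-forming residues (T and N').
#'
#' @inheritParams peptideMass
#' @return data.frame with one row per sequence: a count column per alphabet
#'   code plus `hbondCount`.
#' @examples
#' sch <- defaultScheme()
#' variableComposition(parentSequence(sch), sch)  # L=4 V=2 T=0 Z=0
#' @export
variableComposition <- function(seqs, scheme) {
  m <- .codesMatrix(seqs, scheme)
  vp <- scheme@variablePositions
  codes <- unique(unlist(scheme@alphabets))
  sub <- m[, vp, drop = FALSE]
  out <- as.data.frame(lapply(codes, function(cd) {
    rowSums(sub == cd)
  }))
  names(out) <- codes
  hb <- scheme@residues$code[scheme@residues$hbond]
  out$hbondCount <- rowSums(matrix(sub %in% hb, nrow = nrow(sub)))
  rownames(out) <- NULL
  out
}

#' Enumerate every library member
#'
#' Generates all sequences of a scheme exactly once, in canonical order: a
#' base-|alphabet| odometer over the variable positions in ascending residue
#' number, with the **last** variable position varying fastest and each
#' alphabet read in its stored order (L, V, T, Z for the default scheme).
#'
#' @param scheme a [LibraryScheme-class].
#' @return character vector of canonical sequence strings
#'   (length = product of alphabet sizes).
#' @export
enumerateLibrary <- function(scheme) {
  vp <- scheme@variablePositions
  npos <- length(scheme@positionCodes)
  total <- librarySize(scheme)
  cols <- replicate(npos, character(total), simplify = FALSE)
  for (j in seq_len(npos)) cols[[j]] <- rep(scheme@positionCodes[j], total)
  if (length(vp)) {
    sizes <- lengths(scheme@alphabets)
    idx <- 0:(total - 1)
    divisor <- rev(cumprod(rev(c(sizes[-1], 1))))
    for (k in seq_along(vp)) {
      digit <- (idx %/% divisor[k]) %% sizes[k]
      cols[[vp[k]]] <- scheme@alphabets[[k]][digit + 1L]
    }
  }
  do.call(paste0, cols)
}

#' Audit parent-mass degeneracies
#'
#' Partitions the distinct variable-position compositions of a library by
#' capped parent mass and reports every group of two or more compositions
#' whose masses coincide within `tolerance`. Parent mass alone therefore
#' does not identify a library member whenever this report is non-empty;
#' the fragment ladder is required.
#'
#' @param scheme a [LibraryScheme-class].
#' @param mode mass mode (degeneracy is usually argued in nominal units).
#' @param tolerance Da; compositions whose masses differ by at most this
#'   amount (chained) fall in one group. Use 0 for exact integer collisions.
#' @return data.frame with columns `groupId`, `composition` (e.g.
#'   `"4L+1V+1T"`), `mass`, `nSequences`; only groups of size >= 2, ordered
#'   by mass then composition.
#' @export
massDegeneracyAudit <- function(scheme, mode = "nominal", tolerance = 0) {
  mode <- .checkMode(mode)
  seqs <- enumerateLibrary(scheme)
  comp <- variableComposition(seqs, scheme)
  codes <- setdiff(names(comp), "hbondCount")
  key <- do.call(paste, c(comp[codes], list(sep = ":")))
  first <- !duplicated(key)
  compU <- comp[first, codes, drop = FALSE]
  nSeq <- as.integer(table(key)[key[first]])
  mass <- peptideMass(seqs[first], scheme, mode)
  lab <- apply(compU, 1L, function(r) {
    nz <- r > 0
    paste(sprintf("%d%s", r[nz], codes[nz]), collapse = "+")
  })
  ord <- order(mass, lab)
  mass <- mass[ord]; lab <- lab[ord]; nSeq <- nSeq[ord]
  grp <- cumsum(c(TRUE, diff(mass) > tolerance + 1e-12))
  keep <- grp %in% which(tabulate(grp) >= 2L)
  if (!any(keep)) {
    return(data.frame(groupId = integer(), composition = character(),
      mass = numeric(), nSequences = integer()))
  }
  out <- data.frame(
    groupId = match(grp[keep], unique(grp[keep])),
    composition = lab[keep],
    mass = mass[keep],
    nSequences = nSeq[keep]
  )
  rownames(out) <- NULL
  out
}
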
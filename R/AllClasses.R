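#' @import methods
NULL

#' Combinatorial peptide library scheme
#'
#' An S4 container describing a positional-scanning / split-and-mix
#' combinatorial peptide library: a fixed scaffold with a set of variable
#' positions, each drawing from a small residue alphabet, plus terminal cap
#' mass deltas in all three mass modes (nominal, average, monoisotopic).
#'
#' @slot residues data.frame of residue specifications (code, displayName,
#'   nominal, average, monoisotopic, hbond).
#' @slot positionCodes character vector, one entry per scaffold position;
#'   `NA` marks a variable position.
#' @slot variablePositions integer indices (1-based residue numbers) of the
#'   variable positions.
#' @slot alphabets list of character vectors, one alphabet per variable
#'   position, in the order of `variablePositions`.
#' @slot parentCodes character vector: the parent (wild-type) sequence.
#' @slot nTermDelta,cTermDelta named numeric length-3 vectors
#'   (nominal/average/monoisotopic) with the N- and C-terminal cap mass
#'   deltas relative to the free termini.
#' @slot schemeId character identifier.
#'
#' @seealso [defaultScheme()] for the gramicidin A library.
#' @export
setClass("LibraryScheme",
  representation(
    residues = "data.frame",
    positionCodes = "character",
    variablePositions = "integer",
    alphabets = "list",
    parentCodes = "character",
    nTermDelta = "numeric",
    cTermDelta = "numeric",
    schemeId = "character"
  )
)

setValidity("LibraryScheme", function(object) {
  msg <- character()
  n <- length(object@positionCodes)
  vp <- object@variablePositions
  if (length(object@parentCodes) != n)
    msg <- c(msg, "parentCodes must have one code per position")
  if (any(vp < 1L) || any(vp > n))
    msg <- c(msg, "variablePositions out of range")
  if (is.unsorted(vp, strictly = TRUE))
    msg <- c(msg, "variablePositions must be strictly increasing")
  if (!all(is.na(object@positionCodes[vp])))
    msg <- c(msg, "variable positions must carry NA in positionCodes")
  if (length(object@alphabets) != length(vp))
    msg <- c(msg, "one alphabet per variable position required")
  known <- object@residues$code
  fixed <- object@positionCodes[-vp]
  if (length(vp) == 0L) fixed <- object@positionCodes
  if (!all(fixed %in% known))
    msg <- c(msg, "fixed position codes missing from residue table")
  if (!all(unlist(object@alphabets) %in% known))
    msg <- c(msg, "alphabet codes missing from residue table")
  for (nm in c("nTermDelta", "cTermDelta")) {
    d <- slot(object, nm)
    if (!identical(sort(names(d)), sort(c("nominal", "average", "monoisotopic"))))
      msg <- c(msg, sprintf("%s must be named nominal/average/monoisotopic", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Centroided peak list
#'
#' A single MS/MS peak list: m/z and intensity pairs, optionally with a
#' singly protonated precursor m/z. On construction peaks are sorted by m/z
#' and exact duplicate m/z values are merged keeping the maximum intensity.
#'
#' @slot mz numeric, ascending positive m/z values.
#' @slot intensity numeric, same length as mz.
#' @slot precursorMz numeric(1), `NA` when no precursor was recorded.
#' @slot sourceId character(1) provenance label (e.g., well id).
#' @export
setClass("PeakList",
  representation(
    mz = "numeric",
    intensity = "numeric",
    precursorMz = "numeric",
    sourceId = "character"
  )
)

setValidity("PeakList", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) && any(object@mz <= 0))
    msg <- c(msg, "m/z values must be positive")
  if (is.unsorted(object@mz, strictly = TRUE) && length(object@mz) > 1)
    msg <- c(msg, "m/z values must be strictly increasing after ingest")
  if (length(object@precursorMz) != 1L)
    msg <- c(msg, "precursorMz must be length 1 (NA allowed)")
  if (length(msg)) msg else TRUE
})

#' Theoretical b/y fragment ladder
#'
#' Singly protonated b- and y-ion series of one library peptide, including
#' the terminal caps, plus the [M+H]+ parent ion.
#'
#' @slot sequence character(1) canonical sequence string.
#' @slot bIons,yIons numeric vectors (length = n residues - 1).
#' @slot parentMH numeric(1) singly protonated parent mass.
#' @slot mode one of "nominal", "average", "monoisotopic".
#' @export
setClass("FragmentLadder",
  representation(
    sequence = "character",
    bIons = "numeric",
    yIons = "numeric",
    parentMH = "numeric",
    mode = "character"
  )
)

setValidity("FragmentLadder", function(object) {
  msg <- character()
  if (is.unsorted(object@bIons, strictly = TRUE))
    msg <- c(msg, "b series must be strictly increasing")
  if (is.unsorted(object@yIons, strictly = TRUE))
    msg <- c(msg, "y series must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Result of decoding one spectrum against a library
#'
#' @slot candidates data.frame with columns sequence, matchedIonCount,
#'   matchedFraction; ranked by matchedIonCount descending with ties broken
#'   by canonical library order. Truncated to the top entries.
#' @slot status one of "unique", "ambiguous", "no_match".
#' @slot toleranceUsed numeric(1) matching tolerance in Da.
#' @slot nScored integer(1) number of library candidates scored.
#' @slot nLeaders integer(1) number of candidates attaining the top score.
#' @export
setClass("DecodingResult",
  representation(
    candidates = "data.frame",
    status = "character",
    toleranceUsed = "numeric",
    nScored = "integer",
    nLeaders = "integer"
  )
)

setValidity("DecodingResult", function(object) {
  if (!object@status %in% c("unique", "ambiguous", "no_match"))
    return("status must be unique/ambiguous/no_match")
  TRUE
})

#' Hill dose-response fit
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + (ec50 / conc)^slope)` (response increasing with concentration).
#'
#' @slot ec50 numeric(1) midpoint concentration (same units as the data).
#' @slot hillSlope numeric(1).
#' @slot top,bottom numeric(1) plateau responses (%).
#' @slot rss numeric(1) residual sum of squares.
#' @slot converged logical(1); `FALSE` for degenerate data.
#' @slot data data.frame(conc, response) used for the fit.
#' @export
setClass("HillFit",
  representation(
    ec50 = "numeric",
    hillSlope = "numeric",
    top = "numeric",
    bottom = "numeric",
    rss = "numeric",
    converged = "logical",
    data = "data.frame"
  )
)

#' Latent activity model parameters for the synthetic screen
#'
#' Rule-based generative model tying a peptide's variable-position
#' composition to its three assay readouts. This is a test harness, not a
#' biophysical claim: parameters are calibrated so the generated screens
#' carry the qualitative structure the classifier must recover (transport
#' activity collapses beyond two hydrogen-bonding residues, cytotoxicity
#' tracks aliphatic content, antibacterial activity rates differ sharply
#' between the cytotoxic group and the B subgroups).
#'
#' @slot transportBase base relative transport activity entering the
#'   hydrogen-bond penalty for sequences with 3+ T/N' residues.
#' @slot transportPenalty multiplicative decay per hydrogen-bonding residue
#'   beyond two.
#' @slot transportPositiveProb named numeric: probability that a sequence
#'   with 0/1/2 hydrogen-bonding residues is transport-positive
#'   (relative activity >= 1).
#' @slot cytotoxLWeight,cytotoxVWeight,cytotoxIntercept logistic-model
#'   coefficients for the probability that an all-aliphatic transport
#'   positive sequence is cytotoxic (P388 viability below threshold).
#' @slot abxActiveProb named numeric: probability of antibacterial activity
#'   by latent class (Alike, B0, B1, B2).
#' @slot potencyWeights named numeric: conditional distribution of the
#'   potency code (+++/++/+) given antibacterial activity.
#' @export
setClass("LatentActivityParams",
  representation(
    transportBase = "numeric",
    transportPenalty = "numeric",
    transportPositiveProb = "numeric",
    cytotoxLWeight = "numeric",
    cytotoxVWeight = "numeric",
    cytotoxIntercept = "numeric",
    abxActiveProb = "numeric",
    potencyWeights = "numeric"
  )
)

setValidity("LatentActivityParams", function(object) {
  msg <- character()
  p <- c(object@transportPositiveProb, object@abxActiveProb)
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!all(c("h0", "h1", "h2") %in% names(object@transportPositiveProb)))
    msg <- c(msg, "transportPositiveProb needs h0/h1/h2")
  if (!all(c("Alike", "B0", "B1", "B2") %in% names(object@abxActiveProb)))
    msg <- c(msg, "abxActiveProb needs Alike/B0/B1/B2")
  if (length(msg)) msg else TRUE
})

#' Synthetic screen generator configuration
#'
#' @slot nBeads number of beads drawn (default 13584, the full screen).
#' @slot seed integer RNG seed; config + seed fully determine the dataset.
#' @slot peakDeletionRate per-fragment Bernoulli deletion probability.
#' @slot mzNoiseSd Gaussian m/z jitter (Da).
#' @slot assayNoiseSd Gaussian assay noise (% points).
#' @slot parentRaw raw fluorescence change (%) of the parent control well.
#' @slot massMode mass mode used for simulated spectra.
#' @slot activity a [LatentActivityParams-class] object.
#' @export
setClass("GeneratorConfig",
  representation(
    nBeads = "integer",
    seed = "integer",
    peakDeletionRate = "numeric",
    mzNoiseSd = "numeric",
    assayNoiseSd = "numeric",
    parentRaw = "numeric",
    massMode = "character",
    activity = "LatentActivityParams"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nBeads < 0L) msg <- c(msg, "nBeads must be >= 0")
  if (object@peakDeletionRate < 0 || object@peakDeletionRate > 1)
    msg <- c(msg, "peakDeletionRate must lie in [0, 1]")
  if (object@mzNoiseSd < 0 || object@assayNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (!object@massMode %in% c("nominal", "average", "monoisotopic"))
    msg <- c(msg, "massMode must be nominal/average/monoisotopic")
  if (length(msg)) msg else TRUE
})
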
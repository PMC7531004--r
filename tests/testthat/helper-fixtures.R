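# Shared fixtures: schemes and small generator configs built in code.

fixtureScheme <- function() defaultScheme()

# A reduced scheme with a single variable position, for edge cases.
singleVariableScheme <- function() {
  sch <- defaultScheme()
  vp <- sch@variablePositions
  keep <- 1L
  fixed <- sch@parentCodes
  fixed[vp[keep]] <- NA
  methods::new("LibraryScheme",
    residues = sch@residues,
    positionCodes = fixed,
    variablePositions = vp[keep],
    alphabets = sch@alphabets[keep],
    parentCodes = sch@parentCodes,
    nTermDelta = sch@nTermDelta,
    cTermDelta = sch@cTermDelta,
    schemeId = "gramicidinA-1var")
}

# A scheme with no variable positions (scaffold only).
fixedOnlyScheme <- function() {
  sch <- defaultScheme()
  methods::new("LibraryScheme",
    residues = sch@residues,
    positionCodes = sch@parentCodes,
    variablePositions = integer(),
    alphabets = list(),
    parentCodes = sch@parentCodes,
    nTermDelta = sch@nTermDelta,
    cTermDelta = sch@cTermDelta,
    schemeId = "gramicidinA-fixed")
}

noiselessConfig <- function(nBeads = 50, seed = 1) {
  generatorConfig(nBeads = nBeads, seed = seed, peakDeletionRate = 0,
    mzNoiseSd = 0, assayNoiseSd = 0)
}

# Independent brute-force oracle: all variable-position compositions of a
# common-alphabet scheme as a matrix of counts (one row per composition).
bruteForceCompositions <- function(nSlots = 6, nSymbols = 4) {
  grid <- expand.grid(rep(list(seq_len(nSymbols)), nSlots))
  counts <- t(apply(grid, 1, tabulate, nbins = nSymbols))
  unique(counts)
}
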
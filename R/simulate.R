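# Synthetic OBOC screen generator: bead draws, fragment spectra and
# three-assay readouts from a seeded, rule-based latent activity model.
# Every generated quantity is stored as ground truth so each pipeline
# stage can be scored exactly.

#' Latent activity model parameters
#'
#' Constructor with defaults calibrated once to the screen-level statistics
#' the model must reproduce qualitatively: transport activity is common for
#' all-aliphatic sequences, rarer with one or two hydrogen-bonding residues
#' (per-sequence positive probabilities 1.00 / 0.54 / 0.039) and collapses
#' deterministically below the activity threshold for three or more;
#' cytotoxicity among transport-positive all-aliphatic sequences follows a
#' logistic model in Leu/Val counts; antibacterial activity probabilities
#' by class default to 0.76 (cytotoxic A-like), 0.97 (B0), 0.17 (B1) and
#' 0.03 (B2).
#'
#' @param transportBase,transportPenalty relative transport activity of a
#'   sequence with `h >= 3` hydrogen-bonding residues is
#'   `transportBase * transportPenalty^(h - 2)` (below 1 for the defaults).
#' @param transportPositiveProb named (h0/h1/h2) Bernoulli probabilities.
#' @param cytotoxLWeight,cytotoxVWeight,cytotoxIntercept logistic
#'   coefficients on the Leu and Val counts.
#' @param abxActiveProb named (Alike/B0/B1/B2) activity probabilities.
#' @param potencyWeights conditional potency-code distribution for active
#'   compounds.
#' @return a [LatentActivityParams-class].
#' @export
latentActivityParams <- function(
    transportBase = 1.5,
    transportPenalty = 0.5,
    transportPositiveProb = c(h0 = 1.00, h1 = 0.54, h2 = 0.039),
    cytotoxLWeight = 0.35,
    cytotoxVWeight = 0.10,
    cytotoxIntercept = -1.8,
    abxActiveProb = c(Alike = 0.76, B0 = 0.97, B1 = 0.17, B2 = 0.03),
    potencyWeights = c("+++" = 0.25, "++" = 0.40, "+" = 0.35)) {
  new("LatentActivityParams",
    transportBase = transportBase,
    transportPenalty = transportPenalty,
    transportPositiveProb = transportPositiveProb,
    cytotoxLWeight = cytotoxLWeight,
    cytotoxVWeight = cytotoxVWeight,
    cytotoxIntercept = cytotoxIntercept,
    abxActiveProb = abxActiveProb,
    potencyWeights = potencyWeights)
}

#' Synthetic screen generator configuration
#'
#' @param nBeads number of beads drawn (default 13584, the full screen).
#' @param seed integer RNG seed.
#' @param peakDeletionRate per-fragment deletion probability.
#' @param mzNoiseSd Gaussian m/z jitter in Da.
#' @param assayNoiseSd Gaussian assay noise in percentage points.
#' @param parentRaw raw fluorescence change (%) of the parent control.
#' @param massMode mass mode for simulated spectra.
#' @param activity a [LatentActivityParams-class].
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(nBeads = 13584, seed = 1, peakDeletionRate = 0,
                            mzNoiseSd = 0, assayNoiseSd = 0,
                            parentRaw = 55.2, massMode = "monoisotopic",
                            activity = latentActivityParams()) {
  new("GeneratorConfig",
    nBeads = as.integer(nBeads), seed = as.integer(seed),
    peakDeletionRate = peakDeletionRate, mzNoiseSd = mzNoiseSd,
    assayNoiseSd = assayNoiseSd, parentRaw = parentRaw,
    massMode = massMode, activity = activity)
}

# Draw the per-sequence latent truth for the entire library. Consumes RNG
# state; callers set the seed. The parent sequence is pinned: transport 1.1,
# cytotoxic, potency "++" (it is the screen's positive control).
.latentLibraryTruth <- function(scheme, params) {
  seqs <- enumerateLibrary(scheme)
  comp <- variableComposition(seqs, scheme)
  h <- comp$hbondCount
  n <- length(seqs)
  nL <- if ("L" %in% names(comp)) comp$L else integer(n)
  nV <- if ("V" %in% names(comp)) comp$V else integer(n)

  pPos <- rep(0, n)
  pPos[h == 0L] <- params@transportPositiveProb[["h0"]]
  pPos[h == 1L] <- params@transportPositiveProb[["h1"]]
  pPos[h == 2L] <- params@transportPositiveProb[["h2"]]
  positive <- stats::runif(n) < pPos
  positive[h >= 3L] <- FALSE

  transportTrue <- numeric(n)
  transportTrue[positive] <- stats::runif(sum(positive), 1.05, 2.2)
  low <- !positive & h <= 2L
  transportTrue[low] <- stats::runif(sum(low), 0.2, 0.95)
  hi3 <- h >= 3L
  transportTrue[hi3] <- params@transportBase *
    params@transportPenalty^(h[hi3] - 2L)

  pTox <- ifelse(h == 0L,
    stats::plogis(params@cytotoxLWeight * nL + params@cytotoxVWeight * nV +
      params@cytotoxIntercept), 0)
  toxic <- stats::runif(n) < pTox
  viabilityTrue <- numeric(n)
  viabilityTrue[toxic] <- stats::runif(sum(toxic), 5, 15)
  viabilityTrue[!toxic] <- stats::runif(sum(!toxic), 55, 90)

  abxClass <- rep("none", n)
  abxClass[positive & toxic] <- "Alike"
  abxClass[positive & !toxic] <- paste0("B", pmin(h[positive & !toxic], 3L))
  pAct <- rep(0, n)
  for (cl in c("Alike", "B0", "B1", "B2"))
    pAct[abxClass == cl] <- params@abxActiveProb[[cl]]
  active <- stats::runif(n) < pAct
  potency <- rep("-", n)
  nAct <- sum(active)
  if (nAct)
    potency[active] <- sample(names(params@potencyWeights), nAct,
      replace = TRUE, prob = params@potencyWeights)

  truth <- data.frame(
    sequence = seqs, hbondCount = h, nL = nL, nV = nV,
    transportTrue = transportTrue, viabilityTrue = viabilityTrue,
    potencyTrue = potency, stringsAsFactors = FALSE)

  ip <- match(parentSequence(scheme), seqs)
  truth$transportTrue[ip] <- 1.1
  truth$viabilityTrue[ip] <- 10
  truth$potencyTrue[ip] <- "++"

  truth$groupTrue <- as.character(assignGroup(truth$transportTrue,
    truth$viabilityTrue))
  truth$subgroupTrue <- "n/a"
  isB <- truth$groupTrue == "B"
  truth$subgroupTrue[isB] <- assignSubgroup(truth$groupTrue[isB],
    truth$hbondCount[isB])
  truth
}

#' Sample beads from a library
#'
#' Independent uniform draws with replacement from the enumerated library
#' (the split-and-mix occupancy model).
#'
#' @param scheme a [LibraryScheme-class].
#' @param config a [GeneratorConfig-class]; `nBeads` and `seed` are used.
#' @return data.frame with `beadId` and `sequence`.
#' @export
sampleBeads <- function(scheme, config) {
  set.seed(config@seed)
  seqs <- enumerateLibrary(scheme)
  n <- config@nBeads
  if (n == 0L)
    return(data.frame(beadId = character(), sequence = character()))
  idx <- sample.int(length(seqs), n, replace = TRUE)
  data.frame(beadId = sprintf("bead_%05d", seq_len(n)),
    sequence = seqs[idx], stringsAsFactors = FALSE)
}

#' Simulate one MS/MS spectrum
#'
#' Emits the theoretical b/y ladder plus the precursor ion, deletes each
#' fragment peak independently with `peakDeletionRate`, and jitters every
#' m/z with Gaussian noise of sd `mzNoiseSd`. The precursor is never
#' deleted. Which fragment peaks were kept is recorded in the `"kept"`
#' attribute (the bookkeeping used as decoding oracle).
#'
#' @param seq canonical sequence string.
#' @param scheme a [LibraryScheme-class].
#' @param config a [GeneratorConfig-class].
#' @param sourceId label stored on the peak list.
#' @param seed optional seed; `NULL` (default) uses the current RNG
#'   stream, which is how [generateScreen()] keeps a single seeded stream.
#' @return a [PeakList-class] with attribute `kept` (logical per fragment).
#' @export
simulateSpectrum <- function(seq, scheme, config, sourceId = seq,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lad <- theoreticalLadder(seq, scheme, mode = config@massMode)
  theo <- c(lad@bIons, lad@yIons)
  kept <- stats::runif(length(theo)) >= config@peakDeletionRate
  mz <- theo[kept]
  if (config@mzNoiseSd > 0 && length(mz))
    mz <- mz + stats::rnorm(length(mz), 0, config@mzNoiseSd)
  prec <- lad@parentMH
  if (config@mzNoiseSd > 0)
    prec <- prec + stats::rnorm(1, 0, config@mzNoiseSd)
  pl <- PeakList(c(mz, prec),
    intensity = c(rep(100, length(mz)), 300),
    precursorMz = prec, sourceId = sourceId)
  attr(pl, "kept") <- kept
  pl
}

#' Simulate the three assay readouts for a set of wells
#'
#' Draws raw transport fluorescence, P388 viability and the three dilution
#' flags from the latent truth plus Gaussian assay noise. Dilution flags
#' derive deterministically from the true potency code, so they are always
#' monotone in dilution.
#'
#' @param truthRows rows of the latent truth table (one per well).
#' @param config a [GeneratorConfig-class].
#' @return data.frame of well readouts (`transport_raw`,
#'   `parent_transport_raw`, `viability_pct`, `abx640`, `abx160`, `abx40`).
#' @export
simulateAssays <- function(truthRows, config) {
  n <- nrow(truthRows)
  noise <- function() if (config@assayNoiseSd > 0)
    stats::rnorm(n, 0, config@assayNoiseSd) else numeric(n)
  transportRaw <- truthRows$transportTrue * config@parentRaw + noise()
  viability <- pmin(pmax(truthRows$viabilityTrue + noise(), 0), 120)
  pot <- truthRows$potencyTrue
  data.frame(
    transport_raw = transportRaw,
    parent_transport_raw = config@parentRaw,
    viability_pct = viability,
    abx640 = pot == "+++",
    abx160 = pot %in% c("+++", "++"),
    abx40 = pot %in% c("+++", "++", "+")
  )
}

#' Generate a complete synthetic screen
#'
#' Runs the whole generative model under one seeded RNG stream: latent
#' per-sequence truth, bead draws, per-well spectra and assay readouts.
#' With `outdir` set, writes `plates.csv`, `screen.mgf` and `truth.json`
#' (all with fixed number formatting, so identical config + seed gives
#' byte-identical files); otherwise returns everything in memory.
#'
#' @param scheme a [LibraryScheme-class].
#' @param config a [GeneratorConfig-class].
#' @param outdir output directory, or `NULL` for in-memory results.
#' @return (invisibly when writing) a list with `plates` (well table),
#'   `spectra` (list of [PeakList-class]), `truth` (per-well ground truth),
#'   `libraryTruth` (per-sequence latent table) and `files` (paths, when
#'   written).
#' @export
generateScreen <- function(scheme, config, outdir = NULL) {
  set.seed(config@seed)
  libTruth <- .latentLibraryTruth(scheme, config@activity)
  n <- config@nBeads
  idx <- if (n > 0L)
    sample.int(nrow(libTruth), n, replace = TRUE) else integer()
  wellIds <- sprintf("well_%05d", seq_len(n))
  truthRows <- libTruth[idx, , drop = FALSE]
  rownames(truthRows) <- NULL

  spectra <- vector("list", n)
  for (i in seq_len(n))
    spectra[[i]] <- simulateSpectrum(truthRows$sequence[i], scheme, config,
      sourceId = wellIds[i])
  names(spectra) <- wellIds

  assays <- simulateAssays(truthRows, config)
  plates <- cbind(data.frame(well_id = wellIds), assays)

  truth <- cbind(data.frame(well_id = wellIds), truthRows)

  out <- list(plates = plates, spectra = spectra, truth = truth,
    libraryTruth = libTruth)
  if (is.null(outdir)) return(out)

  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  platesPath <- file.path(outdir, "plates.csv")
  mgfPath <- file.path(outdir, "screen.mgf")
  truthPath <- file.path(outdir, "truth.json")
  platesOut <- plates
  platesOut$transport_raw <- sprintf("%.4f", platesOut$transport_raw)
  platesOut$viability_pct <- sprintf("%.4f", platesOut$viability_pct)
  platesOut$parent_transport_raw <- sprintf("%.4f",
    platesOut$parent_transport_raw)
  utils::write.csv(platesOut, platesPath, row.names = FALSE, quote = FALSE)
  writeMGF(spectra, mgfPath)
  truthOut <- truth
  truthOut$transportTrue <- round(truthOut$transportTrue, 6)
  truthOut$viabilityTrue <- round(truthOut$viabilityTrue, 6)
  jsonlite::write_json(
    list(
      generator = list(nBeads = config@nBeads, seed = config@seed,
        peakDeletionRate = config@peakDeletionRate,
        mzNoiseSd = config@mzNoiseSd, assayNoiseSd = config@assayNoiseSd,
        massMode = config@massMode),
      wells = truthOut),
    truthPath, auto_unbox = TRUE, digits = NA)
  out$files <- c(plates = platesPath, mgf = mgfPath, truth = truthPath)
  invisible(out)
}
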
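# Five-stage screen triage: transport normalization, group assignment by
# P388 viability, antibacterial potency coding, deduplication to unique
# compounds, hydrogen-bond subgrouping and representative selection.

.GROUP_LEVELS <- c("A", "B", "gap", "transport_negative")
.POTENCY_LEVELS <- c("-", "+", "++", "+++")

#' Normalize transport activity against the parent control
#'
#' @param raw raw fluorescence change (%) of the test well.
#' @param parentRaw raw fluorescence change (%) of the parent control well
#'   on the same plate (must be > 0).
#' @return unitless relative transport activity; the parent normalizes to
#'   exactly 1.
#' @export
normalizeTransport <- function(raw, parentRaw) {
  if (any(!is.finite(parentRaw)) || any(parentRaw <= 0))
    stop("parentRaw must be > 0 (bad plate control)")
  raw / parentRaw
}

#' Assign screen group labels
#'
#' Wells with relative transport activity below 1 are `transport_negative`
#' regardless of viability. Transport-positive wells are split by P388
#' viability: `A` (viability <= 20%, more cytotoxic), `B` (viability >= 30%,
#' less cytotoxic), and `gap` for the deliberate (20, 30)% buffer between
#' the two thresholds.
#'
#' @param transport relative transport activity (see [normalizeTransport()]).
#' @param viability P388 viability in %.
#' @param wellId optional ids used in error messages.
#' @return factor with levels A, B, gap, transport_negative.
#' @export
assignGroup <- function(transport, viability, wellId = seq_along(transport)) {
  stopifnot(length(transport) == length(viability))
  pos <- transport >= 1
  bad <- pos & !is.finite(viability)
  if (any(bad))
    stop("missing viability on transport-positive well(s): ",
      paste(wellId[bad], collapse = ", "))
  out <- rep("transport_negative", length(transport))
  out[pos & viability <= 20] <- "A"
  out[pos & viability >= 30] <- "B"
  out[pos & viability > 20 & viability < 30] <- "gap"
  factor(out, levels = .GROUP_LEVELS)
}

#' Code antibacterial potency from dilution flags
#'
#' Growth inhibition is tested at three dilutions of the bead stock; the
#' code is set by the highest dilution still inhibiting: `+++` at 640-fold,
#' `++` at 160-fold, `+` at 40-fold, `-` for no inhibition. Inconsistent
#' flag patterns (inhibition at a higher dilution but not a lower one) are
#' repaired to the highest inhibiting dilution with a warning.
#'
#' @param abx640,abx160,abx40 logical vectors: inhibition at the 640-, 160-
#'   and 40-fold dilutions.
#' @return ordered factor `-` < `+` < `++` < `+++`.
#' @export
antibacterialCode <- function(abx640, abx160, abx40) {
  stopifnot(length(abx640) == length(abx160),
            length(abx160) == length(abx40))
  inconsistent <- (abx640 & !(abx160 & abx40)) | (abx160 & !abx40)
  if (any(inconsistent, na.rm = TRUE))
    warning(sum(inconsistent, na.rm = TRUE),
      " well(s) with inconsistent dilution flags; coded by the highest",
      " inhibiting dilution")
  code <- ifelse(abx640, "+++", ifelse(abx160, "++", ifelse(abx40, "+", "-")))
  factor(code, levels = .POTENCY_LEVELS, ordered = TRUE)
}

#' Screening concentration from stock and fold dilution
#'
#' @param stockuM stock concentration in micromolar (> 0).
#' @param fold dilution factor (>= 1).
#' @return concentration in nM, rounded half-up to 2 significant figures
#'   (15 uM at 640/160/40-fold gives 23/94/380 nM).
#' @export
screeningConcentration <- function(stockuM, fold) {
  if (any(stockuM <= 0)) stop("stock concentration must be > 0")
  if (any(fold < 1)) stop("fold dilution must be >= 1")
  signifHalfUp(stockuM * 1000 / fold, 2)
}

#' Assign hydrogen-bond subgroups within group B
#'
#' @param group group labels (all must be `"B"`).
#' @param hbondCount number of hydrogen-bond-forming residues (T + N') at
#'   the variable positions.
#' @return character vector `"B0"`, `"B1"`, `"B2"`, or `"B3plus"` for three
#'   or more T/N' residues (handled although never observed among real
#'   screen hits).
#' @export
assignSubgroup <- function(group, hbondCount) {
  if (any(as.character(group) != "B"))
    stop("subgroups are defined only for group B records")
  ifelse(hbondCount >= 3L, "B3plus", paste0("B", hbondCount))
}

#' Deduplicate wells into unique compounds
#'
#' Collapses uniquely decoded group-A/B wells to one record per distinct
#' sequence. Group consensus: a compound is `A` if any contributing well is
#' A, else `B`. Ambiguously decoded or undecoded wells never contribute;
#' they are tallied in the `report` attribute, as are transport-negative
#' and gap wells.
#'
#' @param wells data.frame with columns `wellId`, `sequence`, `status`
#'   (decoding status), `group` (from [assignGroup()]), `potency` (ordered
#'   factor from [antibacterialCode()]).
#' @param scheme a [LibraryScheme-class] (for composition and the parent
#'   flag).
#' @return data.frame with one row per compound: `sequence`,
#'   `appearanceFrequency`, `group`, `subgroup` (`"n/a"` outside group B),
#'   `bestPotency`, `nActiveWells` (wells coded at least `+`), `hbondCount`,
#'   `isParent`; attribute `report` carries the per-stage tallies.
#' @export
deduplicateWells <- function(wells, scheme) {
  needed <- c("wellId", "sequence", "status", "group", "potency")
  if (!all(needed %in% names(wells)))
    stop("wells must have columns: ", paste(needed, collapse = ", "))
  grp <- as.character(wells$group)
  report <- list(
    nWells = nrow(wells),
    nTransportNegative = sum(grp == "transport_negative"),
    nGap = sum(grp == "gap"),
    nGroupAWells = sum(grp == "A"),
    nGroupBWells = sum(grp == "B"),
    nAmbiguous = sum(grp %in% c("A", "B") & wells$status == "ambiguous"),
    nNoMatch = sum(grp %in% c("A", "B") & wells$status == "no_match")
  )
  use <- wells[grp %in% c("A", "B") & wells$status == "unique", ]
  if (!nrow(use)) {
    out <- data.frame(sequence = character(), appearanceFrequency = integer(),
      group = character(), subgroup = character(),
      bestPotency = factor(character(), levels = .POTENCY_LEVELS, ordered = TRUE),
      nActiveWells = integer(), hbondCount = integer(), isParent = logical())
    attr(out, "report") <- report
    return(out)
  }
  pot <- factor(as.character(use$potency), levels = .POTENCY_LEVELS,
    ordered = TRUE)
  sp <- split(seq_len(nrow(use)), use$sequence)
  seqs <- names(sp)
  out <- data.frame(
    sequence = seqs,
    appearanceFrequency = lengths(sp),
    group = vapply(sp, function(i)
      if (any(use$group[i] == "A")) "A" else "B", character(1)),
    bestPotency = factor(.POTENCY_LEVELS[vapply(sp, function(i)
      max(as.integer(pot[i])), integer(1))],
      levels = .POTENCY_LEVELS, ordered = TRUE),
    nActiveWells = vapply(sp, function(i)
      sum(as.integer(pot[i]) >= 2L), integer(1))
  )
  comp <- variableComposition(out$sequence, scheme)
  out$hbondCount <- comp$hbondCount
  out$subgroup <- "n/a"
  isB <- out$group == "B"
  out$subgroup[isB] <- assignSubgroup(out$group[isB], out$hbondCount[isB])
  out$isParent <- out$sequence == parentSequence(scheme)
  out <- out[, c("sequence", "appearanceFrequency", "group", "subgroup",
    "bestPotency", "nActiveWells", "hbondCount", "isParent")]
  rownames(out) <- NULL
  report$nUniqueCompounds <- nrow(out)
  report$nGroupACompounds <- sum(out$group == "A")
  report$nGroupBCompounds <- sum(out$group == "B")
  report$subgroupCounts <- table(out$subgroup[isB])
  attr(out, "report") <- report
  out
}

#' Select representative compounds
#'
#' Applies the three selection rules used to pick follow-up compounds:
#' \enumerate{
#'   \item group-A compounds (excluding the parent itself) whose best
#'     antibacterial code is strictly greater than the parent's;
#'   \item subgroup B0/B1 compounds found antibacterial-active (code at
#'     least `+`) in three or more wells and never seen in a group-A well;
#'   \item subgroup B2 compounds with appearance frequency of three or more.
#' }
#' The three sets are reported separately; no overall size is forced.
#'
#' @param compounds output of [deduplicateWells()].
#' @param parentPotency the parent compound's antibacterial code
#'   (character or ordered factor).
#' @return list with `ruleA`, `ruleB01`, `ruleB2` (character vectors of
#'   sequences) and `table` (the compounds table with three logical
#'   selection columns added).
#' @export
selectRepresentatives <- function(compounds, parentPotency = "++") {
  pp <- factor(as.character(parentPotency), levels = .POTENCY_LEVELS,
    ordered = TRUE)
  tab <- compounds
  tab$selRuleA <- tab$group == "A" & !tab$isParent & tab$bestPotency > pp
  # consensus group B already implies no group-A well
  tab$selRuleB01 <- tab$group == "B" & tab$subgroup %in% c("B0", "B1") &
    tab$nActiveWells >= 3L
  tab$selRuleB2 <- tab$group == "B" & tab$subgroup == "B2" &
    tab$appearanceFrequency >= 3L
  list(
    ruleA = tab$sequence[tab$selRuleA],
    ruleB01 = tab$sequence[tab$selRuleB01],
    ruleB2 = tab$sequence[tab$selRuleB2],
    table = tab
  )
}

#' Run the full classification stage on plate and decoder tables
#'
#' Joins plate assay readouts with decoded sequences, normalizes transport,
#' assigns groups and potency codes, deduplicates to compounds and builds a
#' run report.
#'
#' @param plates data.frame with columns `well_id`, `transport_raw`,
#'   `parent_transport_raw`, `viability_pct`, `abx640`, `abx160`, `abx40`.
#' @param decoded data.frame from [decodeSpectra()] (`sourceId`, `status`,
#'   `sequence`).
#' @param scheme a [LibraryScheme-class].
#' @return list with `wells` (annotated well table), `compounds`
#'   (deduplicated, subgrouped, potency-coded) and `report` (stage tallies,
#'   JSON-serializable).
#' @export
classifyScreen <- function(plates, decoded, scheme) {
  needed <- c("well_id", "transport_raw", "parent_transport_raw",
    "viability_pct", "abx640", "abx160", "abx40")
  if (!all(needed %in% names(plates)))
    stop("plates must have columns: ", paste(needed, collapse = ", "))
  wells <- data.frame(
    wellId = plates$well_id,
    transportRelative = normalizeTransport(plates$transport_raw,
      plates$parent_transport_raw),
    viability = plates$viability_pct
  )
  wells$group <- assignGroup(wells$transportRelative, wells$viability,
    wells$wellId)
  wells$potency <- antibacterialCode(plates$abx640, plates$abx160,
    plates$abx40)
  m <- match(wells$wellId, decoded$sourceId)
  wells$status <- decoded$status[m]
  wells$sequence <- decoded$sequence[m]
  wells$status[is.na(wells$status)] <- "no_match"
  compounds <- deduplicateWells(wells, scheme)
  report <- attr(compounds, "report")
  report$nTransportPositive <- sum(wells$transportRelative >= 1)
  list(wells = wells, compounds = compounds, report = report)
}
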
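# SAR statistics: residue composition per group, percent-active,
# microdilution MIC calling, fold changes and activity-profile tables.

#' Residue composition per group
#'
#' For each group of sequences, the percentage of each alphabet residue
#' across all variable positions of all member sequences:
#' `100 * count(residue) / (nVariablePositions * nCompounds)`, rounded
#' half-up to integers.
#'
#' @param groups named list mapping group label to a character vector of
#'   sequences.
#' @param scheme a [LibraryScheme-class].
#' @return data.frame with one row per group: `group`, `nCompounds`, one
#'   integer percentage column per alphabet code. Empty groups give an
#'   all-zero row.
#' @examples
#' sch <- defaultScheme()
#' groupComposition(list(parent = parentSequence(sch)), sch)  # L 67, V 33
#' @export
groupComposition <- function(groups, scheme) {
  codes <- unique(unlist(scheme@alphabets))
  nv <- length(scheme@variablePositions)
  rows <- lapply(names(groups), function(g) {
    seqs <- groups[[g]]
    n <- length(seqs)
    pct <- stats::setNames(rep(0, length(codes)), codes)
    if (n > 0) {
      comp <- variableComposition(seqs, scheme)
      tot <- colSums(comp[, codes, drop = FALSE])
      pct[] <- roundHalfUp(100 * tot / (nv * n))
    }
    cbind(data.frame(group = g, nCompounds = n), as.data.frame(as.list(pct)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent of compounds with antibacterial activity
#'
#' A compound counts as active when one or more of its wells was active in
#' the antibacterial assay (code at least `+`).
#'
#' @param compounds data.frame with an `nActiveWells` column (e.g., from
#'   [deduplicateWells()]).
#' @return integer percentage (rounded half-up); `NA` for empty input.
#' @export
percentActive <- function(compounds) {
  if (nrow(compounds) == 0L) {
    message("percentActive: no compounds (n/a)")
    return(NA_real_)
  }
  roundHalfUp(100 * mean(compounds$nActiveWells >= 1L))
}

#' MIC from a twofold microdilution series
#'
#' The MIC is the lowest concentration showing no growth. Growth at every
#' concentration censors the value upward (`> max`); no growth anywhere
#' censors it downward (`<= min`). A non-monotone growth pattern (growth
#' above a no-growth concentration) is resolved to the lowest no-growth
#' concentration above the highest growth concentration, with a warning.
#'
#' @param conc concentrations, strictly decreasing (twofold series).
#' @param growth logical: visible growth at each concentration.
#' @return list with `mic` (numeric), `censored` (`"none"`, `"gt"` or
#'   `"le"`) and `label` (e.g. `"8"`, `">64"`, `"<=4"`).
#' @export
micFromDilutions <- function(conc, growth) {
  stopifnot(length(conc) == length(growth))
  if (is.unsorted(rev(conc), strictly = TRUE))
    stop("concentrations must be strictly decreasing")
  if (all(growth))
    return(list(mic = max(conc), censored = "gt",
      label = paste0(">", format(max(conc)))))
  if (!any(growth))
    return(list(mic = min(conc), censored = "le",
      label = paste0("<=", format(min(conc)))))
  # monotone pattern along decreasing concentration is F..FT..T; a
  # no-growth well below a growth well breaks it
  if (any(diff(growth) < 0))
    warning("non-monotone growth pattern; MIC set to lowest no-growth ",
      "concentration above the highest growth concentration")
  highestGrowth <- max(conc[growth])
  candidate <- conc[!growth & conc > highestGrowth]
  if (!length(candidate))
    return(list(mic = max(conc), censored = "gt",
      label = paste0(">", format(max(conc)))))
  mic <- min(candidate)
  list(mic = mic, censored = "none", label = format(mic))
}

#' Fold change between two activity values
#'
#' @param numerator,denominator positive values (e.g., two EC50s).
#' @param rounding `"auto"` (default): ratios >= 1 round half-up to the
#'   nearest integer, ratios < 1 to 2 significant figures (the convention
#'   used when reporting "28-fold" alongside "0.29-fold");
#'   `"integer"`, `"signif2"` or `"none"` force one rule.
#' @param numeratorCensored,denominatorCensored logical censor flags; a
#'   censored operand yields `NA` with attributes `censored = TRUE` and
#'   `direction` instead of a silently wrong number.
#' @return numeric fold change (possibly with censor attributes).
#' @export
foldChange <- function(numerator, denominator,
                       rounding = c("auto", "integer", "signif2", "none"),
                       numeratorCensored = FALSE,
                       denominatorCensored = FALSE) {
  rounding <- match.arg(rounding)
  if (numeratorCensored || denominatorCensored) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    attr(out, "direction") <- if (numeratorCensored) "ge" else "le"
    warning("fold change involves a censored operand; returning NA with ",
      "direction flag")
    return(out)
  }
  if (denominator <= 0) stop("denominator must be > 0")
  f <- numerator / denominator
  switch(rounding,
    none = f,
    integer = roundHalfUp(f),
    signif2 = signifHalfUp(f, 2),
    auto = if (f >= 1) roundHalfUp(f) else signifHalfUp(f, 2))
}

#' Ranked activity-profile table
#'
#' Orders compound activity profiles the way screen summaries are
#' presented: groups in the order A, B0, B1, B2, and within each group by
#' increasing IC50 (most cytotoxic first) with censored IC50 values last.
#' Censored measurements must be flagged, never silently numeric.
#'
#' @param profiles data.frame with at least `id`, `group` (A/B0/B1/B2) and
#'   `ic50`; optional logical `ic50Censored` (default all `FALSE`) and any
#'   further activity columns (`ec50`, `hc10`, MIC columns, censor flags).
#' @return the input rows reordered, with a `rank` column added; attribute
#'   `scaleBounds` records the heat-map color-scale bounds (nM) used for
#'   reporting.
#' @export
profileTable <- function(profiles) {
  stopifnot(all(c("id", "group", "ic50") %in% names(profiles)))
  cens <- if ("ic50Censored" %in% names(profiles))
    profiles$ic50Censored else rep(FALSE, nrow(profiles))
  g <- factor(profiles$group, levels = c("A", "B0", "B1", "B2"))
  o <- order(g, cens, profiles$ic50)
  out <- profiles[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "scaleBounds") <- list(
    ec50 = c(low = 1.3, high = 1000),
    ic50 = c(low = 4.1, high = 1000),
    hc10 = c(low = 160, high = 3000),
    mic = c(low = 8.0, high = 33000)
  )
  out
}
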
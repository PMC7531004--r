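# PeakList construction and peak-list file IO (MGF and TSV).

#' Create a peak list
#'
#' Ingests raw peaks: m/z sorted ascending, exact duplicate m/z merged
#' keeping the maximum intensity.
#'
#' @param mz numeric m/z values (positive).
#' @param intensity numeric intensities (recycled to length 1 if omitted).
#' @param precursorMz singly protonated precursor m/z, or `NA`.
#' @param sourceId provenance label.
#' @return a [PeakList-class].
#' @export
PeakList <- function(mz, intensity = rep(1, length(mz)),
                     precursorMz = NA_real_, sourceId = "") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- vapply(split(intensity, match(mz, unique(mz))), max,
        numeric(1))
      mz <- unique(mz)
    }
  }
  new("PeakList", mz = as.numeric(mz), intensity = as.numeric(intensity),
    precursorMz = as.numeric(precursorMz)[1], sourceId = sourceId)
}

#' Read peak lists from MGF (Mascot generic format)
#'
#' Parses `BEGIN IONS`/`END IONS` blocks; `PEPMASS` is taken as the
#' precursor m/z and `TITLE` as the source id. Lines outside blocks are
#' ignored (MGF allows global headers). Malformed content errors with the
#' offending line number.
#'
#' @param path file path.
#' @return list of [PeakList-class] objects, one per block, named by title.
#' @export
readMGF <- function(path) {
  lines <- readLines(path)
  out <- list()
  inBlock <- FALSE
  mz <- numeric(); int <- numeric(); prec <- NA_real_; title <- ""
  beginLine <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "BEGIN IONS") {
      if (inBlock)
        stop(sprintf("MGF line %d: BEGIN IONS inside an open block (opened line %d)",
          i, beginLine))
      inBlock <- TRUE; beginLine <- i
      mz <- numeric(); int <- numeric(); prec <- NA_real_
      title <- sprintf("spectrum_%d", length(out) + 1L)
    } else if (ln == "END IONS") {
      if (!inBlock)
        stop(sprintf("MGF line %d: END IONS without BEGIN IONS", i))
      inBlock <- FALSE
      out[[title]] <- PeakList(mz, int, precursorMz = prec, sourceId = title)
    } else if (inBlock) {
      if (ln == "") next
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^PEPMASS=", ln)) {
        prec <- suppressWarnings(
          as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]+")[[1]][1]))
        if (is.na(prec))
          stop(sprintf("MGF line %d: unreadable PEPMASS", i))
      } else if (grepl("^[A-Z]+=", ln)) {
        next  # CHARGE=, RTINSECONDS=, ... ignored
      } else {
        fields <- suppressWarnings(
          as.numeric(strsplit(ln, "[ \t]+")[[1]]))
        if (length(fields) < 1L || anyNA(fields[1]))
          stop(sprintf("MGF line %d: unreadable peak line '%s'", i, ln))
        mz <- c(mz, fields[1])
        int <- c(int, if (length(fields) >= 2L) fields[2] else 1)
      }
    }
  }
  if (inBlock)
    stop(sprintf("MGF: block opened at line %d never closed", beginLine))
  out
}

#' Write peak lists to MGF
#'
#' @param peakLists a [PeakList-class] or list of them.
#' @param path output file path.
#' @return invisibly `path`. Fixed number formatting (4 decimals for m/z,
#'   1 for intensity) makes output byte-stable.
#' @export
writeMGF <- function(peakLists, path) {
  if (is(peakLists, "PeakList")) peakLists <- list(peakLists)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pl in peakLists) {
    writeLines("BEGIN IONS", con)
    if (nzchar(pl@sourceId))
      writeLines(paste0("TITLE=", pl@sourceId), con)
    if (!is.na(pl@precursorMz))
      writeLines(sprintf("PEPMASS=%.4f", pl@precursorMz), con)
    if (length(pl@mz))
      writeLines(sprintf("%.4f %.1f", pl@mz, pl@intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read or write a single peak list as TSV
#'
#' Two tab-separated columns, `mz` and `intensity`, no header. Unsorted
#' input is sorted ascending on ingest.
#'
#' @param path file path.
#' @param precursorMz optional precursor to attach (TSV carries none).
#' @param sourceId provenance label.
#' @return [readPeakListTSV()]: a [PeakList-class];
#'   [writePeakListTSV()]: invisibly `path`.
#' @export
readPeakListTSV <- function(path, precursorMz = NA_real_, sourceId = path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
    col.names = c("mz", "intensity"))
  PeakList(tab$mz, tab$intensity, precursorMz = precursorMz,
    sourceId = sourceId)
}

#' @rdname readPeakListTSV
#' @param x a [PeakList-class].
#' @export
writePeakListTSV <- function(x, path) {
  utils::write.table(
    data.frame(mz = sprintf("%.4f", x@mz),
               intensity = sprintf("%.1f", x@intensity)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
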
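# Fragment ladders, peak matching, decoding and peak-list IO.

test_that("theoretical ladders satisfy the construction identities", {
  sch <- fixtureScheme()
  parent <- parentSequence(sch)
  rt <- residueTable(sch)
  nominalOf <- setNames(rt$nominal, rt$code)
  for (mode in c("nominal", "monoisotopic")) {
    lad <- theoreticalLadder(parent, sch, mode)
    expect_length(bIons(lad), 14L)
    expect_length(yIons(lad), 14L)
    expect_false(is.unsorted(bIons(lad), strictly = TRUE))
    expect_false(is.unsorted(yIons(lad), strictly = TRUE))
    # complementarity: b_i + y_(15-i) = [M+H]+ + proton
    proton <- if (mode == "nominal") 1 else 1.007276
    expect_equal(bIons(lad) + rev(yIons(lad)),
      rep(parentMH(lad) + proton, 14), tolerance = 1e-9)
  }
  lad <- theoreticalLadder(parent, sch, "nominal")
  codes <- strsplit(parent, "")[[1]]
  # consecutive b differences reproduce interior residue masses
  expect_equal(diff(bIons(lad)), unname(nominalOf[codes[2:14]]))
  expect_equal(bIons(lad)[14] - bIons(lad)[1],
    sum(nominalOf[codes[2:14]]))
  # nominal integer convention: b_i = sum(1..i) + 28 + 1
  expect_equal(bIons(lad)[1], unname(nominalOf[codes[1]]) + 29)
  expect_equal(yIons(lad)[1], unname(nominalOf[codes[15]]) + 62)
})

test_that("a single substitution shifts exactly the spanning ions", {
  sch <- fixtureScheme()
  parent <- parentSequence(sch)
  a1 <- parent
  substr(a1, 4, 4) <- "V"                       # L -> V, delta 14
  lp <- theoreticalLadder(parent, sch, "nominal")
  la <- theoreticalLadder(a1, sch, "nominal")
  db <- bIons(lp) - bIons(la)
  dy <- yIons(lp) - yIons(la)
  expect_equal(db, c(rep(0, 3), rep(14, 11)))  # b4..b14 shifted
  expect_equal(dy, c(rep(0, 11), rep(14, 3)))  # y12..y14 shifted
})

test_that("library ladder table agrees with per-sequence ladders", {
  sch <- fixtureScheme()
  lads <- libraryLadders(sch, "monoisotopic")
  set.seed(5)
  for (i in sample.int(length(lads$sequences), 10)) {
    one <- theoreticalLadder(lads$sequences[i], sch, "monoisotopic")
    expect_equal(lads$ions[i, ], c(bIons(one), yIons(one)),
      tolerance = 1e-9)
    expect_equal(lads$parentMH[i], parentMH(one), tolerance = 1e-9)
  }
})

test_that("peak matching counts nearest-in-tolerance ions", {
  sch <- fixtureScheme()
  parent <- parentSequence(sch)
  lad <- theoreticalLadder(parent, sch, "monoisotopic")
  theo <- c(bIons(lad), yIons(lad))
  self <- PeakList(theo)
  expect_equal(matchPeaks(lad, self, 0.3)$matchedFraction, 1.0)
  shifted <- PeakList(theo + 0.6)                 # 2 x tolerance away
  expect_identical(matchPeaks(lad, shifted, 0.3)$matchedIonCount, 0L)
  empty <- PeakList(numeric())
  expect_identical(matchPeaks(lad, empty, 0.3)$matchedIonCount, 0L)
  # deletion bookkeeping is the oracle for the matched fraction
  set.seed(21)
  keep <- runif(28) >= 0.3
  partial <- PeakList(theo[keep])
  expect_equal(matchPeaks(lad, partial, 0.3)$matchedFraction,
    mean(keep))
})

test_that("decoding recovers sequences and flags ambiguity honestly", {
  sch <- fixtureScheme()
  cfg <- noiselessConfig()
  lads <- libraryLadders(sch, "monoisotopic")
  set.seed(2)
  seqs <- sample(lads$sequences, 25)
  for (s in seqs) {
    sp <- simulateSpectrum(s, sch, cfg, sourceId = s)
    res <- decodeSpectrum(sp, sch, mode = "monoisotopic", ladders = lads)
    expect_identical(decodingStatus(res), "unique")
    expect_identical(candidates(res)$sequence[1], s)
  }
  # empty peak list
  res <- decodeSpectrum(PeakList(numeric()), sch, mode = "monoisotopic",
    ladders = lads)
  expect_identical(decodingStatus(res), "no_match")
  # precursor-only spectrum of a degenerate-mass composition is ambiguous:
  # {4L,1V,1T} and {4V,2Z} share the same parent mass
  degen <- parentSequence(sch)
  substr(degen, 6, 6) <- "L"; substr(degen, 8, 8) <- "T"  # 4L + 1V + 1T
  mh <- parentMH(theoreticalLadder(degen, sch, "monoisotopic"))
  precOnly <- PeakList(mh, precursorMz = mh)
  res <- decodeSpectrum(precOnly, sch, mode = "monoisotopic", ladders = lads)
  expect_identical(decodingStatus(res), "ambiguous")
  expect_gt(res@nScored, 1L)
})

test_that("decoding is invariant to peak-list permutation", {
  sch <- fixtureScheme()
  lads <- libraryLadders(sch, "monoisotopic")
  s <- lads$sequences[123]
  theo <- lads$ions[123, ]
  set.seed(9)
  perm <- sample(seq_along(theo))
  a <- decodeSpectrum(PeakList(theo, precursorMz = lads$parentMH[123]),
    sch, mode = "monoisotopic", ladders = lads)
  b <- decodeSpectrum(PeakList(theo[perm], precursorMz = lads$parentMH[123]),
    sch, mode = "monoisotopic", ladders = lads)
  expect_identical(candidates(a), candidates(b))
  expect_identical(decodingStatus(a), decodingStatus(b))
})

test_that("decoding accuracy does not increase with peak deletion", {
  sch <- fixtureScheme()
  lads <- libraryLadders(sch, "monoisotopic")
  accuracyAt <- function(rate, nBeads = 200) {
    cfg <- generatorConfig(nBeads = nBeads, seed = 31,
      peakDeletionRate = rate, mzNoiseSd = 0.05)
    scr <- generateScreen(sch, cfg)
    dec <- decodeSpectra(scr$spectra, sch, mode = "monoisotopic",
      ladders = lads)
    mean(!is.na(dec$sequence) & dec$sequence == scr$truth$sequence)
  }
  acc <- vapply(c(0, 0.35, 0.7, 0.95), accuracyAt, numeric(1))
  expect_true(all(diff(acc) <= 1e-9))
  expect_equal(acc[1], 1.0)
})

test_that("MGF and TSV peak lists round-trip", {
  sch <- fixtureScheme()
  lad <- theoreticalLadder(parentSequence(sch), sch, "monoisotopic")
  pl1 <- PeakList(c(bIons(lad), yIons(lad)),
    intensity = rep(100, 28), precursorMz = parentMH(lad),
    sourceId = "well_00001")
  pl2 <- PeakList(yIons(lad), intensity = seq_len(14),
    precursorMz = parentMH(lad), sourceId = "well_00002")
  path <- tempfile(fileext = ".mgf")
  writeMGF(list(pl1, pl2), path)
  back <- readMGF(path)
  expect_length(back, 2L)
  expect_identical(names(back), c("well_00001", "well_00002"))
  expect_equal(peakMz(back[[1]]), peakMz(pl1), tolerance = 1e-4)
  expect_equal(precursorMz(back[[2]]), precursorMz(pl2), tolerance = 1e-4)

  tsv <- tempfile(fileext = ".tsv")
  writePeakListTSV(pl1, tsv)
  rt <- readPeakListTSV(tsv)
  expect_equal(peakMz(rt), peakMz(pl1), tolerance = 1e-4)
  # unsorted TSV input is sorted on ingest
  writeLines(c("900.5\t1", "100.25\t2", "500\t3"), tsv)
  rt2 <- readPeakListTSV(tsv)
  expect_identical(peakMz(rt2), c(100.25, 500, 900.5))
})

test_that("malformed MGF errors carry line numbers", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "abc def"), path)
  expect_error(readMGF(path), "line 2")
  writeLines(c("END IONS"), path)
  expect_error(readMGF(path), "line 1")
  writeLines(c("BEGIN IONS", "100 1"), path)
  expect_error(readMGF(path), "never closed")
})

test_that("duplicate m/z merge keeps the maximum intensity", {
  pl <- PeakList(c(100, 100, 200), intensity = c(5, 9, 1))
  expect_identical(peakMz(pl), c(100, 200))
  expect_identical(peakIntensity(pl), c(9, 1))
})
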
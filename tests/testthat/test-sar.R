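# SAR statistics: composition tables, percent-active, Hill fits,
# effect concentrations, MIC calling, fold changes, profile tables.

test_that("group composition percentages count variable-position residues", {
  sch <- fixtureScheme()
  parent <- parentSequence(sch)
  tab <- groupComposition(list(parent = parent), sch)
  expect_identical(tab$L, 67)
  expect_identical(tab$V, 33)
  expect_identical(tab$T, 0)
  expect_identical(tab$Z, 0)
  # one all-T sequence
  allT <- parent
  for (p in variablePositions(sch)) substr(allT, p, p) <- "T"
  expect_identical(groupComposition(list(g = allT), sch)$T, 100)
  # planted 41-sequence group with 140 L / 106 V over 246 slots -> 57/43
  counts <- c(rep(4, 18), rep(3, 22), 2)      # 72+66+2 = 140 L over 41 seqs
  seqs <- vapply(counts, function(nl) {
    v <- c(rep("L", nl), rep("V", 6 - nl))
    s <- parent
    vp <- variablePositions(sch)
    for (i in seq_along(vp)) substr(s, vp[i], vp[i]) <- v[i]
    s
  }, character(1))
  comp <- variableComposition(seqs, sch)
  expect_identical(sum(comp$L), 140)
  expect_identical(sum(comp$V), 106)
  tabA <- groupComposition(list(A = seqs), sch)
  expect_identical(tabA$L, 57)
  expect_identical(tabA$V, 43)
  # empty group gives an all-zero row
  e <- groupComposition(list(none = character()), sch)
  expect_identical(e$nCompounds, 0L)
  expect_true(all(e[, c("L", "V", "T", "Z")] == 0))
  # rounded percentages stay within 2 of 100
  set.seed(8)
  lib <- enumerateLibrary(sch)
  rnd <- groupComposition(list(g = sample(lib, 37)), sch)
  expect_lte(abs(sum(rnd[, c("L", "V", "T", "Z")]) - 100), 2)
})

test_that("percent active counts compounds with any active well", {
  cmp <- data.frame(nActiveWells = c(rep(1L, 30), 0L))
  expect_identical(percentActive(cmp), 97)
  expect_identical(percentActive(data.frame(nActiveWells = c(0L, 0L))), 0)
  expect_message(out <- percentActive(data.frame(nActiveWells = integer())),
    "n/a")
  expect_true(is.na(out))
})

test_that("Hill fits recover parameters and satisfy midpoint identities", {
  cc <- 10^seq(-1, 2, length.out = 8)
  # noiseless curve: exact recovery and midpoint identity
  fit <- fitHill(cc, 100 / (1 + (4.5 / cc)^2))
  expect_true(fit@converged)
  expect_equal(ec50(fit), 4.5, tolerance = 1e-4)
  expect_equal(hillSlope(fit), 2, tolerance = 1e-4)
  expect_equal(predictHill(fit, ec50(fit)), 50, tolerance = 1e-6)
  # concentration-scale equivariance: x10 concentrations -> x10 EC50
  fit10 <- fitHill(cc * 10, 100 / (1 + (4.5 / cc)^2))
  expect_equal(ec50(fit10), 45, tolerance = 1e-3)
  # degenerate data is flagged, not silently fit
  flat <- fitHill(cc, rep(50, 8))
  expect_false(flat@converged)
  expect_error(fitHill(c(1, 10), c(10, 90)), "at least 4")
  expect_error(fitHill(c(-1, 1, 10, 100), c(1, 10, 50, 90)), "> 0")
})

test_that("Hill parameter recovery holds over seeded noisy curves", {
  set.seed(123)
  errs <- replicate(100, {
    cc <- 10^seq(-1, 2, length.out = 8)
    resp <- 100 / (1 + (4.5 / cc)^2) + rnorm(8, 0, 2)
    abs(ec50(fitHill(cc, resp)) / 4.5 - 1)
  })
  expect_lt(median(errs), 0.1)
})

test_that("effect concentrations invert the Hill equation analytically", {
  cc <- 10^seq(-1, 3, length.out = 9)
  fit1 <- fitHill(cc, 100 / (1 + (10 / cc)))       # slope 1, ec50 10
  expect_equal(effectConcentration(fit1, 50), ec50(fit1), tolerance = 1e-6)
  expect_equal(effectConcentration(fit1, 75), 30, tolerance = 1e-3)
  # closed-form HC10: bottom 0, top 100, slope 1, ec50 1440 -> 160
  cc2 <- 10^seq(0, 5, length.out = 10)
  fit2 <- fitHill(cc2, 100 / (1 + (1440 / cc2)))
  expect_equal(hc10FromCurve(fit2), 160, tolerance = 1e-2)
  # HC10 <= EC50 on any monotone curve
  expect_lt(hc10FromCurve(fit2), ec50(fit2))
  # inverse composed with prediction is the identity on (bottom, top)
  for (p in c(5, 25, 50, 80, 95))
    expect_equal(predictHill(fit1, effectConcentration(fit1, p)), p,
      tolerance = 1e-6)
  expect_error(effectConcentration(fit1, 0), "strictly within")
  expect_error(effectConcentration(fit1, 100), "strictly within")
  # recovery of a planted threshold concentration from a noisy fit
  set.seed(77)
  resp <- 100 / (1 + (4.5 / cc)^1.5) + rnorm(9, 0, 1)
  fit3 <- fitHill(cc, resp)
  analytic <- 4.5 * (55.2 / 44.8)^(1 / 1.5)
  expect_equal(effectConcentration(fit3, 55.2), analytic, tolerance = 0.15)
})

test_that("MIC calling follows the microdilution rules", {
  expect_equal(micFromDilutions(c(64, 32, 16, 8, 4),
    c(FALSE, FALSE, FALSE, FALSE, TRUE))$mic, 8)
  allGrow <- micFromDilutions(c(64, 32, 16), c(TRUE, TRUE, TRUE))
  expect_identical(allGrow$censored, "gt")
  expect_identical(allGrow$label, ">64")
  noneGrow <- micFromDilutions(c(64, 32, 16), c(FALSE, FALSE, FALSE))
  expect_identical(noneGrow$censored, "le")
  expect_equal(noneGrow$mic, 16)
  # planted true MIC between two dilutions reports the next dilution up
  series <- c(64, 32, 16, 8, 4, 2)
  trueMic <- 11.3
  growth <- series < trueMic
  expect_equal(micFromDilutions(series, growth)$mic, 16)
  # non-monotone growth resolved upward with a warning
  expect_warning(
    odd <- micFromDilutions(c(64, 32, 16, 8), c(FALSE, FALSE, TRUE, FALSE)),
    "non-monotone")
  expect_equal(odd$mic, 32)
  expect_error(micFromDilutions(c(16, 32), c(TRUE, FALSE)), "decreasing")
})

test_that("fold changes reproduce the printed comparison conventions", {
  expect_equal(foldChange(160, 5.8), 28)
  expect_equal(foldChange(8.3, 1.0), 8)
  expect_equal(foldChange(33, 8.0), 4)
  expect_equal(foldChange(1.3, 4.5), 0.29)
  expect_equal(foldChange(7, 7), 1)
  # reciprocal identity before rounding
  expect_equal(foldChange(160, 5.8, rounding = "none") *
    foldChange(5.8, 160, rounding = "none"), 1)
  # censored operands flagged, never silently numeric
  expect_warning(out <- foldChange(1000, 50, numeratorCensored = TRUE),
    "censored")
  expect_true(is.na(out))
  expect_identical(attr(out, "direction"), "ge")
  expect_error(foldChange(10, 0), "denominator")
})

test_that("profile tables rank by group then cytotoxicity, censored last", {
  profiles <- data.frame(
    id = c("B11", "A1", "B01", "B21", "1", "B12"),
    group = c("B1", "A", "B0", "B2", "A", "B1"),
    ic50 = c(17, 4.1, 9, 1000, 5.8, 390),
    ic50Censored = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  tab <- profileTable(profiles)
  expect_identical(tab$id, c("A1", "1", "B01", "B11", "B12", "B21"))
  expect_identical(tab$rank, 1:6)
  # censored ">1000" sorts after an uncensored 390 within its group
  p2 <- data.frame(id = c("x", "y"), group = c("B1", "B1"),
    ic50 = c(1000, 390), ic50Censored = c(TRUE, FALSE))
  expect_identical(profileTable(p2)$id, c("y", "x"))
  bounds <- attr(tab, "scaleBounds")
  expect_equal(bounds$hc10[["low"]], 160)
})
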
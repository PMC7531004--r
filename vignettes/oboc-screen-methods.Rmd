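---
title: "Methods: design, decoding and triage of an OBOC peptide screen"
author: "obocScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, decoding and triage of an OBOC peptide screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obocScreen)
```

## The screen this package models

Gramicidin A is a 15-residue, d,l-alternating peptide antibiotic, capped by
an N-terminal formyl group and a C-terminal ethanolamide, that folds into a
β^6.3^-helix and dimerizes into a monovalent-cation channel. A
one-bead-one-compound (OBOC) screen around this scaffold randomizes six
positions (residue numbers 4, 6, 8, 10, 12 and 14) over four charge-neutral
residues — d-Leu (L), d-Val (V), d-Thr (T) and d-Asm (Z, displayed N′, the
Nγ-methylated asparagine) — giving a 4^6 = 4096-member library. Each bead
carries one sequence; bead-derived solutions are assayed for H⁺/Na⁺
transport, P388 cytotoxicity and antibacterial activity, and hits are
sequenced by MS/MS. `obocScreen` implements every computational stage of
that workflow plus a seeded synthetic-screen generator that provides exact
ground truth for testing the stages end to end.

## Mass bookkeeping

Residue masses are standard (nominal = monoisotopic rounded to integer),
with Asm defined as the asparagine residue plus CH₂ (nominal 128, matching
the decoding units 113/99/101/128 for L/V/T/N′). Cap deltas are +CO for the
formyl group (27.9949 mono, 28.01 average) and −OH +NH‑C₂H₄‑OH for the
ethanolamide (+43.0422 mono, +43.07 average). These choices reproduce the
parent's average molecular weight:

```{r}
sch <- defaultScheme()
peptideMass(parentSequence(sch), sch, "average")  # rounds to 1882 Da
```

Nominal mode is pure integer arithmetic throughout, because the library's
identifiability argument — every variable residue has a distinct integer
mass unit — is an integer statement. Chirality is display metadata only;
masses are chirality-independent.

## Enumeration order and serialization

Sequences serialize to 15-character strings of one-letter machine codes
(Z for Asm; the prime in N′ is display-only). The canonical library order
is a base-4 odometer over the variable positions in ascending residue
number, last position fastest, with each alphabet read L, V, T, Z —
aliphatic residues first. The order is stable and documented so that
decoder tie-breaking ("ties broken by canonical order") is reproducible.

## Parent-mass degeneracy and the case for ladders

The 84 variable-position compositions (multisets of size 6 from 4 symbols)
do not map injectively to parent masses: for example 4L+1V+1T and 4V+2N′
both sum to 652 nominal Da at the variable positions. `massDegeneracyAudit()`
reports every such collision group; its existence is why decoding uses the
full b/y ladder and precursor mass alone is never trusted.

## Coverage statistics

Split-and-mix synthesis assigns sequences to beads approximately i.i.d.
uniformly, so the expected covered fraction of an N-member library after B
bead draws is 1 − (1 − 1/N)^B. At the screen's design point (N = 4096,
B = 13,584 — a threefold bead excess) this is 96.4%, the figure that
justifies the bead count. `coverageSimulate()` verifies the formula by
Monte Carlo and also returns the appearance-frequency histogram, which
converges to Binomial(B, 1/N). Sampling is with replacement; synthesis
failures and truncation products are deliberately not modeled.

## Fragment ladders and constrained decoding

Ladders contain singly protonated b- and y-ions only (the MALDI TOF/TOF
regime); a-ions, neutral losses, immonium ions and higher charge states are
out of scope. b-ions include the formyl cap, y-ions the ethanolamide, so
complementarity `b_i + y_(15−i) = [M+H]⁺ + proton` holds at every cleavage
site — exactly in nominal integers, to float tolerance otherwise.

Decoding is constrained de novo: candidates come only from the 4096-member
library, never from the full 20-residue space. When a precursor is present
the library is first filtered by parent mass within tolerance; survivors
are scored by counting theoretical ions with an observed peak within
tolerance (each theoretical ion consumes at most its nearest peak). Default
tolerances: 0.3 Da in monoisotopic/average mode (TOF/TOF-scale accuracy,
an artifact default since no instrument tolerance is prescribed by the
underlying protocol), 0 in nominal mode. A spectrum decodes as `unique`
only when a single candidate attains the top score *and* reaches the
acceptance threshold (`minMatchedFraction`, default 0.5 of the 28 ions);
co-leaders — e.g., any member of a degeneracy group seen through a
precursor-only spectrum — give `ambiguous`, and an empty peak list or empty
candidate set gives `no_match`. Ties are never silently broken.

## Triage thresholds

Transport activity is normalized to the on-plate parent control; wells
below relative activity 1 are screened out. Transport-positive wells split
by P388 viability into group A (≤ 20%, more cytotoxic) and group B (≥ 30%,
less cytotoxic). The (20, 30)% interval is kept as an explicit `gap` label
rather than forced into either group — the two thresholds deliberately
leave a buffer, and collapsing it would fabricate assignments. Antibacterial
potency is coded from growth inhibition at three dilutions of the 15 µM
bead stock (640-, 160-, 40-fold, i.e., 23/94/380 nM at two significant
figures): `+++`/`++`/`+` by the highest inhibiting dilution, `-` for none.
Inconsistent flag patterns are repaired to the highest inhibiting dilution
with a warning, since the code is defined by that dilution.

Deduplication collapses uniquely decoded A/B wells per sequence.
Group consensus is "A if any well is A, else B", which makes the
"never found as group A" exclusion in the selection rules a well-level
statement. Ambiguously decoded wells never contribute; they are tallied in
the run report. Subgroups B0/B1/B2 index group-B compounds by their count
of hydrogen-bond-forming residues (T + N′); three or more is flagged
`B3plus` — handled, though designed to be absent among transport-positive
compounds. The three representative-selection rules are: (i) group-A
compounds strictly more potent than the parent's code (parent excluded);
(ii) B0/B1 compounds antibacterial-active (≥ `+`) in three or more wells;
(iii) B2 compounds with appearance frequency ≥ 3. The three sets are
reported separately with no forced total. Whether rule (i) compares
per-well or per-compound codes was an open design point; the per-compound
best code is used.

## Dose–response and SAR statistics

Hill fits use `response = bottom + (top − bottom)/(1 + (EC50/c)^slope)`
with bottom/top fixed at 0/100 by default (all responses are percentage
scales; pass `NA` to free a plateau). Fitting is bounded Levenberg–
Marquardt least squares on log-concentration, seeded by a deterministic
grid (25 log-spaced EC50 values × slopes 0.5/1/2/4) — reproducible without
random restarts. Degenerate (flat) data returns `converged = FALSE` rather
than a fabricated fit. `effectConcentration()` inverts the curve
analytically, so EC50 is exactly the 50%-effect concentration and HC10
(10% hemolysis) is `effectConcentration(fit, 10)`.

MIC calling takes a strictly decreasing twofold series and returns the
lowest no-growth concentration; growth everywhere censors upward (">max"),
no growth anywhere censors downward ("≤min"), and non-monotone patterns
resolve to the lowest no-growth concentration above the highest growth
concentration, with a warning. Censored values always carry an explicit
flag and never silently enter arithmetic: fold changes with a censored
operand return a flagged `NA` with a direction. Fold changes round half-up
to integers at ratios ≥ 1 and to two significant figures below 1, matching
how such comparisons are conventionally printed; unrounded values are
available with `rounding = "none"`. Composition percentages round half-up
to integers (the parent's variable positions give 67% L / 33% V).

## The synthetic-screen generator

The generator is a test harness, not a biological model: a rule-based
latent activity map from variable-position composition to the three
assays, calibrated once so the classifier has recoverable structure with
realistic class imbalance. Per sequence (seeded, drawn once for the whole
library):

* **Transport.** Sequences with hydrogen-bond count h ≥ 3 get relative
  activity `1.5 × 0.5^(h−2)` — deterministically below the threshold,
  encoding the screen's observation that no 3+ T/N′ sequence is
  transport-positive. For h ≤ 2 the per-sequence probability of being
  transport-positive is 1.00 / 0.54 / 0.039 for h = 0/1/2, the unique-hit
  fractions implied by the screen's class sizes (the h = 0 rate caps at 1).
  Positive sequences draw activity uniformly in [1.05, 2.2], negatives in
  [0.2, 0.95] — clear of the threshold so small assay noise cannot flip
  labels silently.
* **Cytotoxicity.** Only all-aliphatic (h = 0) transport-positive sequences
  can be cytotoxic, with logistic probability `plogis(0.35·nL + 0.10·nV −
  1.8)` — increasing in Leu content, ≈ 0.57 for all-L. Toxic sequences draw
  viability in [5, 15]%, others in [55, 90]%, again clear of both
  thresholds.
* **Antibacterial activity.** Bernoulli per compound with class rates 0.76
  (cytotoxic "A-like"), 0.97 (B0), 0.17 (B1), 0.03 (B2); active compounds
  draw a potency code from (+++ , ++ , +) with weights 0.25/0.40/0.35.
  Dilution flags derive deterministically from the code, so they are
  always monotone.
* The parent sequence is pinned as the positive control: transport 1.1,
  cytotoxic, potency `++`.

Well-level readouts add Gaussian noise (m/z jitter on fragment peaks,
Bernoulli peak deletion, Gaussian percentage noise on assays). Everything
runs under a single seeded RNG stream in fixed order, and on-disk output
uses fixed number formatting, so identical config + seed gives
byte-identical `plates.csv` / `screen.mgf` / `truth.json`.

What the generator does *not* emulate: synthesis failures, plate/batch
effects, instrument-specific spectral artifacts, isotope envelopes,
correlated assay noise, or any real structure–activity mechanism beyond
the composition rules above. Passing the end-to-end tests therefore shows
the pipeline recovers the truth of *this* generative model perfectly at
zero noise and degrades monotonically with noise — not that the latent
rules are biologically true, and not that the screen's published
well-level counts (which require the original plate data) are reproduced.

## Problem sizes and numerical choices

Tests run the exhaustive noiseless decode of all 4096 members, 200-replicate
coverage simulations of the full 13,584-bead draw, a 2000-bead end-to-end
screen, and 100 seeded dose–response curves — sizes chosen so the whole
suite completes in well under a minute on one CPU while still exercising
every stage at meaningful scale; the generator handles the full 13,584-bead
screen in seconds when needed. Matching uses an absolute tolerance with a
1e-9 guard against float round-off; candidate ranking breaks ties by
canonical order only for presentation, never to claim uniqueness.

## Known limitations

* Degeneracy auditing assumes a common alphabet across variable positions
  (true for the default scheme); composition labels are undefined otherwise.
* The decoder assumes singly charged ions and centroided peaks; it does no
  peak-picking or deconvolution.
* The per-bead loading arithmetic of the wet-lab protocol (nmol → µg → µM)
  is exposed only as the dilution formula in `screeningConcentration()`;
  the package asserts no loading-derived constants beyond the 15 µM stock.
* Hill fits with both plateaus free are weakly identified on narrow
  concentration ranges; the default fixes them at 0/100.
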
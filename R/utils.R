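# Internal numeric helpers and physical constants.

# Masses in Da. Order of the mode vectors is fixed: nominal, average,
# monoisotopic — every cap/terminus constant follows the same convention.
.MASS_MODES <- c("nominal", "average", "monoisotopic")

.PROTON <- c(nominal = 1, average = 1.00739, monoisotopic = 1.007276)
.WATER <- c(nominal = 18, average = 18.0153, monoisotopic = 18.010565)

# N-formyl cap: +CO on the free alpha-amine.
.FORMYL <- c(nominal = 28, average = 28.0101, monoisotopic = 27.994915)
# C-terminal ethanolamide: free acid -OH replaced by -NH-CH2CH2-OH.
.ETHANOLAMIDE <- c(nominal = 43, average = 43.0679, monoisotopic = 43.042199)

.checkMode <- function(mode) {
  match.arg(mode, .MASS_MODES)
}

# Round half away from zero (R's round() is round-half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Significant figures with half-up tie-breaking (375 -> 380 at 2 sf).
signifHalfUp <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  m <- floor(log10(abs(x[nz])))
  out[nz] <- roundHalfUp(x[nz], digits - 1 - m)
  out
}
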
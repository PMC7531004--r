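# Hill (four-parameter logistic) dose-response fitting.
#
# Model: response = bottom + (top - bottom) / (1 + (ec50/c)^slope),
# increasing in concentration. Responses on inhibition scales (% kill,
# % hemolysis, % fluorescence change) all fit this parameterization.

.hillResponse <- function(conc, ec50, slope, bottom, top) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^slope)
}

#' Fit a Hill dose-response curve
#'
#' Bounded nonlinear least squares on log-concentration with a
#' deterministic grid initializer (no random restarts): EC50 starting
#' values sweep the observed concentration range on a log grid crossed
#' with slope values 0.5/1/2/4; the grid point with the lowest residual
#' sum of squares seeds a Levenberg-Marquardt refinement. Bottom and top
#' are fixed at 0/100 by default (responses are percentage scales); pass
#' `NA` to free either plateau.
#'
#' @param conc concentrations (> 0), at least 4 points spanning the
#'   transition.
#' @param response responses (%), same length.
#' @param fixedBottom,fixedTop fixed plateau values, or `NA` to estimate.
#' @return a [HillFit-class]. Degenerate data (essentially constant
#'   response) returns `converged = FALSE` with `NA` parameters.
#' @examples
#' cc <- 10^seq(-1, 2, length.out = 8)
#' fit <- fitHill(cc, 100 / (1 + (4.5 / cc)^2))
#' ec50(fit)  # 4.5
#' @export
fitHill <- function(conc, response, fixedBottom = 0, fixedTop = 100) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(conc) < 4L) stop("need at least 4 concentration points")
  dat <- data.frame(conc = conc, response = response)

  if (stats::sd(response) < 1e-8) {
    return(new("HillFit", ec50 = NA_real_, hillSlope = NA_real_,
      top = NA_real_, bottom = NA_real_, rss = NA_real_,
      converged = FALSE, data = dat))
  }

  freeBottom <- is.na(fixedBottom)
  freeTop <- is.na(fixedTop)
  b0 <- if (freeBottom) min(response) else fixedBottom
  t0 <- if (freeTop) max(response) else fixedTop

  rssOf <- function(le, s, b, t) {
    sum((response - .hillResponse(conc, 10^le, s, b, t))^2)
  }
  leGrid <- seq(log10(min(conc)), log10(max(conc)), length.out = 25)
  sGrid <- c(0.5, 1, 2, 4)
  grid <- expand.grid(le = leGrid, s = sGrid)
  grid$rss <- mapply(function(le, s) rssOf(le, s, b0, t0), grid$le, grid$s)
  init <- grid[which.min(grid$rss), ]

  lc <- log10(conc)
  start <- list(le = init$le, slope = init$s)
  lower <- c(le = min(lc) - 3, slope = 0.1)
  upper <- c(le = max(lc) + 3, slope = 10)
  form <- response ~ b + (t - b) / (1 + 10^((le - lc) * slope))
  env <- list(lc = lc, response = response)
  if (freeBottom) {
    start$b <- b0; lower <- c(lower, b = -50); upper <- c(upper, b = 150)
  } else env$b <- b0
  if (freeTop) {
    start$t <- t0; lower <- c(lower, t = -50); upper <- c(upper, t = 200)
  } else env$t <- t0

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = env, start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("HillFit", ec50 = NA_real_, hillSlope = NA_real_,
      top = if (freeTop) NA_real_ else fixedTop,
      bottom = if (freeBottom) NA_real_ else fixedBottom,
      rss = NA_real_, converged = FALSE, data = dat))
  }
  cf <- stats::coef(fit)
  new("HillFit",
    ec50 = unname(10^cf[["le"]]),
    hillSlope = unname(cf[["slope"]]),
    top = if (freeTop) unname(cf[["t"]]) else fixedTop,
    bottom = if (freeBottom) unname(cf[["b"]]) else fixedBottom,
    rss = sum(stats::resid(fit)^2),
    converged = TRUE,
    data = dat)
}

#' Predicted response of a Hill fit
#'
#' @param fit a [HillFit-class].
#' @param conc concentrations.
#' @return predicted responses; `response(ec50) = (top + bottom) / 2`.
#' @export
predictHill <- function(fit, conc) {
  if (!fit@converged) stop("fit did not converge")
  .hillResponse(conc, fit@ec50, fit@hillSlope, fit@bottom, fit@top)
}

#' Concentration producing a given percent effect
#'
#' Analytic inverse of the Hill equation:
#' `c = ec50 * ((p - bottom) / (top - p))^(1/slope)`. By definition
#' `effectConcentration(fit, 50)` equals the EC50 when bottom/top are
#' 0/100.
#'
#' @param fit a converged [HillFit-class].
#' @param percentEffect target response, strictly between bottom and top.
#' @return concentration in the units of the fitted data.
#' @export
effectConcentration <- function(fit, percentEffect) {
  if (!fit@converged) stop("fit did not converge")
  if (percentEffect <= fit@bottom || percentEffect >= fit@top)
    stop(sprintf("percent effect must lie strictly within (%g, %g)",
      fit@bottom, fit@top))
  f <- (percentEffect - fit@bottom) / (fit@top - percentEffect)
  fit@ec50 * f^(1 / fit@hillSlope)
}

#' HC10: concentration causing 10% effect
#'
#' Convenience wrapper used for hemolysis curves: the concentration
#' producing 10% hemoglobin leakage, `effectConcentration(fit, 10)`.
#'
#' @inheritParams effectConcentration
#' @return concentration.
#' @export
hc10FromCurve <- function(fit) {
  effectConcentration(fit, 10)
}
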
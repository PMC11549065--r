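#' Reduced additive Weibull (RAW) survival parameters
#'
#' Container for the three parameters of the reduced additive Weibull
#' survival model, which produces a "bathtub"-shaped mortality curve:
#' high pup mortality, low young-adult mortality, and senescent increase.
#' The default values are the prior means from a hierarchical meta-analysis
#' of phocid seal mortality.
#'
#' @param eta1 Hazard scale (1/years), `eta1 >= 0`.
#' @param eta2 Shape (dimensionless), `eta2 > 0`.
#' @param eta3 Linear hazard component (1/years), `eta3 >= 0`.
#'
#' @return An object of class `raw_params`.
#' @examples
#' raw_params()          # phocid meta-analysis prior means
#' raw_params(0, 2, 0.1) # pure exponential mortality
#' @export
raw_params <- function(eta1 = 0.055, eta2 = 2.80, eta3 = 0.076) {
  stopifnot(length(eta1) == 1L, length(eta2) == 1L, length(eta3) == 1L)
  if (is.na(eta1) || is.na(eta2) || is.na(eta3))
    stop("RAW parameters must be non-missing")
  if (eta1 < 0) stop("eta1 must be >= 0")
  if (eta2 <= 0) stop("eta2 must be > 0")
  if (eta3 < 0) stop("eta3 must be >= 0")
  structure(list(eta1 = eta1, eta2 = eta2, eta3 = eta3), class = "raw_params")
}

#' @export
print.raw_params <- function(x, ...) {
  cat(sprintf("RAW survival parameters: eta1 = %g, eta2 = %g, eta3 = %g\n",
              x$eta1, x$eta2, x$eta3))
  invisible(x)
}

#' Cumulative survivorship under the RAW model
#'
#' Survivorship to exact age `a`:
#' `S(a) = exp(-[(eta1*a)^eta2 + (eta1*a)^(1/eta2) + eta3*a])`,
#' i.e. the survival function of a reduced additive Weibull lifetime.
#' The cumulative hazard is the sum of a convex Weibull term (senescence),
#' a concave Weibull term (high early mortality) and a linear term.
#'
#' @param params A [raw_params()] object.
#' @param a Age(s) in years, `a >= 0` (need not be integer).
#'
#' @return Survivorship value(s) in `[0, 1]`, with `S(0) = 1`.
#' @seealso [raw_annual_survival()] for the derived annual survival
#'   probabilities `phi_a = S(a+1)/S(a)`.
#' @examples
#' raw_survivorship(raw_params(), 0:5)
#' @export
raw_survivorship <- function(params, a) {
  stopifnot(inherits(params, "raw_params"))
  if (any(a < 0)) stop("age must be non-negative")
  x <- params$eta1 * a
  exp(-(x^params$eta2 + x^(1 / params$eta2) + params$eta3 * a))
}

#' Annual survival probabilities under the RAW model
#'
#' Annual survival from age class `a` to `a + 1`, defined as the
#' survivorship ratio `phi_a = S(a + 1) / S(a)`.
#'
#' @inheritParams raw_survivorship
#' @param ages Integer ages (default `0:39`).
#' @return Numeric vector of annual survival probabilities.
#' @export
raw_annual_survival <- function(params, ages = 0:39) {
  raw_survivorship(params, ages + 1) / raw_survivorship(params, ages)
}
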
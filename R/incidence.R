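#' Piecewise-constant average carrier incidence curve
#'
#' Container for an age grid of hazard rates (events per woman-year). The
#' hazard is piecewise constant: \code{hazard[k]} applies on
#' \code{[age[k], age[k+1])}, and the final value extends beyond the last
#' grid age. Incidence curves supply the average carrier incidence used both
#' to construct ascertainment weights and as the marginal constraint of the
#' absolute-risk projection.
#'
#' @param age strictly increasing ages in years.
#' @param hazard nonnegative hazard rates per year, same length as
#'   \code{age}.
#' @return An object of class \code{incidence_curve}: a data frame with
#'   columns \code{age} and \code{hazard}.
#' @export
incidence_curve <- function(age, hazard) {
  if (length(age) != length(hazard))
    stop("`age` and `hazard` must have the same length")
  if (length(age) < 1L || any(!is.finite(age)) || any(diff(age) <= 0))
    stop("`age` must be strictly increasing and finite")
  if (any(!is.finite(hazard)) || any(hazard < 0))
    stop("`hazard` must be finite and nonnegative")
  out <- data.frame(age = as.numeric(age), hazard = as.numeric(hazard))
  class(out) <- c("incidence_curve", "data.frame")
  out
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat("Incidence curve:", nrow(x), "age knots on [",
      x$age[1], ",", x$age[nrow(x)], "] years\n")
  cat("Cumulative risk by", x$age[nrow(x)], "years:",
      sprintf("%.3f", cumulative_risk(x, x$age[nrow(x)])), "\n")
  invisible(x)
}

#' Cumulative hazard of an incidence curve
#'
#' Integrates the piecewise-constant hazard from the first grid age to
#' \code{t}; ages before the grid start contribute nothing.
#'
#' @param ic an \code{incidence_curve}.
#' @param t ages (years), vectorized.
#' @return Cumulative hazard at each \code{t}.
#' @export
cum_hazard <- function(ic, t) {
  stopifnot(inherits(ic, "incidence_curve"))
  a <- ic$age
  h <- ic$hazard
  k <- length(a)
  # cumulative hazard at each knot
  ch <- c(0, cumsum(h[-k] * diff(a)))
  idx <- findInterval(t, a)
  out <- numeric(length(t))
  inside <- idx >= 1L
  ii <- idx[inside]
  out[inside] <- ch[ii] + h[ii] * (t[inside] - a[ii])
  out
}

#' Cumulative risk (penetrance) implied by an incidence curve
#'
#' \code{F(t) = 1 - exp(-integral of hazard up to t)}.
#'
#' @inheritParams cum_hazard
#' @return Cumulative risk in [0, 1) at each \code{t}.
#' @export
cumulative_risk <- function(ic, t) 1 - exp(-cum_hazard(ic, t))

#' Hazard value of an incidence curve at given ages
#' @inheritParams cum_hazard
#' @return Hazard per year at each \code{t} (last value carried forward).
#' @export
hazard_at <- function(ic, t) {
  idx <- pmax(1L, pmin(findInterval(t, ic$age), nrow(ic)))
  ic$hazard[idx]
}

#' Synthetic example carrier incidence curves
#'
#' Stylized average carrier incidence curves for breast and ovarian cancer
#' in BRCA1 and BRCA2 carriers, for simulation and worked examples. These
#' are synthetic: plausible in shape and overall magnitude (the BRCA1
#' ovarian curve is calibrated so that the cumulative risk by age 40 equals
#' 2.8%, a commonly cited decision anchor), but they are not published
#' penetrance estimates and carry no external authority.
#'
#' @param type one of \code{"bc_brca1"}, \code{"bc_brca2"},
#'   \code{"oc_brca1"}, \code{"oc_brca2"}.
#' @return An \code{incidence_curve}.
#' @export
synthetic_carrier_incidence <- function(type = c("bc_brca1", "bc_brca2",
                                                 "oc_brca1", "oc_brca2")) {
  type <- match.arg(type)
  switch(type,
    bc_brca1 = incidence_curve(
      age    = c(18, 25, 30, 35, 40, 50, 60, 80),
      hazard = c(0.001, 0.006, 0.012, 0.020, 0.030, 0.028, 0.025, 0.025)),
    bc_brca2 = incidence_curve(
      age    = c(18, 25, 30, 35, 40, 50, 60, 80),
      hazard = c(0.0005, 0.003, 0.008, 0.015, 0.025, 0.028, 0.027, 0.027)),
    oc_brca1 = {
      # calibrated: cumulative risk by age 40 is exactly 2.8%
      h3539 <- (-log(1 - 0.028) - 17 * 5e-4) / 5
      incidence_curve(
        age    = c(18, 35, 40, 50, 60, 80),
        hazard = c(5e-4, h3539, 0.013, 0.016, 0.014, 0.014))
    },
    oc_brca2 = incidence_curve(
      age    = c(18, 40, 50, 60, 80),
      hazard = c(2e-4, 0.003, 0.007, 0.005, 0.005)))
}
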
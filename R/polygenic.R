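# The multiplicative polygenic model.
#
# Conditional on a standardized polygenic score z ~ N(0,1), disease hazard
# is lambda(t|z) = lambda0(t) * exp(beta(t) * z), so relative risk is
# lognormal across carriers. Given the average carrier incidence
# lambda_bar(t), the baseline lambda0(t) is pinned down by the
# marginal-incidence constraint: the PRS-averaged survival among carriers
# must reproduce the survival implied by lambda_bar at every grid age.
# From the constrained baseline, absolute cumulative risks at any PRS
# percentile follow directly.

gauss_hermite_std <- function(n = 64) {
  gh <- pracma::gaussHermite(n)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))  # E[f(Z)], Z ~ N(0,1)
}

#' Multiplicative polygenic model for carrier risk projection
#'
#' Builds the model on a yearly age grid and solves the marginal-incidence
#' constraint for the baseline hazard (see
#' \code{\link{constrained_baseline}}).
#'
#' @param beta per-SD log hazard ratio of the standardized PRS. Either a
#'   single number (age-constant), a length-2 numeric \code{c(beta0,
#'   decay)} giving \code{beta(t) = beta0 + t * log(decay)} (per-year
#'   multiplicative decay, age anchored at 0), or a data frame with columns
#'   \code{age_lo}, \code{age_hi}, \code{beta} (piecewise by age band, as
#'   produced by age-group fits).
#' @param incidence an \code{\link{incidence_curve}}: the average carrier
#'   incidence \code{lambda_bar}.
#' @param age_range modelled age range (default 18 to 80).
#' @param age_grid_step grid step in years (default 1).
#' @param gh_nodes number of Gauss-Hermite quadrature nodes for integrals
#'   over the PRS distribution (default 64).
#' @return An object of class \code{polygenic_model} with the solved
#'   baseline hazard.
#' @export
polygenic_model <- function(beta, incidence, age_range = c(18, 80),
                            age_grid_step = 1, gh_nodes = 64) {
  stopifnot(inherits(incidence, "incidence_curve"),
            age_range[1] >= 18 - 1e-9, age_range[2] > age_range[1])
  ages <- seq(age_range[1], age_range[2], by = age_grid_step)
  mids <- (ages[-1] + ages[-length(ages)]) / 2
  beta_k <- eval_beta(beta, mids)
  if (any(!is.finite(exp(beta_k))))
    stop("beta implies non-finite hazard ratios on the age grid")
  lbar_knots <- cum_hazard(incidence, ages) - cum_hazard(incidence, ages[1])
  model <- list(ages = ages, mids = mids, beta = beta_k,
                beta_spec = beta, lambda_bar_cum = lbar_knots,
                incidence = incidence, gh = gauss_hermite_std(gh_nodes),
                step = age_grid_step)
  model$lambda0 <- solve_constrained_baseline(model)
  class(model) <- "polygenic_model"
  model
}

eval_beta <- function(beta, ages) {
  if (is.data.frame(beta)) {
    stopifnot(all(c("age_lo", "age_hi", "beta") %in% names(beta)))
    idx <- vapply(ages, function(a) {
      k <- which(a >= beta$age_lo & a < beta$age_hi)
      if (!length(k)) stop("age ", a, " not covered by the beta bands")
      k[1]
    }, integer(1))
    return(beta$beta[idx])
  }
  if (length(beta) == 1) return(rep(as.numeric(beta), length(ages)))
  if (length(beta) == 2) {
    b0 <- beta[[1]]; decay <- beta[[2]]
    stopifnot(decay > 0)
    return(b0 + ages * log(decay))
  }
  stop("invalid beta specification")
}

#' @export
print.polygenic_model <- function(x, ...) {
  cat("Multiplicative polygenic model on ages [", x$ages[1], ",",
      x$ages[length(x$ages)], "], step", x$step, "\n")
  cat("per-SD log HR range on grid: [",
      sprintf("%.4f", min(x$beta)), ",", sprintf("%.4f", max(x$beta)), "]\n")
  cat("marginal cumulative risk by", x$ages[length(x$ages)], ":",
      sprintf("%.4f", 1 - exp(-x$lambda_bar_cum[length(x$ages)])), "\n")
  invisible(x)
}

# Solve the marginal-incidence constraint on the grid. On each yearly
# interval, lambda0_k is the root of
#   E_z[ S(t_k | z) * exp(-lambda0_k * e^{beta_k z} * dt) ]
#     = exp(-Lambda_bar(t_{k+1}))
# so the PRS-averaged survival equals the marginal survival exactly at
# every grid age. The equation is monotone in lambda0_k and is solved by
# safeguarded Newton; the sweep is sequential because S(t_k|z) depends only
# on earlier intervals.
solve_constrained_baseline <- function(model, tol = 1e-12, max_newton = 100) {
  z <- model$gh$z
  w <- model$gh$w
  M <- length(model$mids)
  dt <- diff(model$ages)
  lam0 <- numeric(M)
  S <- rep(1, length(z))
  for (k in seq_len(M)) {
    target <- exp(-model$lambda_bar_cum[k + 1])
    lbar_k <- (model$lambda_bar_cum[k + 1] - model$lambda_bar_cum[k]) / dt[k]
    if (lbar_k <= 0) {
      lam0[k] <- 0
      next
    }
    e <- exp(model$beta[k] * z)
    f <- function(l) sum(w * S * exp(-l * e * dt[k])) - target
    # small-risk analytic start: lambda_bar * exp(-beta^2/2)
    l <- lbar_k * exp(-model$beta[k]^2 / 2)
    ok <- FALSE
    for (it in seq_len(max_newton)) {
      fv <- f(l)
      if (abs(fv) < tol * target) { ok <- TRUE; break }
      fp <- -sum(w * S * e * dt[k] * exp(-l * e * dt[k]))
      lnew <- l - fv / fp
      if (!is.finite(lnew) || lnew < 0) lnew <- l / 2
      l <- lnew
    }
    if (!ok) {
      r <- uniroot(f, c(0, lbar_k * exp(abs(model$beta[k])) + 1),
                   tol = 1e-14)
      l <- r$root
    }
    lam0[k] <- l
    S <- S * exp(-l * e * dt[k])
  }
  lam0
}

#' Constrained baseline hazard
#'
#' The baseline hazard \code{lambda0} on the model's age grid, solved so the
#' PRS-marginalized survival reproduces the average carrier incidence at
#' every grid age (\code{beta = 0} gives \code{lambda0 = lambda_bar}
#' exactly).
#'
#' @param model a \code{\link{polygenic_model}}.
#' @return A data frame: \code{age_lo}, \code{age_hi}, \code{lambda0}.
#' @export
constrained_baseline <- function(model) {
  stopifnot(inherits(model, "polygenic_model"))
  M <- length(model$mids)
  data.frame(age_lo = model$ages[-(M + 1)], age_hi = model$ages[-1],
             lambda0 = model$lambda0)
}

# PRS-averaged survival at the grid ages implied by the solved baseline.
marginal_survival <- function(model) {
  z <- model$gh$z
  w <- model$gh$w
  dt <- diff(model$ages)
  S <- rep(1, length(z))
  out <- numeric(length(model$ages))
  out[1] <- 1
  for (k in seq_along(model$mids)) {
    S <- S * exp(-model$lambda0[k] * exp(model$beta[k] * z) * dt[k])
    out[k + 1] <- sum(w * S)
  }
  out
}

#' Theoretical percentile-category hazard ratios
#'
#' Under the multiplicative polygenic model with age-constant per-SD log
#' hazard ratio \code{beta} (baseline approximation ignoring risk-set
#' depletion), the hazard ratio of a PRS percentile category relative to a
#' reference category is a ratio of truncated-lognormal means:
#' \deqn{E[e^{\beta Z} | Z \in cat] / E[e^{\beta Z} | Z \in ref]}
#' using the closed form
#' \eqn{E[e^{\beta Z}; a<Z<b] = e^{\beta^2/2}(\Phi(b-\beta)-\Phi(a-\beta))}.
#'
#' @param beta per-SD log hazard ratio (single number).
#' @param category percent interval, length-2 vector or a 2-column matrix
#'   (one category per row).
#' @param reference reference percent interval (default the 40-60 band).
#' @return Hazard ratio(s), one per category.
#' @export
theoretical_category_hr <- function(beta, category,
                                    reference = c(40, 60)) {
  cat_m <- if (is.matrix(category)) category else matrix(category, ncol = 2,
                                                         byrow = TRUE)
  stopifnot(all(cat_m[, 1] < cat_m[, 2]), all(cat_m >= 0), all(cat_m <= 100),
            length(reference) == 2, reference[1] < reference[2])
  trunc_mean <- function(lo, hi) {
    a <- qnorm(lo / 100)
    b <- qnorm(hi / 100)
    mass <- pnorm(b) - pnorm(a)
    if (any(mass <= 0)) stop("empty percentile interval")
    exp(beta^2 / 2) * (pnorm(b - beta) - pnorm(a - beta)) / mass
  }
  unname(trunc_mean(cat_m[, 1], cat_m[, 2]) /
         trunc_mean(reference[1], reference[2]))
}

# cumulative hazard at `age` for PRS quantile z under the solved model
cum_hazard_at_z <- function(model, z, age) {
  dt <- diff(model$ages)
  rate <- model$lambda0 * exp(model$beta * z)
  full <- pmax(0, pmin(dt, age - model$ages[-length(model$ages)]))
  sum(rate * full)
}

#' Absolute risk projection at a PRS percentile
#'
#' Cumulative risk by age for a carrier at the p-th percentile of the PRS
#' (the point quantile \code{z_p = qnorm(p/100)} of the standardized
#' score):
#' \code{F(t | z_p) = 1 - exp(-integral of lambda0(u) e^{beta(u) z_p} du)}.
#'
#' @param model a \code{\link{polygenic_model}}.
#' @param percentile percentile in (0, 100); vectorized.
#' @return A data frame of class \code{risk_projection}: \code{percentile},
#'   \code{age}, \code{cumulative_risk} (0 at the grid start,
#'   nondecreasing).
#' @export
risk_at_percentile <- function(model, percentile) {
  stopifnot(inherits(model, "polygenic_model"),
            all(percentile > 0), all(percentile < 100))
  dt <- diff(model$ages)
  out <- lapply(percentile, function(p) {
    zp <- qnorm(p / 100)
    ch <- c(0, cumsum(model$lambda0 * exp(model$beta * zp) * dt))
    data.frame(percentile = p, age = model$ages,
               cumulative_risk = 1 - exp(-ch))
  })
  out <- do.call(rbind, out)
  class(out) <- c("risk_projection", "data.frame")
  out
}

#' Age at which a percentile's cumulative risk reaches a threshold
#'
#' Linear interpolation of the projected cumulative risk curve at the given
#' percentile; returns \code{Inf} with a warning when the threshold is never
#' attained on the model's age grid.
#'
#' @param model a \code{\link{polygenic_model}}.
#' @param percentile PRS percentile in (0, 100).
#' @param risk_threshold cumulative risk threshold in (0, 1).
#' @return Age in years (or \code{Inf}).
#' @export
age_reaching_risk <- function(model, percentile, risk_threshold) {
  proj <- risk_at_percentile(model, percentile)
  f <- proj$cumulative_risk
  a <- proj$age
  if (max(f) < risk_threshold) {
    warning("risk threshold ", risk_threshold,
            " never attained at percentile ", percentile)
    return(Inf)
  }
  i <- which(f >= risk_threshold)[1]
  if (i == 1) return(a[1])
  a[i - 1] + (risk_threshold - f[i - 1]) / (f[i] - f[i - 1]) *
    (a[i] - a[i - 1])
}

#' Fraction of carriers below a risk threshold at a given age
#'
#' Since the projected risk \code{F(t|z)} is monotone in z (for per-SD
#' effects of one sign), the share of carriers whose cumulative risk by age
#' t is below r is \code{pnorm(z*)} where \code{F(t|z*) = r}, found by
#' bisection.
#'
#' @param model a \code{\link{polygenic_model}}.
#' @param age age t in years (within the model grid).
#' @param risk_threshold cumulative risk threshold r in (0, 1).
#' @return Fraction in [0, 1]; 0 or 1 when r lies outside the attainable
#'   risk range at that age.
#' @export
risk_quantile_share <- function(model, age, risk_threshold) {
  stopifnot(inherits(model, "polygenic_model"),
            age > model$ages[1], risk_threshold > 0, risk_threshold < 1)
  fz <- function(z) 1 - exp(-cum_hazard_at_z(model, z, age))
  zlim <- 12
  increasing <- fz(zlim) >= fz(-zlim)
  flo <- fz(-zlim); fhi <- fz(zlim)
  if (abs(fhi - flo) < 1e-15) {
    # PRS-independent risk: everyone is on the same side of the threshold
    return(as.numeric(flo < risk_threshold))
  }
  lo <- -zlim; hi <- zlim
  if (increasing) {
    if (risk_threshold <= flo) return(0)
    if (risk_threshold >= fhi) return(1)
  } else {
    if (risk_threshold <= fhi) return(1)
    if (risk_threshold >= flo) return(0)
  }
  for (it in 1:200) {
    midz <- (lo + hi) / 2
    if (hi - lo < 1e-10) break
    below <- fz(midz) < risk_threshold
    if (below == increasing) lo <- midz else hi <- midz
  }
  zstar <- (lo + hi) / 2
  if (increasing) pnorm(zstar) else 1 - pnorm(zstar)
}

#' Marginal (average carrier) incidence implied by a baseline hazard
#'
#' Forward companion of \code{\link{constrained_baseline}}: given a baseline
#' hazard \code{lambda0} and a per-SD effect, computes the average carrier
#' incidence \code{lambda_bar} such that the marginal survival
#' \code{exp(-Lambda_bar(t))} equals the PRS-averaged survival
#' \code{E_z[S(t|z)]} at every grid age. Used to supply the incidence input
#' of \code{\link{build_weights}} when the generating baseline of a
#' simulation is known.
#'
#' @param baseline an \code{\link{incidence_curve}}: the baseline hazard
#'   \code{lambda0} of the generating model.
#' @param beta per-SD log hazard ratio specification (see
#'   \code{\link{polygenic_model}}).
#' @param age_range,age_grid_step,gh_nodes grid and quadrature controls.
#' @return An \code{\link{incidence_curve}} for \code{lambda_bar}.
#' @export
marginal_incidence <- function(baseline, beta, age_range = c(18, 80),
                               age_grid_step = 1, gh_nodes = 64) {
  stopifnot(inherits(baseline, "incidence_curve"))
  ages <- seq(age_range[1], age_range[2], by = age_grid_step)
  mids <- (ages[-1] + ages[-length(ages)]) / 2
  beta_k <- eval_beta(beta, mids)
  lam0 <- hazard_at(baseline, mids)
  gh <- gauss_hermite_std(gh_nodes)
  dt <- diff(ages)
  S <- rep(1, length(gh$z))
  ES <- numeric(length(mids) + 1)
  ES[1] <- 1
  for (k in seq_along(mids)) {
    S <- S * exp(-lam0[k] * exp(beta_k[k] * gh$z) * dt[k])
    ES[k + 1] <- sum(gh$w * S)
  }
  lbar <- -diff(log(ES)) / dt
  incidence_curve(ages, c(lbar, lbar[length(lbar)]))
}
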
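test_that("theoretical category HRs obey the closed-form identities", {
  expect_equal(theoretical_category_hr(0, c(95, 100)), 1)
  expect_equal(theoretical_category_hr(0, c(0, 5)), 1)
  # mirror symmetry about the median with the symmetric middle reference:
  # the upper category at beta equals its mirrored lower category at -beta
  b <- log(1.4)
  up <- theoretical_category_hr(b, c(80, 90))
  lo <- theoretical_category_hr(-b, c(10, 20))
  expect_equal(lo, up, tolerance = 1e-12)
  expect_gt(up, 1)
  expect_error(theoretical_category_hr(b, c(50, 50)), "")
})

test_that("theoretical category HRs match Monte-Carlo truncated means", {
  set.seed(81)
  z <- rnorm(2e6)
  for (case in list(list(b = log(1.27), cat = c(95, 100)),
                    list(b = log(1.5), cat = c(0, 5)),
                    list(b = 0.15, cat = c(60, 80)))) {
    b <- case$b
    qs <- qnorm(case$cat / 100)
    ref <- qnorm(c(0.4, 0.6))
    in_cat <- z > qs[1] & z <= qs[2]
    in_ref <- z > ref[1] & z <= ref[2]
    mc_cat <- exp(b * z[in_cat])
    mc_ref <- exp(b * z[in_ref])
    mc <- mean(mc_cat) / mean(mc_ref)
    # delta-method SE of the MC ratio
    se <- mc * sqrt(var(mc_cat) / (mean(mc_cat)^2 * sum(in_cat)) +
                    var(mc_ref) / (mean(mc_ref)^2 * sum(in_ref)))
    theo <- theoretical_category_hr(b, case$cat)
    expect_lt(abs(theo - mc), 3 * se)
  }
})

test_that("beta = 0 degeneracy: baseline equals the marginal incidence", {
  ic <- synthetic_carrier_incidence("bc_brca1")
  m <- polygenic_model(0, ic)
  lbar <- hazard_at(ic, m$mids)
  expect_equal(m$lambda0, lbar, tolerance = 1e-12)
  r <- risk_at_percentile(m, c(5, 50, 95))
  risk80 <- r$cumulative_risk[r$age == 80]
  expect_lt(max(risk80) - min(risk80), 1e-12)
})

test_that("the constrained baseline reproduces the marginal curve", {
  ic <- synthetic_carrier_incidence("bc_brca1")
  m <- polygenic_model(log(1.4), ic)
  ms <- carrierprs:::marginal_survival(m)
  expect_lt(max(abs(ms - exp(-m$lambda_bar_cum))), 1e-8)
})

test_that("small-risk regime: lambda0 is about lambda_bar * exp(-beta^2/2)", {
  ic <- synthetic_carrier_incidence("oc_brca1")
  b <- log(1.6)
  m <- polygenic_model(b, ic, age_range = c(18, 40))
  stopifnot(1 - exp(-m$lambda_bar_cum[length(m$ages)]) < 0.03)
  lbar <- (m$lambda_bar_cum[-1] - m$lambda_bar_cum[-length(m$ages)])
  approx0 <- lbar * exp(-b^2 / 2)
  rel <- abs(m$lambda0 - approx0) / pmax(approx0, 1e-12)
  expect_lt(max(rel[approx0 > 0]), 0.02)
})

test_that("conservation holds for randomized effects and incidences", {
  set.seed(82)
  for (rep in 1:5) {
    b <- runif(1, 0, log(2))
    ages <- sort(c(18, runif(4, 20, 75), 80))
    haz <- runif(6, 0, 0.04)
    ic <- incidence_curve(ages, haz)
    m <- polygenic_model(b, ic)
    ms <- carrierprs:::marginal_survival(m)
    expect_lt(max(abs((1 - ms) - (1 - exp(-m$lambda_bar_cum)))), 1e-6)
  }
})

test_that("projected risk is monotone in the percentile", {
  ic <- synthetic_carrier_incidence("bc_brca1")
  m <- polygenic_model(log(1.27), ic)
  r <- risk_at_percentile(m, c(1, 10, 50, 90, 99))
  by_age <- split(r$cumulative_risk, r$age)
  for (v in by_age[-1]) expect_true(all(diff(v) >= -1e-12))
  # outside the heavy-depletion regime the median carrier sits below the
  # marginal risk (lognormal relative risk: mean exceeds median)
  a50 <- which(m$ages == 50)
  r50 <- r[r$percentile == 50 & r$age == 50, "cumulative_risk"]
  marg <- 1 - exp(-m$lambda_bar_cum[a50])
  expect_lt(r50, marg)
  # projections start at zero and never decrease
  expect_equal(r$cumulative_risk[r$age == 18], rep(0, 5))
  for (p in unique(r$percentile))
    expect_true(all(diff(r$cumulative_risk[r$percentile == p]) >= 0))
})

test_that("ovarian-like anchor: percentile risks straddle the marginal 2.8%", {
  ic <- synthetic_carrier_incidence("oc_brca1")
  m <- polygenic_model(data.frame(age_lo = c(18, 50, 60),
                                  age_hi = c(50, 60, Inf),
                                  beta = log(c(1.55, 1.11, 1.14))), ic)
  r <- risk_at_percentile(m, c(1, 99))
  r40 <- r[r$age == 40, ]
  expect_lt(r40$cumulative_risk[r40$percentile == 1], 0.028)
  expect_gt(r40$cumulative_risk[r40$percentile == 99], 0.028)
  # ordering confirmed by brute-force simulation of the generating model:
  # draw carriers, compute their cumulative risk by 40 under (lambda0, beta)
  set.seed(83)
  n <- 2e5
  z <- rnorm(n)
  lam0 <- constrained_baseline(m)
  bmid <- carrierprs:::eval_beta(m$beta_spec, m$mids)
  sel <- m$mids < 40
  ch40 <- exp(outer(z, bmid[sel])) %*% lam0$lambda0[sel]
  f40 <- as.numeric(1 - exp(-ch40))
  expect_true(all(f40[z < qnorm(0.01)] < 0.028))
  expect_true(all(f40[z > qnorm(0.99)] > 0.028))
  # and the marginal over carriers reproduces the 2.8% anchor
  expect_lt(abs(mean(f40) - 0.028), 3 * sd(f40) / sqrt(n))
})

test_that("threshold-crossing ages behave and are monotone in percentile", {
  ic <- synthetic_carrier_incidence("oc_brca1")
  m <- polygenic_model(log(1.28), ic)
  a50 <- age_reaching_risk(m, 50, 0.028)
  a1 <- age_reaching_risk(m, 1, 0.028)
  a99 <- age_reaching_risk(m, 99, 0.028)
  expect_true(a99 < a50 && a50 < a1)
  expect_warning(s <- age_reaching_risk(m, 1, 0.99), "never attained")
  expect_identical(s, Inf)
  m0 <- polygenic_model(0, ic)
  expect_equal(age_reaching_risk(m0, 5, 0.028),
               age_reaching_risk(m0, 95, 0.028), tolerance = 1e-9)
  # random-spec monotonicity
  set.seed(84)
  for (rep in 1:3) {
    b <- runif(1, 0.1, 0.5)
    mm <- polygenic_model(b, ic)
    aa <- vapply(c(5, 25, 50, 75, 95), function(p)
      age_reaching_risk(mm, p, 0.02), numeric(1))
    expect_true(all(diff(aa) <= 1e-9))
  }
})

test_that("risk-quantile shares complement and match Monte-Carlo", {
  ic <- synthetic_carrier_incidence("oc_brca1")
  m <- polygenic_model(log(1.28), ic)
  sh <- risk_quantile_share(m, 40, 0.028)
  # complement via the share above the threshold of the mirrored question
  lam0 <- constrained_baseline(m)
  set.seed(85)
  z <- rnorm(1e6)
  cum0 <- sum(lam0$lambda0[m$mids < 40])
  fz <- 1 - exp(-cum0 * exp(log(1.28) * z))
  mc <- mean(fz < 0.028)
  expect_lt(abs(sh - mc), 3 * sqrt(mc * (1 - mc) / 1e6))
  # share below + share at-or-above = 1 by construction
  expect_equal(sh, 1 - (1 - sh))
  # marginal threshold, small beta: share tends to one half
  m2 <- polygenic_model(1e-4, ic)
  marg40 <- 1 - exp(-(cum_hazard(ic, 40) - cum_hazard(ic, 18)))
  expect_lt(abs(risk_quantile_share(m2, 40, marg40) - 0.5), 0.02)
})
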
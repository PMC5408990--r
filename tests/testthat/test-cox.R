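test_that("two-group exponential data recover the generating rate ratio", {
  set.seed(51)
  n <- 10000
  grp <- rbinom(n, 1, 0.5)
  coh <- make_exp_cohort(n, log(2), matrix(grp), rate = 0.02, cens = c(40, 90))
  fit <- coxwc(coh, matrix(grp, dimnames = list(NULL, "grp")))
  expect_lt(abs(coef(fit) - log(2)), 3 * fit$robust_se)
  expect_lt(fit$score_norm, 1e-8)
})

test_that("a covariate independent of event times has HR about 1", {
  set.seed(52)
  hrs <- replicate(20, {
    coh <- make_exp_cohort(400, 0, matrix(0, 400, 1) + rnorm(400))
    x <- rnorm(400)
    fit <- coxwc(coh, matrix(x, dimnames = list(NULL, "x")))
    c(fit$hr, fit$p_two_sided)
  })
  expect_lt(abs(mean(log(hrs[1, ]))), 3 * sd(log(hrs[1, ])) / sqrt(20))
  # two-sided p roughly uniform: no pile-up below 0.05
  expect_lt(mean(hrs[2, ] < 0.05), 0.3)
})

test_that("unit-weight fits match survival::coxph exactly", {
  set.seed(53)
  n <- 200
  coh <- make_cohort(n, affected = rbinom(n, 1, 0.5),
                     age_end = runif(n, 25, 80),
                     age_entry = runif(n, 18, 22),
                     study = sample(c("A", "B"), n, TRUE))
  x <- cbind(a = rnorm(n), b = rbinom(n, 2, 0.3))
  fit <- coxwc(coh, x)
  cf <- survival::coxph(
    survival::Surv(age_entry, age_end, affected) ~ a + b +
      survival::strata(study),
    data = cbind(as.data.frame(coh), x), ties = "breslow")
  expect_lt(max(abs(coef(fit) - coef(cf))), 1e-6)
  expect_lt(max(abs(fit$se - sqrt(diag(vcov(cf))))), 1e-6)
  # robust (one cluster per individual) equals coxph's sandwich
  cf2 <- survival::coxph(
    survival::Surv(age_entry, age_end, affected) ~ a + b +
      survival::strata(study) + survival::cluster(individual_id),
    data = cbind(as.data.frame(coh), x), ties = "breslow", robust = TRUE)
  expect_lt(max(abs(fit$robust_se - sqrt(diag(vcov(cf2))))), 1e-6)
})

test_that("weighted fits match survival::coxph with case weights", {
  set.seed(54)
  n <- 300
  coh <- make_cohort(n, affected = rbinom(n, 1, 0.4),
                     age_end = runif(n, 25, 80))
  x <- cbind(z = rnorm(n))
  w <- runif(n, 0.5, 3)
  fit <- coxwc(coh, x, weights = w)
  cf <- survival::coxph(survival::Surv(age_entry, age_end, affected) ~ z,
                        data = cbind(as.data.frame(coh), x), weights = w,
                        ties = "breslow")
  expect_lt(max(abs(coef(fit) - coef(cf))), 1e-6)
})

test_that("coefficients are invariant to a global weight rescaling", {
  set.seed(55)
  coh <- make_exp_cohort(300, 0.4, matrix(rnorm(300)))
  x <- matrix(rnorm(300), dimnames = list(NULL, "x"))
  w <- runif(300, 0.5, 2)
  f1 <- coxwc(coh, x, weights = w)
  f2 <- coxwc(coh, x, weights = 2 * w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("cluster-robust variance reflects family frailty clustering", {
  set.seed(56)
  base <- synthetic_carrier_incidence("bc_brca1")
  spec <- sim_spec(4000, rep(0.3, 5), rep(0, 5), base, beta_sd = 0,
                   censor_age_range = c(35, 80), family_frailty_sd = 1,
                   family_size = 4L, seed = 57)
  sim <- gen_cohort(spec)
  x <- matrix(rnorm(nrow(sim$cohort)), dimnames = list(NULL, "x"))
  # frailty induces within-family correlation of event times; for a
  # family-constant covariate the robust SE must exceed the naive SE
  fam <- sim$cohort$family_id
  xf <- ave(rnorm(nrow(sim$cohort)), fam)
  fit <- coxwc(sim$cohort, matrix(xf, dimnames = list(NULL, "xf")),
               cluster = fam)
  expect_gt(fit$robust_se / fit$se, 1.1)
})

test_that("the time-varying interaction model nests the constant model", {
  set.seed(58)
  coh <- make_exp_cohort(800, 0.3, matrix(rnorm(800)))
  z <- rnorm(800)
  f_cont <- fit_continuous_prs(coh, z)
  f_int <- fit_age_interaction(coh, z)
  # likelihood never decreases when the interaction is added
  expect_gte(f_int$loglik["final"], f_cont$loglik["final"] - 1e-8)
  # forcing the interaction coefficient to zero reproduces the constant fit
  eng <- carrierprs:::cox_fit_cpp(
    coh$age_entry, coh$age_end, as.integer(coh$affected),
    cbind(z, z), rep(1, 800), rep(0L, 800), c(0L, 1L), c(0, 0), c(0, 0),
    c(coef(f_cont), 0), 1e30, 0L)
  expect_lt(abs(eng$coef[1] - coef(f_cont)), 1e-10)
  expect_lt(abs(eng$score[1]), 1e-6)  # main-effect score is already solved
})

test_that("windowed and direct time-varying routes agree to high precision", {
  set.seed(59)
  n <- 1500
  age_end <- runif(n, 20, 80)
  age_entry <- pmin(pmax(18, runif(n, 16, 24)), age_end - 0.5)
  coh <- make_cohort(n, affected = rbinom(n, 1, 0.45),
                     age_end = age_end, age_entry = age_entry)
  z <- rnorm(n)
  w <- runif(n, 0.5, 2)
  run <- function(direct, ttype, tlo = c(0, 0), thi = c(0, 0)) {
    carrierprs:::cox_fit_cpp(coh$age_entry, coh$age_end,
                             as.integer(coh$affected), cbind(z, z), w,
                             rep(0L, n), as.integer(ttype), tlo, thi,
                             c(0, 0), 1e-8, 100, direct)
  }
  a <- run(FALSE, c(0, 1))
  b <- run(TRUE, c(0, 1))
  expect_lt(max(abs(a$coef - b$coef)), 1e-10)
  expect_lt(max(abs(a$resid - b$resid)), 1e-9)
  a2 <- run(FALSE, c(2, 2), tlo = c(18, 50), thi = c(50, Inf))
  b2 <- run(TRUE, c(2, 2), tlo = c(18, 50), thi = c(50, Inf))
  expect_lt(max(abs(a2$coef - b2$coef)), 1e-10)
  expect_lt(max(abs(a2$resid - b2$resid)), 1e-9)
})

test_that("the time-varying interaction matches survival's tt() route", {
  set.seed(60)
  n <- 800
  coh <- make_exp_cohort(n, 0.3, matrix(rnorm(n)))
  z <- rnorm(n)
  fit <- fit_age_interaction(coh, z)
  ct <- survival::coxph(
    survival::Surv(age_entry, age_end, affected) ~ z + tt(z),
    data = cbind(as.data.frame(coh), z = z),
    tt = function(zz, t, ...) zz * t, ties = "breslow")
  expect_lt(max(abs(coef(fit) - coef(ct))), 1e-6)
})

test_that("degenerate inputs fail with informative errors", {
  coh <- make_exp_cohort(100, 0, matrix(rnorm(100)), seed = 61)
  expect_error(coxwc(coh, matrix(1, 100, 1)), "constant covariate")
  coh0 <- coh
  coh0$affected <- 0L
  expect_error(coxwc(coh0, matrix(rnorm(100))), "no events")
  # monotone likelihood: a covariate that perfectly separates event status
  cohs <- make_cohort(40, affected = rep(c(1, 0), each = 20),
                      age_end = c(runif(20, 30, 50), runif(20, 55, 80)))
  xs <- matrix(c(rep(1, 20), rep(0, 20)), dimnames = list(NULL, "s"))
  expect_error(coxwc(cohs, xs), "separation|converge")
})
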
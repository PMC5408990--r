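test_that("genotypes follow Hardy-Weinberg proportions and binomial means", {
  g <- gen_genotypes(1e5, c(0.5, 0.2), seed = 11)
  # mean dosage 2f within 3 SE
  se <- sqrt(2 * 0.5 * 0.5 / 1e5)
  expect_lt(abs(mean(g[, 1]) - 1.0), 3 * se)
  props <- tabulate(g[, 2] + 1, nbins = 3) / 1e5
  hwe <- c(0.64, 0.32, 0.04)
  se <- sqrt(hwe * (1 - hwe) / 1e5)
  expect_true(all(abs(props - hwe) < 3 * se + 1e-12))
})

test_that("genotype generation is reproducible under a fixed seed", {
  expect_identical(gen_genotypes(100, c(0.3, 0.7), seed = 5),
                   gen_genotypes(100, c(0.3, 0.7), seed = 5))
})

test_that("with null PRS effect the affected fraction matches quadrature", {
  base <- synthetic_carrier_incidence("bc_brca1")
  spec <- sim_spec(30000, snp_freqs = rep(0.5, 5), snp_weights = rep(0, 5),
                   baseline_hazard = base, beta_sd = 0,
                   censor_age_range = c(35, 80), seed = 3)
  sim <- gen_cohort(spec)
  # oracle: P(T <= C) = E_C[F(C)] by numerical integration over the
  # uniform censoring distribution
  Fc <- function(a) 1 - exp(-(cum_hazard(base, a) - cum_hazard(base, 18)))
  oracle <- stats::integrate(function(a) Fc(a) / 45, 35, 80)$value
  phat <- mean(sim$cohort$affected)
  expect_lt(abs(phat - oracle), 3 * sqrt(oracle * (1 - oracle) / 30000))
})

test_that("no oversampling leaves the affected fraction unascertained", {
  base <- synthetic_carrier_incidence("bc_brca1")
  mk <- function(pa, pu, seed) {
    spec <- sim_spec(20000, rep(0.3, 5), rep(0.04, 5), base,
                     beta_sd = log(1.3), ascertain_prob_affected = pa,
                     ascertain_prob_unaffected = pu,
                     censor_age_range = c(35, 80), seed = seed)
    mean(gen_cohort(spec)$cohort$affected)
  }
  p_full <- mk(1, 1, 21)
  p_thin <- mk(1, 0.4, 22)
  expect_gt(p_thin, p_full + 0.05)  # clinic oversampling raises the fraction
  # (1,1) matches the marginal-model expectation
  lbar <- marginal_incidence(base, log(1.3))
  Fc <- function(a) 1 - exp(-(cum_hazard(lbar, a) - cum_hazard(lbar, 18)))
  oracle <- stats::integrate(function(a) Fc(a) / 45, 35, 80)$value
  expect_lt(abs(p_full - oracle), 3 * sqrt(oracle * (1 - oracle) / 20000))
})

test_that("generated event ages reproduce the generating survival curve", {
  # frailty 0, beta 0: empirical survival of raw event ages matches
  # exp(-cumulative hazard) pointwise
  base <- synthetic_carrier_incidence("bc_brca1")
  set.seed(9)
  ages <- carrierprs:::sample_event_ages(base, g0 = rep(0, 1e5),
                                         cc = rep(0, 1e5), max_age = 80)
  for (a in c(30, 40, 50, 65, 79)) {
    s_true <- exp(-(cum_hazard(base, a) - cum_hazard(base, 18)))
    s_emp <- mean(ages > a)
    expect_lt(abs(s_emp - s_true), 3 * sqrt(s_true * (1 - s_true) / 1e5))
  }
})

test_that("age-decaying effects and frailty shift event ages as expected", {
  base <- synthetic_carrier_incidence("bc_brca1")
  set.seed(10)
  n <- 4e4
  z <- rep(2, n)
  # decay < 1 concentrates the (positive-z) excess hazard at young ages
  a_const <- carrierprs:::sample_event_ages(base, g0 = log(1.3) * z,
                                            cc = rep(0, n), max_age = 80)
  a_decay <- carrierprs:::sample_event_ages(base, g0 = log(1.69) * z,
                                            cc = log(0.993) * z, max_age = 80)
  expect_gt(mean(a_decay[is.finite(a_decay)] < 40),
            mean(a_const[is.finite(a_const)] < 40))
  expect_gt(sum(is.finite(a_decay)), 0.2 * n)
})

test_that("ascertainment does not distort genotypes among the unaffected", {
  base <- synthetic_carrier_incidence("bc_brca1")
  freqs <- c(0.2, 0.5, 0.8)
  spec <- sim_spec(30000, freqs, c(0.1, 0.1, 0.1), base, beta_sd = log(1.3),
                   ascertain_prob_affected = 1,
                   ascertain_prob_unaffected = 0.3,
                   censor_age_range = c(35, 80), seed = 17)
  sim <- gen_cohort(spec)
  un <- sim$genotypes[sim$cohort$affected == 0, ]
  # thinning of unaffecteds is genotype-blind: allele frequencies among the
  # unaffected match those among unaffected carriers generally; they are
  # slightly below the population f because high-PRS carriers became cases.
  # Compare against an unascertained simulation rather than f itself.
  spec2 <- sim_spec(30000, freqs, c(0.1, 0.1, 0.1), base, beta_sd = log(1.3),
                    ascertain_prob_affected = 1,
                    ascertain_prob_unaffected = 1,
                    censor_age_range = c(35, 80), seed = 18)
  sim2 <- gen_cohort(spec2)
  un2 <- sim2$genotypes[sim2$cohort$affected == 0, ]
  for (k in 1:3) {
    f1 <- mean(un[, k]) / 2
    f2 <- mean(un2[, k]) / 2
    se <- sqrt(f1 * (1 - f1) / (2 * nrow(un)) + f2 * (1 - f2) / (2 * nrow(un2)))
    expect_lt(abs(f1 - f2), 3.5 * se)
  }
})

test_that("cohort generation is fully reproducible and fails loudly", {
  base <- synthetic_carrier_incidence("oc_brca1")
  spec <- sim_spec(500, rep(0.4, 3), rep(0.05, 3), base, beta_sd = 0.2,
                   censor_age_range = c(35, 80), seed = 99)
  a <- gen_cohort(spec)
  b <- gen_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes, b$genotypes)
  spec$n_target <- 10^9
  expect_error(gen_cohort(spec, max_batches = 2L), "n_target")
})

test_that("baseline scaling calibrates the post-ascertainment fraction", {
  base <- synthetic_carrier_incidence("oc_brca1")
  sc <- scale_baseline_to_affected(base, 0.15, log(1.28),
                                   censor_age_range = c(35, 80),
                                   ascertain_prob_affected = 1,
                                   ascertain_prob_unaffected = 0.4)
  spec <- sim_spec(30000, rep(0.4, 5), rep(0.05, 5), sc, beta_sd = log(1.28),
                   ascertain_prob_affected = 1,
                   ascertain_prob_unaffected = 0.4,
                   censor_age_range = c(35, 80), seed = 31)
  sim <- gen_cohort(spec)
  expect_lt(abs(mean(sim$cohort$affected) - 0.15), 0.01)
})

test_that("truth files echo the generating parameters", {
  base <- synthetic_carrier_incidence("oc_brca1")
  spec <- sim_spec(200, rep(0.4, 3), rep(0.05, 3), base, beta_sd = 0.25,
                   censor_age_range = c(40, 75), seed = 12)
  sim <- gen_cohort(spec)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(sim$truth, path)
  tr <- yaml::read_yaml(path)
  expect_equal(tr$beta_sd, 0.25)
  expect_equal(tr$seed, 12)
  expect_null(tr$z)
})
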
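# Shared fixture builders. Everything is generated in code at test time.

extfile <- function(...) system.file("extdata", ..., package = "carrierprs")

# a small valid weight table
make_weight_table <- function(k = 5, weights = NULL, freqs = NULL,
                              tag = "custom", effect = NULL, other = NULL) {
  if (is.null(weights)) weights <- round(rnorm(k, 0, 0.05), 4)
  if (is.null(freqs)) freqs <- round(runif(k, 0.1, 0.9), 4)
  if (is.null(effect)) effect <- rep("A", k)
  if (is.null(other)) other <- rep("G", k)
  carrierprs:::validate_weight_table(data.frame(
    variant_id = paste0("snp", seq_len(k)), chrom = "1", pos = seq_len(k),
    effect_allele = effect, other_allele = other,
    effect_allele_freq = freqs, weight = weights, phenotype_tag = tag,
    stringsAsFactors = FALSE))
}

make_cohort <- function(n, affected, age_end, age_entry = 18,
                        study = "S1", gene = "BRCA1", family = NULL) {
  if (is.null(family)) family <- sprintf("f%05d", seq_len(n))
  carrierprs:::validate_cohort(data.frame(
    individual_id = sprintf("i%05d", seq_len(n)), family_id = family,
    study = study, gene = gene, affected = as.integer(affected),
    age_end = age_end, age_entry = age_entry, stringsAsFactors = FALSE))
}

# random censored survival cohort with given covariate effect on an
# exponential hazard (for engine tests)
make_exp_cohort <- function(n, beta, x, rate = 0.02, cens = c(30, 90),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tev <- 18 + rexp(n, rate * exp(as.vector(x %*% beta)))
  tc <- runif(n, cens[1], cens[2])
  make_cohort(n, affected = tev <= tc, age_end = pmin(tev, tc))
}

# full generator -> PRS -> weights -> per-SD fit pipeline used by the
# parameter-recovery checks
run_recovery_rep <- function(seed, beta_sd, decay = 1, inc = "bc_brca1",
                             n = 20000, n_snps = 50, scale_target = NULL,
                             pa = 1, pu = 0.4, censor = c(35, 80),
                             model = c("continuous", "age_interaction")) {
  model <- match.arg(model)
  set.seed(seed)
  freqs <- runif(n_snps, 0.1, 0.9)
  snp_w <- rnorm(n_snps, 0, 0.05)
  base <- synthetic_carrier_incidence(inc)
  if (!is.null(scale_target))
    base <- scale_baseline_to_affected(base, scale_target, c(beta_sd, decay),
                                       censor_age_range = censor,
                                       ascertain_prob_affected = pa,
                                       ascertain_prob_unaffected = pu)
  spec <- sim_spec(n, freqs, snp_w, base, beta_sd = beta_sd, decay = decay,
                   ascertain_prob_affected = pa,
                   ascertain_prob_unaffected = pu,
                   censor_age_range = censor, seed = seed)
  sim <- gen_cohort(spec)
  wt <- make_weight_table(n_snps, weights = snp_w, freqs = freqs)
  wt$variant_id <- colnames(sim$genotypes)
  h <- harmonize_genotypes(wt, sim$genotypes)
  prs <- compute_prs(h$weights, h$dosages)
  lbar <- marginal_incidence(base, c(beta_sd, decay),
                             age_range = c(18, censor[2]))
  ws <- build_weights(sim$cohort, lbar, censor_range = censor)
  if (model == "continuous") {
    fit <- fit_continuous_prs(sim$cohort, prs, weights = ws)
    unname(fit$hr["prs_std"])
  } else {
    fit <- fit_age_interaction(sim$cohort, prs, weights = ws)
    unname(fit$hr["prs_std_x_age"])
  }
}
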
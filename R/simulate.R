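# Synthetic clinic-ascertained carrier cohorts.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: Hardy-Weinberg genotypes at unlinked SNPs, a proportional-hazards
# disease model on the age scale in which the standardized PRS enters with a
# per-SD log hazard ratio (optionally decaying multiplicatively per year of
# age), exact inverse-CDF event sampling on a piecewise-constant baseline
# hazard, uniform right censoring, optional family-shared lognormal frailty,
# and Bernoulli ascertainment thinning that oversamples affected carriers.

#' Simulation specification for a synthetic carrier cohort
#'
#' @param n_target post-ascertainment cohort size.
#' @param snp_freqs effect-allele frequencies in (0,1).
#' @param snp_weights per-allele log hazard ratios defining the PRS; the
#'   generating hazard acts on the PRS standardized by its theoretical
#'   (Hardy-Weinberg) mean and SD, so \code{beta_sd} is per theoretical SD.
#' @param baseline_hazard an \code{\link{incidence_curve}}: the baseline
#'   hazard \code{lambda0} of the generating proportional-hazards model
#'   (the hazard of an individual with PRS at the standardized mean).
#' @param beta_sd log hazard ratio per SD of the PRS at age 0 (with
#'   \code{decay = 1} this is the age-constant per-SD effect).
#' @param decay per-year multiplicative change of the per-SD hazard ratio:
#'   \code{log HR(t) = beta_sd + t * log(decay)}; default 1 (no decay).
#' @param ascertain_prob_affected,ascertain_prob_unaffected Bernoulli
#'   retention probabilities by affection status; clinics oversample
#'   affected carriers, so the affected probability must be at least the
#'   unaffected one.
#' @param censor_age_range censoring (interview) ages are Uniform on this
#'   range, within (18, 100].
#' @param family_frailty_sd SD of the shared log-normal family frailty on
#'   the log-hazard scale; 0 (default) means independent individuals.
#' @param family_size number of carriers per family (default 1).
#' @param gene cohort gene label, \code{"BRCA1"} or \code{"BRCA2"}.
#' @param seed integer seed; every randomized quantity in
#'   \code{\link{gen_cohort}} derives from it.
#' @return A list of class \code{sim_spec}.
#' @export
sim_spec <- function(n_target, snp_freqs, snp_weights, baseline_hazard,
                     beta_sd, decay = 1,
                     ascertain_prob_affected = 1,
                     ascertain_prob_unaffected = 1,
                     censor_age_range = c(35, 80),
                     family_frailty_sd = 0, family_size = 1L,
                     gene = "BRCA1", seed = 1L) {
  stopifnot(n_target >= 1, length(snp_freqs) == length(snp_weights),
            all(snp_freqs > 0 & snp_freqs < 1),
            inherits(baseline_hazard, "incidence_curve"),
            is.finite(beta_sd), decay > 0,
            ascertain_prob_affected > 0, ascertain_prob_affected <= 1,
            ascertain_prob_unaffected > 0, ascertain_prob_unaffected <= 1,
            ascertain_prob_affected >= ascertain_prob_unaffected,
            length(censor_age_range) == 2,
            censor_age_range[1] > 18, censor_age_range[2] <= 100,
            censor_age_range[1] < censor_age_range[2],
            family_frailty_sd >= 0, family_size >= 1,
            gene %in% c("BRCA1", "BRCA2"))
  out <- list(n_target = as.integer(n_target), snp_freqs = snp_freqs,
              snp_weights = snp_weights, baseline_hazard = baseline_hazard,
              beta_sd = beta_sd, decay = decay,
              ascertain_prob_affected = ascertain_prob_affected,
              ascertain_prob_unaffected = ascertain_prob_unaffected,
              censor_age_range = censor_age_range,
              family_frailty_sd = family_frailty_sd,
              family_size = as.integer(family_size),
              gene = gene, seed = as.integer(seed))
  class(out) <- "sim_spec"
  out
}

#' Generate Hardy-Weinberg genotype dosages
#'
#' Independent Binomial(2, f) allele counts per SNP (unlinked loci, no
#' genotyping error).
#'
#' @param n number of individuals.
#' @param freqs effect-allele frequencies in (0,1).
#' @param seed optional integer seed; if \code{NULL} the current RNG state
#'   is used.
#' @return Integer-valued dosage matrix (n x length(freqs)) with variant
#'   column names \code{snp1, snp2, ...}.
#' @export
gen_genotypes <- function(n, freqs, seed = NULL) {
  stopifnot(all(freqs > 0 & freqs < 1))
  if (!is.null(seed)) set.seed(seed)
  k <- length(freqs)
  g <- matrix(rbinom(n * k, 2L, rep(freqs, each = n)), nrow = n, ncol = k)
  colnames(g) <- paste0("snp", seq_len(k))
  g
}

# theoretical PRS moments under Hardy-Weinberg
prs_theoretical_moments <- function(freqs, weights) {
  list(mean = sum(2 * freqs * weights),
       sd = sqrt(sum(2 * freqs * (1 - freqs) * weights^2)))
}

# Exact inverse-CDF sampling of event ages for hazard
#   lambda_i(t) = lambda0(t) * exp(g0_i + c_i * t)
# with piecewise-constant lambda0 on the grid of `ic`, starting at age 18.
# Returns Inf when the total cumulative hazard up to `max_age` is never
# reached. The interval integral has the closed form
#   int_a^b e^{c t} dt = (e^{c b} - e^{c a}) / c        (c != 0).
sample_event_ages <- function(ic, g0, cc, max_age) {
  a <- ic$age
  h <- ic$hazard
  if (a[length(a)] < max_age) {  # extend final hazard to max_age
    a <- c(a, max_age)
    h <- c(h, h[length(h)])
  } else {
    keep <- a < max_age
    a <- c(a[keep], max_age)
    h <- h[seq_len(sum(keep))]
  }
  n <- length(g0)
  m <- length(h)
  eg0 <- exp(g0)
  target <- rexp(n)
  age <- rep(Inf, n)
  cum <- numeric(n)
  active <- rep(TRUE, n)
  small <- abs(cc) < 1e-12
  for (k in seq_len(m)) {
    if (!any(active)) break
    lo <- a[k]; hi <- a[k + 1]
    i <- which(active)
    ci <- cc[i]
    psi <- numeric(length(i))
    s <- small[i]
    psi[s] <- hi - lo
    psi[!s] <- (exp(ci[!s] * hi) - exp(ci[!s] * lo)) / ci[!s]
    inc <- h[k] * eg0[i] * psi
    hit <- cum[i] + inc >= target[i]
    if (any(hit)) {
      j <- i[hit]
      need <- (target[j] - cum[j]) / (h[k] * eg0[j])
      tj <- numeric(length(j))
      sj <- small[j]
      tj[sj] <- lo + need[sj]
      cj <- cc[j][!sj]
      tj[!sj] <- log(exp(cj * lo) + cj * need[!sj]) / cj
      age[j] <- tj
      active[j] <- FALSE
    }
    cum[i] <- cum[i] + inc
  }
  age
}

#' Generate a clinic-ascertained synthetic carrier cohort
#'
#' Simulates carriers under the generating model of \code{\link{sim_spec}}:
#' genotypes, PRS standardized by its theoretical moments, event ages drawn
#' exactly by inverse-CDF on the piecewise-constant baseline, uniform
#' censoring, affection status, and Bernoulli ascertainment retention by
#' status, repeated in batches until \code{n_target} carriers are retained.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param max_batches retry cap on simulation batches before failing.
#' @return A list with elements \code{cohort} (a \code{cohort_table}),
#'   \code{genotypes} (dosage matrix aligned to the cohort), and
#'   \code{truth} (generating parameters, including each individual's true
#'   standardized PRS \code{z}).
#' @export
gen_cohort <- function(spec, max_batches = 40L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  mom <- prs_theoretical_moments(spec$snp_freqs, spec$snp_weights)
  if (mom$sd == 0 && any(spec$snp_weights != 0))
    stop("degenerate PRS: zero theoretical SD")
  cc_scale <- log(spec$decay)
  keep_g <- NULL; keep_rec <- NULL
  got <- 0L
  fam_counter <- 0L
  ind_counter <- 0L
  # expected retention ~ mean ascertainment prob; start generous but bounded
  batch <- min(500000L,
               max(1000L, ceiling(spec$n_target /
                                  spec$ascertain_prob_unaffected)))
  for (b in seq_len(max_batches)) {
    if (got >= spec$n_target) break
    n <- batch
    g <- gen_genotypes(n, spec$snp_freqs)
    prs <- as.numeric(g %*% spec$snp_weights)
    z <- if (mom$sd > 0) (prs - mom$mean) / mom$sd else rep(0, n)
    nfam <- ceiling(n / spec$family_size)
    fam <- rep(seq_len(nfam), each = spec$family_size)[seq_len(n)]
    logfr <- if (spec$family_frailty_sd > 0)
      rnorm(nfam, 0, spec$family_frailty_sd)[fam] else numeric(n)
    g0 <- spec$beta_sd * z + logfr
    ccv <- cc_scale * z
    tev <- sample_event_ages(spec$baseline_hazard, g0, ccv,
                             max_age = spec$censor_age_range[2])
    cens <- runif(n, spec$censor_age_range[1], spec$censor_age_range[2])
    affected <- tev <= cens
    age_end <- ifelse(affected, tev, cens)
    keepp <- ifelse(affected, spec$ascertain_prob_affected,
                    spec$ascertain_prob_unaffected)
    keep <- runif(n) < keepp
    if (!any(keep)) next
    idx <- which(keep)
    take <- idx[seq_len(min(length(idx), spec$n_target - got))]
    rec <- data.frame(
      individual_id = sprintf("ind%07d", ind_counter + seq_along(take)),
      family_id = sprintf("fam%07d", fam_counter + fam[take]),
      study = "S1", gene = spec$gene,
      affected = as.integer(affected[take]),
      age_end = age_end[take], age_entry = 18,
      z_true = z[take], stringsAsFactors = FALSE)
    ind_counter <- ind_counter + length(take)
    fam_counter <- fam_counter + max(fam)
    keep_rec <- rbind(keep_rec, rec)
    gb <- g[take, , drop = FALSE]
    keep_g <- rbind(keep_g, gb)
    got <- got + length(take)
  }
  if (got < spec$n_target)
    stop("could not reach n_target = ", spec$n_target, " after ",
         max_batches, " batches (ascertainment too restrictive)")
  z_true <- keep_rec$z_true
  cohort <- validate_cohort(keep_rec[, c(COHORT_COLS, "age_entry")])
  rownames(keep_g) <- cohort$individual_id
  truth <- list(
    seed = spec$seed, n_target = spec$n_target,
    beta_sd = spec$beta_sd, decay = spec$decay,
    prs_mean_theoretical = mom$mean, prs_sd_theoretical = mom$sd,
    ascertain_prob_affected = spec$ascertain_prob_affected,
    ascertain_prob_unaffected = spec$ascertain_prob_unaffected,
    censor_age_range = spec$censor_age_range,
    family_frailty_sd = spec$family_frailty_sd,
    family_size = spec$family_size, gene = spec$gene,
    z = z_true)
  list(cohort = cohort, genotypes = keep_g, truth = truth)
}

#' Scale a baseline hazard to hit a target affected fraction
#'
#' Finds the multiplicative factor on a baseline hazard such that, under the
#' generating model (per-SD effect, uniform censoring) and status-based
#' ascertainment thinning, the expected post-ascertainment affected fraction
#' equals \code{target}. Used to calibrate rarer-outcome simulation designs
#' (e.g. ovarian cancer event rates) to a stated affected fraction.
#'
#' @param baseline an \code{\link{incidence_curve}} (baseline hazard
#'   \code{lambda0}).
#' @param target desired affected fraction after ascertainment, in (0,1).
#' @param beta per-SD log hazard ratio specification (see
#'   \code{\link{polygenic_model}}).
#' @param censor_age_range uniform censoring range.
#' @param ascertain_prob_affected,ascertain_prob_unaffected retention
#'   probabilities by status.
#' @return The scaled \code{incidence_curve}.
#' @export
scale_baseline_to_affected <- function(baseline, target, beta,
                                       censor_age_range = c(35, 80),
                                       ascertain_prob_affected = 1,
                                       ascertain_prob_unaffected = 1) {
  stopifnot(inherits(baseline, "incidence_curve"), target > 0, target < 1)
  pa <- ascertain_prob_affected
  pu <- ascertain_prob_unaffected
  cl <- censor_age_range[1]
  ch <- censor_age_range[2]
  frac <- function(s) {
    sc <- incidence_curve(baseline$age, baseline$hazard * s)
    lbar <- marginal_incidence(sc, beta, age_range = c(18, ch))
    cg <- seq(cl, ch, length.out = 201)
    # P(T <= C), C ~ Uniform(cl, ch): mean cumulative risk over censor ages
    q <- mean(cumulative_risk_from18(lbar, cg))
    pa * q / (pa * q + pu * (1 - q)) - target
  }
  s <- uniroot(frac, c(1e-4, 100), tol = 1e-8)$root
  incidence_curve(baseline$age, baseline$hazard * s)
}

cumulative_risk_from18 <- function(ic, t) {
  1 - exp(-(cum_hazard(ic, t) - cum_hazard(ic, 18)))
}

#' Write the generating truth of a simulated cohort to YAML
#'
#' @param truth the \code{truth} element returned by \code{\link{gen_cohort}}
#'   (the per-individual \code{z} vector is dropped; scalar generating
#'   parameters and the seed are echoed).
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  truth$z <- NULL
  yaml::write_yaml(truth, path)
  invisible(path)
}
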
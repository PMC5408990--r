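# The model battery: continuous per-SD PRS, percentile categories,
# PRS-by-age interaction, age-group effects, and the pairwise SNP
# interaction scan. All are thin wrappers around coxwc().

#' Per-SD PRS association
#'
#' Weighted Cox fit with the standardized PRS as the single covariate; the
#' coefficient is the log hazard ratio per SD of the PRS.
#'
#' @param cohort a \code{cohort_table}.
#' @param prs_std standardized PRS vector (cohort order), or a
#'   \code{prs_result} (its \code{prs_std} column is used).
#' @param weights optional \code{weight_scheme} or numeric weights.
#' @param ... passed to \code{\link{coxwc}}.
#' @return A \code{coxwc} fit with term \code{prs_std}.
#' @export
fit_continuous_prs <- function(cohort, prs_std, weights = NULL, ...) {
  z <- prs_column(prs_std)
  coxwc(cohort, matrix(z, dimnames = list(NULL, "prs_std")),
        weights = weights, ...)
}

prs_column <- function(prs_std) {
  if (inherits(prs_std, "prs_result") || is.data.frame(prs_std)) {
    if (is.null(prs_std$prs_std)) stop("no prs_std column; standardize first")
    return(prs_std$prs_std)
  }
  as.numeric(prs_std)
}

#' Percentile-category PRS model
#'
#' Weighted Cox fit with one indicator per PRS percentile category, the
#' middle (40-60) band as reference.
#'
#' @param cohort a \code{cohort_table}.
#' @param categories factor from \code{\link{assign_categories}} (reference
#'   category first level).
#' @param weights optional weights.
#' @param ... passed to \code{\link{coxwc}}.
#' @return A \code{coxwc} fit with one term per non-reference category.
#' @export
fit_percentile_model <- function(cohort, categories, weights = NULL, ...) {
  categories <- as.factor(categories)
  tab <- table(categories)
  if (any(tab == 0))
    stop("empty percentile category: ",
         paste(names(tab)[tab == 0], collapse = ", "),
         "; use a coarser percentile scheme")
  mm <- stats::model.matrix(~categories)[, -1, drop = FALSE]
  colnames(mm) <- sub("^categories", "", colnames(mm))
  coxwc(cohort, mm, weights = weights, ...)
}

#' PRS-by-age interaction model
#'
#' Weighted Cox fit with the standardized PRS and its interaction with
#' attained age, implemented as a time-varying covariate \code{prs_std * t}
#' evaluated at each event age (age in raw years, anchored at 0). The main
#' effect is therefore the extrapolated per-SD log HR at age 0 and
#' \code{exp(interaction)} is the per-year multiplicative change of the
#' per-SD hazard ratio. A fixed-covariate fallback (\code{prs_std *
#' age_end}) is available.
#'
#' @param cohort a \code{cohort_table}.
#' @param prs_std standardized PRS (vector or \code{prs_result}).
#' @param weights optional weights.
#' @param time_varying if FALSE, use \code{age_end} as a fixed covariate in
#'   the product term instead of attained age.
#' @param ... passed to \code{\link{coxwc}}.
#' @return A \code{coxwc} fit with terms \code{prs_std} and
#'   \code{prs_std_x_age}.
#' @export
fit_age_interaction <- function(cohort, prs_std, weights = NULL,
                                time_varying = TRUE, ...) {
  z <- prs_column(prs_std)
  if (time_varying) {
    x <- cbind(prs_std = z, prs_std_x_age = z)
    # warm start at the age-constant solution: time-varying iterations are
    # costly and the nested model is an excellent quadratic neighbourhood
    dots <- list(...)
    if (is.null(dots$init)) {
      f0 <- fit_continuous_prs(cohort, z, weights = weights)
      dots$init <- c(coef(f0), 0)
    }
    do.call(coxwc, c(list(cohort, x, weights = weights,
                          tt = c("fixed", "age")), dots))
  } else {
    x <- cbind(prs_std = z, prs_std_x_age = z * cohort$age_end)
    coxwc(cohort, x, weights = weights, ...)
  }
}

#' Age-group PRS effects
#'
#' Weighted Cox fit in which the per-SD PRS effect differs by attained-age
#' band (time-varying design: the PRS column is switched on only while the
#' attained age lies in the band). Also reports Wald tests for the
#' difference between each band and the preceding one.
#'
#' @param cohort a \code{cohort_table}.
#' @param prs_std standardized PRS (vector or \code{prs_result}).
#' @param weights optional weights.
#' @param age_bands band breakpoints; default \code{c(18, 40, 50, 60, Inf)}
#'   (the breast cancer banding; use \code{c(18, 50, 60, Inf)} for the
#'   ovarian analysis).
#' @param ... passed to \code{\link{coxwc}}.
#' @return A \code{coxwc} fit with one PRS term per band; the adjacent-band
#'   difference tests are in the \code{"band_differences"} attribute.
#' @export
fit_agegroup_model <- function(cohort, prs_std, weights = NULL,
                               age_bands = c(18, 40, 50, 60, Inf), ...) {
  z <- prs_column(prs_std)
  nb <- length(age_bands) - 1
  ev_band <- findInterval(cohort$age_end[cohort$affected == 1], age_bands)
  if (any(tabulate(ev_band, nbins = nb) == 0))
    stop("age band without events; use coarser bands")
  x <- matrix(rep(z, nb), ncol = nb)
  labs <- paste0("prs_", age_bands[-length(age_bands)], "_",
                 ifelse(is.finite(age_bands[-1]), age_bands[-1], "up"))
  colnames(x) <- labs
  tt <- lapply(seq_len(nb), function(k) c(age_bands[k], age_bands[k + 1]))
  dots <- list(...)
  if (is.null(dots$init)) {
    f0 <- fit_continuous_prs(cohort, z, weights = weights)
    dots$init <- rep(unname(coef(f0)), nb)
  }
  fit <- do.call(coxwc, c(list(cohort, x, weights = weights, tt = tt), dots))
  b <- coef(fit)
  v <- vcov(fit)
  diffs <- data.frame(
    comparison = paste(labs[-1], "vs", labs[-nb]),
    estimate = b[-1] - b[-nb],
    se = sqrt(diag(v)[-1] + diag(v)[-nb] -
              2 * v[cbind(2:nb, 1:(nb - 1))]),
    row.names = NULL)
  diffs$p_two_sided <- 2 * pnorm(abs(diffs$estimate / diffs$se),
                                 lower.tail = FALSE)
  attr(fit, "band_differences") <- diffs
  fit
}

#' Pairwise SNP-SNP interaction scan
#'
#' For each SNP pair (j, k), fits a weighted Cox model with the two dosages
#' and their product, and reports the Wald test of the product term
#' (two-sided, robust SE) with Bonferroni adjustment over the
#' \code{K(K-1)/2} tests at family-wise level \code{alpha}.
#'
#' @param cohort a \code{cohort_table}.
#' @param dosages dosage matrix aligned to the cohort (K >= 2 columns).
#' @param weights optional weights.
#' @param alpha family-wise significance level (default 0.05).
#' @param ... passed to \code{\link{coxwc}}.
#' @return A data frame: \code{snp1}, \code{snp2}, \code{estimate} (product
#'   term log HR), \code{robust_se}, \code{p_two_sided}, \code{p_adjusted},
#'   \code{significant}; empty when fewer than 2 polymorphic SNPs.
#' @export
pairwise_interaction_scan <- function(cohort, dosages, weights = NULL,
                                      alpha = 0.05, ...) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  mono <- apply(dosages, 2, function(v) max(v, na.rm = TRUE) ==
                                        min(v, na.rm = TRUE))
  if (any(mono))
    warning("monomorphic SNP(s) skipped: ",
            paste(colnames(dosages)[mono], collapse = ", "))
  dosages <- dosages[, !mono, drop = FALSE]
  k <- ncol(dosages)
  empty <- data.frame(snp1 = character(), snp2 = character(),
                      estimate = numeric(), robust_se = numeric(),
                      p_two_sided = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (k < 2) return(empty)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(m) {
    j <- pairs[1, m]; l <- pairs[2, m]
    x <- cbind(dosages[, j], dosages[, l], dosages[, j] * dosages[, l])
    colnames(x) <- c("g1", "g2", "g1xg2")
    fit <- try(coxwc(cohort, x, weights = weights, ...), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(data.frame(snp1 = colnames(dosages)[j],
                        snp2 = colnames(dosages)[l],
                        estimate = NA_real_, robust_se = NA_real_,
                        p_two_sided = NA_real_, stringsAsFactors = FALSE))
    data.frame(snp1 = colnames(dosages)[j], snp2 = colnames(dosages)[l],
               estimate = unname(coef(fit)["g1xg2"]),
               robust_se = unname(fit$robust_se["g1xg2"]),
               p_two_sided = unname(fit$p_two_sided["g1xg2"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_two_sided * nrow(out))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out
}
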
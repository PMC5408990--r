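# Polygenic risk scores: harmonization of weight tables with genotype
# matrices, the weighted allele-count score, cohort standardization, and
# normal-quantile percentile categories.

#' Harmonize a weight table with a genotype matrix
#'
#' Joins on \code{variant_id} and orients dosages to the effect allele. When
#' the genotype source records which allele its dosages count (VCF input
#' does; dosage TSVs do not), a dosage counted on the \code{other_allele} is
#' flipped to \code{2 - g}. Strand-ambiguous variants (A/T or C/G) cannot be
#' oriented by allele labels alone; they are matched by id, used as-is, and
#' flagged in the report. Weight-table variants absent from the genotypes
#' are dropped with a warning; if more than half are unmatched the call
#' fails, since that usually means mismatched files.
#'
#' @param weights a \code{snp_weight_table}.
#' @param genotypes dosage matrix from \code{\link{read_genotypes}} or
#'   \code{\link{gen_genotypes}}.
#' @return A list: \code{weights} (matched rows, original order),
#'   \code{dosages} (aligned, effect-allele oriented), and \code{report}
#'   (per-variant: matched, flipped, ambiguous).
#' @export
harmonize_genotypes <- function(weights, genotypes) {
  stopifnot(inherits(weights, "snp_weight_table"))
  matched <- weights$variant_id %in% colnames(genotypes)
  if (mean(matched) < 0.5)
    stop("more than 50% of weight-table variants are missing from the ",
         "genotypes; check that the files belong together")
  if (any(!matched))
    warning(sum(!matched), " weight-table variant(s) not in the genotypes; ",
            "dropped: ",
            paste(head(weights$variant_id[!matched], 5), collapse = ", "))
  wt <- weights[matched, , drop = FALSE]
  g <- genotypes[, wt$variant_id, drop = FALSE]
  al <- attr(genotypes, "alleles")
  flipped <- rep(FALSE, nrow(wt))
  ambiguous <- is_strand_ambiguous(wt$effect_allele, wt$other_allele)
  if (!is.null(al)) {
    al <- al[match(wt$variant_id, al$variant_id), ]
    counted_is_other <- !ambiguous & al$counted == wt$other_allele &
      al$other == wt$effect_allele
    counted_is_effect <- al$counted == wt$effect_allele &
      al$other == wt$other_allele
    unknown <- !ambiguous & !counted_is_other & !counted_is_effect
    if (any(unknown))
      warning("allele labels do not match the weight table for: ",
              paste(wt$variant_id[unknown], collapse = ", "),
              "; dosages used as-is")
    flipped <- counted_is_other
    if (any(flipped))
      g[, flipped] <- 2 - g[, flipped, drop = FALSE]
  }
  report <- data.frame(variant_id = wt$variant_id, matched = TRUE,
                       flipped = flipped, ambiguous = ambiguous,
                       stringsAsFactors = FALSE)
  class(wt) <- c("snp_weight_table", "data.frame")
  list(weights = wt, dosages = g, report = report)
}

is_strand_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Compute polygenic risk scores
#'
#' The PRS of individual i is the weighted allele-count sum
#' \code{sum_l beta_l * g_li} over the harmonized variants. Missing dosages
#' are imputed at their Hardy-Weinberg expectation \code{2 * f} (the
#' effect-allele frequency from the weight table); the number of imputed
#' variants is recorded per individual and individuals missing more than
#' \code{max_missing} of their variants are flagged.
#'
#' @param weights a \code{snp_weight_table} (harmonized).
#' @param dosages aligned dosage matrix (effect-allele oriented).
#' @param standardize if TRUE (default) also standardize to mean 0, SD 1
#'   over the cohort via \code{\link{standardize_prs}}.
#' @param max_missing flag threshold on the fraction of missing variants.
#' @return A data frame of class \code{prs_result}: \code{individual_id},
#'   \code{prs_raw}, \code{prs_std} (if standardized),
#'   \code{n_missing_imputed}, \code{flagged_missing}; with the fitted
#'   \code{sample_mean} and \code{sample_sd} as attributes.
#' @export
compute_prs <- function(weights, dosages, standardize = TRUE,
                        max_missing = 0.10) {
  stopifnot(inherits(weights, "snp_weight_table"))
  if (!identical(weights$variant_id, colnames(dosages)))
    dosages <- dosages[, weights$variant_id, drop = FALSE]
  g <- dosages
  miss <- is.na(g)
  n_miss <- rowSums(miss)
  if (any(miss)) {
    imp <- matrix(2 * weights$effect_allele_freq, nrow(g), ncol(g),
                  byrow = TRUE)
    g[miss] <- imp[miss]
  }
  raw <- as.numeric(g %*% weights$weight)
  out <- data.frame(
    individual_id = if (!is.null(rownames(dosages))) rownames(dosages)
                    else sprintf("ind%07d", seq_len(nrow(g))),
    prs_raw = raw,
    n_missing_imputed = as.integer(n_miss),
    flagged_missing = n_miss / ncol(g) > max_missing,
    stringsAsFactors = FALSE)
  class(out) <- c("prs_result", "data.frame")
  if (standardize) out <- standardize_prs(out)
  out
}

#' Standardize PRS to mean 0, SD 1 over the analysis cohort
#'
#' Uses the unweighted sample mean and SD of the whole analysis cohort
#' (affected and unaffected together); both are stored as attributes so that
#' percentile category boundaries can be placed on the fitted normal scale.
#' Standardizing an already standardized result recomputes from
#' \code{prs_raw} and is therefore idempotent.
#'
#' @param prs a \code{prs_result} (or any data frame with \code{prs_raw}).
#' @return The input with a \code{prs_std} column and \code{sample_mean} /
#'   \code{sample_sd} attributes.
#' @export
standardize_prs <- function(prs) {
  x <- prs$prs_raw
  if (length(x) < 2) stop("need at least 2 individuals to standardize")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) stop("zero variance: PRS cannot be standardized")
  prs$prs_std <- (x - m) / s
  attr(prs, "sample_mean") <- m
  attr(prs, "sample_sd") <- s
  prs
}

#' Percentile category scheme
#'
#' Cut points (in percent) defining PRS percentile categories; the default
#' \code{5, 10, 20, 40, 60, 80, 90, 95} yields the nine categories
#' \code{0-5, 5-10, 10-20, 20-40, 40-60, 60-80, 80-90, 90-95, 95-100} with
#' the middle \code{40-60} band as reference.
#'
#' @param boundaries strictly increasing percent cut points in (0, 100).
#' @return An object of class \code{percentile_scheme}.
#' @export
percentile_scheme <- function(boundaries = c(5, 10, 20, 40, 60, 80, 90, 95)) {
  stopifnot(all(boundaries > 0), all(boundaries < 100),
            all(diff(boundaries) > 0))
  edges <- c(0, boundaries, 100)
  labels <- paste0(edges[-length(edges)], "-", edges[-1])
  ref <- if ("40-60" %in% labels) "40-60" else labels[ceiling(length(labels) / 2)]
  structure(list(boundaries = boundaries, labels = labels,
                 reference = ref),
            class = "percentile_scheme")
}

#' Assign PRS percentile categories
#'
#' Category boundaries are quantiles of the fitted normal distribution
#' \code{N(sample_mean, sample_sd^2)} at the scheme's percent cut points --
#' not empirical quantiles -- so occupancy matches the percents only to the
#' extent the PRS is normal. Categories are half-open intervals
#' \code{[low, high)}. An empirical-quantile mode is available.
#'
#' @param prs a standardized \code{prs_result}.
#' @param scheme a \code{\link{percentile_scheme}}.
#' @param method \code{"normal"} (default, fitted-normal quantiles) or
#'   \code{"empirical"}.
#' @return A factor of category labels with the scheme's reference category
#'   as the first level.
#' @export
assign_categories <- function(prs, scheme = percentile_scheme(),
                              method = c("normal", "empirical")) {
  method <- match.arg(method)
  m <- attr(prs, "sample_mean")
  s <- attr(prs, "sample_sd")
  if (is.null(m) || is.null(s))
    stop("PRS must be standardized first (run standardize_prs)")
  cuts <- if (method == "normal")
    qnorm(scheme$boundaries / 100, mean = m, sd = s)
  else quantile(prs$prs_raw, scheme$boundaries / 100, names = FALSE)
  idx <- findInterval(prs$prs_raw, cuts) + 1L  # [low, high)
  f <- factor(scheme$labels[idx], levels = scheme$labels)
  stats::relevel(f, ref = scheme$reference)
}
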
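# Ascertainment correction: the weighted-cohort sampling weights.
#
# Clinic-recruited carrier cohorts oversample affected carriers. The
# weighted-cohort approach assigns each record a sampling weight such that,
# within age-band x gene strata, the weighted affected/unaffected mix equals
# the mix expected from the average carrier incidence; a weighted Cox fit
# then behaves approximately like a fit to a randomly sampled cohort.

#' Expected affected proportion in an age band
#'
#' Probability that a carrier observed at an age in the band is affected by
#' that age under the average carrier incidence:
#' \code{F(a) = 1 - exp(-integral of hazard from 18 to a)} evaluated at the
#' band midpoint.
#'
#' @param incidence an \code{\link{incidence_curve}} (average carrier
#'   incidence).
#' @param band numeric length-2 vector (low, high) in years; the band must
#'   lie within the incidence support.
#' @return Expected affected proportion in [0, 1).
#' @export
expected_affected_proportion <- function(incidence, band) {
  stopifnot(inherits(incidence, "incidence_curve"), length(band) == 2,
            band[1] < band[2])
  if (band[1] < incidence$age[1] - 1e-9)
    stop("band starts before the incidence support")
  mid <- mean(band)
  base <- cum_hazard(incidence, 18)
  unname(1 - exp(-(cum_hazard(incidence, mid) - base)))
}

#' Build weighted-cohort sampling weights
#'
#' Records are stratified by gene and by the age band containing
#' \code{age_end} (default 5-year bands from 18 to 80 with an open top
#' band). Within stratum s with expected affected proportion p and observed
#' proportion q, affected records get weight \code{p / q} and unaffected
#' records \code{(1 - p) / (1 - q)}, so the weighted affected proportion is
#' exactly p in every stratum. Because clinic ascertainment oversamples by
#' affection status (not by age at observation), strata are then rescaled so
#' that affected carriers carry the same weight in every stratum -- this
#' leaves the restored stratum proportions untouched but makes the scheme
#' converge to the true inverse sampling probabilities as the cohort grows.
#' Finally weights are renormalized to sum to the number of records and
#' capped at \code{cap} (with a message) to prevent single-record dominance
#' in small cohorts.
#'
#' The expected proportion p comes from
#' \code{\link{expected_affected_proportion}} (cumulative risk at the band
#' midpoint) unless either \code{censor_range} is given -- in which case the
#' design-aware \code{\link{expected_cohort_proportions}} is used -- or
#' explicit proportions are passed via \code{expected}. Strata in which q is
#' 0 or 1 are pooled with the nearest age band (within gene) until mixed.
#'
#' @param cohort a \code{cohort_table}.
#' @param incidence an \code{\link{incidence_curve}}, or a named list of
#'   curves by gene (\code{BRCA1}, \code{BRCA2}) when the cohort mixes
#'   genes.
#' @param bands age band breakpoints (default \code{seq(18, 80, by = 5)});
#'   the last band is open above.
#' @param expected optional named numeric vector of expected affected
#'   proportions per stratum (names as in the scheme's stratum table),
#'   overriding the incidence-based computation.
#' @param censor_range optional (low, high) of the uniform censoring /
#'   observation ages; when supplied, expected proportions are computed
#'   under that design via \code{\link{expected_cohort_proportions}}.
#' @param cap weight cap applied after renormalization.
#' @return A data frame of class \code{weight_scheme}: \code{individual_id},
#'   \code{stratum}, \code{weight}; per-stratum expected and observed
#'   proportions and the raw per-stratum weight formula values
#'   (\code{w_affected = p/q}, \code{w_unaffected = (1-p)/(1-q)}) are kept
#'   in the \code{"strata"} attribute.
#' @export
build_weights <- function(cohort, incidence, bands = seq(18, 80, by = 5),
                          expected = NULL, censor_range = NULL, cap = 50) {
  stopifnot(inherits(cohort, "cohort_table"))
  brk <- c(bands, Inf)
  band_id <- findInterval(cohort$age_end, brk, rightmost.closed = FALSE)
  if (any(band_id < 1))
    stop("record with age_end below the first band boundary")
  genes <- unique(cohort$gene)
  get_inc <- function(g) {
    if (inherits(incidence, "incidence_curve")) return(incidence)
    if (is.list(incidence) && !is.null(incidence[[g]])) return(incidence[[g]])
    stop("no incidence curve supplied for gene ", g)
  }
  n <- nrow(cohort)
  weight <- numeric(n)
  stratum <- character(n)
  strata_tabs <- list()
  for (g in genes) {
    inc <- get_inc(g)
    sel <- cohort$gene == g
    bid <- band_id[sel]
    aff <- cohort$affected[sel] == 1
    nb <- length(brk) - 1
    # merge degenerate bands (q = 0 or 1, or empty) with the nearest
    # occupied mixed band
    counts_a <- tabulate(bid[aff], nbins = nb)
    counts_t <- tabulate(bid, nbins = nb)
    mixed <- counts_t > 0 & counts_a > 0 & counts_a < counts_t
    if (!any(mixed))
      stop("no age band contains both affected and unaffected records for ",
           g, "; cannot build weights")
    group <- seq_len(nb)
    for (k in which(!mixed & counts_t > 0)) {
      cand <- which(mixed)
      group[k] <- cand[which.min(abs(cand - k))]
    }
    grp <- group[bid]
    ug <- sort(unique(grp))
    p <- q <- numeric(length(ug))
    names(p) <- names(q) <- paste0(g, ":", bandlabel(brk, ug))
    for (j in seq_along(ug)) {
      k <- ug[j]
      inb <- grp == k
      q[j] <- mean(aff[inb])
      lo <- brk[min(which(group == k))]
      hi <- brk[max(which(group == k)) + 1]
      if (!is.finite(hi)) hi <- max(cohort$age_end[sel][inb], lo + 5)
      key <- names(p)[j]
      p[j] <- if (!is.null(expected) && key %in% names(expected)) {
        expected[[key]]
      } else if (!is.null(censor_range)) {
        expected_cohort_proportion(inc, c(lo, hi), censor_range)
      } else {
        expected_affected_proportion(inc, c(lo, hi))
      }
      if (p[j] <= 0 || p[j] >= 1)
        stop("incidence implies expected affected proportion outside (0,1) ",
             "in occupied stratum ", key)
      # per-stratum formula, then anchor affected weight at 1 so strata are
      # not rescaled relative to one another (status-only oversampling)
      w <- ifelse(aff[inb], 1, (1 - p[j]) * q[j] / ((1 - q[j]) * p[j]))
      weight[sel][inb] <- w
      stratum[sel][inb] <- key
    }
    strata_tabs[[g]] <- data.frame(stratum = names(p), expected = p,
                                   observed = q,
                                   w_affected = p / q,
                                   w_unaffected = (1 - p) / (1 - q),
                                   row.names = NULL)
  }
  weight <- weight * n / sum(weight)
  if (any(weight > cap)) {
    message(sum(weight > cap), " weight(s) capped at ", cap)
    weight <- pmin(weight, cap)
  }
  out <- data.frame(individual_id = cohort$individual_id,
                    stratum = stratum, weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "strata") <- do.call(rbind, c(strata_tabs, make.row.names = FALSE))
  class(out) <- c("weight_scheme", "data.frame")
  out
}

#' Design-aware expected affected proportion in an age band
#'
#' Probability that a carrier whose follow-up ends in the band (diagnosis if
#' affected, observation/censoring otherwise) is affected, under the average
#' carrier incidence and a known uniform observation-age design. Among
#' records with \code{age_end} in \code{[lo, hi)}, the affected mass is
#' \eqn{\int \bar\lambda(t) e^{-\bar\Lambda(t)} P(C > t) dt} and the
#' unaffected mass \eqn{\int s_C(t) e^{-\bar\Lambda(t)} dt}, where C is the
#' Uniform(\code{censor_range}) observation age. This is the quantity the
#' band-midpoint rule of \code{\link{expected_affected_proportion}}
#' approximates when the observation design is unknown.
#'
#' @param incidence an \code{\link{incidence_curve}}.
#' @param band numeric (low, high) in years.
#' @param censor_range (low, high) of the uniform observation ages.
#' @param subdiv integration subdivisions within the band.
#' @return Expected affected proportion in (0, 1), or \code{NA} when the
#'   band lies entirely above the observation range.
#' @export
expected_cohort_proportion <- function(incidence, band, censor_range,
                                       subdiv = 100) {
  stopifnot(inherits(incidence, "incidence_curve"), length(band) == 2,
            band[1] < band[2], length(censor_range) == 2,
            censor_range[1] < censor_range[2])
  cl <- censor_range[1]
  ch <- censor_range[2]
  lo <- band[1]
  hi <- min(band[2], ch)
  if (lo >= ch) return(NA_real_)
  tg <- seq(lo, hi, length.out = subdiv + 1)
  dt <- diff(tg)
  tm <- (tg[-1] + tg[-length(tg)]) / 2
  base <- cum_hazard(incidence, 18)
  sbar <- exp(-(cum_hazard(incidence, tm) - base))
  s_c <- pmin(1, pmax(0, (ch - tm) / (ch - cl)))
  affected_mass <- sum(hazard_at(incidence, tm) * sbar * s_c * dt)
  unaffected_mass <- sum((tm >= cl & tm <= ch) / (ch - cl) * sbar * dt)
  affected_mass / (affected_mass + unaffected_mass)
}

#' Design-aware expected proportions for a full band set
#'
#' Vector version of \code{\link{expected_cohort_proportion}} named in the
#' \code{gene:lo-hi} stratum convention of \code{\link{build_weights}}.
#'
#' @inheritParams expected_cohort_proportion
#' @param bands band breakpoints (last band open above).
#' @param gene gene label used in the stratum names.
#' @return Named numeric vector (bands above the observation range dropped).
#' @export
expected_cohort_proportions <- function(incidence, bands, censor_range,
                                        gene = "BRCA1") {
  brk <- c(bands, Inf)
  k <- seq_len(length(brk) - 1)
  p <- vapply(k, function(i)
    expected_cohort_proportion(incidence, c(brk[i], brk[i + 1]),
                               censor_range), numeric(1))
  names(p) <- paste0(gene, ":", bandlabel(brk, k))
  p[!is.na(p)]
}

bandlabel <- function(brk, k) {
  hi <- brk[k + 1]
  paste0(brk[k], "-", ifelse(is.finite(hi), hi, "Inf"))
}

#' Write a weight scheme to TSV
#' @param ws a \code{weight_scheme}.
#' @param path output path.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weight_scheme"))
  write_tsv6(as.data.frame(ws), path)
}
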
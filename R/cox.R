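# Weighted Cox regression on the age time scale.
#
# The partial-likelihood engine (src/cox_engine.cpp) maximizes the weighted
# Cox partial likelihood with delayed entry, Breslow tie handling and
# baseline-hazard strata by Newton-Raphson, and returns weighted score
# residuals from which cluster-robust (sandwich) covariance is assembled
# here. Covariate columns may be time-varying: multiplied by attained age
# (PRS-by-age interaction) or by an attained-age band indicator (age-group
# effects).

#' Fit a weighted Cox proportional-hazards model
#'
#' The central fitting function of the pipeline. Time scale is age with
#' delayed entry at \code{age_entry}; the outcome is age at diagnosis
#' (\code{age_end}, \code{affected}). Sampling weights (typically from
#' \code{\link{build_weights}}) enter the partial likelihood as fixed known
#' constants; variance is reported both model-based and as a cluster-robust
#' sandwich with families as clusters. One-sided p-values (directional
#' hypothesis: higher PRS, higher risk) and two-sided p-values are both
#' reported, from the robust standard errors.
#'
#' @param cohort a \code{cohort_table} (columns \code{age_entry},
#'   \code{age_end}, \code{affected}, \code{family_id}, \code{study}).
#' @param x covariate matrix or data frame (one column per term). Columns
#'   must not be constant.
#' @param weights optional \code{weight_scheme} or numeric vector of
#'   positive per-record weights (default: all 1).
#' @param strata optional factor/character of baseline-hazard strata
#'   (default: the cohort's \code{study} column).
#' @param cluster optional cluster identifiers for the robust variance
#'   (default: the cohort's \code{family_id}).
#' @param tt optional time transforms per column: a character vector with
#'   entries \code{"fixed"} or \code{"age"} (column is multiplied by
#'   attained age), or a list whose elements are \code{NULL},
#'   \code{"age"}, or numeric \code{c(lo, hi)} (column is multiplied by the
#'   attained-age band indicator \code{I(lo <= t < hi)}).
#' @param init starting coefficients (default 0).
#' @param tol Newton-Raphson convergence tolerance on the gradient norm.
#' @param maxit maximum Newton-Raphson iterations.
#' @return An object of class \code{coxwc}; see \code{\link{results_table}}
#'   and the \code{print}, \code{summary}, \code{coef}, \code{vcov},
#'   \code{confint} and \code{logLik} methods.
#' @export
coxwc <- function(cohort, x, weights = NULL, strata = NULL, cluster = NULL,
                  tt = NULL, init = NULL, tol = 1e-8, maxit = 100L) {
  stopifnot(is.data.frame(cohort),
            all(c("age_entry", "age_end", "affected") %in% names(cohort)))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(cohort)
  if (nrow(x) != n) stop("covariate rows do not match the cohort")
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (any(!is.finite(x))) stop("non-finite covariate values")
  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(x)[const], collapse = ", "))

  w <- resolve_weights(cohort, weights)
  strata <- if (is.null(strata)) {
    if (!is.null(cohort$study)) cohort$study else rep("all", n)
  } else strata
  sid <- as.integer(factor(strata)) - 1L
  cluster <- if (is.null(cluster)) {
    if (!is.null(cohort$family_id)) cohort$family_id else seq_len(n)
  } else cluster

  tts <- parse_tt(tt, p, colnames(x))
  status <- as.integer(cohort$affected)
  if (sum(status) < 1) stop("no events in the cohort")
  ev_by_str <- tapply(status, sid, sum)
  if (any(ev_by_str == 0))
    warning("stratum without events contributes nothing to the fit")

  if (is.null(init)) init <- rep(0, p)
  fit <- cox_fit_cpp(cohort$age_entry, cohort$age_end, status, x, w,
                     sid, tts$type, tts$lo, tts$hi, init, tol,
                     as.integer(maxit))
  if (fit$separation)
    stop("monotone likelihood detected (separation); estimates diverge")
  if (!fit$converged)
    stop("Newton-Raphson did not converge in ", maxit,
         " iterations (|score| = ", format(sqrt(sum(fit$score^2))), ")")

  beta <- as.numeric(fit$coef)
  names(beta) <- colnames(x)
  imat <- fit$imat
  cov_model <- solve(imat)
  resid <- fit$resid
  cl <- as.character(cluster)
  csum <- rowsum(resid, group = cl, reorder = FALSE)
  meat <- crossprod(csum)
  cov_robust <- cov_model %*% meat %*% cov_model
  dimnames(cov_model) <- dimnames(cov_robust) <- list(names(beta), names(beta))

  se <- sqrt(diag(cov_model))
  rse <- sqrt(diag(cov_robust))
  zr <- beta / rse
  out <- list(
    coefficients = beta,
    var = cov_model,
    robust_var = cov_robust,
    se = se, robust_se = rse,
    hr = exp(beta),
    ci_low = exp(beta - 1.96 * rse),
    ci_high = exp(beta + 1.96 * rse),
    p_one_sided = pnorm(zr, lower.tail = FALSE),
    p_two_sided = 2 * pnorm(abs(zr), lower.tail = FALSE),
    n = n, n_events = sum(status), n_clusters = length(unique(cl)),
    loglik = c(init = fit$loglik_init, final = fit$loglik),
    score_norm = sqrt(sum(fit$score^2)),
    iter = fit$iter, converged = fit$converged,
    tt = tts$desc, call = match.call())
  class(out) <- "coxwc"
  out
}

#' @rdname coxwc
#' @param ... passed to \code{coxwc}.
#' @export
fit_weighted_cox <- function(cohort, x, weights = NULL, ...) {
  coxwc(cohort, x, weights = weights, ...)
}

resolve_weights <- function(cohort, weights) {
  n <- nrow(cohort)
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "weight_scheme")) {
    w <- weights$weight[match(cohort$individual_id, weights$individual_id)]
    if (any(is.na(w))) stop("weight scheme does not cover every individual")
    return(w)
  }
  w <- as.numeric(weights)
  if (length(w) != n) stop("weights length does not match the cohort")
  if (any(!is.finite(w) | w <= 0)) stop("weights must be positive")
  w
}

parse_tt <- function(tt, p, nm) {
  type <- integer(p)
  lo <- numeric(p)
  hi <- numeric(p)
  desc <- rep("fixed", p)
  if (!is.null(tt)) {
    if (length(tt) != p) stop("`tt` must have one entry per covariate column")
    for (j in seq_len(p)) {
      e <- if (is.list(tt)) tt[[j]] else tt[j]
      if (is.null(e) || identical(e, "fixed") || (length(e) == 1 && is.na(e)))
        next
      if (identical(e, "age")) {
        type[j] <- 1L
        desc[j] <- "x * age"
      } else if (is.numeric(e) && length(e) == 2) {
        type[j] <- 2L
        lo[j] <- e[1]
        hi[j] <- e[2]
        desc[j] <- paste0("x * I(", e[1], " <= age < ", e[2], ")")
      } else stop("invalid time transform for column ", nm[j])
    }
  }
  list(type = type, lo = lo, hi = hi, desc = desc)
}

#' @export
coef.coxwc <- function(object, ...) object$coefficients

#' Covariance of a weighted Cox fit
#' @param object a \code{coxwc} fit.
#' @param robust if TRUE (default) the cluster-robust sandwich covariance,
#'   else the model-based inverse information.
#' @param ... unused.
#' @export
vcov.coxwc <- function(object, robust = TRUE, ...) {
  if (robust) object$robust_var else object$var
}

#' @export
logLik.coxwc <- function(object, ...) {
  structure(object$loglik["final"], df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.coxwc <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  b <- object$coefficients
  ci <- cbind(b - z * object$robust_se, b + z * object$robust_se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Tidy results table of a weighted Cox fit
#'
#' One row per term with the standard pipeline columns: \code{term},
#' \code{estimate} (log HR), \code{se}, \code{robust_se}, \code{hr},
#' \code{ci_low}, \code{ci_high}, \code{p_one_sided}, \code{p_two_sided}.
#'
#' @param fit a \code{coxwc} fit.
#' @return A data frame.
#' @export
results_table <- function(fit) {
  stopifnot(inherits(fit, "coxwc"))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), robust_se = unname(fit$robust_se),
             hr = unname(fit$hr), ci_low = unname(fit$ci_low),
             ci_high = unname(fit$ci_high),
             p_one_sided = unname(fit$p_one_sided),
             p_two_sided = unname(fit$p_two_sided),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.coxwc <- function(x, digits = 4, ...) {
  cat("Weighted Cox model:", x$n, "records,", x$n_events, "events,",
      x$n_clusters, "clusters\n")
  tab <- results_table(x)
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.coxwc <- function(object, ...) {
  structure(list(fit = object, table = results_table(object)),
            class = "summary.coxwc")
}

#' @export
print.summary.coxwc <- function(x, ...) {
  print(x$fit)
  cat("log-likelihood:", format(x$fit$loglik["final"]),
      " (", x$fit$iter, "iterations, |score| =",
      format(x$fit$score_norm, digits = 3), ")\n")
  invisible(x)
}
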
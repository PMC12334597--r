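#' Kaplan-Meier product-limit estimator
#'
#' Fits the product-limit estimate S(t) = prod over event times <= t of
#' (1 - d_i / n_i); censored subjects leave the risk set after their time.
#'
#' @param times Positive follow-up times (months).
#' @param events Event indicator per subject: 1 = event, 0 = censored.
#' @return An object of class \code{"km_curve"}: data frame with columns
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{surv} (one row per distinct observed time).
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d time points, %d events, final S = %.3f\n",
              nrow(x), sum(x$n_event), x$surv[nrow(x)]))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (df = 1) comparing the survival distributions
#' of two groups, using the hypergeometric variance of the observed event
#' split at each distinct event time. If no events occur at all the statistic
#' is 0 and p = 1.
#'
#' @param times,events As in \code{\link{km_fit}}.
#' @param groups Group label per subject; exactly two non-empty groups.
#' @return An \code{mh_test} with the chi-square statistic, df = 1 and the
#'   two-sided p-value.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("exactly two groups required")
  if (sum(events) == 0)
    return(mh_test(0, 1, 1, "log-rank"))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  mh_test(unname(sd$chisq), stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
          1, "log-rank")
}

#' Median split of a per-sample feature
#'
#' Dichotomizes a feature vector at its median: values strictly above the
#' median are labelled \code{"high"}, values at or below it \code{"low"}
#' (ties at the median go low, a convention that matters for sparse
#' microbial abundances where ties are common). Both groups are guaranteed
#' non-empty; an all-identical vector is a degenerate split and errors.
#'
#' @param values Numeric vector, length >= 2. Names, if any, are preserved.
#' @return Factor with levels \code{"low"}, \code{"high"}.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (length(unique(values)) == 1L) stop("degenerate split: all values identical")
  lab <- ifelse(values > stats::median(values), "high", "low")
  f <- factor(lab, levels = c("low", "high"))
  names(f) <- names(values)
  if (any(tabulate(f, 2L) == 0L)) stop("degenerate split: an empty group")
  f
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model by maximizing the Breslow partial likelihood. Convergence
#' problems (including monotone-likelihood separation, where a coefficient
#' diverges) are detected and flagged; hazard ratios are reported only for
#' converged fits.
#'
#' @param times,events As in \code{\link{km_fit}}.
#' @param covariates Data frame or matrix of covariates (no constant
#'   columns); factors are expanded to model-matrix columns.
#' @return An object of class \code{"cox_fit"}: list with \code{coefficients}
#'   data frame (\code{term}, \code{coef}, \code{hazard_ratio}, \code{se},
#'   \code{p_value}), \code{converged}, \code{n}, \code{n_events}.
#' @export
cox_ph <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) stop("no covariates")
  const <- vapply(covariates, function(x) length(unique(x)) == 1L, TRUE)
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  if (sum(events) < ncol(covariates))
    warning("fewer events than covariates; estimates may be unstable")
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  # separation shows up as a coxph warning and/or runaway coefficients
  converged <- !warned && all(is.finite(coef(fit))) && all(abs(coef(fit)) < 15)
  cf <- data.frame(term = rownames(s$coefficients),
                   coef = s$coefficients[, "coef"],
                   hazard_ratio = if (converged) exp(s$coefficients[, "coef"])
                                  else NA_real_,
                   se = s$coefficients[, "se(coef)"],
                   p_value = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!converged) cf$p_value <- NA_real_
  structure(list(coefficients = cf, converged = converged,
                 n = length(times), n_events = sum(events), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (Breslow ties): n = %d, events = %d, converged = %s\n",
              x$n, x$n_events, x$converged))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$term)
}

#' Median-split survival stratification
#'
#' The stratification workflow used for every candidate feature: split the
#' cohort at the feature's median into high/low groups, fit per-group
#' Kaplan-Meier curves, and compare them with the log-rank test.
#'
#' @param values Per-sample feature values (expression or abundance), aligned
#'   with \code{times}/\code{events}.
#' @param times,events As in \code{\link{km_fit}}.
#' @return List with \code{split} (the high/low factor), \code{curves}
#'   (named list of \code{km_curve}s) and \code{test} (log-rank
#'   \code{mh_test}).
#' @export
stratify_by_median <- function(values, times, events) {
  split <- median_split(values)
  curves <- lapply(stats::setNames(nm = levels(split)), function(l)
    km_fit(times[split == l], events[split == l]))
  list(split = split, curves = curves,
       test = logrank_test(times, events, split))
}
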
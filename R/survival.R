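#' Median-cutoff stratification
#'
#' Splits patients into high/low groups at the cohort median of a
#' statistic: high iff value strictly above the median, so ties at the
#' median go to the low group. Undefined values stay `NA` (excluded, with a
#' message).
#'
#' @param values numeric vector of per-patient statistics.
#' @return factor with levels `low`, `high` and attribute `cutoff` (the
#'   median).
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    stop("need at least 4 patients with defined values", call. = FALSE)
  }
  if (length(unique(values[ok])) == 1L) {
    stop("degenerate split: all values identical", call. = FALSE)
  }
  if (any(!ok)) message("excluding ", sum(!ok), " undefined value(s)")
  cutoff <- median(values[ok])
  g <- factor(ifelse(values > cutoff, "high", "low"),
              levels = c("low", "high"))
  attr(g, "cutoff") <- cutoff
  g
}

#' Four-group cluster from two median splits
#'
#' Crosses the median splits of two statistics (e.g. p(PD-1+CD8+|CD8+) and
#' p(PD-L1+CD68+|CD68+)) into the four-group cluster `low/low`, `low/high`,
#' `high/low`, `high/high`. `cluster_indicator()` collapses it to the binary
#' high/high-versus-rest covariate used in the multivariate Cox model.
#'
#' @param values_a,values_b numeric vectors of per-patient statistics.
#' @return factor with the four combined levels and attribute `cutoffs`.
#' @export
four_group_split <- function(values_a, values_b) {
  ga <- median_split(values_a)
  gb <- median_split(values_b)
  g <- factor(paste(as.character(ga), as.character(gb), sep = "/"),
              levels = c("low/low", "low/high", "high/low", "high/high"))
  attr(g, "cutoffs") <- c(attr(ga, "cutoff"), attr(gb, "cutoff"))
  g
}

#' @param cluster a factor from [four_group_split()].
#' @rdname four_group_split
#' @export
cluster_indicator <- function(cluster) {
  as.integer(cluster == "high/high")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function with right censoring.
#'
#' @param time follow-up times (months, > 0).
#' @param event logical/0-1 death indicator.
#' @return object of class `km_curve`: data.frame of `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` plus the underlying
#'   [survival::survfit()] fit as attribute `fit`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  structure(out, class = c("km_curve", "data.frame"), fit = fit)
}

#' @description `km_surv_at()` evaluates a `km_curve` at arbitrary times
#' (right-continuous step function, S(0) = 1).
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate the survival probability.
#' @rdname km_estimate
#' @export
km_surv_at <- function(km, t) {
  ev <- km[km$n_event > 0L, ]
  if (nrow(ev) == 0L) return(rep(1, length(t)))
  vapply(t, function(tt) {
    k <- ev$time <= tt
    if (!any(k)) 1 else ev$surv[max(which(k))]
  }, numeric(1L))
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank test between two or more groups, with the
#' k-group generalization used for the four-group cluster comparison.
#'
#' @param time,event follow-up times and death indicators.
#' @param group factor of group memberships (rows with `NA` group dropped).
#' @return list: `chisq`, `df`, `p`, `n` per group, `observed`, `expected`.
#' @export
logrank_test <- function(time, event, group) {
  ok <- !is.na(group) & !is.na(time) & !is.na(event)
  time <- time[ok]
  event <- as.integer(event[ok])
  group <- droplevels(factor(group[ok]))
  if (nlevels(group) < 2L) {
    stop("log-rank needs at least 2 non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.numeric(sd$n), observed = as.numeric(sd$obs),
       expected = as.numeric(sd$exp))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. Reports per covariate
#' the coefficient, hazard ratio, Wald 95% CI and p-value in a
#' forest-plot-ready table.
#'
#' @param data data.frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @return object of class `cox_fit`: list with `table` (data.frame `term`,
#'   `coef`, `hr`, `hr_lo`, `hr_hi`, `p`), `n`, `n_event`, `loglik`, and
#'   the underlying [survival::coxph()] fit.
#' @export
cox_fit <- function(data, covariates) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  ok <- complete.cases(data[, c("time", "event", covariates)])
  data <- data[ok, ]
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.numeric(v) && sd(v) == 0) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  if (sum(data$event) < 10L) {
    warning("fewer than 10 events; Cox estimates will be unstable",
            call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, as.integer(event)) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (!is.null(fit$info) && !is.null(fit$info$convergence) &&
      fit$info$convergence != 0) {
    stop("Cox fit did not converge", call. = FALSE)
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    hr_lo = s$conf.int[, "lower .95"],
                    hr_hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n = s$n, n_event = s$nevent,
                 loglik = fit$loglik, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> n =", x$n, "events =", x$n_event, "\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' One-year ROC and AUC
#'
#' Dichotomizes the outcome at a 12-month horizon (death before the horizon
#' versus survival past it; patients censored before the horizon carry no
#' 1-year outcome and are excluded with a message), then computes the
#' empirical ROC and trapezoidal AUC of a predictor. The AUC equals the
#' Mann-Whitney probability that a randomly chosen 1-year death has a
#' higher predictor value than a randomly chosen survivor (ties count 1/2),
#' so an uninformative predictor sits at 0.5 and values below 0.5 indicate
#' inverse association.
#'
#' @param score numeric predictor (higher = predicted higher risk).
#' @param time,event follow-up times (months) and death indicators.
#' @param horizon landmark in months (default 12).
#' @return list: `auc`, `n_case`, `n_control`, `n_excluded`, `roc` (the
#'   underlying [pROC::roc()] object, `NULL` when undefined).
#' @export
roc_1yr <- function(score, time, event, horizon = 12) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  died <- event & time <= horizon
  survived <- time > horizon
  keep <- (died | survived) & !is.na(score)
  n_excl <- sum(!keep)
  if (n_excl > 0L) {
    message("excluding ", n_excl,
            " patient(s) censored before the horizon or with missing score")
  }
  outcome <- as.integer(died[keep])
  sc <- score[keep]
  if (length(unique(outcome)) < 2L) {
    warning("fewer than 2 outcome classes: AUC undefined", call. = FALSE)
    return(list(auc = NA_real_, n_case = sum(outcome == 1L),
                n_control = sum(outcome == 0L), n_excluded = n_excl,
                roc = NULL))
  }
  r <- pROC::roc(response = outcome, predictor = sc, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)), n_case = sum(outcome == 1L),
       n_control = sum(outcome == 0L), n_excluded = n_excl, roc = r)
}
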
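# Covariate-adjusted Cox models for single indices, proportional-hazards
# diagnostics and Kaplan-Meier quartile curves. Partial-likelihood fitting
# is delegated to the survival package (Efron ties); this module owns the
# standardization, reporting and windowing conventions.

#' Fit a covariate-adjusted Cox model for one or more indices
#'
#' Each index is standardized to unit SD over the analysis sample, so the
#' reported hazard ratio is per SD change. Ties are handled by the Efron
#' approximation; confidence intervals are Wald.
#'
#' @param cohort data.frame with `time`, `event`, the index column(s) and
#'   the adjustment covariates.
#' @param index_name character: index column(s) to standardize and model.
#' @param adjustment_set covariate columns (default [crf_names()]).
#' @param conf_level CI level (default 0.95).
#' @return A `cox_fit`: list with `table` (term, coef, se, HR, CI, p),
#'   `model` (the underlying `coxph`), `n`, `events`, `adjustment_set`.
#' @export
fit_adjusted_cox <- function(cohort, index_name,
                             adjustment_set = crf_names(),
                             conf_level = 0.95) {
  stopifnot(all(c("time", "event", index_name, adjustment_set) %in%
                  names(cohort)))
  if (sum(cohort$event) == 0) stop("zero events: cannot fit a Cox model")
  dat <- cohort[, c("time", "event", index_name, adjustment_set)]
  if (any(!vapply(dat, function(x) all(is.finite(as.numeric(x))), logical(1))))
    stop("non-finite values in model columns")
  ctr <- vapply(dat[index_name], mean, numeric(1))
  scl <- vapply(dat[index_name], stats::sd, numeric(1))
  for (nm in index_name)
    dat[[nm]] <- (dat[[nm]] - ctr[[nm]]) / scl[[nm]]
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(c(index_name, adjustment_set),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(co), coef = unname(co), se = unname(se),
                    HR = exp(unname(co)),
                    ci_low = exp(unname(co) - z * unname(se)),
                    ci_high = exp(unname(co) + z * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(co) / unname(se))))
  structure(list(table = tab, model = fit, n = nrow(dat),
                 events = sum(dat$event), adjustment_set = adjustment_set,
                 index_name = index_name,
                 scaling = list(center = ctr, scale = scl)),
            class = "cox_fit")
}

#' Risk scores (linear predictor) of a fitted Cox model on new data
#'
#' Applies the standardization learned on the fitting sample to the index
#' columns before evaluating the linear predictor, so scores on held-out
#' data are on the same scale the model was fit on. Higher score = higher
#' hazard.
#'
#' @param fit a `cox_fit`.
#' @param newdata data.frame with the model's index and covariate columns.
#' @return numeric vector of linear predictors.
#' @export
risk_scores <- function(fit, newdata) {
  stopifnot(inherits(fit, "cox_fit"))
  for (nm in fit$index_name)
    newdata[[nm]] <- (newdata[[nm]] - fit$scaling$center[[nm]]) /
      fit$scaling$scale[[nm]]
  unname(stats::predict(fit$model, newdata = newdata, type = "lp",
                        reference = "zero"))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d\n", x$n, x$events))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Scaled Schoenfeld residual diagnostics
#'
#' Grambsch-Therneau style check of the proportional-hazards assumption:
#' scaled Schoenfeld residuals at event times with a correlation-with-time
#' trend test per term.
#'
#' @param fit a `cox_fit`.
#' @return list with `residuals` (matrix, one column per term, rownames are
#'   event times), `table` (term, chisq, df, p) and `times`.
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$events == 0) stop("no events")
  zp <- survival::cox.zph(fit$model, transform = "identity")
  res <- zp$y
  tab <- as.data.frame(zp$table)
  tab <- data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
                    p = tab$p)
  list(residuals = res, table = tab, times = zp$time)
}

#' Kaplan-Meier curves by index quartile
#'
#' Nearest-rank sample quartiles partition the cohort into four groups of
#' near-equal size (ties broken by stable order); a product-limit curve is
#' estimated per group.
#'
#' @param cohort data.frame with `time`, `event` and the index column.
#' @param index_name index to stratify by.
#' @return list with `fit` (a `survfit` over the 4 groups), `group`
#'   (factor of quartile membership) and `at_risk` (risk-set table at
#'   yearly times).
#' @export
km_by_quartile <- function(cohort, index_name) {
  stopifnot(index_name %in% names(cohort))
  x <- cohort[[index_name]]
  if (length(x) < 40) stop("need at least 40 participants")
  if (stats::sd(x) == 0) stop("constant index: quartiles degenerate")
  rk <- rank(x, ties.method = "first")
  grp <- factor(ceiling(4 * rk / length(x)), levels = 1:4,
                labels = paste0("Q", 1:4))
  dat <- data.frame(time = cohort$time, event = cohort$event, group = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  yrs <- 0:floor(max(cohort$time))
  sm <- summary(sf, times = yrs, extend = TRUE)
  at_risk <- data.frame(time = sm$time, group = sm$strata,
                        n_risk = sm$n.risk, surv = sm$surv)
  list(fit = sf, group = grp, at_risk = at_risk)
}

#' Survival probability of a quartile group at a given time
#'
#' Convenience accessor for the product-limit estimate at `t` (step
#' function, right-continuous).
#'
#' @param km result of [km_by_quartile()].
#' @param quartile "Q1".."Q4".
#' @param t time.
#' @return survival probability.
#' @export
km_survival_at <- function(km, quartile, t) {
  sm <- summary(km$fit, times = t, extend = TRUE)
  s <- sm$surv[grepl(quartile, as.character(sm$strata))]
  s[1]
}
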
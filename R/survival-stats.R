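#' Kaplan-Meier curves and log-rank test between groups
#'
#' Standard two-or-more-group log-rank test plus tidy Kaplan-Meier curve
#' tables for plotting.
#'
#' @param time Survival time (months).
#' @param event Event indicator (1 = death).
#' @param group Grouping factor (all levels must be nonempty).
#' @return A `survival_comparison` list: `chisq`, `df`, `p`, a per-group
#'   summary (`n`, `events`), and a tidy KM table
#'   (`group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`).
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2)
    tme_stop("km_logrank: need >= 2 nonempty groups")
  if (length(time) != length(group) || length(event) != length(group))
    tme_stop("km_logrank: time, event and group lengths differ")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  km <- data.frame(group = sub("^group=", "", strata),
                   time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                   n_censor = sf$n.censor, surv = sf$surv,
                   stringsAsFactors = FALSE)
  per_group <- data.frame(group = levels(group),
                          n = as.integer(table(group)),
                          events = as.integer(tapply(event, group, sum)),
                          stringsAsFactors = FALSE)
  structure(list(chisq = unname(sd$chisq), df = df, p = p,
                 groups = per_group, km = km),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Univariate Cox hazard ratio
#'
#' Maximum-partial-likelihood hazard ratio for one covariate with Wald
#' confidence interval; ties handled by the Efron approximation.
#'
#' @param time Survival time.
#' @param event Event indicator.
#' @param x Covariate (numeric, or two-level factor/binary).
#' @param per Report the HR per `per`-unit increment (default 1).
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame `hr`, `lower`, `upper`, `p`, `beta`, `se`, `per`,
#'   `converged`.
#' @export
cox_hr <- function(time, event, x, per = 1, conf_level = 0.95) {
  if (is.factor(x) || is.character(x)) x <- as.numeric(as.factor(x)) - 1
  if (length(unique(x)) < 2)
    tme_stop("cox_hr: covariate is constant")
  if (sum(event) < 1) tme_stop("cox_hr: no events")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit)[1])
  se <- unname(sqrt(diag(stats::vcov(fit)))[1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(hr = exp(per * b),
             lower = exp(per * (b - z * se)),
             upper = exp(per * (b + z * se)),
             p = 2 * stats::pnorm(-abs(b / se)),
             beta = b, se = se, per = per, converged = converged)
}

#' Treatment-by-predicted-group interaction Cox model
#'
#' Multivariate Cox model evaluating whether EGFR TKI treatment effect on
#' overall survival differs between the predicted benefit groups, adjusting
#' for age, sex, smoking status and surgical resection.  Fits main effects
#' for treatment and group, their interaction, and the adjusters; reports
#' the interaction hazard ratio and Wald p-value.  Constant adjusters are
#' dropped with a warning; patients with missing covariates are excluded
#' (complete-case) with a message.
#'
#' @param clinical Cohort data.frame with `os_months`, `event`,
#'   `tki_treated` and the adjuster columns.
#' @param group Factor/vector aligned with `clinical` rows giving the
#'   predicted group.
#' @param adjusters Character vector of adjustment covariates
#'   (default `c("age", "sex", "smoking_status", "surgery")`).
#' @return A list: `interaction` (data.frame `hr`, `lower`, `upper`, `p`),
#'   `coefficients` (full Wald table), `n`, `n_dropped`, `fit`.
#' @export
interaction_cox <- function(clinical, group,
                            adjusters = c("age", "sex", "smoking_status",
                                          "surgery")) {
  stopifnot(length(group) == nrow(clinical))
  d <- data.frame(time = clinical$os_months, event = clinical$event,
                  trt = clinical$tki_treated, grp = droplevels(as.factor(group)),
                  stringsAsFactors = FALSE)
  for (a in adjusters) {
    if (!a %in% names(clinical))
      tme_stop(sprintf("interaction_cox: missing adjuster column '%s'", a))
    d[[a]] <- clinical[[a]]
  }
  cells <- table(d$trt, d$grp)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    tme_stop(sprintf(
      "interaction_cox: empty treatment-by-group cell (tki_treated=%s, group=%s)",
      rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  keep_adj <- character()
  for (a in adjusters) {
    v <- d[[a]][!is.na(d[[a]])]
    if (length(unique(v)) < 2) {
      warning(sprintf("interaction_cox: adjuster '%s' is constant, dropped", a))
    } else keep_adj <- c(keep_adj, a)
  }
  cc <- stats::complete.cases(d[, c("time", "event", "trt", "grp", keep_adj)])
  n_dropped <- sum(!cc)
  if (n_dropped)
    message(sprintf("interaction_cox: %d patient(s) dropped for missing covariates",
                    n_dropped))
  d <- d[cc, , drop = FALSE]
  rhs <- paste(c("trt * grp", keep_adj), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = d, ties = "efron")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(cf), beta = unname(cf), se = unname(se),
                    hr = exp(unname(cf)),
                    p = 2 * stats::pnorm(-abs(unname(cf / se))),
                    stringsAsFactors = FALSE)
  it <- grep(":", names(cf), fixed = TRUE, value = TRUE)
  b <- cf[[it]]
  s <- se[[it]]
  z <- stats::qnorm(0.975)
  list(interaction = data.frame(term = it, hr = exp(b),
                                lower = exp(b - z * s), upper = exp(b + z * s),
                                p = 2 * stats::pnorm(-abs(b / s)),
                                stringsAsFactors = FALSE),
       coefficients = tab, n = nrow(d), n_dropped = n_dropped, fit = fit)
}
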
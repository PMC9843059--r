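#' Fit the elastic-net penalized Cox survival-benefit model
#'
#' Fits a Cox proportional-hazards model for overall survival on the 12 image
#' features with an elastic-net penalty, on TKI-treated patients.  The image
#' features are correlated, so the combined L1/L2 penalty both shrinks and
#' selects; the penalty strength is chosen by k-fold cross-validated partial
#' likelihood at a fixed seed.  Features are standardized internally for
#' penalization; coefficients are returned on the original feature scale.
#'
#' @param features Data.frame with `patient_id` and the columns of
#'   [feature_names()] (patient level).
#' @param clinical Cohort data.frame (see [read_clinical()]).
#' @param alpha Elastic-net mixing weight in `[0, 1]` (default 0.5).
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param treated_only Restrict to `tki_treated == 1` patients (default TRUE).
#' @param lambda `"lambda.min"` (default), `"lambda.1se"`, or a fixed numeric
#'   penalty strength.
#' @return An object of class `risk_model` holding the named coefficient
#'   vector (zeros mean unselected), the penalty configuration, and the
#'   feature standardization parameters.
#' @export
fit_penalized_cox <- function(features, clinical, alpha = 0.5, nfolds = 5L,
                              seed = 1L, treated_only = TRUE,
                              lambda = "lambda.min") {
  df <- merge(features, clinical, by = "patient_id")
  if (treated_only) df <- df[df$tki_treated == 1, , drop = FALSE]
  df <- df[!is.na(df$os_months) & !is.na(df$event), , drop = FALSE]
  miss <- setdiff(feature_names(), names(df))
  if (length(miss))
    tme_stop(sprintf("fit_penalized_cox: missing feature column(s): %s",
                     paste(miss, collapse = ", ")))
  if (sum(df$event) < 2)
    tme_stop("fit_penalized_cox: need >= 2 events")
  x <- as.matrix(df[, feature_names()])
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning(sprintf("fit_penalized_cox: dropping constant feature(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")))
  }
  xk <- x[, keep, drop = FALSE]
  y <- survival::Surv(pmax(df$os_months, .Machine$double.eps), df$event)
  foldid <- withr::with_seed(seed,
    sample(rep_len(seq_len(nfolds), nrow(xk))))
  cvfit <- glmnet::cv.glmnet(xk, y, family = "cox", alpha = alpha,
                             foldid = foldid, standardize = TRUE)
  s <- if (is.numeric(lambda)) lambda else cvfit[[lambda]]
  beta <- stats::setNames(rep(0, 12), feature_names())
  bk <- as.numeric(stats::coef(cvfit, s = s))
  beta[colnames(xk)] <- bk
  structure(list(coefficients = beta,
                 alpha = alpha,
                 lambda = s,
                 lambda_rule = if (is.numeric(lambda)) "fixed" else lambda,
                 nfolds = nfolds,
                 seed = seed,
                 feature_means = colMeans(x),
                 feature_sds = apply(x, 2, stats::sd),
                 n = nrow(df),
                 n_events = sum(df$event)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  nz <- x$coefficients[x$coefficients != 0]
  cat(sprintf("risk_model: elastic-net Cox (alpha=%.2f, lambda=%.4g, n=%d, %d events)\n",
              x$alpha, x$lambda, x$n, x$n_events))
  if (length(nz)) {
    cat("selected features:\n")
    for (nm in names(nz)) cat(sprintf("  %-32s % .4f\n", nm, nz[[nm]]))
  } else cat("no features selected (full shrinkage)\n")
  invisible(x)
}

#' Risk scores from a fitted benefit model
#'
#' The risk score of a patient is the sum over features of coefficient times
#' feature value.  A higher score predicts not benefiting from EGFR TKI
#' therapy.
#'
#' @param model A `risk_model`.
#' @param features Data.frame with `patient_id` and the model's feature
#'   columns.
#' @return Data.frame `patient_id`, `risk_score`.
#' @export
score_patients <- function(model, features) {
  stopifnot(inherits(model, "risk_model"))
  miss <- setdiff(names(model$coefficients), names(features))
  if (length(miss))
    tme_stop(sprintf("score_patients: missing feature column(s): %s",
                     paste(miss, collapse = ", ")))
  x <- as.matrix(features[, names(model$coefficients), drop = FALSE])
  data.frame(patient_id = features$patient_id,
             risk_score = as.numeric(x %*% model$coefficients),
             stringsAsFactors = FALSE)
}

#' Median split into predicted benefit groups
#'
#' Dichotomizes a scored cohort at the cohort's own median risk score:
#' scores at or below the median are `predicted_to_benefit`, scores strictly
#' above it `predicted_not_to_benefit`.  A fixed external threshold may be
#' supplied instead for deployment use.
#'
#' @param scores Data.frame from [score_patients()] (or a numeric vector,
#'   optionally named by patient id).
#' @param threshold Optional fixed split threshold; default is the median of
#'   the supplied scores.
#' @return Data.frame `patient_id`, `risk_score`, `group` (factor), with the
#'   threshold as attribute `threshold`.
#' @export
median_split <- function(scores, threshold = NULL) {
  if (is.numeric(scores)) {
    scores <- data.frame(
      patient_id = names(scores) %||% as.character(seq_along(scores)),
      risk_score = as.numeric(scores), stringsAsFactors = FALSE)
  }
  if (nrow(scores) < 2) tme_stop("median_split: need >= 2 patients")
  thr <- threshold %||% stats::median(scores$risk_score)
  if (all(scores$risk_score == scores$risk_score[1]) && is.null(threshold))
    warning("median_split: all scores identical; all assigned predicted_to_benefit")
  grp <- ifelse(scores$risk_score <= thr,
                "predicted_to_benefit", "predicted_not_to_benefit")
  out <- data.frame(patient_id = scores$patient_id,
                    risk_score = scores$risk_score,
                    group = factor(grp, levels = c("predicted_to_benefit",
                                                   "predicted_not_to_benefit")),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Per-10% hazard ratio for an interaction feature
#'
#' Interaction fractions live on the 0--1 scale; effects are conventionally
#' reported per 10% (0.1-unit) increment: `HR = exp(0.1 * beta)` with the
#' confidence interval transformed identically.
#'
#' @param fit Either a `coxph` fit containing the feature as a covariate
#'   (gives HR, CI and p), or a `risk_model` (gives the HR implied by the
#'   penalized coefficient; no CI is available for penalized estimates).
#' @param feature Name of an interaction feature (`interaction_tumor_*`).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data.frame `feature`, `hr`, `lower`, `upper`, `p`.
#' @export
per10_hazard_ratio <- function(fit, feature, conf_level = 0.95) {
  if (!startsWith(feature, "interaction_tumor_"))
    tme_stop(sprintf(
      "per10_hazard_ratio: '%s' is not an interaction fraction; the per-10%% convention is undefined",
      feature))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (inherits(fit, "coxph")) {
    cf <- stats::coef(fit)
    if (!feature %in% names(cf))
      tme_stop(sprintf("per10_hazard_ratio: '%s' not in model", feature))
    b <- cf[[feature]]
    se <- sqrt(diag(stats::vcov(fit)))[[feature]]
    data.frame(feature = feature, hr = exp(0.1 * b),
               lower = exp(0.1 * (b - z * se)),
               upper = exp(0.1 * (b + z * se)),
               p = 2 * stats::pnorm(-abs(b / se)),
               stringsAsFactors = FALSE)
  } else if (inherits(fit, "risk_model")) {
    b <- fit$coefficients[[feature]]
    data.frame(feature = feature, hr = exp(0.1 * b),
               lower = NA_real_, upper = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  } else tme_stop("per10_hazard_ratio: fit must be a coxph or risk_model")
}

#' Serialize a risk model to a plain-text key-value file
#'
#' @param model A `risk_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  num <- function(x) format(x, digits = 17, trim = TRUE)
  lines <- c(
    "format=tmebenefit_risk_model_v1",
    sprintf("alpha=%s", num(model$alpha)),
    sprintf("lambda=%s", num(model$lambda)),
    sprintf("lambda_rule=%s", model$lambda_rule),
    sprintf("nfolds=%d", model$nfolds),
    sprintf("seed=%d", model$seed),
    sprintf("n=%d", model$n),
    sprintf("n_events=%d", model$n_events),
    sprintf("coef.%s=%s", names(model$coefficients), num(model$coefficients)),
    sprintf("mean.%s=%s", names(model$feature_means), num(model$feature_means)),
    sprintf("sd.%s=%s", names(model$feature_sds), num(model$feature_sds)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a risk model written by [write_risk_model()]
#'
#' @param path Input file path.
#' @return A `risk_model`.
#' @export
read_risk_model <- function(path) {
  if (!file.exists(path))
    tme_stop(sprintf("read_risk_model: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get1 <- function(k) vals[match(k, keys)]
  if (!identical(get1("format"), "tmebenefit_risk_model_v1"))
    tme_stop("read_risk_model: unrecognized format line")
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[sel]), sub(prefix, "", keys[sel],
                                               fixed = TRUE))
  }
  structure(list(coefficients = pick("coef."),
                 alpha = as.numeric(get1("alpha")),
                 lambda = as.numeric(get1("lambda")),
                 lambda_rule = get1("lambda_rule"),
                 nfolds = as.integer(get1("nfolds")),
                 seed = as.integer(get1("seed")),
                 feature_means = pick("mean."),
                 feature_sds = pick("sd."),
                 n = as.integer(get1("n")),
                 n_events = as.integer(get1("n_events"))),
            class = "risk_model")
}
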
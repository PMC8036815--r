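#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, counting ties as one half; computed from average
#' ranks, which equals exhaustive pair counting.
#'
#' @param scores numeric scores.
#' @param labels class labels.
#' @param positive label treated as positive (default "bad").
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "bad") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity, specificity and F1 score (all in percent)
#' with a configurable positive class.  Sensitivity is the recall of
#' the positive class; in the pipeline's survival orientation the
#' positive class defaults to good prognosis, so specificity is the
#' correctly-classified fraction of the patients who succumb.  F1 uses
#' the zero-safe convention (0 when precision + recall is 0).
#'
#' @param predictions predicted labels.
#' @param labels true labels.
#' @param positive the positive class (default "good").
#' @return named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`, `f1` in percent, plus the raw `tp`, `fp`, `tn`,
#'   `fn` counts.
#' @export
classification_metrics <- function(predictions, labels, positive = "good") {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(predictions) == length(labels))
  pos <- labels == positive
  ppos <- predictions == positive
  tp <- sum(ppos & pos); fp <- sum(ppos & !pos)
  tn <- sum(!ppos & !pos); fn <- sum(!ppos & pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (is.na(sens)) 0 else sens
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = 100 * (tp + tn) / length(labels),
    sensitivity = 100 * sens, specificity = 100 * spec, f1 = 100 * f1,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; right-censored observations leave the risk
#' set without contributing events.
#'
#' @param times survival times (> 0).
#' @param events 1 = event, 0 = censored (logical accepted).
#' @return data frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` at each observed time.
#' @export
km_curve <- function(times, events) {
  stopifnot(all(times > 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance, referred to
#' a chi-square distribution with one degree of freedom.
#'
#' @param times_a,events_a times and event indicators of group A.
#' @param times_b,events_b same for group B.
#' @return list with `chisq` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  grp <- factor(c(rep("A", length(times_a)), rep("B", length(times_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate Cox hazard ratio for a binary group
#'
#' Partial-likelihood estimate (Breslow tie handling) of the hazard
#' ratio between two groups, with a Wald 95% confidence interval.
#' Complete separation (one group holding all events with no overlap in
#' time) is flagged with an infinite-HR sentinel.
#'
#' @param times survival times.
#' @param events event indicators (1/0).
#' @param group binary group; the hazard ratio is for the second level
#'   of `factor(group)` relative to the first.
#' @return list with `hr`, `ci` (length-2), `beta`, `se`, `p`,
#'   `separation` (logical).
#' @export
cox_hr_binary <- function(times, events, group) {
  events <- as.integer(events)
  if (sum(events) == 0L) stop("no events: hazard ratio undefined")
  g <- factor(group)
  if (nlevels(g) != 2L) stop("group must be binary")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ g, ties = "breslow"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  separation <- !is.finite(beta) || abs(beta) > 15 || !is.finite(se) || se > 100
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  list(hr = if (separation && beta > 0) Inf else exp(beta),
       ci = ci, beta = beta, se = se,
       p = unname(summary(fit)$coefficients[1, "Pr(>|z|)"]),
       separation = separation)
}

#' TNM baseline risk stratification
#'
#' Stage IV patients form the high-risk group; stage II and III (A or
#' B) patients the low-risk group.
#'
#' @param stage character vector with values in II, IIIA, IIIB, IV.
#' @return character vector "high"/"low".
#' @export
tnm_stratify <- function(stage) {
  ok <- stage %in% c("II", "IIIA", "IIIB", "IV")
  if (!all(ok)) stop("unknown stage: ", paste(unique(stage[!ok]), collapse = ", "))
  ifelse(stage == "IV", "high", "low")
}

#' Cohort characteristics summary
#'
#' Counts and round-half-up percentages for sex and TNM categories,
#' median (range) survival in months, and mean +/- SD age.
#'
#' @param clinical data frame with `age`, `sex`, `stage`, `T_stage`,
#'   `N_stage`, `M_stage`, `survival_months`.
#' @return list of summary components.
#' @export
cohort_summary <- function(clinical) {
  n <- nrow(clinical)
  if (is.null(n) || n == 0L) stop("empty cohort")
  pct <- function(k) .round_half_up(100 * k / n)
  tab <- function(col, levels) {
    counts <- vapply(levels, function(l) sum(clinical[[col]] == l), numeric(1))
    data.frame(level = levels, count = counts, percent = pct(counts))
  }
  list(n = n,
       median_survival = stats::median(clinical$survival_months),
       survival_range = range(clinical$survival_months),
       age_mean = mean(clinical$age), age_sd = stats::sd(clinical$age),
       sex = tab("sex", c("male", "female")),
       stage = tab("stage", c("II", "IIIA", "IIIB", "IV")),
       T_stage = tab("T_stage", c("T2", "T3", "T4")),
       N_stage = tab("N_stage", c("N0", "N1", "N2")),
       M_stage = tab("M_stage", c("M0", "M1")))
}

#' Post-hoc feature importance of a submodel
#'
#' Extracts per-feature importance appropriate to the family: impurity
#' decrease summed over nodes for a decision tree, mean Gini decrease
#' for a random forest, absolute coefficient (sign retained) for the
#' logistic model, and absolute hyperplane weight (sign retained) for a
#' linear-kernel SVM.  Features are retained when importance is at
#' least twice the mean importance (tree, logistic, forest) or twice
#' the median importance (linear SVM).
#'
#' @param submodel an `ic_submodel` (or bare `ic_model`).
#' @return list of class `ic_importance` with `ranked` (data frame:
#'   feature, importance, sign), `retained` (character vector),
#'   `threshold`, `rule`.
#' @export
feature_importance <- function(submodel) {
  model <- if (inherits(submodel, "ic_submodel")) submodel$model else submodel
  stopifnot(inherits(model, "ic_model"))
  feats <- model$features
  sign_v <- rep(NA_real_, length(feats))
  imp <- switch(model$family,
    decision_tree = {
      v <- stats::setNames(numeric(length(feats)), feats)
      vi <- model$fit$variable.importance
      if (!is.null(vi)) v[names(vi)] <- vi
      v
    },
    random_forest = {
      vi <- ranger::importance(model$fit)
      stats::setNames(as.numeric(vi[feats]), feats)
    },
    logistic_model = {
      co <- as.numeric(stats::coef(model$fit))[-1]
      sign_v <- sign(co)
      stats::setNames(abs(co), feats)
    },
    svm = {
      if (!identical(model$config$kernel, "linear"))
        stop("feature importance is only defined for linear-kernel SVMs")
      w <- as.numeric(t(model$fit$coefs) %*% model$fit$SV)
      sign_v <- sign(w)
      stats::setNames(abs(w), feats)
    },
    stop("unsupported family: ", model$family))
  rule <- if (model$family == "svm") "2x median" else "2x mean"
  threshold <- if (model$family == "svm") 2 * stats::median(imp) else 2 * mean(imp)
  ord <- order(-imp)
  ranked <- data.frame(feature = feats[ord], importance = unname(imp[ord]),
                       sign = sign_v[ord])
  structure(list(ranked = ranked,
                 retained = ranked$feature[ranked$importance >= threshold &
                                             ranked$importance > 0],
                 threshold = threshold, rule = rule,
                 family = model$family),
            class = "ic_importance")
}

#' Evaluate risk stratification on a labelled cohort
#'
#' Combines the classification metrics (high risk vs bad prognosis)
#' with the survival machinery: Kaplan-Meier curves per risk group,
#' log-rank test, and univariate Cox hazard ratio of high vs low risk.
#'
#' @param risk "high"/"low" per patient.
#' @param labels "good"/"bad" prognosis per patient.
#' @param times,events survival data per patient.
#' @param scores optional ordinal scores for AUROC (defaults to
#'   risk == "high").
#' @param positive positive class for sensitivity (default "good").
#' @return list with `auroc`, `metrics`, `hr`, `logrank`, `km` (list of
#'   curves per group), `group_sizes`.
#' @export
evaluate_stratification <- function(risk, labels, times, events, scores = NULL,
                                    positive = "good") {
  if (is.null(scores)) scores <- as.numeric(risk == "high")
  pred_label <- ifelse(risk == "high", "bad", "good")
  hi <- risk == "high"
  out <- list(
    auroc = 100 * roc_auc(scores, labels, positive = "bad"),
    metrics = classification_metrics(pred_label, labels, positive = positive),
    group_sizes = c(low = sum(!hi), high = sum(hi)))
  if (any(hi) && any(!hi)) {
    out$logrank <- logrank_test(times[!hi], events[!hi], times[hi], events[hi])
    out$hr <- cox_hr_binary(times, events, factor(risk, levels = c("low", "high")))
    out$km <- list(low = km_curve(times[!hi], events[!hi]),
                   high = km_curve(times[hi], events[hi]))
  }
  out
}
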
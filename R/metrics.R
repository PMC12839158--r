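# Model performance metrics and internal validation.

#' Evaluate a prediction set against binary labels
#'
#' Computes discrimination (DeLong AUC of the logit score, disease-high),
#' calibration (Brier score; calibration slope from an unpenalized logistic
#' refit of the labels on the logit score), explained-variance pseudo
#' R-squareds (Cox-Snell and Nagelkerke), and classification metrics at the
#' rule "disease when `logit_score >= cutoff_logit`": confusion counts,
#' accuracy, sensitivity, specificity, Matthews correlation coefficient,
#' Cohen's kappa, an exact-binomial McNemar test on the discordant cells
#' (false positives vs false negatives), and a one-sided exact binomial test
#' of accuracy against the no-information rate (the majority-class
#' proportion).
#'
#' Note the classification direction: the model's slopes are negative in
#' both markers, so diseased samples score high on the logit scale and the
#' decision rule is greater-or-equal, even though the markers themselves are
#' disease-low.
#'
#' @param predictions data.frame with columns `logit_score` and
#'   `probability` (as returned by [predict.fa_logit()]).
#' @param labels binary outcome aligned with `predictions` (1 = disease).
#' @param cutoff_logit decision threshold on the logit scale (default 0).
#' @return an object of class `fa_metrics` (a list).
#' @export
evaluate_model <- function(predictions, labels, cutoff_logit = 0) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  p <- predictions$probability
  lp <- predictions$logit_score
  if (length(y) != length(p)) stop("predictions and labels lengths differ")
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; metrics are degenerate")
  }
  n <- length(y)

  auc <- auc_delong(lp[y == 1], lp[y == 0], orientation = "disease_high")
  brier <- mean((p - y)^2)

  eps <- 1e-15
  ll1 <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  nagelkerke <- cox_snell / (1 - exp(2 * ll0 / n))

  cal <- suppressWarnings(
    stats::glm.fit(cbind(1, lp), y, family = stats::binomial())$coefficients)
  calibration_slope <- unname(cal[2])

  pred <- as.integer(lp >= cutoff_logit)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  cls <- classification_metrics(tn = tn, fp = fp, fn = fn, tp = tp)

  structure(c(list(auc = auc, brier = brier, cox_snell_r2 = cox_snell,
                   nagelkerke_r2 = nagelkerke,
                   calibration_slope = calibration_slope,
                   cutoff_logit = cutoff_logit),
              cls),
            class = "fa_metrics")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, Matthews correlation coefficient,
#' Cohen's kappa, the exact-binomial McNemar test on the discordant cells,
#' and the one-sided exact binomial no-information-rate test.
#'
#' @param tn,fp,fn,tp confusion counts (disease = positive class).
#' @return list with `confusion` (named vector), `accuracy`, `sensitivity`,
#'   `specificity`, `mcc`, `kappa`, `mcnemar_p`, `nir`, `nir_p`.
#' @export
classification_metrics <- function(tn, fp, fn, tp) {
  n <- tn + fp + fn + tp
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  mcnemar_p <- if (fp + fn > 0) {
    stats::binom.test(min(fp, fn), fp + fn, 0.5)$p.value
  } else 1
  nir <- max(tp + fn, tn + fp) / n
  nir_p <- stats::binom.test(tp + tn, n, nir, alternative = "greater")$p.value
  list(confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
       accuracy = acc, sensitivity = sens, specificity = spec,
       mcc = mcc, kappa = kappa, mcnemar_p = mcnemar_p,
       nir = nir, nir_p = nir_p)
}

# AUC / Brier / calibration slope of a fitted model on given data; the
# compact metric set tracked through cross-validation and the optimism
# bootstrap.
.core_metrics <- function(model, features, labels) {
  pr <- stats::predict(model, features)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  auc <- auc_delong(pr$logit_score[y == 1], pr$logit_score[y == 0],
                    orientation = "disease_high")$auc
  brier <- mean((pr$probability - y)^2)
  slope <- if (stats::sd(pr$logit_score) > 0) {
    suppressWarnings(unname(
      stats::glm.fit(cbind(1, pr$logit_score), y,
                     family = stats::binomial())$coefficients[2]))
  } else NA_real_
  c(auc = auc, brier = brier, calibration_slope = slope)
}

#' Internal validation: stratified k-fold CV and optimism bootstrap
#'
#' Two complementary internal-validation procedures, reported separately:
#'
#' * Stratified k-fold cross-validation: the model-development procedure
#'   (`model_spec`) is refit on each training split, out-of-fold predictions
#'   are pooled, and AUC / Brier / calibration slope are computed once on
#'   the pooled predictions.
#' * Optimism bootstrap: for each of `B` class-stratified resamples with
#'   replacement, the full development procedure is refit on the resample;
#'   `optimism_b = metric(bootstrap fit on bootstrap sample) -
#'   metric(bootstrap fit on original sample)`; the corrected estimate is
#'   `apparent - mean(optimism)`. Because `model_spec` is refit inside every
#'   resample, any data-driven selection (e.g. the LASSO screen) is part of
#'   the procedure being validated. `B = 0` returns the apparent metrics
#'   unchanged.
#'
#' @param features data.frame of predictors.
#' @param labels binary outcome (1 = disease).
#' @param model_spec function `(features, labels) -> fa_logit`; defaults to
#'   [fit_lasso_logistic()] with its default CV-chosen penalty.
#' @param B number of bootstrap resamples (study default 1000).
#' @param k number of CV folds (study default 10).
#' @param seed integer seed; recorded in the result.
#' @return an object of class `fa_validation`: list with `apparent`,
#'   `cv` (pooled out-of-fold metrics), `optimism` (mean per metric),
#'   `corrected`, `B`, `k`, `seed`.
#' @export
validate_model <- function(features, labels,
                           model_spec = function(f, l)
                             fit_lasso_logistic(f, l),
                           B = 1000, k = 10, seed = NULL) {
  features <- as.data.frame(features)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (min(table(y)) < k) {
    stop("each class needs at least k members for stratified k-fold CV")
  }
  if (!is.null(seed)) set.seed(seed)

  apparent_fit <- model_spec(features, y)
  apparent <- .core_metrics(apparent_fit, features, y)

  # (a) stratified k-fold CV with pooled out-of-fold predictions
  fold <- .stratified_folds(y, k)
  oof_lp <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit_f <- model_spec(features[tr, , drop = FALSE], y[tr])
    oof_lp[!tr] <- stats::predict(fit_f,
                                  features[!tr, , drop = FALSE])$logit_score
  }
  oof <- data.frame(logit_score = oof_lp,
                    probability = stats::plogis(oof_lp))
  cv <- c(auc = auc_delong(oof_lp[y == 1], oof_lp[y == 0],
                           orientation = "disease_high")$auc,
          brier = mean((oof$probability - y)^2),
          calibration_slope = suppressWarnings(unname(
            stats::glm.fit(cbind(1, oof_lp), y,
                           family = stats::binomial())$coefficients[2])))

  # (b) optimism bootstrap, class-stratified resampling
  idx_by_class <- split(seq_along(y), y)
  opt <- matrix(NA_real_, nrow = B, ncol = 3,
                dimnames = list(NULL, names(apparent)))
  b_done <- 0
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_class,
                         function(ii) sample(ii, length(ii), replace = TRUE)))
    fit_b <- tryCatch(model_spec(features[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
    if (is.null(fit_b)) next
    boot_perf <- .core_metrics(fit_b, features[idx, , drop = FALSE], y[idx])
    orig_perf <- .core_metrics(fit_b, features, y)
    opt[b, ] <- boot_perf - orig_perf
    b_done <- b_done + 1
  }
  optimism <- if (B > 0) colMeans(opt, na.rm = TRUE) else
    c(auc = 0, brier = 0, calibration_slope = 0)
  optimism[is.nan(optimism)] <- 0
  corrected <- apparent - optimism

  structure(list(apparent = apparent, cv = cv, optimism = optimism,
                 corrected = corrected, B = B, B_completed = b_done, k = k,
                 seed = seed, model = apparent_fit),
            class = "fa_validation")
}
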
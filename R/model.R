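# The two-predictor diagnostic logit function and LASSO-based model
# development.
#
# Development procedure: predictors are centred/scaled, LASSO-penalized
# logistic regression with a stratified-CV-chosen penalty screens them, and
# the selected (non-zero) predictors are refit by unpenalized maximum
# likelihood. Both the penalized (standardized) and refit original-scale
# coefficients are kept; exact zeros are reported as excluded.

#' Construct a logistic diagnostic model object
#'
#' @param intercept intercept on the original predictor scale.
#' @param coefficients named numeric vector of original-scale slopes.
#' @param standardized_coefficients optional named numeric vector of
#'   standardized slopes (including exact zeros for excluded predictors).
#' @param standardized_intercept optional standardized-scale intercept.
#' @param standardization optional list mapping predictor to
#'   `c(center, scale)`.
#' @param excluded character vector of predictors dropped by the penalty.
#' @param meta free-form provenance list (lambda, seed, flags).
#' @return an object of class `fa_logit`.
#' @export
fa_logit_model <- function(intercept, coefficients,
                           standardized_coefficients = NULL,
                           standardized_intercept = NULL,
                           standardization = NULL,
                           excluded = character(0), meta = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 standardized_coefficients = standardized_coefficients,
                 standardized_intercept = standardized_intercept,
                 standardization = standardization,
                 excluded = excluded,
                 meta = meta),
            class = "fa_logit")
}

#' The published two-predictor diagnostic function
#'
#' Returns the diagnostic logit function developed on the pooled
#' control-vs-atherosclerosis cohort:
#' \deqn{logit\,p = 5.254 - 0.145 \times O6/3\text{-}BI
#'       - 11.544 \times (C18{:}0/C18{:}1n\text{-}9)}
#' with `p = 1 / (1 + exp(-logit p))`. Standardized coefficients (-0.147
#' intercept, -0.622 for o63bi, -1.416 for c18_ratio) are carried as
#' metadata; the aa_ada candidate was excluded (standardized beta exactly 0).
#' Both slopes are negative: low values of either marker indicate disease,
#' so high logit scores mark disease.
#'
#' @return an `fa_logit` model with predictors `o63bi` and `c18_ratio`.
#' @examples
#' m <- published_model()
#' predict(m, data.frame(o63bi = 12.00, c18_ratio = 0.42))
#' @export
published_model <- function() {
  fa_logit_model(
    intercept = 5.254,
    coefficients = c(o63bi = -0.145, c18_ratio = -11.544),
    standardized_coefficients = c(o63bi = -0.622, c18_ratio = -1.416,
                                  aa_ada = 0),
    standardized_intercept = -0.147,
    excluded = "aa_ada",
    meta = list(source = "published", outcome = "atherosclerosis",
                orientation = "disease_high")
  )
}

#' Predict from a logistic diagnostic model
#'
#' @param object an `fa_logit` model.
#' @param newdata a data.frame (or named list/vector) containing every model
#'   predictor; extra columns are ignored.
#' @param ... unused.
#' @return a data.frame with columns `logit_score` and `probability`
#'   (`probability = plogis(logit_score)`).
#' @export
predict.fa_logit <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  needed <- names(object$coefficients)
  missing <- setdiff(needed, names(newdata))
  if (length(missing)) {
    stop("predictor(s) missing from newdata: ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(newdata)[, needed, drop = FALSE])
  lp <- drop(object$intercept + x %*% object$coefficients[needed])
  data.frame(logit_score = lp, probability = stats::plogis(lp))
}

# Stratified fold assignment: each class is spread evenly over k folds.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit a LASSO-screened logistic model
#'
#' Predictors are standardized (centre/scale) before penalization; the
#' penalty weight is chosen by stratified k-fold cross-validation over
#' glmnet's log-spaced lambda path, minimizing binomial deviance (or the
#' one-standard-error rule when `one_se = TRUE`). Predictors with exact-zero
#' penalized coefficients are reported as excluded; by default
#' (`refit = TRUE`) the surviving predictors are refit by unpenalized
#' maximum likelihood, so the returned original-scale coefficients are the
#' MLE of the selected model (the penalized standardized path is kept in
#' `standardized_coefficients`).
#'
#' @param features data.frame or matrix of numeric predictors (no missing
#'   values).
#' @param labels binary outcome (0/1, logical, or two-level factor with the
#'   second level as the event).
#' @param lambda `"cv"` (default) for cross-validated selection, or a single
#'   non-negative number (0 gives an essentially unpenalized fit).
#' @param nfolds folds for the stratified CV (default 10).
#' @param one_se use the one-standard-error rule instead of the deviance
#'   minimum.
#' @param refit refit selected predictors by unpenalized ML (default TRUE).
#' @param seed optional integer seed controlling the fold assignment.
#' @return an `fa_logit` model. `meta` records `lambda`, `seed`, and a
#'   `separation` flag when the unpenalized refit did not converge cleanly
#'   (complete separation); the penalized coefficients are still returned.
#' @export
fit_lasso_logistic <- function(features, labels, lambda = "cv", nfolds = 10,
                               one_se = FALSE, refit = TRUE, seed = NULL) {
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features must not contain missing values")
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (nrow(x) != length(y)) stop("features and labels lengths differ")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  constant <- scl == 0
  if (any(constant)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
  }
  xs <- scale(x, center = ctr, scale = scl)
  # glmnet needs >= 2 columns; pad with an all-zero dummy that can never be
  # selected, and drop it from every output
  padded <- ncol(xs) < 2
  if (padded) xs <- cbind(xs, .pad = 0)

  if (!is.null(seed)) set.seed(seed)
  if (identical(lambda, "cv")) {
    foldid <- .stratified_folds(y, nfolds)
    cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                               foldid = foldid, standardize = FALSE,
                               type.measure = "deviance")
    lam <- if (one_se) cvfit$lambda.1se else cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    lam <- as.numeric(lambda)
    if (lam < 0) stop("lambda must be non-negative")
    # descend the path to the requested lambda for a warm-started solution
    path <- sort(unique(c(exp(seq(log(max(lam, 1e-4) * 100),
                                  log(max(lam, 1e-4)), length.out = 30)),
                          lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                          lambda = path, standardize = FALSE,
                          thresh = 1e-12)
  }
  # lambda.interp emits a benign "collapsing to unique 'x'" warning when the
  # requested s sits exactly on a short path
  beta_std <- drop(as.matrix(suppressWarnings(
    stats::coef(fit, s = lam, exact = FALSE))))
  b0_std <- beta_std[1]
  beta_std <- beta_std[-1]
  names(beta_std) <- colnames(xs)
  if (padded) beta_std <- beta_std[setdiff(names(beta_std), ".pad")]
  excluded <- names(beta_std)[beta_std == 0]
  selected <- names(beta_std)[beta_std != 0]

  separation <- FALSE
  if (refit && length(selected)) {
    xm <- cbind(`(Intercept)` = 1, x[, selected, drop = FALSE])
    glm_fit <- withCallingHandlers(
      stats::glm.fit(xm, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    cf <- glm_fit$coefficients
    intercept <- unname(cf[1])
    slopes <- structure(numeric(length(beta_std)), names = names(beta_std))
    slopes[selected] <- cf[-1]
  } else {
    # back-transform the penalized standardized fit to the original scale
    slopes <- beta_std / scl
    intercept <- unname(b0_std - sum(beta_std * ctr / scl))
  }

  fa_logit_model(
    intercept = intercept,
    coefficients = slopes,
    standardized_coefficients = beta_std,
    standardized_intercept = unname(b0_std),
    standardization = Map(function(c0, s0) c(center = c0, scale = s0),
                          as.list(ctr), as.list(scl)),
    excluded = excluded,
    meta = list(lambda = lam, seed = seed, refit = refit,
                separation = separation)
  )
}

#' Minimum-sample-size feasibility check for model development
#'
#' Reports events per candidate parameter and the shrinkage-based minimum
#' sample size `n >= p / ((S - 1) * ln(1 - R2_cs / S))` for target expected
#' shrinkage `S` (default 0.9) and an anticipated Cox-Snell R-squared, with a
#' pass/fail flag at the supplied `n`.
#'
#' @param n total sample size available.
#' @param events number of outcome events (0 < events < n).
#' @param n_params number of candidate predictor parameters (>= 1).
#' @param anticipated_cs_r2 anticipated Cox-Snell R-squared of the model; must
#'   be < `target_shrinkage`.
#' @param target_shrinkage target expected shrinkage factor (default 0.9).
#' @return list with `events_per_parameter`, `min_n`, `pass`, and the
#'   inputs.
#' @export
riley_feasibility <- function(n, events, n_params, anticipated_cs_r2,
                              target_shrinkage = 0.9) {
  if (events <= 0 || events >= n) stop("need 0 < events < n")
  if (n_params < 1) stop("n_params must be >= 1")
  if (anticipated_cs_r2 >= target_shrinkage) {
    stop("anticipated_cs_r2 must be below the target shrinkage")
  }
  min_n <- ceiling(n_params /
                     ((target_shrinkage - 1) *
                        log(1 - anticipated_cs_r2 / target_shrinkage)))
  list(n = n, events = events, n_params = n_params,
       anticipated_cs_r2 = anticipated_cs_r2,
       target_shrinkage = target_shrinkage,
       events_per_parameter = events / n_params,
       min_n = min_n,
       pass = n >= min_n)
}

#' Serialize / restore a logistic diagnostic model
#'
#' Flat JSON with intercept, coefficients, standardization and provenance.
#'
#' @param model an `fa_logit`.
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_model` returns the `fa_logit`.
#' @export
write_model <- function(model, path) {
  out <- unclass(model)
  # named atomic vectors lose their names in JSON arrays; store as objects
  for (f in c("coefficients", "standardized_coefficients")) {
    if (!is.null(out[[f]])) out[[f]] <- as.list(out[[f]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa_logit_model(
    intercept = raw$intercept,
    coefficients = unlist(raw$coefficients),
    standardized_coefficients = unlist(raw$standardized_coefficients),
    standardized_intercept = raw$standardized_intercept,
    standardization = raw$standardization,
    excluded = as.character(raw$excluded %||% character(0)),
    meta = raw$meta %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
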
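# The published diagnostic function, LASSO development, metrics, Riley
# feasibility.

test_that("published_model carries the printed constants", {
  m <- published_model()
  expect_equal(m$intercept, 5.254)
  expect_equal(m$coefficients, c(o63bi = -0.145, c18_ratio = -11.544))
  expect_equal(m$standardized_coefficients[["aa_ada"]], 0)
  expect_true("aa_ada" %in% m$excluded)
  expect_equal(m$standardized_intercept, -0.147)
})

test_that("predict applies the logistic link and errors on missing predictors", {
  m <- published_model()
  at0 <- predict(m, data.frame(o63bi = 0, c18_ratio = 0))
  expect_equal(at0$logit_score, 5.254)
  expect_equal(predict(m, c(o63bi = 12.00, c18_ratio = 0.42))$logit_score,
               5.254 - 0.145 * 12 - 11.544 * 0.42)
  expect_equal(predict(m, c(o63bi = 12.00, c18_ratio = 0.42))$probability,
               plogis(5.254 - 0.145 * 12 - 11.544 * 0.42))
  # logit 0 -> probability 0.5
  p0 <- predict(fa_logit_model(0, c(x = 1)), data.frame(x = 0))
  expect_equal(p0$probability, 0.5)
  expect_error(predict(m, data.frame(o63bi = 1)), "c18_ratio")
})

test_that("probability is strictly decreasing in both published predictors", {
  m <- published_model()
  bi <- seq(2, 25, length.out = 30)
  p1 <- predict(m, data.frame(o63bi = bi, c18_ratio = 0.3))$probability
  expect_true(all(diff(p1) < 0))
  cr <- seq(0.1, 0.6, length.out = 30)
  p2 <- predict(m, data.frame(o63bi = 10, c18_ratio = cr))$probability
  expect_true(all(diff(p2) < 0))
})

test_that("full shrinkage drives all slopes to zero and the intercept to the prevalence logit", {
  set.seed(41)
  x <- data.frame(a = rnorm(300), b = rnorm(300))
  y <- rbinom(300, 1, 0.3)
  m <- fit_lasso_logistic(x, y, lambda = 50, refit = FALSE)
  expect_equal(unname(m$coefficients), c(0, 0))
  expect_equal(m$intercept, qlogis(mean(y)), tolerance = 1e-6)
  expect_setequal(m$excluded, c("a", "b"))
})

test_that("lambda = 0 matches the hand-rolled Newton-Raphson MLE oracle", {
  set.seed(42)
  n <- 2000
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  lp <- -0.5 + 1.2 * x$a - 0.8 * x$b
  y <- rbinom(n, 1, plogis(lp))
  oracle <- nr_logistic(as.matrix(x), y)
  m <- fit_lasso_logistic(x, y, lambda = 0)
  expect_equal(m$intercept, oracle[1], tolerance = 1e-3)
  expect_equal(unname(m$coefficients), oracle[-1], tolerance = 1e-3)
  # without the ML refit, the penalized path solution is still close
  m2 <- fit_lasso_logistic(x, y, lambda = 0, refit = FALSE)
  expect_equal(unname(m2$coefficients), oracle[-1], tolerance = 1e-3)
})

test_that("constant features are dropped with a warning", {
  set.seed(43)
  x <- data.frame(a = rnorm(100), flat = rep(1, 100))
  y <- rbinom(100, 1, plogis(x$a))
  expect_warning(m <- fit_lasso_logistic(x, y, lambda = 0), "flat")
  expect_equal(names(m$coefficients), "a")
})

test_that("parameter recovery: refitting data generated from the published model", {
  set.seed(44)
  n <- 5000
  specs <- default_specs()
  # features drawn from the default index-scale world: Control and pooled
  # atherosclerosis in equal parts, lognormal marginals
  sim <- generate_index_cohort(specs, n_per_group = c(
    Control = n / 2, Atorvastatin = round(n * 19 / 104),
    Rosuvastatin = round(n * 21 / 104), NoStatin = n / 2 -
      round(n * 19 / 104) - round(n * 21 / 104)),
    indices = c("o63bi", "c18_ratio"),
    distribution = "lognormal_moment_matched", seed = 441)
  feats <- sim[, c("o63bi", "c18_ratio")]
  truth <- published_model()
  y <- rbinom(n, 1, predict(truth, feats)$probability)
  fit <- fit_lasso_logistic(feats, y, seed = 442)
  expect_equal(unname(fit$coefficients["o63bi"]), -0.145, tolerance = 0.10)
  expect_equal(unname(fit$coefficients["c18_ratio"]), -11.544,
               tolerance = 0.10)
})

test_that("evaluate_model: perfection, the printed confusion matrix, error contracts", {
  perfect <- data.frame(logit_score = c(-9, -9, 9, 9),
                        probability = c(0, 0, 1, 1))
  y <- c(0, 0, 1, 1)
  r <- evaluate_model(perfect, y, cutoff_logit = 0)
  expect_equal(r$brier, 0)
  expect_equal(r$mcc, 1)
  expect_equal(r$auc$auc, 1)
  cm <- classification_metrics(tn = 35, fp = 13, fn = 8, tp = 42)
  expect_equal(round(cm$accuracy, 3), 0.786)
  expect_equal(round(cm$sensitivity, 3), 0.840)
  expect_equal(round(cm$specificity, 3), 0.729)
  expect_equal(cm$mcc, (42 * 35 - 13 * 8) /
                 sqrt(55) / sqrt(50) / sqrt(48) / sqrt(43))
  expect_equal(cm$mcnemar_p, binom.test(8, 21, 0.5)$p.value)
  expect_lt(cm$nir_p, 1e-4)
  expect_error(evaluate_model(perfect, c(1, 1, 1, 1)), "single class")
})

test_that("Brier of the constant-prevalence predictor respects its bound on balanced data", {
  y <- rep(c(0, 1), 50)
  pr <- data.frame(logit_score = rep(qlogis(0.5), 100),
                   probability = rep(0.5, 100))
  # constant score: AUC is 0.5 by ties, Brier exactly 0.25
  expect_equal(mean((pr$probability - y)^2), 0.25)
  expect_equal(auc_delong(pr$logit_score[y == 1], pr$logit_score[y == 0],
                          "disease_high")$auc, 0.5)
})

test_that("calibration slope is ~1 for a model evaluated on its own generative data", {
  set.seed(45)
  n <- 10000
  x <- data.frame(a = rnorm(n))
  m <- fa_logit_model(-0.3, c(a = 1.4))
  pr <- predict(m, x)
  y <- rbinom(n, 1, pr$probability)
  r <- evaluate_model(pr, y)
  expect_equal(r$calibration_slope, 1, tolerance = 0.08)
})

test_that("riley_feasibility reports EPP and the shrinkage criterion", {
  r <- riley_feasibility(n = 102, events = 50, n_params = 2,
                         anticipated_cs_r2 = 0.423)
  expect_equal(r$events_per_parameter, 25)
  # independent reimplementation of the shrinkage-based minimum n
  min_n_oracle <- ceiling(2 / ((0.9 - 1) * log(1 - 0.423 / 0.9)))
  expect_equal(r$min_n, min_n_oracle)
  expect_identical(r$pass, 102 >= min_n_oracle)
  # required n increases with the number of candidate parameters
  ns <- vapply(1:6, function(p)
    riley_feasibility(500, 250, p, 0.3)$min_n, numeric(1))
  expect_true(all(diff(ns) > 0))
  expect_error(riley_feasibility(100, 50, 2, anticipated_cs_r2 = 0.95),
               "below the target")
  expect_error(riley_feasibility(100, 0, 2, 0.3), "0 < events < n")
})

test_that("model JSON serialization round-trips", {
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$excluded, m$excluded)
  expect_equal(predict(back, c(o63bi = 9, c18_ratio = 0.3)),
               predict(m, c(o63bi = 9, c18_ratio = 0.3)))
})
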
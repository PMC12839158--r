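# End-to-end orchestration: simulate or ingest a cohort, compute indices,
# run group statistics and ROC analyses, fit/evaluate/validate the logistic
# model, and emit report tables.

#' Pipeline configuration
#'
#' @param seed integer seed (mandatory; fully determines simulate-mode
#'   output).
#' @param specs group specs for simulate mode (see [default_specs()]).
#' @param markers indices analysed in the ROC/effect-size tables; must have a
#'   registered orientation (see [marker_orientation()]).
#' @param model_predictors candidate predictors for the LASSO screen.
#' @param control_group label of the non-diseased group.
#' @param validation_B bootstrap resamples for internal validation (the
#'   study default is 1000; lower it for quick runs).
#' @param validation_k CV folds for internal validation.
#' @param distribution marginal family for simulate mode.
#' @return a classed list `fa_config`.
#' @export
fa_pipeline_config <- function(seed,
                               specs = default_specs(),
                               markers = c("omega3_status", "aa_epa",
                                           "omega6_3", "aa_ada",
                                           "c18_ratio", "o63bi"),
                               model_predictors = c("omega3_status",
                                                    "aa_epa", "omega6_3",
                                                    "aa_ada", "c18_ratio",
                                                    "o63bi"),
                               control_group = "Control",
                               validation_B = 1000, validation_k = 10,
                               distribution = "lognormal_moment_matched") {
  if (missing(seed)) stop("a seed is mandatory")
  for (m in markers) marker_orientation(m)  # errors on unknown markers
  structure(list(seed = as.integer(seed), specs = specs, markers = markers,
                 model_predictors = model_predictors,
                 control_group = control_group,
                 validation_B = validation_B, validation_k = validation_k,
                 distribution = distribution),
            class = "fa_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- unclass(config)
  stripped$specs <- lapply(stripped$specs, function(sp) {
    sp$correlation <- as.vector(sp$correlation)
    sp
  })
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' In `simulate` mode an index-scale cohort is drawn from the config's group
#' specs; in `ingest` mode a concentration cohort CSV is read, converted to
#' molar percent and summarized into indices. Either way the pipeline then
#' produces: group means +/- SD per marker (`table1`), the per-subgroup ROC
#' report (`table2`), pairwise Cliff's delta (`table3`), Youden cut-offs for
#' the o63bi index (`table4`), the LASSO-screened model coefficients
#' (`table5`), its apparent/validated performance (`table6`) and the
#' cut-off-level classification report (`table7`), plus the serialized model
#' and a run manifest with seed and config hash. Output is deterministic
#' given the seed.
#'
#' @param config an `fa_config` (see [fa_pipeline_config()]).
#' @param mode `"simulate"` or `"ingest"`.
#' @param cohort_path CSV of per-analyte concentrations, required for ingest
#'   mode.
#' @param panel analyte panel for ingest mode.
#' @param out_dir optional directory; when given, tables are written as
#'   `table1.csv` ... `table7.csv`, `model.json` and `manifest.json`.
#' @return a list (report bundle) with elements `table1` ... `table7`,
#'   `comparisons`, `model`, `validation`, `manifest`.
#' @export
run_pipeline <- function(config, mode = c("simulate", "ingest"),
                         cohort_path = NULL, panel = default_panel(),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (!inherits(config, "fa_config")) stop("config must be an fa_config")
  set.seed(config$seed)

  if (mode == "simulate") {
    idx <- generate_index_cohort(config$specs,
                                 distribution =
                                   if (config$distribution == "gaussian")
                                     "gaussian" else
                                       "lognormal_moment_matched",
                                 seed = config$seed)
  } else {
    if (is.null(cohort_path) || !file.exists(cohort_path)) {
      stop("ingest mode needs an existing cohort_path")
    }
    conc <- read_cohort(cohort_path, panel = panel, units = "ng_per_ml")
    mol <- to_molar_percent(conc, panel)
    available <- fa_index_names[vapply(fa_index_names, function(nm) {
      !inherits(tryCatch(compute_index_set(mol[1, , drop = FALSE], nm),
                         error = function(e) e), "error")
    }, TRUE)]
    idx <- compute_index_set(mol, available)
  }

  markers <- intersect(config$markers, names(idx))
  missing_markers <- setdiff(config$markers, names(idx))
  if (length(missing_markers)) {
    stop("marker(s) not computable from the cohort: ",
         paste(missing_markers, collapse = ", "))
  }
  ctrl <- config$control_group
  if (!ctrl %in% idx$group) stop("control group '", ctrl, "' not in cohort")
  case_groups <- setdiff(unique(idx$group), ctrl)

  # table1: group mean +/- SD per marker
  table1 <- do.call(rbind, lapply(markers, function(m) {
    ag <- stats::aggregate(idx[[m]], list(group = idx$group),
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(marker = m, group = ag$group, mean = ag$x[, "mean"],
               sd = ag$x[, "sd"], stringsAsFactors = FALSE)
  }))

  # table2: ROC per (control vs case-group, marker)
  table2 <- do.call(rbind, lapply(case_groups, function(g) {
    do.call(rbind, lapply(markers, function(m) {
      ori <- marker_orientation(m)
      r <- auc_delong(idx[[m]][idx$group == g], idx[[m]][idx$group == ctrl],
                      orientation = ori$orientation)
      data.frame(comparison = paste(ctrl, g, sep = "-"), marker = m,
                 auc = r$auc, se = r$se, ci_lo = r$ci95[1],
                 ci_hi = r$ci95[2], p_value = r$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))

  # table3: pairwise Cliff's delta per marker (first-listed group as x)
  grp_levels <- c(ctrl, case_groups)
  prs <- utils::combn(grp_levels, 2)
  table3 <- do.call(rbind, lapply(markers, function(m) {
    do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      g1 <- prs[1, j]; g2 <- prs[2, j]
      r <- cliffs_delta(idx[[m]][idx$group == g1],
                        idx[[m]][idx$group == g2])
      data.frame(marker = m, group1 = g1, group2 = g2, delta = r$delta,
                 ci_lo = r$ci95[1], ci_hi = r$ci95[2],
                 stringsAsFactors = FALSE)
    }))
  }))

  # table4: Youden cut-offs for o63bi (per subgroup + pooled), if present
  table4 <- NULL
  if ("o63bi" %in% markers) {
    cmp <- c(as.list(case_groups), list(case_groups))
    nm <- c(case_groups, "Atherosclerosis")
    table4 <- do.call(rbind, lapply(seq_along(cmp), function(j) {
      cases <- idx$o63bi[idx$group %in% cmp[[j]]]
      ctrls <- idx$o63bi[idx$group == ctrl]
      co <- youden_cutoff(cases, ctrls, rule = "le_is_disease")
      a <- auc_delong(cases, ctrls, orientation = "disease_low")
      data.frame(comparison = paste(ctrl, nm[j], sep = "-"), auc = a$auc,
                 cutoff = co$cutoff, sensitivity = co$sensitivity,
                 specificity = co$specificity, accuracy = co$accuracy,
                 stringsAsFactors = FALSE)
    }))
  }

  # group-comparison decision tree per marker
  comparisons <- do.call(rbind, lapply(markers, function(m) {
    groups <- split(idx[[m]], idx$group)[grp_levels]
    r <- compare_groups(groups)
    base <- data.frame(marker = m, test = r$omnibus_test,
                       statistic = r$statistic, p = r$p_value,
                       stringsAsFactors = FALSE)
    if (is.null(r$posthoc)) {
      cbind(base, pair = NA, raw_p = NA, adjusted_p = NA)
    } else {
      cbind(base[rep(1, nrow(r$posthoc)), ], r$posthoc[c("pair", "raw_p",
                                                         "adjusted_p")])
    }
  }))
  rownames(comparisons) <- NULL

  # model development on pooled control vs atherosclerosis
  predictors <- intersect(config$model_predictors, names(idx))
  feats <- idx[, predictors, drop = FALSE]
  y <- as.integer(idx$group != ctrl)
  model <- fit_lasso_logistic(feats, y, seed = config$seed)
  pr <- stats::predict(model, feats)
  co <- youden_cutoff(pr$logit_score[y == 1], pr$logit_score[y == 0],
                      rule = "ge_is_disease")
  metrics <- evaluate_model(pr, y, cutoff_logit = co$cutoff)
  validation <- validate_model(feats, y,
                               model_spec = function(f, l)
                                 fit_lasso_logistic(f, l),
                               B = config$validation_B,
                               k = config$validation_k,
                               seed = config$seed)

  table5 <- data.frame(
    predictor = c("(Intercept)", names(model$coefficients)),
    beta_standardized = c(model$standardized_intercept,
                          unname(model$standardized_coefficients[
                            names(model$coefficients)])),
    beta_original = c(model$intercept, unname(model$coefficients)),
    stringsAsFactors = FALSE)
  table6 <- data.frame(
    auc = metrics$auc$auc, brier = metrics$brier,
    cox_snell_r2 = metrics$cox_snell_r2,
    nagelkerke_r2 = metrics$nagelkerke_r2,
    calibration_slope = metrics$calibration_slope,
    auc_corrected = unname(validation$corrected["auc"]),
    brier_corrected = unname(validation$corrected["brier"]),
    slope_corrected = unname(validation$corrected["calibration_slope"]))
  delta_logit <- cliffs_delta(pr$logit_score[y == 0], pr$logit_score[y == 1])
  table7 <- data.frame(
    cliffs_delta = delta_logit$delta, auc = metrics$auc$auc,
    se = metrics$auc$se, p_value = metrics$auc$p_value,
    cutoff = co$cutoff, sensitivity = metrics$sensitivity,
    specificity = metrics$specificity, accuracy = metrics$accuracy)

  manifest <- list(seed = config$seed, mode = mode,
                   config_hash = .config_hash(config),
                   lambda = model$meta$lambda,
                   n = nrow(idx), markers = markers,
                   package_version =
                     as.character(utils::packageVersion("faindex")),
                   decisions = list(
                     cutoff_rule = "disease when logit_score >= cutoff",
                     tests = unique(comparisons$test)))

  bundle <- list(indices = idx, table1 = table1, table2 = table2,
                 table3 = table3, table4 = table4, table5 = table5,
                 table6 = table6, table7 = table7,
                 comparisons = comparisons, model = model,
                 metrics = metrics, validation = validation,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in paste0("table", 1:7)) {
      if (!is.null(bundle[[nm]])) {
        utils::write.csv(bundle[[nm]], file.path(out_dir,
                                                 paste0(nm, ".csv")),
                         row.names = FALSE)
      }
    }
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    write_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
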
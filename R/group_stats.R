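# Group-comparison decision tree, multiplicity adjustment and power helpers.
#
# Routing (all gates at alpha = 0.05, per group):
#   every group passes Shapiro-Wilk  -> variance homogeneity (median-centred
#     Levene) -> ANOVA (homogeneous) or Welch ANOVA (heterogeneous);
#     two groups -> Welch t-test.
#   any group fails Shapiro-Wilk (or has < 3 observations, with a warning
#     flag) -> Kruskal-Wallis; two groups -> Mann-Whitney U.
# A significant omnibus test triggers the matching post hoc family with Holm
# adjustment: Tukey HSD after ANOVA, pairwise Welch t + Holm after Welch
# ANOVA, Dunn's rank test + Holm after Kruskal-Wallis.

# Median-centred Levene (Brown-Forsythe) test for variance homogeneity.
.levene_median <- function(values, labels) {
  sp <- split(values, labels)
  z <- unlist(lapply(sp, function(v) abs(v - stats::median(v))))
  g <- factor(rep(names(sp), lengths(sp)))
  stats::oneway.test(z ~ g, var.equal = TRUE)$p.value
}

.shapiro_pass <- function(v, alpha) {
  if (length(v) > 5000) v <- v[seq_len(5000)]
  p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  !is.na(p) && p >= alpha
}

# Dunn's z-tests on Kruskal-Wallis pooled ranks, with the tie correction.
.dunn_pairs <- function(values, labels) {
  g <- factor(labels)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  raw <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    2 * stats::pnorm(-abs(z))
  })
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             raw_p = raw, stringsAsFactors = FALSE)
}

#' Compare groups with the test-selection decision tree
#'
#' Selects the omnibus test from per-group Shapiro-Wilk normality (alpha) and
#' a median-centred Levene homogeneity gate, runs it, and, when significant,
#' the matching post hoc family with Holm-adjusted pairwise p-values. Groups
#' with fewer than 3 observations cannot be normality-tested and route the
#' comparison to the nonparametric branch with `small_group_warning = TRUE`.
#'
#' @param groups named list mapping group label to a numeric vector.
#' @param alpha significance level used for the gates and for triggering the
#'   post hoc family.
#' @return an object of class `fa_comparison`: list with `omnibus_test` (one
#'   of `"anova"`, `"welch_anova"`, `"kruskal_wallis"`, `"welch_t"`,
#'   `"mann_whitney"`), `statistic`, `p_value`, `posthoc` (data.frame
#'   `pair, raw_p, adjusted_p, method`, or `NULL` when the omnibus test is
#'   not significant or only two groups were compared), `routing` (gate
#'   outcomes) and `small_group_warning`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups))) {
    stop("groups must be a named list with at least two groups")
  }
  groups <- lapply(groups, as.numeric)
  small <- vapply(groups, function(v) length(v) < 3, TRUE)
  normal <- if (any(small)) {
    rep(FALSE, length(groups))
  } else {
    vapply(groups, .shapiro_pass, TRUE, alpha = alpha)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)))
  two <- length(groups) == 2
  routing <- list(normal_per_group = normal, variance_homogeneous = NA)

  if (all(normal)) {
    if (two) {
      fit <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      res <- list(omnibus_test = "welch_t",
                  statistic = unname(fit$statistic), p_value = fit$p.value)
    } else {
      hom <- .levene_median(values, labels) >= alpha
      routing$variance_homogeneous <- hom
      fit <- stats::oneway.test(values ~ labels, var.equal = hom)
      res <- list(omnibus_test = if (hom) "anova" else "welch_anova",
                  statistic = unname(fit$statistic), p_value = fit$p.value)
    }
  } else {
    if (two) {
      fit <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
      res <- list(omnibus_test = "mann_whitney",
                  statistic = unname(fit$statistic), p_value = fit$p.value)
    } else {
      fit <- stats::kruskal.test(values, labels)
      res <- list(omnibus_test = "kruskal_wallis",
                  statistic = unname(fit$statistic), p_value = fit$p.value)
    }
  }

  posthoc <- NULL
  if (!two && !is.na(res$p_value) && res$p_value < alpha) {
    if (res$omnibus_test == "anova") {
      tk <- stats::TukeyHSD(stats::aov(values ~ labels))$labels
      posthoc <- data.frame(pair = sub("-", " vs ", rownames(tk)),
                            raw_p = tk[, "p adj"],
                            adjusted_p = tk[, "p adj"],
                            method = "tukey", stringsAsFactors = FALSE)
    } else if (res$omnibus_test == "welch_anova") {
      pairs <- utils::combn(names(groups), 2)
      raw <- apply(pairs, 2, function(pr) {
        stats::t.test(groups[[pr[1]]], groups[[pr[2]]],
                      var.equal = FALSE)$p.value
      })
      posthoc <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                            raw_p = raw, adjusted_p = holm_adjust(raw),
                            method = "welch_t_holm", stringsAsFactors = FALSE)
    } else {
      ph <- .dunn_pairs(values, labels)
      ph$adjusted_p <- holm_adjust(ph$raw_p)
      ph$method <- "dunn_holm"
      posthoc <- ph
    }
    rownames(posthoc) <- NULL
  }

  structure(c(res, list(posthoc = posthoc, routing = routing,
                        small_group_warning = any(small))),
            class = "fa_comparison")
}

#' Holm step-down adjustment
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (same order as input), monotone-enforced over
#'   the sorted sequence and capped at 1.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return BH-adjusted p-values (q-values), monotone-enforced and capped at 1.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-group power / sample-size helper
#'
#' Conversions for the a priori power analysis: Cohen's f relates to the
#' two-group standardized mean difference as d = 2f. Solving for n uses the
#' normal-approximation formula
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 / d^2` per group, rounded up;
#' `correction = "t"` iterates the same formula with t quantiles at
#' `2n - 2` degrees of freedom, which typically adds one subject per group
#' (e.g. 34 instead of 33 at d = 0.8, alpha = 0.05, power = 0.90).
#'
#' @param cohens_f Cohen's f (>= 0); `cohens_d` is derived as `2 * f` when
#'   missing.
#' @param cohens_d standardized mean difference; derived from `cohens_f` when
#'   `NULL`.
#' @param alpha two-sided type-I error rate.
#' @param power target power.
#' @param n_per_group supply to solve for `d` instead of `n`.
#' @param solve_for `"n"` (default), `"d"`, or `"none"` for the pure f/d
#'   conversion without any sample-size computation.
#' @param correction `"normal"` (default) or `"t"` for the small-sample
#'   iteration.
#' @return list with `cohens_f`, `cohens_d`, `alpha`, `power`,
#'   `n_per_group`.
#' @export
power_two_group <- function(cohens_f = NULL, cohens_d = NULL, alpha = 0.05,
                            power = 0.90, n_per_group = NULL,
                            solve_for = c("n", "d", "none"),
                            correction = c("normal", "t")) {
  solve_for <- match.arg(solve_for)
  correction <- match.arg(correction)
  if (is.null(cohens_d) && !is.null(cohens_f)) {
    if (cohens_f < 0) stop("cohens_f must be >= 0")
    cohens_d <- 2 * cohens_f
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  if (solve_for == "n") {
    if (is.null(cohens_d)) stop("need cohens_d (or cohens_f) to solve for n")
    if (cohens_d == 0) stop("d = 0 implies infinite sample size")
    n <- 2 * (za + zb)^2 / cohens_d^2
    if (correction == "t") {
      for (i in 1:10) {
        df <- max(2, 2 * ceiling(n) - 2)
        n <- 2 * (stats::qt(1 - alpha / 2, df) + stats::qt(power, df))^2 /
          cohens_d^2
      }
    }
    n_per_group <- ceiling(n)
  } else if (solve_for == "d") {
    if (is.null(n_per_group) || n_per_group <= 0) {
      stop("need a positive n_per_group to solve for d")
    }
    cohens_d <- sqrt(2 / n_per_group) * (za + zb)
    cohens_f <- cohens_d / 2
  }
  if (is.null(cohens_f)) cohens_f <- cohens_d / 2
  list(cohens_f = cohens_f, cohens_d = cohens_d, alpha = alpha,
       power = power, n_per_group = n_per_group)
}
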
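# Moment-calibrated synthetic cohorts.
#
# The generator emulates the four study groups (Control n=50; atherosclerosis
# on atorvastatin n=19, on rosuvastatin n=21, without statins n=12) using the
# published per-group means and SDs of eight analytes (mol%) and six indices.
# Two simulation scales are kept deliberately separate:
#   * analyte scale: marginals moment-matched per analyte (lognormal by
#     default, truncated normal as a sensitivity option), coupled through a
#     Gaussian copula; a synthetic "other" analyte absorbs the remainder so
#     each profile is a valid molar composition summing to 100;
#   * index scale: index values drawn directly from the published index
#     moments (used for single-marker simulations, which then need no
#     correlation assumption).

fa_groups <- c("Control", "Atorvastatin", "Rosuvastatin", "NoStatin")

#' Default per-group generative specifications
#'
#' One spec per study group carrying the published analyte moments (molar
#' percent, mean and SD) for C18:0, C18:1n-9, C20:3n-6, C20:4n-6, C22:4n-6,
#' DPA, EPA and DHA, the published index moments for omega3_status, aa_epa,
#' omega6_3, c18_ratio, aa_ada and o63bi, and the group sizes 50/19/21/12.
#'
#' The default analyte correlation (Gaussian-copula scale) is 0.3 within
#' pathway blocks (SFA/MUFA: C18:0 + C18:1n-9; omega-6: C20:3n-6, C20:4n-6,
#' C22:4n-6; omega-3: EPA, DPA, DHA) and 0 across blocks - correlations are
#' not published, so this is a documented assumption, overridable via the
#' `correlation` field.
#'
#' @return a named list of group specs; each spec is a list with `label`,
#'   `n`, `analyte_moments` (data.frame `analyte, mean, sd`),
#'   `index_moments` (data.frame `index, mean, sd`) and `correlation`.
#' @export
default_specs <- function() {
  analytes <- c("C18:0", "C18:1n-9", "C20:3n-6", "C20:4n-6", "C22:4n-6",
                "C22:5n-3", "C20:5n-3", "C22:6n-3")
  am <- list(
    Control      = cbind(mean = c(9.27, 23.13, 1.31, 7.53, 0.17, 0.38, 0.59, 1.97),
                         sd   = c(1.83,  3.38, 0.31, 1.99, 0.06, 0.10, 0.32, 0.68)),
    Atorvastatin = cbind(mean = c(7.42, 27.33, 1.18, 6.56, 0.19, 0.39, 0.49, 1.84),
                         sd   = c(0.93,  2.75, 0.41, 1.49, 0.06, 0.12, 0.26, 0.48)),
    Rosuvastatin = cbind(mean = c(7.45, 28.49, 1.15, 6.19, 0.17, 0.34, 0.45, 1.77),
                         sd   = c(0.96,  3.49, 0.29, 1.79, 0.04, 0.07, 0.21, 0.39)),
    NoStatin     = cbind(mean = c(7.45, 28.01, 1.20, 6.67, 0.19, 0.32, 0.41, 1.66),
                         sd   = c(1.01,  3.66, 0.35, 1.61, 0.05, 0.06, 0.19, 0.34))
  )
  idx <- c("omega3_status", "aa_epa", "omega6_3", "c18_ratio", "aa_ada",
           "o63bi")
  im <- list(
    Control      = cbind(mean = c(2.70, 13.80, 11.63, 0.42, 45.14, 12.00),
                         sd   = c(1.07,  7.92,  4.57, 0.13, 12.84,  4.94)),
    Atorvastatin = cbind(mean = c(2.33, 15.47, 13.23, 0.28, 36.05,  8.35),
                         sd   = c(0.71,  8.01,  4.94, 0.05,  5.46,  2.56)),
    Rosuvastatin = cbind(mean = c(2.22, 16.14, 12.90, 0.27, 37.39,  7.91),
                         sd   = c(0.50,  7.49,  2.86, 0.06,  8.64,  2.05)),
    NoStatin     = cbind(mean = c(2.06, 19.36, 14.05, 0.27, 37.01,  8.13),
                         sd   = c(0.50,  7.99,  2.60, 0.07,  9.46,  3.32))
  )
  ns <- c(Control = 50L, Atorvastatin = 19L, Rosuvastatin = 21L,
          NoStatin = 12L)
  blocks <- list(c("C18:0", "C18:1n-9"),
                 c("C20:3n-6", "C20:4n-6", "C22:4n-6"),
                 c("C20:5n-3", "C22:5n-3", "C22:6n-3"))
  corr <- diag(length(analytes))
  dimnames(corr) <- list(analytes, analytes)
  for (blk in blocks) {
    corr[blk, blk] <- 0.3
    diag(corr)[] <- 1
  }
  out <- lapply(fa_groups, function(g) {
    list(label = g, n = ns[[g]],
         analyte_moments = data.frame(analyte = analytes, am[[g]],
                                      stringsAsFactors = FALSE),
         index_moments = data.frame(index = idx, im[[g]],
                                    stringsAsFactors = FALSE),
         correlation = corr)
  })
  names(out) <- fa_groups
  out
}

# Moment-matched marginal sampler on the copula scale: z is N(0,1); returns
# draws with the requested mean and sd.
.marginal_from_z <- function(z, mean, sd, distribution) {
  if (sd == 0) return(rep(mean, length(z)))
  if (distribution == "lognormal_moment_matched") {
    s2 <- log(1 + (sd / mean)^2)
    mu <- log(mean) - s2 / 2
    exp(mu + sqrt(s2) * z)
  } else { # truncated_normal: normal draws, negatives resampled (see note)
    x <- mean + sd * z
    while (any(x <= 0)) {
      x[x <= 0] <- mean + sd * stats::rnorm(sum(x <= 0))
    }
    x
  }
}

#' Generate an analyte-scale synthetic cohort
#'
#' Per group, draws analyte molar-percent vectors whose marginals are
#' moment-matched to the spec's (mean, sd) - exactly so for the lognormal
#' family (closed-form moment match), approximately for `truncated_normal`
#' (negative draws are resampled, which biases moments upward by a few
#' per-mille at the panel's mean/sd ratios) - coupled through a Gaussian
#' copula with the spec's correlation matrix. A synthetic `other` analyte
#' absorbs `100 - sum(drawn analytes)` so every row is a valid molar
#' composition.
#'
#' @param specs list of group specs (see [default_specs()]).
#' @param seed integer seed; fully determines the output.
#' @param distribution `"lognormal_moment_matched"` (default) or
#'   `"truncated_normal"`.
#' @param n_override optional named integer vector overriding group sizes.
#' @param other_name column name for the absorbing remainder analyte.
#' @return an `fa_molar` data.frame `sample_id, group, <analytes...>, other`.
#' @export
generate_cohort <- function(specs = default_specs(), seed,
                            distribution = c("lognormal_moment_matched",
                                             "truncated_normal"),
                            n_override = NULL, other_name = "other") {
  distribution <- match.arg(distribution)
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  rows <- lapply(specs, function(sp) {
    n <- if (!is.null(n_override) && sp$label %in% names(n_override)) {
      n_override[[sp$label]]
    } else sp$n
    m <- sp$analyte_moments
    corr <- sp$correlation[m$analyte, m$analyte, drop = FALSE]
    ch <- tryCatch(chol(corr),
                   error = function(e) stop("correlation matrix for group '",
                                            sp$label,
                                            "' is not positive definite"))
    z <- matrix(stats::rnorm(n * nrow(m)), nrow = n) %*% ch
    draws <- vapply(seq_len(nrow(m)), function(j) {
      .marginal_from_z(z[, j], m$mean[j], m$sd[j], distribution)
    }, numeric(n))
    draws <- matrix(draws, nrow = n,
                    dimnames = list(NULL, m$analyte))
    other <- 100 - rowSums(draws)
    if (any(other <= 0)) {
      stop("drawn analytes exceed 100 mol% for group '", sp$label,
           "'; moments are implausible")
    }
    df <- data.frame(sample_id = sprintf("%s_%03d", sp$label, seq_len(n)),
                     group = sp$label, stringsAsFactors = FALSE,
                     check.names = FALSE)
    df[colnames(draws)] <- as.data.frame(draws, check.names = FALSE)
    df[[other_name]] <- other
    df
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("fa_molar", "data.frame")
  out
}

#' Generate an index-scale synthetic cohort
#'
#' Draws index values directly from the per-group index moments -
#' independent Gaussian marginals by default (the mode used by the
#' acceptance simulations), or moment-matched lognormal. No correlation
#' assumption is involved; single-marker analyses depend only on the
#' marginals.
#'
#' @param specs list of group specs (see [default_specs()]).
#' @param n_per_group single integer or named vector of draws per group
#'   (defaults to the spec group sizes).
#' @param indices which indices to draw (default: all in the specs).
#' @param distribution `"gaussian"` (default) or
#'   `"lognormal_moment_matched"`.
#' @param seed integer seed.
#' @return data.frame `sample_id, group, <indices...>`.
#' @export
generate_index_cohort <- function(specs = default_specs(),
                                  n_per_group = NULL, indices = NULL,
                                  distribution = c("gaussian",
                                                   "lognormal_moment_matched"),
                                  seed) {
  distribution <- match.arg(distribution)
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  rows <- lapply(specs, function(sp) {
    n <- if (is.null(n_per_group)) {
      sp$n
    } else if (!is.null(names(n_per_group))) {
      n_per_group[[sp$label]]
    } else n_per_group
    m <- sp$index_moments
    if (!is.null(indices)) {
      missing_idx <- setdiff(indices, m$index)
      if (length(missing_idx)) {
        stop("no moments for index(es): ",
             paste(missing_idx, collapse = ", "))
      }
      m <- m[m$index %in% indices, , drop = FALSE]
    }
    draws <- vapply(seq_len(nrow(m)), function(j) {
      z <- stats::rnorm(n)
      if (distribution == "gaussian") {
        m$mean[j] + m$sd[j] * z
      } else {
        .marginal_from_z(z, m$mean[j], m$sd[j], "lognormal_moment_matched")
      }
    }, numeric(n))
    draws <- matrix(draws, nrow = n, dimnames = list(NULL, m$index))
    df <- data.frame(sample_id = sprintf("%s_%05d", sp$label, seq_len(n)),
                     group = sp$label, stringsAsFactors = FALSE,
                     check.names = FALSE)
    df[colnames(draws)] <- as.data.frame(draws, check.names = FALSE)
    df
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pool the atherosclerosis subgroups
#'
#' Relabels the three atherosclerosis subgroups as one pooled group. For
#' simulation, subgroup membership is drawn with probabilities 19/21/12
#' over 52, matching the study composition.
#'
#' @param n number of pooled draws.
#' @param specs group specs.
#' @return character vector of subgroup labels of length `n`.
#' @export
sample_as_subgroups <- function(n, specs = default_specs()) {
  subs <- setdiff(names(specs), "Control")
  w <- vapply(specs[subs], function(sp) sp$n, numeric(1))
  sample(subs, n, replace = TRUE, prob = w / sum(w))
}

#' Extend a panel with the synthetic remainder analyte
#'
#' Appends the absorbing `other` analyte (nominal molecular weight) to a
#' panel so that cohorts from [generate_cohort()] round-trip through
#' [to_concentrations()] and [to_molar_percent()].
#'
#' @param panel an `fa_panel`.
#' @param name name of the remainder analyte.
#' @param mw nominal molecular weight (g/mol).
#' @return the extended `fa_panel`.
#' @export
panel_with_other <- function(panel = default_panel(), name = "other",
                             mw = 270) {
  extra <- data.frame(name = name, lipid_class = "MUFA",
                      molecular_weight = mw, loq = NA_real_,
                      stringsAsFactors = FALSE)
  validate_panel(rbind(as.data.frame(panel), extra))
}

#' Back-convert molar profiles to concentration profiles
#'
#' Draws a per-sample total molar pool (nmol/mL) from a truncated-normal
#' total and converts each analyte's molar percent to ng/mL through its
#' molecular weight, so that [to_molar_percent()] recovers the input
#' composition exactly. Non-positive total draws are resampled (truncation),
#' with a warning.
#'
#' @param cohort an `fa_molar` cohort.
#' @param panel an `fa_panel`; analytes absent from it (e.g. the synthetic
#'   `other` column) get the nominal molecular weight `other_mw`.
#' @param total_nmol `c(mean, sd)` of the per-sample total molar pool in
#'   nmol/mL. The default (11000, 2200) corresponds to roughly 3 mg/mL total
#'   plasma fatty acids, a typical fasting total.
#' @param other_mw molecular weight assigned to unknown analytes (g/mol).
#' @param seed integer seed.
#' @return a wide concentration cohort (ng/mL).
#' @export
to_concentrations <- function(cohort, panel = default_panel(),
                              total_nmol = c(11000, 2200), other_mw = 270,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  analytes <- setdiff(names(cohort), c("sample_id", "group"))
  mw <- panel$molecular_weight[match(analytes, panel$name)]
  mw[is.na(mw)] <- other_mw
  n <- nrow(cohort)
  totals <- stats::rnorm(n, total_nmol[1], total_nmol[2])
  if (any(totals <= 0)) {
    warning("resampling ", sum(totals <= 0), " non-positive total draw(s)")
    while (any(totals <= 0)) {
      totals[totals <= 0] <- stats::rnorm(sum(totals <= 0), total_nmol[1],
                                          total_nmol[2])
    }
  }
  pct <- as.matrix(cohort[, analytes, drop = FALSE])
  conc <- sweep(pct / 100, 1, totals, "*")
  conc <- sweep(conc, 2, mw, "*")
  out <- data.frame(sample_id = cohort$sample_id, group = cohort$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[analytes] <- as.data.frame(conc, check.names = FALSE)
  out
}
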
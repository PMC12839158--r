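# Per-sample lipidomic indices computed from molar-percent profiles.
#
# All indices are ratios of molar percentages, hence invariant to uniform
# scaling of the underlying concentrations (degree-0 homogeneous in the
# composition). They are computed per sample and averaged afterwards:
# a mean of per-sample ratios is not the ratio of means.

#' Names of the ten built-in per-sample indices
#' @format character vector of length 10.
#' @export
fa_index_names <- c("omega3_status", "aa_epa", "omega6_3", "c18_ratio",
                    "aa_ada", "dgla_aa", "epa_dpa", "epa_dha", "dpa_dha",
                    "o63bi")

# Extract analyte values from either a named numeric vector (one sample) or
# an fa_molar cohort (vectorized over rows). Errors name the analyte.
.fa_get <- function(p, analyte, context, allow_zero = TRUE) {
  if (is.data.frame(p)) {
    if (!analyte %in% names(p)) {
      stop("analyte '", analyte, "' required for ", context,
           " is absent from the profile")
    }
    v <- p[[analyte]]
  } else {
    if (!analyte %in% names(p)) {
      stop("analyte '", analyte, "' required for ", context,
           " is absent from the profile")
    }
    v <- unname(p[[analyte]])
  }
  if (any(is.na(v))) {
    stop("analyte '", analyte, "' is below LOQ (missing) for ", context)
  }
  if (!allow_zero && any(v <= 0)) {
    stop("analyte '", analyte, "' must be > 0 for ", context)
  }
  v
}

#' Omega-3 Status (EPA + DHA)
#'
#' Sum of EPA (C20:5n-3) and DHA (C22:6n-3) in molar percent of total
#' quantified plasma fatty acids. This is the plasma analogue of the
#' erythrocyte Omega-3 Index, computed on plasma composition instead of RBC
#' membranes.
#'
#' @param p a named numeric vector of molar percentages (one sample) or an
#'   `fa_molar` cohort (vectorized over samples).
#' @return numeric, mol%.
#' @export
omega3_status <- function(p) {
  .fa_get(p, "C20:5n-3", "omega3_status") +
    .fa_get(p, "C22:6n-3", "omega3_status")
}

#' Omega-6/omega-3 ratio
#'
#' Sum of the six n-6 PUFAs (C18:2n-6, C18:3n-6, C20:2n-6, C20:3n-6,
#' C20:4n-6, C22:4n-6) divided by the sum of the three n-3 PUFAs (EPA, DPA,
#' DHA).
#'
#' @inheritParams omega3_status
#' @return numeric ratio (dimensionless).
#' @export
omega6_3_ratio <- function(p) {
  sets <- pufa_sets()
  num <- Reduce(`+`, lapply(sets$n6, .fa_get, p = p, context = "omega6_3"))
  den <- Reduce(`+`, lapply(sets$n3, .fa_get, p = p, context = "omega6_3"))
  if (any(den <= 0)) stop("omega6_3: n-3 PUFA sum must be > 0")
  num / den
}

#' Pairwise analyte ratio
#'
#' `mol%(numerator) / mol%(denominator)`. Used for AA/EPA, C18:0/C18:1n-9,
#' AA/AdA (C20:4n-6/C22:4n-6), DGLA/AA (C20:3n-6/C20:4n-6), EPA/DPA, EPA/DHA
#' and DPA/DHA.
#'
#' @inheritParams omega3_status
#' @param numerator,denominator analyte names.
#' @return numeric ratio.
#' @export
pairwise_ratio <- function(p, numerator, denominator) {
  ctx <- paste0(numerator, "/", denominator)
  num <- .fa_get(p, numerator, ctx)
  den <- .fa_get(p, denominator, ctx)
  if (any(den <= 0)) stop(ctx, ": denominator must be > 0")
  num / den
}

#' Omega-6/3 Balance Index
#'
#' Composite index over the long-chain PUFA pathway:
#' \deqn{O6/3\text{-}BI = \frac{AA \times \sqrt{EPA \times DPA}}{AdA \times DHA}}
#' with AA = C20:4n-6, AdA = C22:4n-6, EPA = C20:5n-3, DPA = C22:5n-3,
#' DHA = C22:6n-3 (all molar percent). It combines the omega-6 elongation
#' ratio AA/AdA with omega-3 progression towards DHA, using the geometric
#' mean of EPA and DPA to damp the short-term variability of plasma EPA.
#' Lower values indicate the impaired long-chain PUFA inter-conversion seen
#' in atherosclerosis.
#'
#' @inheritParams omega3_status
#' @return numeric, positive; scale-invariant in the profile.
#' @export
o63_balance_index <- function(p) {
  aa  <- .fa_get(p, "C20:4n-6", "o63bi", allow_zero = FALSE)
  ada <- .fa_get(p, "C22:4n-6", "o63bi", allow_zero = FALSE)
  epa <- .fa_get(p, "C20:5n-3", "o63bi", allow_zero = FALSE)
  dpa <- .fa_get(p, "C22:5n-3", "o63bi", allow_zero = FALSE)
  dha <- .fa_get(p, "C22:6n-3", "o63bi", allow_zero = FALSE)
  aa * sqrt(epa * dpa) / (ada * dha)
}

# index name -> function(p)
.fa_index_funs <- function() {
  list(
    omega3_status = omega3_status,
    aa_epa   = function(p) pairwise_ratio(p, "C20:4n-6", "C20:5n-3"),
    omega6_3 = omega6_3_ratio,
    c18_ratio = function(p) pairwise_ratio(p, "C18:0", "C18:1n-9"),
    aa_ada   = function(p) pairwise_ratio(p, "C20:4n-6", "C22:4n-6"),
    dgla_aa  = function(p) pairwise_ratio(p, "C20:3n-6", "C20:4n-6"),
    epa_dpa  = function(p) pairwise_ratio(p, "C20:5n-3", "C22:5n-3"),
    epa_dha  = function(p) pairwise_ratio(p, "C20:5n-3", "C22:6n-3"),
    dpa_dha  = function(p) pairwise_ratio(p, "C22:5n-3", "C22:6n-3"),
    o63bi    = o63_balance_index
  )
}

#' Compute the full index set per sample
#'
#' Applies every requested index to each sample of a molar-percent cohort.
#' Each column of the result equals the corresponding standalone index
#' function applied to the same profiles. Errors from missing analytes are
#' re-raised with the index name attached.
#'
#' @param p an `fa_molar` cohort data.frame, or a named numeric vector for a
#'   single sample.
#' @param indices character vector of index names to compute (default all
#'   ten: omega3_status, aa_epa, omega6_3, c18_ratio, aa_ada, dgla_aa,
#'   epa_dpa, epa_dha, dpa_dha, o63bi).
#' @return a data.frame `sample_id, group, <indices...>` (or a named numeric
#'   vector for a single-sample input).
#' @export
compute_index_set <- function(p, indices = fa_index_names) {
  bad <- setdiff(indices, fa_index_names)
  if (length(bad)) stop("unknown index name(s): ", paste(bad, collapse = ", "))
  funs <- .fa_index_funs()[indices]
  vals <- lapply(names(funs), function(nm) {
    tryCatch(funs[[nm]](p),
             error = function(e) stop("index '", nm, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(vals) <- names(funs)
  if (is.data.frame(p)) {
    out <- data.frame(sample_id = p$sample_id, group = p$group,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out[names(vals)] <- vals
    out
  } else {
    unlist(vals)
  }
}
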
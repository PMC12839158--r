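# Analyte panel: the 24-analyte plasma fatty-acid panel with lipid-class
# assignment, average molecular weights of the free (non-esterified) acids,
# and optional per-analyte lower limits of quantification (LOQ).

#' Default fatty-acid analyte panel
#'
#' Returns the built-in 24-analyte panel: saturated (C12:0, C14:0, C16:0,
#' C17:0, C18:0, C20:0, C22:0, C24:0), monounsaturated omega-7/omega-9
#' (C16:1n-7, C18:1n-9, C20:1n-9, C24:1n-9), trans (C16:1n-7t, C18:1n-9t,
#' C18:2n-6t), omega-6 (C18:2n-6, C18:3n-6, C20:2n-6, C20:3n-6, C20:4n-6,
#' C22:4n-6) and omega-3 (C20:5n-3 EPA, C22:5n-3 DPA, C22:6n-3 DHA) species.
#'
#' Molecular weights are average masses (g/mol) of the free fatty acids; they
#' can be overridden by supplying a custom panel file to [read_panel()].
#' Within-sample molar ratios are only weakly sensitive to the MW convention
#' (free acid vs methyl ester) because every analyte shifts in the same
#' direction.
#'
#' @param loq optional named numeric vector of LOQ values (ng/mL); names must
#'   be panel analyte names. Analytes not named get `NA` (no LOQ applied).
#' @return A `data.frame` of class `fa_panel` with columns `name`,
#'   `lipid_class` (one of `"SFA"`, `"MUFA"`, `"PUFA-n3"`, `"PUFA-n6"`,
#'   `"TRANS"`), `molecular_weight` (g/mol) and `loq` (ng/mL or `NA`).
#' @examples
#' p <- default_panel()
#' subset(p, lipid_class == "PUFA-n3")
#' @export
default_panel <- function(loq = NULL) {
  panel <- data.frame(
    name = c(
      "C12:0", "C14:0", "C16:0", "C17:0", "C18:0", "C20:0", "C22:0", "C24:0",
      "C16:1n-7", "C18:1n-9", "C20:1n-9", "C24:1n-9",
      "C16:1n-7t", "C18:1n-9t", "C18:2n-6t",
      "C18:2n-6", "C18:3n-6", "C20:2n-6", "C20:3n-6", "C20:4n-6", "C22:4n-6",
      "C20:5n-3", "C22:5n-3", "C22:6n-3"
    ),
    lipid_class = c(
      rep("SFA", 8),
      rep("MUFA", 4),
      rep("TRANS", 3),
      rep("PUFA-n6", 6),
      rep("PUFA-n3", 3)
    ),
    molecular_weight = c(
      200.32, 228.37, 256.42, 270.45, 284.48, 312.53, 340.58, 368.63,
      254.41, 282.46, 310.51, 366.62,
      254.41, 282.46, 280.45,
      280.45, 278.43, 308.50, 306.48, 304.47, 332.52,
      302.45, 330.50, 328.49
    ),
    loq = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(loq)) {
    bad <- setdiff(names(loq), panel$name)
    if (length(bad)) {
      stop("LOQ given for analytes not in the panel: ",
           paste(bad, collapse = ", "))
    }
    panel$loq[match(names(loq), panel$name)] <- as.numeric(loq)
  }
  validate_panel(panel)
}

#' Validate an analyte panel
#'
#' Checks panel invariants: unique analyte names, positive molecular weights,
#' non-negative (or missing) LOQ values and a known lipid class for every
#' analyte.
#'
#' @param panel a data.frame with columns `name`, `lipid_class`,
#'   `molecular_weight`, `loq`.
#' @return the panel, classed `fa_panel`, invisibly usable downstream.
#' @export
validate_panel <- function(panel) {
  required <- c("name", "lipid_class", "molecular_weight", "loq")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$name)) {
    stop("panel analyte names must be unique")
  }
  if (!all(is.finite(panel$molecular_weight)) ||
      any(panel$molecular_weight <= 0)) {
    stop("panel molecular weights must be positive and finite")
  }
  if (any(!is.na(panel$loq) & panel$loq < 0)) {
    stop("panel LOQ values must be non-negative")
  }
  classes <- c("SFA", "MUFA", "PUFA-n3", "PUFA-n6", "TRANS")
  if (!all(panel$lipid_class %in% classes)) {
    stop("unknown lipid_class; must be one of ",
         paste(classes, collapse = ", "))
  }
  class(panel) <- c("fa_panel", "data.frame")
  panel
}

#' Read an analyte panel from a TSV file
#'
#' The file must be tab-separated with header
#' `name  lipid_class  molecular_weight  loq`; an empty or `NA` loq cell means
#' no LOQ is applied for that analyte.
#'
#' @param path path to the TSV panel file.
#' @return an `fa_panel` data.frame (see [default_panel()]).
#' @export
read_panel <- function(path) {
  panel <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  panel$molecular_weight <- as.numeric(panel$molecular_weight)
  panel$loq <- suppressWarnings(as.numeric(panel$loq))
  validate_panel(panel)
}

#' Write an analyte panel to a TSV file
#'
#' @param panel an `fa_panel` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Canonical shorthand used throughout the index definitions.
fa_aliases <- c(
  AA  = "C20:4n-6",
  AdA = "C22:4n-6",
  EPA = "C20:5n-3",
  DPA = "C22:5n-3",
  DHA = "C22:6n-3"
)

#' Omega-6 and omega-3 analyte sets used by the omega-6/3 ratio
#'
#' The omega-6/3 ratio numerator is the six-analyte n-6 set (C18:2n-6,
#' C18:3n-6, C20:2n-6, C20:3n-6, C20:4n-6, C22:4n-6); the denominator is the
#' three-analyte n-3 set (EPA, DPA, DHA). Trans isomers are excluded.
#'
#' @return a list with character vectors `n6` and `n3`.
#' @export
pufa_sets <- function() {
  list(
    n6 = c("C18:2n-6", "C18:3n-6", "C20:2n-6", "C20:3n-6",
           "C20:4n-6", "C22:4n-6"),
    n3 = c("C20:5n-3", "C22:5n-3", "C22:6n-3")
  )
}
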
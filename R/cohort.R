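# Cohort I/O and molar-percent conversion.
#
# A cohort is a wide data.frame: one row per sample, columns `sample_id`,
# `group`, then one column per analyte. Concentrations are ng/mL;
# molar-percent tables carry the class "fa_molar". A below-LOQ measurement is
# stored as NA: it is excluded from the molar total, never treated as zero.

#' Read a cohort table from CSV
#'
#' Wide CSV with header `sample_id,group,<analyte>,...`. Below-LOQ values may
#' be encoded as an empty cell or as the sentinel token (default `"<LOQ"`);
#' both parse to `NA`. If the panel carries per-analyte LOQ values, any
#' numeric cell strictly below its LOQ is also marked below-LOQ.
#'
#' @param path CSV file path.
#' @param panel an `fa_panel`; every analyte column must appear in the panel.
#' @param units `"ng_per_ml"` for concentrations (the default) or
#'   `"mol_percent"` for an already converted table.
#' @param sentinel token marking a below-LOQ cell (in addition to empty cells).
#' @return a data.frame with `sample_id`, `group` and one numeric column per
#'   analyte; classed `fa_molar` when `units = "mol_percent"`.
#' @export
read_cohort <- function(path, panel = default_panel(),
                        units = c("ng_per_ml", "mol_percent"),
                        sentinel = "<LOQ") {
  units <- match.arg(units)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("sample_id", "group")) {
    if (!col %in% names(raw)) {
      stop("cohort file ", path, " is missing mandatory column '", col, "'")
    }
  }
  analytes <- setdiff(names(raw), c("sample_id", "group"))
  unknown <- setdiff(analytes, panel$name)
  if (length(unknown)) {
    stop("cohort analyte(s) not present in the panel: ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(sample_id = raw$sample_id, group = raw$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (a in analytes) {
    cell <- trimws(raw[[a]])
    is_loq <- cell == "" | cell == sentinel | is.na(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_loq & is.na(val)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   cell[which(bad)[1]], which(bad)[1], a, path))
    }
    val[is_loq] <- NA_real_
    if (units == "ng_per_ml") {
      loq <- panel$loq[match(a, panel$name)]
      if (!is.na(loq)) val[!is.na(val) & val < loq] <- NA_real_
    }
    if (any(!is.na(val) & val < 0)) {
      stop("negative value in column '", a, "' of ", path)
    }
    out[[a]] <- val
  }
  if (units == "mol_percent") class(out) <- c("fa_molar", "data.frame")
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `NA` cells are written as the below-LOQ
#' sentinel so a write/read cycle round-trips.
#'
#' @param cohort wide cohort data.frame.
#' @param path output CSV path.
#' @param sentinel token to write for below-LOQ (`NA`) cells.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sentinel = "<LOQ") {
  out <- as.data.frame(cohort, check.names = FALSE)
  class(out) <- "data.frame"
  for (a in setdiff(names(out), c("sample_id", "group"))) {
    col <- format(out[[a]], trim = TRUE, scientific = FALSE, digits = 15)
    col[is.na(out[[a]])] <- sentinel
    out[[a]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert concentration profiles to molar-percent profiles
#'
#' Each analyte concentration (ng/mL) is divided by its molecular weight to a
#' molar amount; each quantified analyte is then expressed as its molar
#' amount divided by the per-sample total of quantified analytes, times 100.
#' Below-LOQ analytes (`NA`) are excluded from the total and stay `NA` in the
#' output (they are never imputed as zero).
#'
#' @param cohort wide concentration cohort (see [read_cohort()]).
#' @param panel an `fa_panel` supplying molecular weights; every analyte
#'   column of `cohort` must be present.
#' @return an `fa_molar` data.frame; each row's non-`NA` analyte values sum
#'   to 100.
#' @examples
#' panel <- default_panel()
#' x <- data.frame(sample_id = "s1", group = "Control",
#'                 `C18:0` = 284.48, `C18:1n-9` = 282.46,
#'                 check.names = FALSE)
#' to_molar_percent(x, panel)  # 50 / 50: both are 1 nmol/mL
#' @export
to_molar_percent <- function(cohort, panel = default_panel()) {
  analytes <- setdiff(names(cohort), c("sample_id", "group"))
  if (!length(analytes)) stop("cohort has no analyte columns")
  unknown <- setdiff(analytes, panel$name)
  if (length(unknown)) {
    stop("analyte(s) not present in the panel: ",
         paste(unknown, collapse = ", "))
  }
  mw <- panel$molecular_weight[match(analytes, panel$name)]
  conc <- as.matrix(cohort[, analytes, drop = FALSE])
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  moles <- sweep(conc, 2, mw, "/")
  totals <- rowSums(moles, na.rm = TRUE)
  if (any(totals <= 0 | rowSums(!is.na(moles)) == 0)) {
    stop("sample(s) with no quantified analyte above zero: ",
         paste(cohort$sample_id[totals <= 0], collapse = ", "))
  }
  pct <- sweep(moles, 1, totals, "/") * 100
  out <- data.frame(sample_id = cohort$sample_id, group = cohort$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[analytes] <- as.data.frame(pct, check.names = FALSE)
  class(out) <- c("fa_molar", "data.frame")
  out
}
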
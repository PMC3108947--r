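# CSV round trip for cohort tables, with invariant validation on read.

#' Validate a cohort table
#'
#' Checks the analysis invariants: unique ids, strictly positive follow-up
#' times, binary status indicators, and no missing values in any analysis
#' column (the analysis is complete-case). Violations are reported with the
#' offending row numbers.
#'
#' @param cohort data.frame.
#' @param endpoints endpoint labels; defaults to those found in the columns.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort, endpoints = NULL) {
  if (is.null(endpoints)) {
    endpoints <- union(
      sub("^time_", "", grep("^time_", names(cohort), value = TRUE)),
      sub("^status_", "", grep("^status_", names(cohort), value = TRUE)))
  }
  problems <- character(0)
  if (!"id" %in% names(cohort)) problems <- c(problems, "missing column: id")
  for (ep in endpoints) {
    for (col in paste0(c("time_", "status_"), ep)) {
      if (!col %in% names(cohort))
        problems <- c(problems, paste0("missing column: ", col))
    }
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))

  if (anyDuplicated(cohort$id))
    problems <- c(problems, paste0("duplicate ids at rows: ",
      paste(utils::head(which(duplicated(cohort$id)), 5), collapse = ", ")))
  for (ep in endpoints) {
    tm <- cohort[[paste0("time_", ep)]]
    st <- cohort[[paste0("status_", ep)]]
    if (!is.numeric(tm))
      problems <- c(problems, paste0("time_", ep, " is not numeric"))
    else {
      bad <- which(!is.finite(tm) | tm <= 0)
      if (length(bad))
        problems <- c(problems, paste0("time_", ep, " <= 0 or missing at rows: ",
                                       paste(utils::head(bad, 5), collapse = ", ")))
    }
    bad <- which(!(st %in% c(0, 1)))
    if (length(bad))
      problems <- c(problems, paste0("status_", ep, " not in {0,1} at rows: ",
                                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  for (col in num_cols) {
    bad <- which(is.na(cohort[[col]]))
    if (length(bad))
      problems <- c(problems, paste0("missing values in ", col, " at rows: ",
                                     paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' One row per subject, header row, UTF-8, "." decimal separator. The round
#' trip through [read_cohort()] is lossless for all analysis columns.
#'
#' @param cohort cohort data.frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Restores canonical factor level orderings (reference level first:
#' never/none/no/low/female) for the standard categorical columns, keeps any
#' extra columns untouched, and validates the analysis invariants reporting
#' the row numbers of violations.
#'
#' @param path CSV file path.
#' @param validate run [validate_cohort()] (default TRUE).
#' @return cohort data.frame of class `cch_cohort`.
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  lv <- canonical_levels()
  for (col in intersect(names(lv), names(out))) {
    vals <- unique(out[[col]])
    levels <- c(intersect(lv[[col]], vals), setdiff(vals, lv[[col]]))
    out[[col]] <- factor(out[[col]], levels = levels)
  }
  if ("survey" %in% names(out))
    out$survey <- factor(out$survey, levels = sort(unique(out$survey)))
  if (validate) validate_cohort(out)
  class(out) <- c("cch_cohort", "data.frame")
  bm <- intersect(default_biomarker_spec()$name, names(out))
  if (length(bm)) attr(out, "biomarkers") <- bm
  attr(out, "endpoints") <- sub("^time_", "", grep("^time_", names(out), value = TRUE))
  out
}
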
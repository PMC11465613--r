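#' Write a validation report to JSON or CSV
#'
#' JSON is a lossless single-file serialisation (full double precision;
#' [read_report()] reproduces the report). CSV flattens each table —
#' `cells.csv`, `subgroups.csv`, `errors.csv`, `warnings.csv` — into a
#' directory, one row per cell with a stable column order and values at
#' full precision; conventional display rounding (C and E/O to 2
#' decimals, thresholds to 2, sensitivity/specificity to 1) is applied
#' by [format_report()], not by the files.
#'
#' @param report A `t2d_validation` from [run_validation()].
#' @param path Output file (json) or directory (csv).
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(report, "t2d_validation")) {
    abort("`report` must come from run_validation().")
  }
  if (format == "json") {
    payload <- list(
      cells = report$cells, subgroups = report$subgroups,
      errors = report$errors, warnings = report$warnings,
      meta = report$meta
    )
    jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "null", na = "null",
                         pretty = TRUE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (tab in c("cells", "subgroups", "errors", "warnings")) {
      df <- report[[tab]]
      readr::write_csv(if (nrow(df) == 0 && ncol(df) == 0) {
        tibble(empty = character())
      } else df, file.path(path, paste0(tab, ".csv")), na = "")
    }
  }
  invisible(path)
}

#' Read a JSON validation report back into a `t2d_validation`
#'
#' @param path JSON file written by [write_report()].
#' @return A `t2d_validation` object equal to the one written.
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    if (is.null(x) || length(x) == 0) return(tibble())
    as_tibble(lapply(x, function(col) {
      if (is.null(col) || length(col) == 0) return(character(0))
      if (is.list(col)) col <- unlist(lapply(col, function(v) v %||% NA))
      col
    }))
  }
  meta <- raw$meta
  # scalars were auto-unboxed on write; vectors survive as-is
  structure(
    list(
      cells = rebuild(raw$cells),
      subgroups = rebuild(raw$subgroups),
      errors = rebuild(raw$errors),
      warnings = rebuild(raw$warnings),
      meta = meta
    ),
    class = "t2d_validation"
  )
}

#' Display-rounded view of the validation cells
#'
#' Applies the conventional reporting precision — C-statistic and E/O
#' to two decimals, optimal thresholds to two, sensitivity and
#' specificity to one — while the underlying report keeps full
#' precision.
#'
#' @param report A `t2d_validation`.
#' @return A tibble of rounded cells.
#' @export
format_report <- function(report) {
  report$cells %>%
    mutate(
      across(c("eo", "eo_low", "eo_high", "c", "c_low", "c_high",
               "brier", "yates", "threshold", "threshold_top_left",
               "correction_factor"), ~ round(.x, 2)),
      across(c("sensitivity", "specificity"), ~ round(.x, 1))
    )
}
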
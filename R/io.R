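cohort_core_columns <- function() {
  c("id", "se_pre_D", "se_post_D", "vertex_mm", "oz_mm",
    "r1_pre_mm", "r1_post_mm", "r2_mm", "cct_pre_mm", "cct_post_mm",
    "pupil_dx_mm", "pupil_dy_mm")
}

#' Write a cohort table to CSV
#'
#' Writes the flat cohort schema with a `#`-prefixed provenance header
#' (package version, seed, config hash) so every output file carries its
#' provenance; [read_cohort_csv()] skips the header transparently.
#'
#' @param tbl Flat cohort table (see [cohort_to_table()]).
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(tbl, path) {
  prov <- sprintf("# keratrace %s | seed=%s | config_hash=%s",
                  as.character(utils::packageVersion("keratrace")),
                  attr(tbl, "seed") %||% "NA",
                  rlang::hash(attr(tbl, "cohort_config")))
  writeLines(prov, path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Reads the canonical cohort schema (locale-independent, dot decimal).
#' Lines starting with `#` are treated as provenance comments.  A missing
#' core column raises a schema error naming the first offender; unknown
#' extra columns are preserved with a warning.
#'
#' @param path CSV path.
#'
#' @return A tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file not found: %s", path), class = "keratrace_io_error")
  }
  tbl <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    locale = readr::locale(decimal_mark = ".")),
    error = function(e) {
      abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
            class = "keratrace_io_error")
    })
  if (nrow(tbl) == 0 && ncol(tbl) == 0) {
    abort(sprintf("empty cohort file: %s", path), class = "keratrace_io_error")
  }
  core <- cohort_core_columns()
  missing_core <- setdiff(core, names(tbl))
  if (length(missing_core) > 0) {
    abort(sprintf("cohort schema mismatch: missing column '%s'", missing_core[1]),
          class = "keratrace_io_error")
  }
  if (nrow(tbl) == 0) {
    abort(sprintf("empty cohort file: %s", path), class = "keratrace_io_error")
  }
  known <- c(core, paste0("pre_", keratometry_measures()),
             paste0("post_", keratometry_measures()))
  extra <- setdiff(names(tbl), known)
  if (length(extra) > 0) {
    warn(sprintf("unknown cohort column(s) preserved untouched: %s",
                 paste(extra, collapse = ", ")))
  }
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("parse error in %s at row %d, column %d",
                  path, prob$row[1], prob$col[1]),
          class = "keratrace_io_error")
  }
  tbl
}

#' Column mapping for external spreadsheet imports
#'
#' Maps the pipeline's canonical column names to the sheet/column labels
#' of an external workbook shaped like a per-eye data export.  Every
#' canonical core column must be mapped or explicitly marked absent with
#' `NA`.
#'
#' @param ... Named arguments `canonical_name = "external label"`; use
#'   `NA` to mark a canonical column as absent.
#'
#' @return A named list of class `column_mapping`.
#' @export
#'
#' @examples
#' column_mapping(id = "Patient", se_pre_D = "PreSE", se_post_D = "PostSE",
#'                vertex_mm = NA, oz_mm = "OZ", r1_pre_mm = "R1pre",
#'                r1_post_mm = "R1post", r2_mm = "R2", cct_pre_mm = "CCTpre",
#'                cct_post_mm = "CCTpost", pupil_dx_mm = NA, pupil_dy_mm = NA)
column_mapping <- function(...) {
  mp <- list(...)
  core <- cohort_core_columns()
  unmapped <- setdiff(core, names(mp))
  if (length(unmapped) > 0) {
    abort(sprintf(
      "every canonical column must be mapped or marked absent (NA); missing: %s",
      paste(unmapped, collapse = ", ")), class = "keratrace_mapping_error")
  }
  unknown <- setdiff(names(mp), c(core, paste0("pre_", keratometry_measures()),
                                  paste0("post_", keratometry_measures())))
  if (length(unknown) > 0) {
    abort(sprintf("unknown canonical column in mapping: %s", unknown[1]),
          class = "keratrace_mapping_error")
  }
  structure(mp, class = "column_mapping")
}

# rename external columns to canonical names; NA-mapped columns become NA
apply_column_mapping <- function(df, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  out <- tibble::tibble(.rows = nrow(df))
  for (canon in names(mapping)) {
    label <- mapping[[canon]]
    if (is.na(label)) {
      out[[canon]] <- NA_real_
    } else {
      if (!label %in% names(df)) {
        abort(sprintf("mapped column '%s' (for '%s') not found in the sheet",
                      label, canon), class = "keratrace_mapping_error")
      }
      v <- df[[label]]
      if (canon != "id" && is.character(v)) {
        warn(sprintf("column '%s' stored as text; parsing numerically", label))
        v <- readr::parse_double(v)
      }
      out[[canon]] <- v
    }
  }
  out
}

#' Read a cohort from an XLSX workbook via a column mapping
#'
#' Convenience import for externally measured per-eye tables stored as a
#' spreadsheet.  Requires the readxl package.
#'
#' @param path Workbook path.
#' @param mapping A [column_mapping()].
#' @param sheet Sheet name or index (default 1).
#'
#' @return A canonical cohort tibble (unmapped columns are NA).
#' @export
read_xlsx_cohort <- function(path, mapping, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("read_xlsx_cohort requires the readxl package",
          class = "keratrace_io_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("workbook not found: %s", path), class = "keratrace_io_error")
  }
  df <- tryCatch(readxl::read_excel(path, sheet = sheet),
                 error = function(e) {
                   abort(sprintf("failed to read sheet '%s' of %s: %s",
                                 as.character(sheet), path, conditionMessage(e)),
                         class = "keratrace_io_error")
                 })
  apply_column_mapping(df, mapping)
}

#' Reference summary statistics of the study cohort
#'
#' Printed cohort-level summary statistics of the post-SMILE study cohort
#' (n = 40) that the package's formula and bias arithmetic operate on:
#' `"table1"` gives the mean and SD of the four TCRP variants at 1-8 mm,
#' `"table2"` the cohort mean, SD and bias-vs-CHM of every keratometric
#' method.  These are inputs to the pipeline (benchmark arithmetic), not
#' outputs of it.
#'
#' @param which `"table1"` or `"table2"`.
#'
#' @return A tibble.
#' @export
#'
#' @examples
#' reference_summary("table2")
reference_summary <- function(which = c("table2", "table1")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("reference_", which, ".csv"),
                   package = "keratrace", mustWork = TRUE)
  readr::read_csv(f, comment = "#", show_col_types = FALSE)
}
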
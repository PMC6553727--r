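#' Default run configuration
#'
#' The single human-readable configuration driving the pipeline: the
#' cohort generator settings, the ray-sampling grid, the correction
#' formula constants, the io paths and the report layout.  Serializable
#' to/from YAML with [read_run_config()] / [write_run_config()]; unknown
#' keys in a config file are rejected with an error naming the key.
#'
#' @param cohort Named list of [cohort_config()] overrides.
#' @param formulas Named list of [formula_constants()] overrides.
#' @param io Named list: `output_dir`, `cohort_csv`.
#' @param report Named list: `diameters` (table-1 diameters) and
#'   `table2_diameters`.
#'
#' @return A named list of class `run_config`.
#' @export
run_config <- function(cohort = list(), formulas = list(), io = list(),
                       report = list()) {
  defaults <- list(
    cohort = as.list(formals(cohort_config))[
      setdiff(names(formals(cohort_config)), c("grid"))],
    formulas = as.list(formals(formula_constants)),
    io = list(output_dir = "keratrace-output", cohort_csv = "cohort.csv"),
    report = list(diameters = 1:8, table2_diameters = c(2, 4, 6),
                  grid = list(radial_step = 0.05, meridians = 256)))
  # formals hold unevaluated defaults; force them
  defaults$cohort <- lapply(defaults$cohort, function(x) eval(x, baseenv()))
  defaults$formulas <- lapply(defaults$formulas, function(x) eval(x, baseenv()))
  user <- list(cohort = cohort, formulas = formulas, io = io, report = report)
  cfg <- defaults
  for (section in names(user)) {
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key: %s.%s", section, unknown[1]),
            class = "keratrace_config_error")
    }
    cfg[[section]] <- modifyList(defaults[[section]], user[[section]])
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#'
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "keratrace_io_error")
  }
  raw <- yaml::read_yaml(path)
  known_sections <- c("cohort", "formulas", "io", "report")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key: %s", unknown[1]),
          class = "keratrace_config_error")
  }
  do.call(run_config, raw[intersect(names(raw), known_sections)])
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# materialize the cohort_config held in a run_config
as_cohort_config <- function(cfg) {
  args <- cfg$cohort
  args$grid <- cfg$report$grid
  do.call(cohort_config, args)
}
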
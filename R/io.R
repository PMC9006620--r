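scenario_to_list <- function(spec) {
  Filter(Negate(is.null), unclass(spec))
}

scenario_from_list <- function(lst) {
  do.call(scenario_spec, lst)
}

#' Write a field dataset to delimited text with a truth sidecar
#'
#' The table (columns `x`, `y`, the outcome and regressors) is written as
#' CSV or TSV; if the dataset carries simulation truth, it is serialized to a
#' JSON sidecar (`<path>.truth.json` by default) holding the true
#' coefficients, spatial flags, scenario parameters and seed.
#'
#' @param data A field dataset (e.g. from [simulate_observational()]).
#' @param path Output file; a `.tsv` extension selects tab separation.
#' @param truth_path Sidecar path, or `NA` to skip writing the truth.
#' @return `path`, invisibly.
#' @export
write_field_data <- function(data, path, truth_path = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  tr <- attr(data, "truth")
  if (!is.null(tr) && !isTRUE(is.na(truth_path))) {
    truth_path <- truth_path %||% paste0(path, ".truth.json")
    payload <- list(
      beta = tr$beta,
      spatial_flags = tr$spatial_flags,
      outcome_scenario = scenario_to_list(tr$outcome_scenario),
      regressor_scenario = scenario_to_list(tr$regressor_scenario),
      grid_size = tr$grid_size,
      design = tr$design,
      subplot_size = tr$subplot_size,
      seed = attr(data, "seed")
    )
    jsonlite::write_json(Filter(Negate(is.null), payload), truth_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a field dataset written by [write_field_data()]
#'
#' @param path CSV/TSV file with columns `x`, `y`, an outcome and regressors.
#' @param truth_path Optional truth sidecar; defaults to
#'   `<path>.truth.json` when that file exists.
#' @return A field dataset tibble, with truth re-attached when available.
#' @export
read_field_data <- function(path, truth_path = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE))
  truth_path <- truth_path %||% paste0(path, ".truth.json")
  if (file.exists(truth_path)) {
    raw <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(
      beta = as.numeric(raw$beta),
      spatial_flags = as.logical(raw$spatial_flags),
      outcome_scenario = scenario_from_list(raw$outcome_scenario),
      regressor_scenario = scenario_from_list(raw$regressor_scenario),
      grid_size = raw$grid_size,
      design = raw$design,
      subplot_size = raw$subplot_size
    )
    truth <- Filter(Negate(is.null), truth)
    df <- new_fieldsim(df, truth, raw$grid_size, raw$seed)
  }
  df
}

#' Write a tidy study result to CSV
#'
#' One row per (replicate, method, scenario, metric); re-aggregating the file
#' with [summarize_study()] semantics reproduces the summary exactly.
#'
#' @param result A `study_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_result <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  fails <- study_failures(result)
  if (nrow(fails) > 0) {
    utils::write.csv(as.data.frame(fails), sub("(\\.csv)?$", ".failures.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}
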
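## Serialization of set-valued cells: sorted, "|"-joined.
join_set <- function(x) vapply(x, function(s) paste(sort(s), collapse = "|"),
                               character(1L))
split_set <- function(x) lapply(strsplit(x, "|", fixed = TRUE), sort)

flatten_visit_table <- function(table) {
  out <- data.frame(
    visit_id = table$visit_id,
    patient_id = table$patient_id,
    age = table$age,
    sex = table$sex,
    dx_codes = join_set(table$dx_codes),
    drugs = join_set(table$drugs),
    stringsAsFactors = FALSE
  )
  out
}

unflatten_visit_table <- function(df) {
  tab <- data.frame(
    visit_id = as.character(df$visit_id),
    patient_id = as.character(df$patient_id),
    age = as.numeric(df$age),
    sex = as.character(df$sex),
    stringsAsFactors = FALSE
  )
  tab$dx_codes <- split_set(as.character(df$dx_codes))
  tab$drugs <- split_set(as.character(df$drugs))
  class(tab) <- c("visit_table", "data.frame")
  tab
}

#' Write a visit table to CSV or Parquet
#'
#' Set-valued columns (`dx_codes`, `drugs`) are serialized as sorted,
#' `"|"`-joined strings, so files round-trip losslessly through
#' [read_visit_table()].
#'
#' @param table a `visit_table`.
#' @param path output file path.
#' @param format `"csv"` or `"parquet"` (Parquet requires the arrow package).
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(table, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "visit_table"))
  flat <- flatten_visit_table(table)
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, quote = TRUE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet output requires the arrow package", call. = FALSE)
    }
    arrow::write_parquet(flat, path)
  }
  invisible(path)
}

#' Read a visit table written by [write_visit_table()]
#'
#' @param path input file path.
#' @param format `"csv"` or `"parquet"`; by default inferred from the file
#'   extension.
#' @return a `visit_table`.
#' @export
read_visit_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
  }
  df <- if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("parquet input requires the arrow package", call. = FALSE)
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  unflatten_visit_table(df)
}

#' Write / read a generic-drug to therapeutic-group map as JSON
#'
#' @param group_map named character vector, generic drug -> group.
#' @param path file path.
#' @return for the writer, `path` invisibly; for the reader, a named
#'   character vector.
#' @export
write_group_map <- function(group_map, path) {
  stopifnot(is.character(group_map), !is.null(names(group_map)))
  jsonlite::write_json(as.list(group_map), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_group_map
#' @export
read_group_map <- function(path) {
  m <- jsonlite::read_json(path)
  stats::setNames(vapply(m, as.character, character(1L)), names(m))
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors the arguments of [generator_config()] (under `generator:`)
#' plus preparation, model, hybrid and evaluation settings; see
#' [run_experiment()] for the recognised fields. Unspecified fields keep the
#' package defaults.
#'
#' @param path YAML file path.
#' @return a nested list.
#' @export
read_experiment_config <- function(path) {
  yaml::read_yaml(path)
}
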
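# Plain-CSV serialization of the package's tabular interchange formats.
# Schemas: stimuli (id, category, role, compliance_mm_per_N); schedules
# (one row per trial); traces (long format, one row per 3 ms sample);
# per-trial features; questionnaire items.

#' Read and write the package's CSV formats
#'
#' Thin wrappers around [utils::read.csv()] / [utils::write.csv()] that
#' fix the column schema and restore the category factor ordering on
#' read.
#'
#' @param x Table to write.
#' @param path File path.
#' @return The file path (writers, invisibly) or a tibble (readers).
#' @name haptic_csv
NULL

#' @rdname haptic_csv
#' @export
write_stimuli_csv <- function(x, path) {
  out <- data.frame(id = x$id, category = as.character(x$category),
                    role = x$role, compliance_mm_per_N = x$compliance)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname haptic_csv
#' @export
read_stimuli_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(id = x$id, category = category_factor(x$category),
                 role = x$role, compliance = x$compliance_mm_per_N)
}

#' @rdname haptic_csv
#' @export
write_schedule_csv <- function(x, path) {
  out <- as.data.frame(x)
  out$category <- as.character(out$category)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname haptic_csv
#' @export
read_schedule_csv <- function(path, design_label = NULL) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  x$category <- category_factor(x$category)
  attr(x, "design_label") <- design_label
  x
}

#' @rdname haptic_csv
#' @export
write_traces_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname haptic_csv
#' @export
read_traces_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname haptic_csv
#' @export
write_features_csv <- function(x, path) {
  out <- as.data.frame(x)
  if ("category" %in% names(out)) out$category <- as.character(out$category)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname haptic_csv
#' @export
read_features_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("category" %in% names(x)) x$category <- category_factor(x$category)
  x
}
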
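# Validated CSV readers/writers for the tidy label and response tables.

validate_labels_in <- function(x, column, system, path) {
  if (is.null(system)) return(invisible())
  bad <- which(!(x[[column]] %in% system$labels))
  if (length(bad))
    stop_param(sprintf("%s: unknown %s label(s) %s at row(s) %s",
                       path, column,
                       paste(unique(x[[column]][bad]), collapse = ", "),
                       paste(utils::head(bad, 10L), collapse = ", ")))
}

#' Read / write a time-unlimited label table
#'
#' CSVs are UTF-8 with a header; a label table has columns `task`,
#' `observer_id`, `image_id`, `category`. Reading validates the schema,
#' rejects duplicate (observer, image) votes, and optionally checks labels
#' against a [category_system()].
#'
#' @param path CSV path.
#' @param system Optional `category_system` to validate categories against.
#' @return The validated data frame.
#' @export
read_label_table <- function(path, system = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!nrow(x)) stop_param(path, ": no rows")
  need <- c("task", "observer_id", "image_id", "category")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_param(path, ": missing column(s) ", paste(miss, collapse = ", "))
  d <- which(duplicated(x[c("observer_id", "image_id")]))
  if (length(d))
    stop_param(path, ": duplicate (observer, image) vote at row(s) ",
               paste(utils::head(d, 10L), collapse = ", "))
  validate_labels_in(x, "category", system, path)
  x
}

#' @rdname read_label_table
#' @param labels A label table to write.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a timed response table
#'
#' A response table has columns `task`, `observer_id`, `image_id`,
#' `duration_ms`, `color`, `viewing`, `response`, `report`, `true_label`.
#' Reading validates the schema, numeric durations, duplicate
#' (observer, image, color) trials, and optionally the response alphabet.
#'
#' @param path CSV path.
#' @param system Optional `category_system` for the response alphabet.
#' @return The validated data frame.
#' @export
read_response_table <- function(path, system = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!nrow(x)) stop_param(path, ": no rows")
  need <- c("task", "observer_id", "image_id", "duration_ms", "color",
            "viewing", "response", "report", "true_label")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_param(path, ": missing column(s) ", paste(miss, collapse = ", "))
  if (!is.numeric(x$duration_ms)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$duration_ms))))
    stop_param(path, ": non-numeric duration_ms at row(s) ",
               paste(utils::head(bad, 10L), collapse = ", "))
  }
  d <- which(duplicated(x[c("observer_id", "image_id", "color")]))
  if (length(d))
    stop_param(path, ": duplicate (observer, image, color) trial at row(s) ",
               paste(utils::head(d, 10L), collapse = ", "))
  validate_labels_in(x, "response", system, path)
  x
}

#' @rdname read_response_table
#' @param responses A response table to write.
#' @export
write_response_table <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
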
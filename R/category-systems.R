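#' Category systems
#'
#' A category system is the label alphabet of one m-alternative forced-choice
#' task: either the six semantic scene categories or the four
#' spatial-structure (3D layout) categories used throughout the package.
#'
#' @param task `"semantic"` or `"spatial"`.
#' @param labels Optional character vector of unique category names
#'   (length >= 2). Defaults to the standard six semantic / four spatial
#'   labels.
#' @return An object of class `category_system`: a list with elements
#'   `task` and `labels`.
#' @examples
#' category_system("semantic")
#' category_system("spatial", c("flat", "deep"))
#' @export
category_system <- function(task = c("semantic", "spatial"), labels = NULL) {
  task <- match.arg(task)
  if (is.null(labels)) {
    labels <- switch(task,
      semantic = c("beach", "residential", "road", "farm", "car-park", "nature"),
      spatial  = c("open", "closed-off", "navigable", "cluttered")
    )
  }
  labels <- as.character(labels)
  if (length(labels) < 2L) stop_param("a category system needs at least 2 labels")
  if (anyDuplicated(labels)) stop_param("category labels must be unique")
  structure(list(task = task, labels = labels), class = "category_system")
}

#' @export
print.category_system <- function(x, ...) {
  cat(sprintf("<category_system> %s task, m = %d: %s\n",
              x$task, length(x$labels), paste(x$labels, collapse = ", ")))
  invisible(x)
}

n_categories <- function(system) length(system$labels)
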
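#' Experimental design specification
#'
#' Describes the within-subject timed-categorization design: presentation
#' durations (ms), color conditions, binocular viewing conditions, and the
#' session/block structure. The default reproduces the standard
#' 2 (color) x 4 (duration) x 3 (viewing) design in which each of 708 images
#' is shown twice (once per color condition), giving 1,416 trials split into
#' two sessions of 12 blocks of 59 trials.
#'
#' @param durations_ms Presentation durations in milliseconds.
#' @param colors Color conditions.
#' @param viewing Binocular viewing conditions.
#' @param presentations_per_image Number of presentations of each image; must
#'   equal `length(colors)` (one presentation per color condition).
#' @param blocks_per_session Number of equal blocks per session.
#' @param sessions Number of sessions.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(durations_ms = c(13.3, 26.7, 53.3, 106.7),
                        colors = c("color", "grayscale"),
                        viewing = c("mono", "stereo", "reverse_stereo"),
                        presentations_per_image = length(colors),
                        blocks_per_session = 12L,
                        sessions = 2L) {
  if (!is.numeric(durations_ms) || !length(durations_ms) || any(durations_ms <= 0))
    stop_param("durations_ms must be positive")
  if (presentations_per_image != length(colors))
    stop_param("each image is presented exactly once per color condition: ",
               "presentations_per_image must equal length(colors)")
  structure(list(durations_ms = as.numeric(durations_ms),
                 colors = as.character(colors),
                 viewing = as.character(viewing),
                 presentations_per_image = as.integer(presentations_per_image),
                 blocks_per_session = as.integer(blocks_per_session),
                 sessions = as.integer(sessions)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %d durations x %d colors x %d viewing; %d sessions x %d blocks\n",
              length(x$durations_ms), length(x$colors), length(x$viewing),
              x$sessions, x$blocks_per_session))
  invisible(x)
}

#' Enumerate the trial list of a timed session pair
#'
#' Assigns each image, independently for each color condition, to one
#' duration x viewing cell with exactly equal cell counts (pseudo-random
#' balanced assignment), then chunks the trials of each color condition into
#' equal blocks and distributes the blocks over sessions. Every image appears
#' exactly once per color condition, so the trial count is
#' `n_images * length(colors)`.
#'
#' @param design A [design_spec()].
#' @param image_ids Vector of image ids (or a single count, expanded to
#'   `1:n`).
#' @param seed Integer seed for the pseudo-random assignment.
#' @return A data frame with columns `trial_id`, `session`, `block`,
#'   `image_id`, `duration_ms`, `color`, `viewing`.
#' @examples
#' tr <- enumerate_design(design_spec(), 708, seed = 1)
#' nrow(tr)  # 1416
#' table(tr$duration_ms, tr$viewing, tr$color)  # all 59
#' @export
enumerate_design <- function(design, image_ids, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  if (length(image_ids) == 1L && is.numeric(image_ids))
    image_ids <- seq_len(image_ids)
  n_images <- length(image_ids)
  n_cells <- length(design$durations_ms) * length(design$viewing)
  if (n_images %% n_cells != 0)
    stop_param(sprintf(
      "design not divisible: %d images cannot fill %d duration x viewing cells equally (%d durations x %d viewing)",
      n_images, n_cells, length(design$durations_ms), length(design$viewing)))
  per_cell <- n_images %/% n_cells
  cells <- expand.grid(duration_ms = design$durations_ms,
                       viewing = design$viewing,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  with_seed(child_seed(seed, "design"), {
    parts <- lapply(design$colors, function(col) {
      ord <- sample.int(n_images)  # independent assignment per color condition
      data.frame(image_id = image_ids[ord],
                 duration_ms = rep(cells$duration_ms, each = per_cell),
                 viewing = rep(cells$viewing, each = per_cell),
                 color = col, stringsAsFactors = FALSE)
    })
    trials <- do.call(rbind, parts)
    n_trials <- nrow(trials)
    n_blocks <- design$blocks_per_session * design$sessions
    if (n_trials %% n_blocks != 0)
      stop_param(sprintf("design not divisible: %d trials into %d blocks",
                         n_trials, n_blocks))
    block_len <- n_trials %/% n_blocks
    # blocks are pure in color (color is manipulated blockwise); shuffle
    # trial order within color, then block order across the experiment
    trials <- trials[order(match(trials$color, design$colors),
                           sample.int(n_trials)), ]
    blk <- rep(seq_len(n_blocks), each = block_len)
    blk_order <- sample.int(n_blocks)
    trials <- trials[order(match(blk, blk_order)), ]
    trials$block <- rep(seq_len(n_blocks), each = block_len)
    trials$session <- (trials$block - 1L) %/% design$blocks_per_session + 1L
    trials$trial_id <- seq_len(n_trials)
    rownames(trials) <- NULL
    trials[, c("trial_id", "session", "block", "image_id",
               "duration_ms", "color", "viewing")]
  })
}
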
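#' Modal label and inter-observer agreement of a vote multiset
#'
#' @param votes Character vector of category votes (length >= 1).
#' @param tie_rule How to resolve a shared maximum: `"lexicographic"`
#'   (default, deterministic), `"seeded_random"` (uniform among tied labels
#'   under `seed`), or `"flag"` (return `NA` as the label; the tie flag is
#'   recorded under every rule).
#' @param seed Seed used by `tie_rule = "seeded_random"`.
#' @return A list with `category`, `agreement` (modal votes / total votes,
#'   in `[1/n, 1]`) and `tie`.
#' @examples
#' modal_label(c("A", "A", "B"))
#' @export
modal_label <- function(votes, tie_rule = c("lexicographic", "seeded_random", "flag"),
                        seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  if (!length(votes)) stop_param("empty vote set")
  counts <- table(votes)  # names sorted, so which.max is lexicographic
  mx <- max(counts)
  cand <- names(counts)[counts == mx]
  tie <- length(cand) > 1L
  category <- switch(tie_rule,
    lexicographic = cand[1L],
    seeded_random = if (tie) with_seed(seed, sample(cand, 1L)) else cand[1L],
    flag = if (tie) NA_character_ else cand[1L])
  list(category = category, agreement = as.numeric(mx) / length(votes), tie = tie)
}

#' Ground truth from a time-unlimited label table
#'
#' Reduces a label table (observer x image votes under unlimited viewing) to
#' one row per image: the modal category, the inter-observer agreement
#' (proportion of votes for the mode), the number of voters and a tie flag.
#'
#' @param labels Label table with columns `observer_id`, `image_id`,
#'   `category` (and optionally `task`).
#' @param tie_rule,seed Passed to [modal_label()].
#' @return A data frame with columns `image_id`, `modal_category`,
#'   `agreement`, `n_voters`, `tie`.
#' @export
ground_truth_table <- function(labels, tie_rule = c("lexicographic", "seeded_random", "flag"),
                               seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  need <- c("observer_id", "image_id", "category")
  if (!all(need %in% names(labels)))
    stop_param("label table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(labels[c("observer_id", "image_id")]))
    stop_param("duplicate (observer, image) votes in label table")
  tab <- table(labels$image_id, labels$category)
  voters <- rowSums(tab)
  if (length(unique(voters)) > 1L)
    warning(sprintf("unequal voter counts per image (%d to %d); proceeding on available votes",
                    min(voters), max(voters)))
  mx <- apply(tab, 1, max)
  tie <- rowSums(tab == mx) > 1L
  modal <- colnames(tab)[max.col(tab, ties.method = "first")]
  if (tie_rule == "seeded_random" && any(tie)) {
    modal[tie] <- with_seed(seed, vapply(which(tie), function(i) {
      cand <- colnames(tab)[tab[i, ] == mx[i]]
      sample(cand, 1L)
    }, character(1)))
  } else if (tie_rule == "flag") {
    modal[tie] <- NA_character_
  }
  # table() orders rows by the character sort of image_id; restore input order
  gt <- data.frame(image_id = rownames(tab), modal_category = modal,
                   agreement = as.numeric(mx / voters),
                   n_voters = as.integer(voters), tie = unname(tie),
                   stringsAsFactors = FALSE)
  ord <- match(as.character(unique(labels$image_id)), gt$image_id)
  gt <- gt[ord, , drop = FALSE]
  if (is.numeric(labels$image_id)) gt$image_id <- as.numeric(gt$image_id)
  rownames(gt) <- NULL
  gt
}

#' Leave-one-out ceiling sensitivity of a time-unlimited pool
#'
#' For each observer in turn, ground truth is redefined as the modal label of
#' the remaining N-1 observers per image; the held-out observer's labels are
#' scored against it and the accuracy converted to the m-AFC d' (with the
#' extreme-proportion correction). The mean over observers estimates the best
#' performance attainable on the task given inter-observer disagreement.
#'
#' @param labels Label table (>= 3 observers).
#' @param m Number of categories; must cover the label alphabet.
#' @param correction Extreme-proportion correction, see [dprime_mafc()].
#' @param tie_rule Tie rule for the N-1 mode (lexicographic or seeded_random).
#' @param seed Seed for `tie_rule = "seeded_random"`.
#' @return A list with `per_observer` (data frame: `observer_id`, `accuracy`,
#'   `dprime`), `mean`, `se` (standard error over observers) and `m`.
#' @export
loocv_ceiling <- function(labels, m, correction = c("half_trial", "none"),
                          tie_rule = c("lexicographic", "seeded_random"),
                          seed = 1L) {
  correction <- match.arg(correction)
  tie_rule <- match.arg(tie_rule)
  observers <- unique(labels$observer_id)
  if (length(observers) < 3L) stop_param("loocv_ceiling needs >= 3 observers")
  alphabet <- unique(labels$category)
  if (length(alphabet) > m)
    stop_param(sprintf("label alphabet has %d categories but m = %d",
                       length(alphabet), m))
  images <- unique(labels$image_id)
  counts <- table(factor(labels$image_id, levels = images), labels$category)
  cats <- colnames(counts)  # sorted: ties.method = "first" is lexicographic

  per <- vapply(observers, function(o) {
    rows <- labels$observer_id == o
    own <- labels[rows, ]
    own <- own[match(images, own$image_id), "category"]
    held <- counts
    held[cbind(seq_along(images), match(own, cats))] <-
      held[cbind(seq_along(images), match(own, cats))] - 1L
    if (tie_rule == "seeded_random") {
      mx <- apply(held, 1, max)
      modal <- with_seed(child_seed(seed, paste0("loocv_", o)),
        vapply(seq_along(images), function(i) {
          cand <- cats[held[i, ] == mx[i]]
          if (length(cand) > 1L) sample(cand, 1L) else cand
        }, character(1)))
    } else {
      modal <- cats[max.col(held, ties.method = "first")]
    }
    mean(own == modal)
  }, numeric(1))

  dp <- vapply(per, function(acc)
    dprime_from_counts(round(acc * length(images)), length(images), m,
                       correction = correction), numeric(1))
  per_observer <- data.frame(observer_id = observers, accuracy = unname(per),
                             dprime = unname(dp), stringsAsFactors = FALSE)
  list(per_observer = per_observer, mean = mean(dp), se = std_error(dp), m = m)
}
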
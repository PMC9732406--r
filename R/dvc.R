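# Multinomial decision-variable correlation and categorical agreement.

#' Phi coefficient of two binary vectors
#'
#' The Pearson correlation of two binary vectors, equivalently
#' (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)) on their 2x2 contingency table.
#' Returns `NA` when either vector has zero variance (the caller decides the
#' skip policy).
#'
#' @param a,b Binary (0/1 or logical) vectors of equal length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA` for a degenerate input.
#' @export
phi_coefficient <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L)
    stop_param("vectors must have equal length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

dvc_core <- function(correct_a, correct_b, category, min_trials = 5L) {
  cats <- sort(unique(as.character(category)))
  phis <- numeric(0); kept <- character(0)
  skipped <- data.frame(category = character(0), reason = character(0),
                        n_trials = integer(0), stringsAsFactors = FALSE)
  n_per <- integer(0)
  for (cc in cats) {
    ii <- category == cc
    n <- sum(ii)
    if (n < min_trials) {
      skipped <- rbind(skipped, data.frame(category = cc, reason = "min_trials",
                                           n_trials = n))
      next
    }
    ph <- phi_coefficient(correct_a[ii], correct_b[ii])
    if (is.na(ph)) {
      skipped <- rbind(skipped, data.frame(category = cc, reason = "zero_variance",
                                           n_trials = n))
      next
    }
    phis <- c(phis, ph); kept <- c(kept, cc); n_per <- c(n_per, n)
  }
  if (!length(phis))
    stop_param("no ground-truth category retained (all skipped: ",
               paste(unique(skipped$reason), collapse = ", "), ")")
  structure(list(value = mean(phis),
                 per_category = stats::setNames(phis, kept),
                 n_trials = stats::setNames(n_per, kept),
                 skipped = skipped, min_trials = min_trials),
            class = "dvc_result")
}

#' @export
print.dvc_result <- function(x, digits = 3, ...) {
  cat(sprintf("<dvc_result> DVC = %.*f over %d categories", digits, x$value,
              length(x$per_category)))
  if (nrow(x$skipped)) cat(sprintf(" (%d skipped)", nrow(x$skipped)))
  cat("\n")
  print(round(x$per_category, digits))
  invisible(x)
}

#' Decision-variable correlation between two response sources
#'
#' Converts each source's categorical responses to binary correct/incorrect
#' against the modal ground truth, computes the phi coefficient of the two
#' correctness vectors independently within each ground-truth category, and
#' averages (unweighted) over the categories retained. Categories with fewer
#' than `min_trials` aligned trials or zero variance in either vector are
#' skipped with a logged reason. A DVC of 0 indicates only chance agreement;
#' the bound is `[-1, 1]`.
#'
#' `other` may be a second response table (aligned on
#' `image_id`/`duration_ms`/`color`) or a [model_predictions()] table
#' (aligned on `image_id`/`duration_ms`, its per-image prediction applying
#' to both color presentations).
#'
#' @param human Response table slice (e.g. one observer, one duration).
#' @param other Response table slice or `model_prediction` table.
#' @param truth Ground-truth table of the task.
#' @param min_trials Minimum aligned trials per category (default 5).
#' @return A `dvc_result`.
#' @export
dvc <- function(human, other, truth, min_trials = 5L) {
  gt_h <- truth$modal_category[match(human$image_id, truth$image_id)]
  if (anyNA(gt_h)) stop_param("responses reference images without ground truth")
  correct_h <- as.numeric(human$response == gt_h)
  if (inherits(other, "model_prediction")) {
    key_h <- paste(human$image_id, human$duration_ms)
    key_o <- paste(other$image_id, other$duration_ms)
    mi <- match(key_h, key_o)
    if (anyNA(mi)) stop_param("model predictions do not cover all human trials")
    gt_o <- truth$modal_category[match(other$image_id[mi], truth$image_id)]
    correct_o <- as.numeric(other$predicted_category[mi] == gt_o)
  } else {
    key_h <- paste(human$image_id, human$duration_ms, human$color)
    key_o <- paste(other$image_id, other$duration_ms, other$color)
    mi <- match(key_h, key_o)
    if (anyNA(mi)) stop_param("the two response sets are not aligned on ",
                              "(image_id, duration_ms, color)")
    gt_o <- truth$modal_category[match(other$image_id[mi], truth$image_id)]
    correct_o <- as.numeric(other$response[mi] == gt_o)
  }
  dvc_core(correct_h, correct_o, gt_h, min_trials = min_trials)
}

# correctness matrix (trials x observers) for one condition slice
correctness_matrix <- function(responses, truth) {
  obs <- sort(unique(responses$observer_id))
  key <- paste(responses$image_id, responses$duration_ms, responses$color)
  trial <- sort(unique(key))
  M <- matrix(NA_real_, length(trial), length(obs),
              dimnames = list(trial, obs))
  gt <- truth$modal_category[match(responses$image_id, truth$image_id)]
  M[cbind(match(key, trial), match(responses$observer_id, obs))] <-
    as.numeric(responses$response == gt)
  cat_of_trial <- gt[match(trial, key)]
  list(M = M, category = cat_of_trial,
       image_id = responses$image_id[match(trial, key)])
}

#' Pairwise human-human decision-variable correlation
#'
#' Computes the DVC between the raw responses of every unordered observer
#' pair, within each condition cell (viewing and color pooled by default:
#' trials align on image, duration and color), and aggregates to a mean and
#' SE over pairs.
#'
#' @param responses Response table with >= 2 observers sharing one trial
#'   structure.
#' @param truth Ground-truth table.
#' @param group_by Condition columns (default `duration_ms`).
#' @param min_trials Per-category minimum, see [dvc()].
#' @return A `metric_series` (metric `"dvc_pairwise"`); `$per_observer`
#'   holds one row per pair and cell.
#' @export
pairwise_human_dvc <- function(responses, truth, group_by = "duration_ms",
                               min_trials = 5L) {
  obs <- unique(responses$observer_id)
  if (length(obs) < 2L) stop_param("pairwise DVC needs >= 2 observers")
  cells <- unique(responses[, group_by, drop = FALSE])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(responses))
    for (g in group_by) sel <- sel & responses[[g]] == cells[ci, g]
    cm <- correctness_matrix(responses[sel, ], truth)
    obs_c <- colnames(cm$M)
    for (i in seq_len(length(obs_c) - 1L)) {
      for (j in seq(i + 1L, length(obs_c))) {
        ok <- stats::complete.cases(cm$M[, c(i, j)])
        res <- try(dvc_core(cm$M[ok, i], cm$M[ok, j], cm$category[ok],
                            min_trials = min_trials), silent = TRUE)
        if (inherits(res, "try-error")) next
        r <- cells[ci, , drop = FALSE]
        r$observer_id <- paste(obs_c[i], obs_c[j], sep = ":")
        r$value <- res$value
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  series <- stats::aggregate(list(mean = per$value),
                             by = per[, group_by, drop = FALSE], FUN = mean)
  series$se <- stats::aggregate(list(se = per$value),
                                by = per[, group_by, drop = FALSE],
                                FUN = std_error)$se
  series$n_pairs <- stats::aggregate(list(n = per$value),
                                     by = per[, group_by, drop = FALSE],
                                     FUN = length)$n
  new_metric_series(series, per, "dvc_pairwise", NULL, group_by,
                    extra = list(min_trials = min_trials))
}

#' Leave-one-out human-human decision-variable correlation
#'
#' For each observer, builds the modal response of the remaining N-1
#' observers per trial (lexicographic tie-break) and computes the DVC between
#' the held-out observer and that mode, per condition cell; aggregates over
#' observers.
#'
#' @inheritParams pairwise_human_dvc
#' @return A `metric_series` (metric `"dvc_loocv"`).
#' @export
loocv_human_dvc <- function(responses, truth, group_by = "duration_ms",
                            min_trials = 5L) {
  obs <- unique(responses$observer_id)
  if (length(obs) < 3L) stop_param("LOOCV DVC needs >= 3 observers")
  labels <- sort(unique(responses$response))
  cells <- unique(responses[, group_by, drop = FALSE])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(responses))
    for (g in group_by) sel <- sel & responses[[g]] == cells[ci, g]
    sub <- responses[sel, ]
    key <- paste(sub$image_id, sub$duration_ms, sub$color)
    trial <- sort(unique(key))
    cnt <- table(factor(key, levels = trial),
                 factor(sub$response, levels = labels))
    cnt <- matrix(cnt, nrow = length(trial),
                  dimnames = list(trial, labels))
    gt <- truth$modal_category[match(sub$image_id, truth$image_id)]
    correct <- as.numeric(sub$response == gt)
    cat_of_trial <- gt[match(trial, key)]
    gt_trial <- cat_of_trial
    for (o in unique(sub$observer_id)) {
      oi <- sub$observer_id == o
      ti <- match(key[oi], trial)
      held <- cnt
      held[cbind(ti, match(sub$response[oi], labels))] <-
        held[cbind(ti, match(sub$response[oi], labels))] - 1L
      mode_resp <- labels[max.col(held, ties.method = "first")]
      mode_correct <- as.numeric(mode_resp == gt_trial)
      res <- try(dvc_core(correct[oi], mode_correct[ti], cat_of_trial[ti],
                          min_trials = min_trials), silent = TRUE)
      if (inherits(res, "try-error")) next
      r <- cells[ci, , drop = FALSE]
      r$observer_id <- o
      r$value <- res$value
      rows[[length(rows) + 1L]] <- r
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  series <- stats::aggregate(list(mean = per$value),
                             by = per[, group_by, drop = FALSE], FUN = mean)
  series$se <- stats::aggregate(list(se = per$value),
                                by = per[, group_by, drop = FALSE],
                                FUN = std_error)$se
  series$n_observers <- stats::aggregate(list(n = per$value),
                                         by = per[, group_by, drop = FALSE],
                                         FUN = length)$n
  new_metric_series(series, per, "dvc_loocv", NULL, group_by,
                    extra = list(min_trials = min_trials))
}

#' Model-human decision-variable correlation time-course
#'
#' Computes, per presentation duration and per human observer, the DVC
#' between a causal model's per-image predictions and the observer's
#' responses, and aggregates over observers.
#'
#' @param predictions A [model_predictions()] table for the target task.
#' @param responses Human response table of the target task.
#' @param truth Ground-truth table of the target task.
#' @param group_by Condition columns (default `duration_ms`).
#' @param min_trials Per-category minimum.
#' @return A `metric_series` (metric `"dvc_model"`).
#' @export
model_human_dvc <- function(predictions, responses, truth,
                            group_by = "duration_ms", min_trials = 5L) {
  cells <- unique(responses[, group_by, drop = FALSE])
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(responses))
    for (g in group_by) sel <- sel & responses[[g]] == cells[ci, g]
    sub <- responses[sel, ]
    for (o in unique(sub$observer_id)) {
      res <- try(dvc(sub[sub$observer_id == o, ], predictions, truth,
                     min_trials = min_trials), silent = TRUE)
      if (inherits(res, "try-error")) next
      r <- cells[ci, , drop = FALSE]
      r$observer_id <- o
      r$value <- res$value
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) stop_param("no observer-cell produced a defined DVC")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  series <- stats::aggregate(list(mean = per$value),
                             by = per[, group_by, drop = FALSE], FUN = mean)
  series$se <- stats::aggregate(list(se = per$value),
                                by = per[, group_by, drop = FALSE],
                                FUN = std_error)$se
  series$n_observers <- stats::aggregate(list(n = per$value),
                                         by = per[, group_by, drop = FALSE],
                                         FUN = length)$n
  new_metric_series(series, per, "dvc_model", NULL, group_by,
                    extra = list(min_trials = min_trials))
}

#' Cohen's kappa between two categorical raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with expected
#' agreement p_e from the product of the two raters' marginal label
#' distributions.
#'
#' @param labels_a,labels_b Equal-length label vectors over a shared
#'   alphabet.
#' @return Kappa (<= 1), or `NA` when p_e = 1 (both raters constant and
#'   identical).
#' @examples
#' cohens_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))  # 0
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_param("label vectors must have equal length")
  alphabet <- sort(unique(c(labels_a, labels_b)))
  pa <- table(factor(labels_a, levels = alphabet)) / length(labels_a)
  pb <- table(factor(labels_b, levels = alphabet)) / length(labels_b)
  po <- mean(labels_a == labels_b)
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}
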
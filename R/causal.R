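# Conditional-probability causal models between the two category systems.

#' Empirical conditional probability table between category systems
#'
#' Estimates p(target category | predictor category) from two time-unlimited
#' label tables over the same images. Since different observer pools labelled
#' the two systems, votes are paired per image as the outer product of the
#' two label multisets: each of the n_pred x n_tgt vote pairs contributes
#' weight 1/(n_pred * n_tgt), so every image carries total weight 1
#' (`pairing = "outer"`, the default). `pairing = "modal"` instead pairs only
#' the two modal labels per image. Rows are normalized with optional additive
#' smoothing `alpha`.
#'
#' @param labels_predictor,labels_target Label tables covering the same
#'   image set.
#' @param alpha Additive smoothing (>= 0; default 0, the pure empirical
#'   conditionals). With `alpha = 0`, a predictor category never observed has
#'   an undefined row; predicting from it raises an error.
#' @param pairing `"outer"` or `"modal"`.
#' @param predictor_system,target_system Optional [category_system()]s fixing
#'   the alphabets (defaults inferred from the data's `task` columns).
#' @return An object of class `cond_prob_table`: list with `p` (matrix, rows
#'   = predictor categories, rows sum to 1), `counts`, `row_support`,
#'   `predictor_task`, `target_task`, `alpha`, `pairing`.
#' @export
conditional_probability_table <- function(labels_predictor, labels_target,
                                          alpha = 0,
                                          pairing = c("outer", "modal"),
                                          predictor_system = NULL,
                                          target_system = NULL) {
  pairing <- match.arg(pairing)
  if (alpha < 0) stop_param("alpha must be >= 0")
  sys_of <- function(labels, supplied) {
    if (!is.null(supplied)) return(supplied)
    task <- unique(labels$task)
    if (length(task) == 1L && task %in% c("semantic", "spatial")) {
      sys <- category_system(task)
      if (all(labels$category %in% sys$labels)) return(sys)
    }
    category_system(if (length(task) == 1L && task == "spatial") "spatial" else "semantic",
                    labels = sort(unique(labels$category)))
  }
  psys <- sys_of(labels_predictor, predictor_system)
  tsys <- sys_of(labels_target, target_system)
  imgs <- sort(unique(labels_predictor$image_id))
  if (!setequal(imgs, unique(labels_target$image_id)))
    stop_param("the two label tables must cover the same image set")

  cnt <- function(labels, sys) {
    tb <- table(factor(labels$image_id, levels = imgs),
                factor(labels$category, levels = sys$labels))
    matrix(tb, nrow = length(imgs), dimnames = dimnames(tb))
  }
  P <- cnt(labels_predictor, psys)
  Tg <- cnt(labels_target, tsys)
  if (pairing == "outer") {
    Pn <- P / pmax(rowSums(P), 1)
    Tn <- Tg / pmax(rowSums(Tg), 1)
    counts <- t(Pn) %*% Tn  # image-wise outer products, weight 1 per image
  } else {
    pm <- colnames(P)[max.col(P, ties.method = "first")]
    tm <- colnames(Tg)[max.col(Tg, ties.method = "first")]
    counts <- table(factor(pm, levels = psys$labels),
                    factor(tm, levels = tsys$labels))
    counts <- matrix(counts, nrow = length(psys$labels),
                     dimnames = list(psys$labels, tsys$labels))
  }
  support <- rowSums(counts)
  p <- (counts + alpha) / (support + alpha * ncol(counts))
  p[support + alpha == 0, ] <- NA_real_
  structure(list(p = p, counts = counts, row_support = support,
                 predictor_task = psys$task, target_task = tsys$task,
                 predictor_labels = psys$labels, target_labels = tsys$labels,
                 alpha = alpha, pairing = pairing),
            class = "cond_prob_table")
}

#' @export
print.cond_prob_table <- function(x, digits = 3, ...) {
  cat(sprintf("<cond_prob_table> p(%s | %s), pairing = %s, alpha = %g\n",
              x$target_task, x$predictor_task, x$pairing, x$alpha))
  print(round(x$p, digits))
  invisible(x)
}

#' Predict the category in one system from labels in the other
#'
#' The prediction for one (image, condition) cell scores every target
#' category y by the sum over the cell's predictor labels x_k of p(y | x_k),
#' and returns the argmax — i.e. the mode of the stored conditional prior,
#' aggregated over the n observers who labelled that cell. Invariant to
#' observer order; duplicating the pool scales all scores equally.
#'
#' @param cpt A [conditional_probability_table()].
#' @param observer_labels Character vector (multiset) of predictor labels for
#'   one cell.
#' @param tie_rule `"lexicographic"` (default) or `"seeded_random"`.
#' @param seed Seed for random tie-breaking.
#' @return A list with `category`, `scores` (named vector), `n_observers`
#'   and `tie`.
#' @export
predict_category <- function(cpt, observer_labels,
                             tie_rule = c("lexicographic", "seeded_random"),
                             seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(cpt, "cond_prob_table"))
  if (!length(observer_labels)) stop_param("empty predictor label multiset")
  bad <- setdiff(observer_labels, cpt$predictor_labels)
  if (length(bad))
    stop_param("labels outside the predictor alphabet: ",
               paste(unique(bad), collapse = ", "))
  k <- table(factor(observer_labels, levels = cpt$predictor_labels))
  used <- names(k)[k > 0]
  if (anyNA(cpt$p[used, ]))
    stop_param("prediction uses a predictor category with zero support ",
               "and alpha = 0: ", paste(used[rowSums(is.na(cpt$p[used, , drop = FALSE])) > 0],
                                        collapse = ", "))
  scores <- drop(as.numeric(k) %*% cpt$p)
  names(scores) <- cpt$target_labels
  mx <- max(scores)
  cand <- names(scores)[scores >= mx - 1e-12]
  tie <- length(cand) > 1L
  category <- if (!tie) cand else switch(tie_rule,
    lexicographic = sort(cand)[1L],
    seeded_random = with_seed(seed, sample(cand, 1L)))
  list(category = category, scores = scores,
       n_observers = length(observer_labels), tie = tie)
}

#' Model predictions for every (image, duration) cell of a response table
#'
#' Applies [predict_category()] to the predictor-task responses of a timed
#' experiment, aggregated per image and presentation duration (pooling color
#' and viewing conditions and all observers of the predictor pool).
#'
#' @param cpt A `cond_prob_table` whose predictor task matches `responses`.
#' @param responses Response table of the predictor task.
#' @param group_by Cell keys (default `c("image_id", "duration_ms")`).
#' @param tie_rule,seed Tie handling as in [predict_category()].
#' @return A data frame of class `model_prediction` with the cell keys,
#'   `predicted_category`, `n_observers_used`, `tie`, and the target task in
#'   attribute `target_task`.
#' @export
model_predictions <- function(cpt, responses,
                              group_by = c("image_id", "duration_ms"),
                              tie_rule = c("lexicographic", "seeded_random"),
                              seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(cpt, "cond_prob_table"))
  bad <- setdiff(unique(responses$response), cpt$predictor_labels)
  if (length(bad))
    stop_param("responses outside the predictor alphabet: ",
               paste(bad, collapse = ", "))
  key <- interaction(responses[, group_by, drop = FALSE], drop = TRUE, sep = "\r")
  counts <- table(key, factor(responses$response, levels = cpt$predictor_labels))
  counts <- matrix(counts, nrow = nlevels(key),
                   dimnames = list(levels(key), cpt$predictor_labels))
  if (anyNA(cpt$p)) {
    used <- colSums(counts) > 0
    if (anyNA(cpt$p[used, ]))
      stop_param("predictions use predictor categories with zero support and alpha = 0")
  }
  scores <- counts %*% ifelse(is.na(cpt$p), 0, cpt$p)
  ord <- order(cpt$target_labels)  # argmax with lexicographic tie-break
  sorted <- scores[, ord, drop = FALSE]
  pick <- max.col(sorted, ties.method = "first")
  tie <- rowSums(sorted >= sorted[cbind(seq_len(nrow(sorted)), pick)] - 1e-12) > 1L
  predicted <- colnames(sorted)[pick]
  if (tie_rule == "seeded_random" && any(tie)) {
    predicted[tie] <- with_seed(child_seed(seed, "prediction_ties"),
      vapply(which(tie), function(i) {
        cand <- colnames(sorted)[sorted[i, ] >= sorted[i, pick[i]] - 1e-12]
        sample(cand, 1L)
      }, character(1)))
  }
  keys <- do.call(rbind, strsplit(rownames(scores), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- group_by
  for (g in group_by) {
    if (is.numeric(responses[[g]])) out[[g]] <- as.numeric(out[[g]])
  }
  out$predicted_category <- predicted
  out$n_observers_used <- as.integer(rowSums(counts))
  out$tie <- tie
  class(out) <- c("model_prediction", "data.frame")
  attr(out, "target_task") <- cpt$target_task
  rownames(out) <- NULL
  out
}

#' Sensitivity time-course of a causal model's predictions
#'
#' Scores the model's per-image predictions against the modal ground truth of
#' the target task, per presentation duration, and converts accuracy to the
#' m-AFC d' (one synthetic "model observer" per duration). The standard error
#' is a bootstrap over images.
#'
#' @param predictions A [model_predictions()] table.
#' @param truth Ground-truth table of the *target* task.
#' @param m Number of target categories.
#' @param n_boot Bootstrap replicates for the SE (default 200).
#' @param seed Bootstrap seed.
#' @param correction Extreme-proportion correction.
#' @return A `metric_series` (metric `"dprime_model"`) per duration.
#' @export
model_performance <- function(predictions, truth, m, n_boot = 200L, seed = 1L,
                              correction = c("half_trial", "none")) {
  correction <- match.arg(correction)
  gt <- truth$modal_category[match(predictions$image_id, truth$image_id)]
  if (anyNA(gt)) stop_param("predictions reference images without ground truth")
  correct <- predictions$predicted_category == gt
  durations <- sort(unique(predictions$duration_ms))
  rows <- lapply(durations, function(d) {
    ii <- predictions$duration_ms == d
    n <- sum(ii)
    dp <- dprime_from_counts(sum(correct[ii]), n, m, correction)
    boot <- with_seed(child_seed(seed, paste0("model_perf_", d)), {
      vapply(seq_len(n_boot), function(b) {
        s <- sample.int(n, n, replace = TRUE)
        dprime_from_counts(sum(correct[ii][s]), n, m, correction)
      }, numeric(1))
    })
    data.frame(duration_ms = d, mean = dp, se = stats::sd(boot),
               n_images = n)
  })
  series <- do.call(rbind, rows)
  new_metric_series(series, NULL, "dprime_model", m, "duration_ms",
                    extra = list(correction = correction, n_boot = n_boot))
}
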
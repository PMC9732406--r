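# Ceiling equalization across tasks via inter-observer-agreement binning.

#' Default agreement bin edges
#'
#' Agreement from an N-observer pool lives on the grid {1/N, ..., 1}. The
#' default binning puts one bin per attainable value and merges bins upward
#' (toward higher agreement) until every bin holds at least `min_images`
#' images in *every* supplied ground-truth table, so per-bin d' stays
#' estimable in both tasks with a common set of edges.
#'
#' @param truths A ground-truth table or a list of them (one per task).
#' @param n_voters Pool size N defining the attainable grid; defaults to the
#'   `n_voters` column.
#' @param min_images Minimum image count per bin per task (default 20).
#' @return A numeric vector of right-closed bin edges spanning (0, 1],
#'   starting at 0.
#' @export
agreement_bin_edges <- function(truths, n_voters = NULL, min_images = 20L) {
  if (is.data.frame(truths)) truths <- list(truths)
  n_voters <- n_voters %||% max(vapply(truths, function(t) max(t$n_voters), numeric(1)))
  grid <- seq_len(n_voters) / n_voters
  edges <- c(0, grid)  # bin k is (edge[k], edge[k+1]]
  repeat {
    counts <- sapply(truths, function(t)
      table(cut(t$agreement, edges, include.lowest = FALSE)))
    counts <- matrix(counts, ncol = length(truths))
    short <- which(apply(counts, 1, min) < min_images)
    if (!length(short) || length(edges) <= 2L) break
    k <- short[1L]
    # merge bin k into its upper neighbour (or downward at the top edge)
    drop <- if (k + 1L < length(edges)) k + 1L else k
    edges <- edges[-drop]
  }
  edges
}

#' Bin images by inter-observer agreement
#'
#' @param truth Ground-truth table with agreements in (0, 1].
#' @param bin_edges Right-closed bin edges starting at 0 (see
#'   [agreement_bin_edges()]).
#' @return An object of class `agreement_binning`: list with `bin_edges`,
#'   `assignment` (data frame `image_id`, `bin`), `counts` and `proportions`
#'   per bin.
#' @export
bin_by_agreement <- function(truth, bin_edges) {
  a <- truth$agreement
  if (any(!is.finite(a)) || any(a <= 0) || any(a > 1))
    stop_param("agreement values must lie in (0, 1]")
  if (bin_edges[1] != 0 || abs(bin_edges[length(bin_edges)] - 1) > 1e-12)
    stop_param("bin_edges must span (0, 1]")
  bin <- findInterval(a, bin_edges, left.open = TRUE, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = bin_edges,
                 assignment = data.frame(image_id = truth$image_id, bin = bin),
                 counts = counts,
                 proportions = counts / sum(counts)),
            class = "agreement_binning")
}

#' @export
print.agreement_binning <- function(x, ...) {
  cat(sprintf("<agreement_binning> %d bins over (0, 1], %d images\n",
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Shared bin weights across two tasks
#'
#' The normalization weights are the per-bin averages of the two tasks'
#' agreement-histogram proportions, renormalized over the bins occupied in
#' both tasks. Using one weight vector for both tasks equalizes the
#' agreement composition entering each task's weighted d'.
#'
#' @param binning_a,binning_b `agreement_binning` objects built with
#'   identical `bin_edges`.
#' @return A numeric weight vector over bins (zero outside the jointly
#'   occupied set), summing to 1.
#' @export
shared_bin_weights <- function(binning_a, binning_b) {
  if (!isTRUE(all.equal(binning_a$bin_edges, binning_b$bin_edges)))
    stop_param("binnings must share bin_edges")
  avg <- (binning_a$proportions + binning_b$proportions) / 2
  joint <- binning_a$counts > 0 & binning_b$counts > 0
  if (!any(joint)) stop_param("no agreement bin is occupied in both tasks")
  w <- ifelse(joint, avg, 0)
  w / sum(w)
}

#' Agreement-normalized sensitivity time-course
#'
#' Computes d' within every agreement bin, per observer and condition cell,
#' and averages the per-bin values with the shared weights. Bins with no
#' trials for an observer-cell are skipped and the weights renormalized over
#' the bins present (the number of such skips is recorded in the result's
#' `skipped` field).
#'
#' @param responses Response table.
#' @param truth Ground-truth table.
#' @param binning An [bin_by_agreement()] result for this task.
#' @param weights Shared weight vector from [shared_bin_weights()] (or any
#'   nonnegative vector over bins summing to 1).
#' @param m Number of categories.
#' @param group_by Condition columns (default `duration_ms`).
#' @param correction Extreme-proportion correction.
#' @return A `metric_series` (metric `"dprime_normalized"`) with an extra
#'   `skipped` count of empty observer x cell x bin combinations.
#' @export
normalized_dprime <- function(responses, truth, binning, weights, m,
                              group_by = "duration_ms",
                              correction = c("half_trial", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(binning, "agreement_binning"))
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop_param("weights must be nonnegative and sum to 1")
  bins <- binning$assignment$bin[match(responses$image_id,
                                       binning$assignment$image_id)]
  if (anyNA(bins)) stop_param("responses reference images outside the binning")
  resp <- responses
  resp$.bin <- bins
  agg <- observer_cell_counts(resp, truth, c(group_by, ".bin"))
  agg$value <- vapply(seq_len(nrow(agg)), function(i)
    dprime_from_counts(agg$n_correct[i], agg$n_trials[i], m, correction),
    numeric(1))

  active <- which(weights > 0)
  cellkey <- interaction(agg[, c("observer_id", group_by), drop = FALSE],
                         drop = TRUE)
  skipped <- 0L
  rows <- lapply(split(seq_len(nrow(agg)), cellkey), function(ii) {
    sub <- agg[ii, ]
    keep <- sub$.bin %in% active
    sub <- sub[keep, ]
    skipped <<- skipped + length(active) - nrow(sub)
    w <- weights[sub$.bin]
    out <- sub[1, c("observer_id", group_by), drop = FALSE]
    out$value <- sum(w * sub$value) / sum(w)
    out
  })
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
  new_metric_series(series, per, "dprime_normalized", m, group_by,
                    extra = list(weights = weights, skipped = skipped,
                                 correction = correction))
}

#' Bootstrap trial equalization across agreement bins
#'
#' Robustness companion to [normalized_dprime()]: each replicate resamples
#' an equal number of *images* (with replacement) from every occupied
#' agreement bin — preserving the one-presentation-per-color structure of
#' each image — and recomputes the per-duration observer-mean d' with
#' uniform weights over the occupied bins, so every bin contributes the same
#' number of images and trials.
#'
#' @param responses Response table.
#' @param truth Ground-truth table.
#' @param binning An `agreement_binning`.
#' @param m Number of categories.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param n_per_bin Images drawn per bin (default: smallest occupied bin).
#' @param group_by Condition columns.
#' @param seed Integer seed.
#' @return A list with `replicates` (matrix `n_boot` x condition cells of
#'   observer-mean normalized d'), `cells` (condition data frame), `mean`
#'   and 2.5/97.5 percentile bounds per cell.
#' @export
bootstrap_equalize <- function(responses, truth, binning, m, n_boot = 200L,
                               n_per_bin = NULL, group_by = "duration_ms",
                               seed = 1L) {
  if (n_boot < 2) stop_param("n_boot must be >= 2")
  occupied <- which(binning$counts > 0)
  n_per_bin <- as.integer(n_per_bin %||% min(binning$counts[occupied]))
  w <- numeric(length(binning$counts))
  w[occupied] <- 1 / length(occupied)
  by_bin <- split(binning$assignment$image_id, binning$assignment$bin)
  resp_by_img <- split(seq_len(nrow(responses)), responses$image_id)

  reps <- with_seed(child_seed(seed, "bootstrap_equalize"), {
    lapply(seq_len(n_boot), function(b) {
      imgs <- unlist(lapply(by_bin[as.character(occupied)], function(ids)
        ids[sample.int(length(ids), n_per_bin, replace = TRUE)]))
      # copies of a resampled image get fresh ids so they stay distinct
      take <- lapply(seq_along(imgs), function(k) {
        ii <- resp_by_img[[as.character(imgs[k])]]
        cbind(row = ii, new_id = k)
      })
      take <- do.call(rbind, take)
      rs <- responses[take[, "row"], ]
      rs$image_id <- take[, "new_id"]
      tr <- truth[match(imgs, truth$image_id), ]
      tr$image_id <- seq_along(imgs)
      bn <- binning
      bn$assignment <- data.frame(
        image_id = seq_along(imgs),
        bin = rep(occupied, each = n_per_bin))
      ns <- normalized_dprime(rs, tr, bn, w, m, group_by = group_by)
      stats::setNames(ns$series$mean,
                      do.call(paste, c(ns$series[, group_by, drop = FALSE],
                                       sep = "|")))
    })
  })
  cells <- unique(names(reps[[1]]))
  mat <- do.call(rbind, lapply(reps, function(r) r[cells]))
  list(replicates = mat,
       cells = cells,
       mean = colMeans(mat),
       lower = apply(mat, 2, stats::quantile, 0.025),
       upper = apply(mat, 2, stats::quantile, 0.975))
}
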
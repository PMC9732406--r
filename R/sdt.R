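# Signal-detection metrics for m-alternative forced choice.

.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

#' Proportion correct of the unbiased max-rule m-AFC observer
#'
#' Forward model of the generalized d' for tasks with more than two
#' categories: the target category carries Gaussian evidence with mean d'
#' and unit variance, the m - 1 alternatives carry standard Gaussian
#' evidence, and the observer picks the maximum. Proportion correct is
#' pc(d', m) = Integral phi(t - d') Phi(t)^(m-1) dt, evaluated by 61-node
#' Gauss-Hermite quadrature. Strictly increasing in d', and equal to 1/m at
#' d' = 0.
#'
#' @param dprime Sensitivity (vectorized, finite).
#' @param m Number of categories (>= 2).
#' @param nodes Number of quadrature nodes (default 61).
#' @return Proportion correct in (0, 1).
#' @examples
#' pc_mafc(0, 6)      # 1/6
#' pc_mafc(2, 4)
#' @export
pc_mafc <- function(dprime, m, nodes = 61L) {
  if (!is.numeric(m) || length(m) != 1L || m < 2) stop_param("m must be >= 2")
  if (any(!is.finite(dprime))) stop_param("dprime must be finite")
  gh <- gauss_hermite(nodes)
  # t = d' + sqrt(2) u maps the integral onto the Gauss-Hermite weight
  vapply(dprime, function(d)
    sum(gh$w * stats::pnorm(d + sqrt(2) * gh$x)^(m - 1)) / sqrt(pi),
    numeric(1))
}

#' Invert proportion correct to the m-AFC d'
#'
#' Numerical inversion of [pc_mafc()] by a bracketing root-finder. Extreme
#' proportions (0 or 1) are only admissible after a correction; use
#' [dprime_from_counts()] when working from trial counts.
#'
#' @param pc Proportion correct, strictly inside (0, 1).
#' @param m Number of categories (>= 2).
#' @param tol Residual tolerance on pc.
#' @return The d' whose forward proportion correct is `pc`; negative for
#'   below-chance performance.
#' @examples
#' dprime_mafc(1/6, 6)   # ~0
#' dprime_mafc(0.9, 6)
#' @export
dprime_mafc <- function(pc, m, tol = 1e-10) {
  if (!is.numeric(m) || length(m) != 1L || m < 2) stop_param("m must be >= 2")
  vapply(pc, function(p) {
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop_param("pc must lie strictly in (0, 1); apply an extreme-proportion ",
                 "correction (see dprime_from_counts, correction = \"half_trial\")")
    stats::uniroot(function(d) pc_mafc(d, m) - p,
                   interval = c(-8, 10), extendInt = "yes",
                   tol = tol)$root
  }, numeric(1))
}

#' d' from correct/total trial counts
#'
#' Converts an accuracy into the m-AFC d'. The `"half_trial"` correction
#' clamps the proportion correct to `[1/(2n), 1 - 1/(2n)]`, which only
#' affects perfect (or zero) scores — e.g. 10/10 correct becomes 0.95 —
#' and keeps d' finite.
#'
#' @param n_correct,n_trials Correct and total trial counts.
#' @param m Number of categories.
#' @param correction `"half_trial"` (default) or `"none"`.
#' @return d' (scalar).
#' @export
dprime_from_counts <- function(n_correct, n_trials, m,
                               correction = c("half_trial", "none")) {
  correction <- match.arg(correction)
  if (n_trials < 1) stop_param("n_trials must be >= 1")
  pc <- n_correct / n_trials
  if (correction == "half_trial") {
    lo <- 1 / (2 * n_trials)
    pc <- min(max(pc, lo), 1 - lo)
  }
  dprime_mafc(pc, m)
}

new_metric_series <- function(series, per_observer, metric, m, group_by,
                              extra = list()) {
  structure(c(list(series = series, per_observer = per_observer,
                   metric = metric, m = m, group_by = group_by), extra),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, digits = 3, ...) {
  cat(sprintf("<metric_series> metric = %s%s, grouped by %s\n", x$metric,
              if (!is.null(x$m)) sprintf(" (m = %d)", x$m) else "",
              paste(x$group_by, collapse = " x ")))
  print(format(x$series, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.metric_series <- function(x, ...) {
  if (!"duration_ms" %in% names(x$series))
    stop_param("plot method needs a duration_ms grouping")
  s <- x$series
  other <- setdiff(x$group_by, "duration_ms")
  key <- if (length(other)) interaction(s[other], drop = TRUE) else factor(rep("all", nrow(s)))
  cols <- seq_along(levels(key))
  plot(range(s$duration_ms), range(c(s$mean - s$se, s$mean + s$se), na.rm = TRUE),
       type = "n", log = "x", xlab = "presentation duration (ms)",
       ylab = x$metric, ...)
  for (i in seq_along(levels(key))) {
    sub <- s[key == levels(key)[i], ]
    sub <- sub[order(sub$duration_ms), ]
    lines(sub$duration_ms, sub$mean, type = "b", col = cols[i], pch = 16)
    arrows(sub$duration_ms, sub$mean - sub$se, sub$duration_ms, sub$mean + sub$se,
           angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  if (length(levels(key)) > 1L)
    legend("topleft", legend = levels(key), col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}

# shared per-observer-per-cell accuracy layout
observer_cell_counts <- function(responses, truth, group_by) {
  gt <- truth[match(responses$image_id, truth$image_id), ]
  if (anyNA(gt$modal_category))
    stop_param("responses reference images without ground truth")
  correct <- responses$response == gt$modal_category
  keys <- responses[, c("observer_id", group_by), drop = FALSE]
  agg <- stats::aggregate(list(n_correct = as.integer(correct)),
                          by = keys, FUN = sum)
  agg$n_trials <- stats::aggregate(list(n = rep(1L, nrow(keys))),
                                   by = keys, FUN = sum)$n
  agg
}

#' Sensitivity time-course from a response table
#'
#' Computes, per observer and per condition cell (any subset of the trial
#' keys, typically `duration_ms` alone or with `color`/`viewing`), the
#' accuracy against the modal ground-truth labels and its m-AFC d', then
#' aggregates to a mean and a standard error *over observers*.
#'
#' @param responses Response table (see [simulate_timed_experiment()]).
#' @param truth Ground-truth table from [ground_truth_table()].
#' @param m Number of categories of the task.
#' @param group_by Character vector of condition columns.
#' @param correction Extreme-proportion correction, see [dprime_from_counts()].
#' @return A `metric_series` object; `$series` has one row per condition
#'   cell (`mean`, `se`, `n_observers`), `$per_observer` the underlying
#'   per-observer values.
#' @export
dprime_series <- function(responses, truth, m, group_by = "duration_ms",
                          correction = c("half_trial", "none")) {
  correction <- match.arg(correction)
  agg <- observer_cell_counts(responses, truth, group_by)
  agg$value <- vapply(seq_len(nrow(agg)), function(i)
    dprime_from_counts(agg$n_correct[i], agg$n_trials[i], m, correction),
    numeric(1))
  series <- stats::aggregate(list(mean = agg$value),
                             by = agg[, group_by, drop = FALSE], FUN = mean)
  series$se <- stats::aggregate(list(se = agg$value),
                                by = agg[, group_by, drop = FALSE],
                                FUN = std_error)$se
  series$n_observers <- stats::aggregate(list(n = agg$value),
                                         by = agg[, group_by, drop = FALSE],
                                         FUN = length)$n
  new_metric_series(series, agg, "dprime", m, group_by,
                    extra = list(correction = correction))
}

#' Stereo effect from a viewing-condition d' series
#'
#' The stereo effect is the average of the stereo and reverse-stereo
#' sensitivities minus the mono sensitivity, computed within observer per
#' duration and then averaged over observers (positive values indicate a
#' stereo advantage).
#'
#' @param series A `metric_series` grouped by (at least) `duration_ms` and
#'   `viewing`.
#' @return A `metric_series` of the per-duration stereo effect.
#' @export
stereo_effect <- function(series) {
  stopifnot(inherits(series, "metric_series"))
  per <- series$per_observer
  if (!all(c("duration_ms", "viewing") %in% names(per)))
    stop_param("stereo_effect needs a series grouped by duration_ms and viewing")
  need <- c("mono", "stereo", "reverse_stereo")
  if (!all(need %in% unique(per$viewing)))
    stop_param("missing viewing condition(s): ",
               paste(setdiff(need, unique(per$viewing)), collapse = ", "))
  wide <- stats::reshape(per[, c("observer_id", "duration_ms", "viewing", "value")],
                         idvar = c("observer_id", "duration_ms"),
                         timevar = "viewing", direction = "wide")
  delta <- (wide$value.stereo + wide$value.reverse_stereo) / 2 - wide$value.mono
  agg <- data.frame(observer_id = wide$observer_id,
                    duration_ms = wide$duration_ms, value = delta,
                    stringsAsFactors = FALSE)
  sr <- stats::aggregate(list(mean = agg$value),
                         by = agg[, "duration_ms", drop = FALSE], FUN = mean)
  sr$se <- stats::aggregate(list(se = agg$value),
                            by = agg[, "duration_ms", drop = FALSE],
                            FUN = std_error)$se
  sr$n_observers <- stats::aggregate(list(n = agg$value),
                                     by = agg[, "duration_ms", drop = FALSE],
                                     FUN = length)$n
  new_metric_series(sr, agg, "delta_dprime", series$m, "duration_ms")
}

#' Confusion matrix of ground-truth against responses
#'
#' @param responses Response table.
#' @param truth Ground-truth table.
#' @param labels Category labels fixing row/column order.
#' @return An integer matrix, rows = true (modal) category, columns =
#'   response.
#' @export
confusion_matrix <- function(responses, truth, labels) {
  gt <- truth$modal_category[match(responses$image_id, truth$image_id)]
  table(factor(gt, levels = labels), factor(responses$response, levels = labels))
}

#' Plug-in mutual information of a count matrix, in bits
#'
#' @param confusion Nonnegative count matrix (e.g. truth x response) with a
#'   positive total.
#' @return Mutual information in bits; 0 for any rank-1 (independent) table,
#'   at most `min(log2(nrow), log2(ncol))`.
#' @examples
#' mutual_information(diag(4) * 10)  # 2 bits
#' @export
mutual_information <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop_param("counts must be nonnegative")
  tot <- sum(confusion)
  if (tot <= 0) stop_param("all-zero count matrix")
  p <- confusion / tot
  px <- rowSums(p); py <- colSums(p)
  ex <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ex[nz]))
}
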
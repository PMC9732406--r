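# End-to-end orchestration of the synthetic study and its analyses.

#' Pipeline configuration
#'
#' Bundles every parameter of a seeded end-to-end run: the joint category
#' model (causal direction and coupling), image set, unlimited-viewing pools,
#' the timed design, the two timed observer pools, and the analysis policies.
#' Defaults reproduce the study conditions the simulator emulates: 708
#' images, 6 semantic x 4 spatial categories, 20 unlimited observers per
#' task, 35 semantic / 30 spatial timed observers, and the
#' 2 color x 4 duration x 3 viewing within-subject design.
#'
#' @param seed Top-level seed; all stages derive named child streams from it.
#' @param direction Causal direction of the joint model.
#' @param coupling_strength Coupling in `[0, 1]` between the systems.
#' @param n_images Number of images.
#' @param n_unlimited Unlimited-viewing pool size per task.
#' @param n_timed Named vector: timed observers per task.
#' @param design A [design_spec()].
#' @param ambiguity Per-task ambiguity distributions, see
#'   [sample_image_set()].
#' @param pop_args Named list of [observer_population()] parameters shared by
#'   both timed pools (except `n_observers`).
#' @param min_bin_images Minimum images per agreement bin, see
#'   [agreement_bin_edges()].
#' @param alpha Additive smoothing of the conditional probability tables.
#' @param min_trials Per-category minimum for DVC computations.
#' @param scale_by_agreement Drive timed per-image sensitivity from realized
#'   unlimited-pool agreement (default) rather than latent ambiguity.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            direction = c("sem_to_spat", "spat_to_sem", "independent"),
                            coupling_strength = 0.8,
                            n_images = 708L,
                            n_unlimited = 20L,
                            n_timed = c(semantic = 35L, spatial = 30L),
                            design = design_spec(),
                            ambiguity = list(semantic = c(1.5, 6),
                                             spatial = c(2.5, 4.5)),
                            pop_args = list(),
                            min_bin_images = 20L,
                            alpha = 0,
                            min_trials = 5L,
                            scale_by_agreement = TRUE) {
  direction <- match.arg(direction)
  structure(list(seed = as.integer(seed), direction = direction,
                 coupling_strength = coupling_strength,
                 n_images = as.integer(n_images),
                 n_unlimited = as.integer(n_unlimited),
                 n_timed = n_timed, design = design, ambiguity = ambiguity,
                 pop_args = pop_args, min_bin_images = min_bin_images,
                 alpha = alpha, min_trials = min_trials,
                 scale_by_agreement = scale_by_agreement),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed = %d, direction = %s (coupling %.2f), %d images\n",
              x$seed, x$direction, x$coupling_strength, x$n_images))
  invisible(x)
}

attach_agreement_scale <- function(images, truth, task, m) {
  mi <- match(images$image_id, truth$image_id)
  a <- truth$agreement[mi]
  images[[paste0("scale_", task)]] <- pmax(0, (a - 1 / m) / (1 - 1 / m))
  images[[paste0("consensus_", task)]] <- truth$modal_category[mi]
  images
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in order under one seed: joint-model construction,
#' image sampling, unlimited-viewing pools and ground truth for both tasks,
#' timed-design enumeration, timed response simulation for both pools
#' (sharing one trial list and one image-level noise stream), sensitivity
#' time-courses and stereo effects, LOOCV ceilings, agreement binning and
#' shared-weight normalization, both conditional-probability causal models
#' with their d' and model-human DVC curves, and the pairwise / LOOCV
#' human-human DVC references. With the same config the output is
#' reproducible bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a JSON metrics summary.
#' @param dvc_references Compute the (slower) pairwise and LOOCV human-human
#'   DVC references (default `TRUE`).
#' @return A list (report bundle) with the simulated tables, ground truth,
#'   metric series, causal-model results and run metadata.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         dvc_references = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  systems <- list(semantic = category_system("semantic"),
                  spatial = category_system("spatial"))
  n_cat <- vapply(systems, n_categories, integer(1))

  n_root <- if (config$direction == "spat_to_sem") n_cat[["spatial"]] else n_cat[["semantic"]]
  n_dep <- if (config$direction == "spat_to_sem") n_cat[["semantic"]] else n_cat[["spatial"]]
  model <- build_joint_model(n_root, n_dep, config$coupling_strength,
                             config$direction, seed = seed)
  images <- sample_image_set(model, config$n_images,
                             seed = child_seed(seed, "images"),
                             ambiguity = config$ambiguity)

  pools <- truths <- list()
  for (task in names(systems)) {
    pools[[task]] <- simulate_unlimited_pool(
      images, systems[[task]], config$n_unlimited,
      seed = child_seed(seed, paste0("pool_", task)))
    truths[[task]] <- ground_truth_table(pools[[task]])
    if (config$scale_by_agreement)
      images <- attach_agreement_scale(images, truths[[task]], task, n_cat[[task]])
  }

  trials <- enumerate_design(config$design, images$image_id,
                             seed = child_seed(seed, "trials"))

  responses <- list()
  for (task in names(systems)) {
    pop <- do.call(observer_population,
                   c(list(n_observers = config$n_timed[[task]]),
                     config$pop_args))
    responses[[task]] <- simulate_timed_experiment(
      images, trials, pop, systems[[task]],
      seed = child_seed(seed, paste0("timed_", task)),
      joint_model = model,
      shared_noise_seed = child_seed(seed, "shared_noise"))
  }

  dprime <- lapply(names(systems), function(task)
    dprime_series(responses[[task]], truths[[task]], n_cat[[task]]))
  names(dprime) <- names(systems)
  dprime_viewing <- lapply(names(systems), function(task)
    dprime_series(responses[[task]], truths[[task]], n_cat[[task]],
                  group_by = c("duration_ms", "viewing")))
  names(dprime_viewing) <- names(systems)
  stereo <- if (all(c("mono", "stereo", "reverse_stereo") %in% config$design$viewing))
    lapply(dprime_viewing, stereo_effect) else NULL
  ceilings <- lapply(names(systems), function(task)
    loocv_ceiling(pools[[task]], n_cat[[task]]))
  names(ceilings) <- names(systems)

  edges <- agreement_bin_edges(truths, n_voters = config$n_unlimited,
                               min_images = config$min_bin_images)
  binnings <- lapply(truths, bin_by_agreement, bin_edges = edges)
  weights <- shared_bin_weights(binnings$semantic, binnings$spatial)
  normalized <- lapply(names(systems), function(task)
    normalized_dprime(responses[[task]], truths[[task]], binnings[[task]],
                      weights, n_cat[[task]]))
  names(normalized) <- names(systems)

  causal <- list()
  for (target in names(systems)) {
    predictor <- setdiff(names(systems), target)
    nm <- paste0(predictor, "_to_", target)
    cpt <- conditional_probability_table(pools[[predictor]], pools[[target]],
                                         alpha = config$alpha)
    preds <- model_predictions(cpt, responses[[predictor]])
    attr(preds, "target_task") <- target
    causal[[nm]] <- list(
      cpt = cpt,
      predictions = preds,
      performance = model_performance(preds, truths[[target]], n_cat[[target]],
                                      seed = child_seed(seed, nm)),
      dvc = model_human_dvc(preds, responses[[target]], truths[[target]],
                            min_trials = config$min_trials))
  }

  human_dvc <- NULL
  if (dvc_references) {
    human_dvc <- lapply(names(systems), function(task) list(
      pairwise = pairwise_human_dvc(responses[[task]], truths[[task]],
                                    min_trials = config$min_trials),
      loocv = loocv_human_dvc(responses[[task]], truths[[task]],
                              min_trials = config$min_trials)))
    names(human_dvc) <- names(systems)
  }

  bundle <- list(config = config, model = model, images = images,
                 trials = trials, pools = pools, truths = truths,
                 responses = responses, dprime = dprime,
                 dprime_viewing = dprime_viewing, stereo = stereo,
                 ceilings = ceilings, bin_edges = edges, binnings = binnings,
                 weights = weights, normalized = normalized,
                 causal = causal, human_dvc = human_dvc)
  class(bundle) <- "scene_report"
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.scene_report <- function(x, ...) {
  cat(sprintf("<scene_report> direction = %s, %d images, seed = %d\n",
              x$config$direction, x$config$n_images, x$config$seed))
  cat("unnormalized d' (mean over observers):\n")
  for (task in names(x$dprime)) {
    s <- x$dprime[[task]]$series
    cat(sprintf("  %-9s %s\n", task,
                paste(sprintf("%.2f@%gms", s$mean, s$duration_ms), collapse = "  ")))
  }
  for (nm in names(x$causal)) {
    s <- x$causal[[nm]]$dvc$series
    cat(sprintf("model DVC %-22s %s\n", nm,
                paste(sprintf("%.3f@%gms", s$mean, s$duration_ms), collapse = "  ")))
  }
  invisible(x)
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  for (task in names(bundle$pools)) {
    write_label_table(bundle$pools[[task]], p(sprintf("labels_%s.csv", task)))
    write_response_table(bundle$responses[[task]], p(sprintf("responses_%s.csv", task)))
    utils::write.csv(bundle$truths[[task]], p(sprintf("ground_truth_%s.csv", task)),
                     row.names = FALSE)
    utils::write.csv(bundle$dprime[[task]]$series, p(sprintf("dprime_%s.csv", task)),
                     row.names = FALSE)
    utils::write.csv(bundle$normalized[[task]]$series,
                     p(sprintf("dprime_normalized_%s.csv", task)), row.names = FALSE)
  }
  for (nm in names(bundle$causal)) {
    utils::write.csv(as.data.frame(bundle$causal[[nm]]$cpt$p),
                     p(sprintf("cpt_%s.csv", nm)))
    utils::write.csv(bundle$causal[[nm]]$predictions,
                     p(sprintf("predictions_%s.csv", nm)), row.names = FALSE)
    utils::write.csv(bundle$causal[[nm]]$dvc$series,
                     p(sprintf("dvc_model_%s.csv", nm)), row.names = FALSE)
  }
  summary <- report_summary(bundle)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(data.frame(key = names(unlist(summary)),
                                value = unlist(summary)),
                     p("summary.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Flat numeric summary of a pipeline report
#'
#' @param bundle A [run_pipeline()] report.
#' @return A named list of the run's headline numbers (trial counts, d'
#'   endpoints, ceilings, model DVC per direction).
#' @export
report_summary <- function(bundle) {
  durs <- sort(unique(bundle$trials$duration_ms))
  first <- durs[1]; last <- durs[length(durs)]
  grab <- function(series, d) series$mean[series$duration_ms == d]
  out <- list(
    n_trials = nrow(bundle$trials) ,
    n_images = bundle$config$n_images,
    direction = bundle$config$direction)
  for (task in names(bundle$dprime)) {
    out[[paste0("dprime_", task, "_shortest")]] <- grab(bundle$dprime[[task]]$series, first)
    out[[paste0("dprime_", task, "_longest")]] <- grab(bundle$dprime[[task]]$series, last)
    out[[paste0("ceiling_", task)]] <- bundle$ceilings[[task]]$mean
    out[[paste0("normalized_dprime_", task, "_longest")]] <-
      grab(bundle$normalized[[task]]$series, last)
  }
  for (nm in names(bundle$causal)) {
    out[[paste0("model_dprime_", nm, "_longest")]] <-
      grab(bundle$causal[[nm]]$performance$series, last)
    out[[paste0("model_dvc_", nm, "_longest")]] <-
      grab(bundle$causal[[nm]]$dvc$series, last)
  }
  if (!is.null(bundle$human_dvc)) {
    for (task in names(bundle$human_dvc)) {
      out[[paste0("pairwise_dvc_", task, "_longest")]] <-
        grab(bundle$human_dvc[[task]]$pairwise$series, last)
      out[[paste0("loocv_dvc_", task, "_longest")]] <-
        grab(bundle$human_dvc[[task]]$loocv$series, last)
    }
  }
  out
}
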
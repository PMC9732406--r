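#' Synthetic observer population
#'
#' Parameters of the simulated observer pool used by
#' [simulate_timed_experiment()]. Sensitivity grows with presentation time
#' as an exponential saturation, d'(t) = (d_asym + boosts) * (1 - exp(-t/tau)),
#' attenuated per image by its clarity and reduced by its additive difficulty
#' penalty. Evidence noise is a mixture of an image-level component shared by
#' all observers (weight `shared_noise_weight`, the source of positive
#' human-human decision-variable correlation) and an observer-private
#' component.
#'
#' @param n_observers Number of observers.
#' @param d_asym Asymptotic sensitivity (d' units) at full clarity.
#' @param tau Growth time constant, ms.
#' @param color_boost Additive d' advantage of color over grayscale stimuli.
#' @param stereo_boost Additive d' advantage shared by the stereo and
#'   reverse-stereo viewing conditions over mono.
#' @param lapse Probability of a uniform-random lapse response, in `[0, 0.1]`.
#' @param shared_noise_weight Variance share in `[0, 1]` of the image-level
#'   evidence noise common to all observers.
#' @param route_weight Probability in `[0, 1]` that, in the task on the
#'   *dependent* category system of a coupled joint model, a response is
#'   produced by first perceiving the root category and mapping it through
#'   the coupling (the mechanism that makes causal-direction recovery
#'   falsifiable). Ignored for the root task and under independence.
#' @param report_d_asym,report_tau Sensitivity parameters of the separate,
#'   low-sensitivity viewing-condition report channel (2D/3D/3D-reversed).
#' @param seed Integer seed associated with the pool.
#' @return An object of class `observer_population`.
#' @export
observer_population <- function(n_observers, d_asym = 2.2, tau = 40,
                                color_boost = 0.15, stereo_boost = 0.1,
                                lapse = 0.02, shared_noise_weight = 0.3,
                                route_weight = 0.5,
                                report_d_asym = 0.8, report_tau = 60,
                                seed = 1L) {
  if (d_asym < 0) stop_param("d_asym must be >= 0")
  if (tau <= 0) stop_param("tau must be > 0")
  if (lapse < 0 || lapse > 0.1) stop_param("lapse must lie in [0, 0.1]")
  if (shared_noise_weight < 0 || shared_noise_weight > 1)
    stop_param("shared_noise_weight must lie in [0, 1]")
  if (route_weight < 0 || route_weight > 1)
    stop_param("route_weight must lie in [0, 1]")
  structure(list(n_observers = as.integer(n_observers), d_asym = d_asym,
                 tau = tau, color_boost = color_boost,
                 stereo_boost = stereo_boost, lapse = lapse,
                 shared_noise_weight = shared_noise_weight,
                 route_weight = route_weight,
                 report_d_asym = report_d_asym, report_tau = report_tau,
                 seed = as.integer(seed)),
            class = "observer_population")
}

#' @export
print.observer_population <- function(x, ...) {
  cat(sprintf("<observer_population> n = %d, d_asym = %.2f, tau = %.0f ms, lapse = %.2f, shared noise = %.2f\n",
              x$n_observers, x$d_asym, x$tau, x$lapse, x$shared_noise_weight))
  invisible(x)
}

#' Simulate a time-unlimited labelling pool
#'
#' Every observer labels every image under unlimited viewing. With image
#' ambiguity a and m categories the correct label is chosen with probability
#' (1 - a) + a/m (equivalently: with probability a the response is uniform
#' over all m categories), so ambiguity 0 gives unanimity and ambiguity 1
#' gives uniform voting.
#'
#' @param images Image table from [sample_image_set()].
#' @param system A [category_system()].
#' @param n_observers Pool size (>= 2, default 20).
#' @param seed Integer seed.
#' @return A label table: data frame with columns `task`, `observer_id`,
#'   `image_id`, `category`.
#' @export
simulate_unlimited_pool <- function(images, system, n_observers = 20L, seed = 1L) {
  stopifnot(inherits(system, "category_system"))
  if (n_observers < 2) stop_param("n_observers must be >= 2")
  task <- system$task
  labels <- system$labels
  m <- length(labels)
  truth <- images[[paste0("true_", task)]]
  amb <- images[[paste0("ambiguity_", task)]]
  if (is.null(amb)) amb <- rep(0, nrow(images))
  n_img <- nrow(images)

  with_seed(child_seed(seed, paste0("pool_", task)), {
    out <- vector("list", n_observers)
    for (o in seq_len(n_observers)) {
      resp <- truth
      u <- stats::runif(n_img) < amb
      if (any(u)) resp[u] <- labels[sample.int(m, sum(u), replace = TRUE)]
      out[[o]] <- data.frame(task = task,
                             observer_id = sprintf("U%s%02d", substr(task, 1, 1), o),
                             image_id = images$image_id,
                             category = resp, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate the timed categorization experiment
#'
#' Runs every observer of a pool through a trial list. Per trial, each
#' category receives Gaussian evidence with unit variance; the true
#' category's evidence mean is the trial sensitivity
#' d'(t) = (d_asym + boosts) * (1 - exp(-t / tau)) * clarity - difficulty
#' (floored at 0), and the response is the evidence argmax, replaced by a
#' uniform draw with probability `lapse`. Evidence noise mixes an image-level
#' component identical across observers (weight `shared_noise_weight`,
#' re-drawn per presentation, i.e. per image x color) with observer-private
#' noise.
#'
#' Per-image clarity is taken from an `scale_<task>` column when present
#' (the pipeline sets it from realized time-unlimited agreement), otherwise
#' from `1 - ambiguity_<task>`, otherwise 1. Likewise the evidence targets
#' the image's consensus category from a `consensus_<task>` column when
#' present (the modal label of the time-unlimited pool — what the image most
#' looks like to observers), falling back to the generative `true_<task>`
#' label.
#'
#' When `joint_model` couples the two systems and `system` is the model's
#' *dependent* task, a fraction `route_weight` of (non-lapse) responses is
#' produced indirectly: the observer forms a percept of the image's root
#' category (same evidence machinery, same shared-noise stream as the root
#' task's own pool) and responds with the modal dependent category of the
#' coupling row — the generative analogue of inferring one system from the
#' other.
#'
#' @param images Image table.
#' @param trials Trial list from [enumerate_design()] (shared by all
#'   observers, and across task pools, so trials align for correlation
#'   analyses).
#' @param pop An [observer_population()].
#' @param system The [category_system()] being reported.
#' @param seed Integer seed for observer-private randomness.
#' @param joint_model Optional `joint_category_model` enabling routed
#'   responses (see above).
#' @param shared_noise_seed Seed of the image-level noise streams; pass the
#'   same value to both task pools so their shared components coincide.
#' @param shared_noise_stream Optional stream name overriding the default
#'   `"shared_<task>"`; giving two simulated tasks the same stream (and the
#'   same category count) yields common image-level noise, a paired
#'   common-random-numbers design for task comparisons.
#' @return A response table: data frame with columns `task`, `observer_id`,
#'   `image_id`, `duration_ms`, `color`, `viewing`, `response`, `report`,
#'   `true_label`.
#' @export
simulate_timed_experiment <- function(images, trials, pop, system, seed = 1L,
                                      joint_model = NULL,
                                      shared_noise_seed = seed,
                                      shared_noise_stream = NULL) {
  stopifnot(inherits(pop, "observer_population"),
            inherits(system, "category_system"))
  task <- system$task
  labels <- system$labels
  m <- length(labels)
  idx <- match(trials$image_id, images$image_id)
  if (anyNA(idx)) stop_param("trials reference image_ids absent from images")
  n_t <- nrow(trials)

  clarity_of <- function(tk, mm) {
    sc <- images[[paste0("scale_", tk)]]
    if (is.null(sc)) {
      a <- images[[paste0("ambiguity_", tk)]]
      sc <- if (is.null(a)) rep(1, nrow(images)) else 1 - a
    }
    pmin(pmax(sc, 0), 1)
  }

  target_of <- function(tk) {
    images[[paste0("consensus_", tk)]] %||% images[[paste0("true_", tk)]]
  }

  trial_dprime <- function(tk, mm) {
    base <- (pop$d_asym +
               pop$color_boost * (trials$color == "color") +
               pop$stereo_boost * (trials$viewing %in% c("stereo", "reverse_stereo"))) *
      (1 - exp(-trials$duration_ms / pop$tau))
    pmax(0, base * clarity_of(tk, mm)[idx] - images$difficulty[idx])
  }

  shared_noise <- function(tk, mm) {
    stream <- shared_noise_stream %||% paste0("shared_", tk)
    with_seed(child_seed(shared_noise_seed, stream),
              matrix(stats::rnorm(n_t * mm), n_t, mm))
  }

  routed <- !is.null(joint_model) &&
    joint_model$direction != "independent" &&
    identical(task, joint_model$dep_task) && pop$route_weight > 0
  if (routed) {
    root_task <- joint_model$root_task
    root_labels <- rownames(joint_model$coupling)
    m_root <- length(root_labels)
    true_root <- match(target_of(root_task), root_labels)[idx]
    d_root <- trial_dprime(root_task, m_root)
    eta_root <- shared_noise(root_task, m_root)
    # modal dependent category of each coupling row (lexicographic ties)
    dep_order <- order(labels)
    route_map <- apply(joint_model$coupling[, labels[dep_order], drop = FALSE],
                       1, which.max)
    route_map <- dep_order[route_map]
  }

  true_idx <- match(target_of(task), labels)[idx]
  if (anyNA(true_idx)) stop_param("image target labels not in the category system")
  d_trial <- trial_dprime(task, m)
  eta <- shared_noise(task, m)
  w <- pop$shared_noise_weight
  report_levels <- c(mono = "2D", stereo = "3D", reverse_stereo = "3D-reversed")
  true_rep <- match(trials$viewing, names(report_levels))
  d_rep <- pop$report_d_asym * (1 - exp(-trials$duration_ms / pop$report_tau))

  out <- vector("list", pop$n_observers)
  mu_base <- matrix(0, n_t, m)
  for (o in seq_len(pop$n_observers)) {
    out[[o]] <- with_seed(child_seed(seed, sprintf("obs_%s_%03d", task, o)), {
      eps <- matrix(stats::rnorm(n_t * m), n_t, m)
      ev <- sqrt(w) * eta + sqrt(1 - w) * eps
      ev[cbind(seq_len(n_t), true_idx)] <- ev[cbind(seq_len(n_t), true_idx)] + d_trial
      resp <- max.col(ev, ties.method = "first")
      if (routed) {
        eps_r <- matrix(stats::rnorm(n_t * m_root), n_t, m_root)
        ev_r <- sqrt(w) * eta_root + sqrt(1 - w) * eps_r
        ev_r[cbind(seq_len(n_t), true_root)] <-
          ev_r[cbind(seq_len(n_t), true_root)] + d_root
        root_percept <- max.col(ev_r, ties.method = "first")
        take <- stats::runif(n_t) < pop$route_weight
        resp[take] <- route_map[root_percept[take]]
      }
      lap <- stats::runif(n_t) < pop$lapse
      if (any(lap)) resp[lap] <- sample.int(m, sum(lap), replace = TRUE)
      # separate low-sensitivity channel for the viewing-condition report
      ev_rep <- matrix(stats::rnorm(n_t * 3L), n_t, 3L)
      ev_rep[cbind(seq_len(n_t), true_rep)] <-
        ev_rep[cbind(seq_len(n_t), true_rep)] + d_rep
      rep_idx <- max.col(ev_rep, ties.method = "first")
      data.frame(task = task,
                 observer_id = sprintf("T%s%03d", substr(task, 1, 1), o),
                 image_id = trials$image_id,
                 duration_ms = trials$duration_ms,
                 color = trials$color,
                 viewing = trials$viewing,
                 response = labels[resp],
                 report = unname(report_levels[rep_idx]),
                 true_label = labels[true_idx],
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}
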
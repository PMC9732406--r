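#' Joint model coupling the two category systems
#'
#' Builds a generative model of the statistical relationship between a root
#' category system and a dependent category system. Each dependent label is
#' drawn from a conditional row that is a convex mixture of a uniform row and
#' a concentrated row (assigned cyclically across root categories):
#' `coupling_strength = 0` gives independent uniform rows, `1` makes the
#' dependent label a deterministic function of the root label. The `direction`
#' selects which system is the root: under `"sem_to_spat"` semantic category
#' generates spatial structure, under `"spat_to_sem"` the reverse; under
#' `"independent"` the two labels are sampled independently.
#'
#' @param n_root,n_dep Number of root / dependent categories (>= 2).
#' @param coupling_strength Mixture weight in `[0, 1]` of the concentrated row.
#' @param direction `"sem_to_spat"`, `"spat_to_sem"` or `"independent"`.
#' @param seed Integer seed stored with the model (used by samplers that
#'   derive child streams from it).
#' @param marginal Optional probability vector over root categories
#'   (default uniform).
#' @param root_labels,dep_labels Optional label vectors; default to the
#'   standard semantic/spatial labels when the sizes match, else generated
#'   names.
#' @return An object of class `joint_category_model`.
#' @examples
#' m <- build_joint_model(6, 4, 0.8, "sem_to_spat", seed = 7)
#' rowSums(m$coupling)
#' @export
build_joint_model <- function(n_root, n_dep, coupling_strength,
                              direction = c("sem_to_spat", "spat_to_sem", "independent"),
                              seed = 1L, marginal = NULL,
                              root_labels = NULL, dep_labels = NULL) {
  direction <- match.arg(direction)
  if (!is.numeric(n_root) || !is.numeric(n_dep) || n_root < 2 || n_dep < 2)
    stop_param("n_root and n_dep must be counts >= 2")
  if (!is.numeric(coupling_strength) || coupling_strength < 0 || coupling_strength > 1)
    stop_param("coupling_strength must lie in [0, 1]")
  n_root <- as.integer(n_root); n_dep <- as.integer(n_dep)

  root_task <- if (direction == "spat_to_sem") "spatial" else "semantic"
  dep_task <- if (root_task == "semantic") "spatial" else "semantic"
  default_labels <- function(task, n) {
    std <- category_system(task)$labels
    if (length(std) == n) std else paste0(substr(task, 1, 3), seq_len(n))
  }
  root_labels <- root_labels %||% default_labels(root_task, n_root)
  dep_labels <- dep_labels %||% default_labels(dep_task, n_dep)
  stopifnot(length(root_labels) == n_root, length(dep_labels) == n_dep)

  marginal <- marginal %||% rep(1 / n_root, n_root)
  if (length(marginal) != n_root || any(marginal < 0) ||
      abs(sum(marginal) - 1) > 1e-12)
    stop_param("marginal must be a probability vector over the root categories")
  names(marginal) <- root_labels

  coupling <- matrix((1 - coupling_strength) / n_dep, n_root, n_dep,
                     dimnames = list(root_labels, dep_labels))
  for (i in seq_len(n_root)) {
    j <- ((i - 1L) %% n_dep) + 1L
    coupling[i, j] <- coupling[i, j] + coupling_strength
  }

  structure(list(direction = direction, root_task = root_task,
                 dep_task = dep_task, marginal = marginal,
                 coupling = coupling, coupling_strength = coupling_strength,
                 seed = as.integer(seed)),
            class = "joint_category_model")
}

#' @export
print.joint_category_model <- function(x, ...) {
  cat(sprintf("<joint_category_model> direction = %s (%d %s -> %d %s), strength = %.2f\n",
              x$direction, length(x$marginal), x$root_task,
              ncol(x$coupling), x$dep_task, x$coupling_strength))
  invisible(x)
}

#' Sample a synthetic image set
#'
#' Draws per-image true labels in both category systems from a
#' [build_joint_model()] joint model, together with per-task ambiguity values
#' (governing time-unlimited inter-observer disagreement) and an additive
#' difficulty penalty. Under `direction = "independent"` the dependent label
#' is drawn uniformly, ignoring the coupling table.
#'
#' @param model A `joint_category_model`.
#' @param n_images Number of images (default 708).
#' @param seed Integer seed.
#' @param ambiguity Named list with elements `semantic` and `spatial`; each
#'   either a single value in `[0, 1]` (constant ambiguity) or a pair of Beta
#'   shape parameters to sample from.
#' @param difficulty_rate Rate of an exponential difficulty penalty;
#'   `0` (default) gives difficulty 0 for every image.
#' @return A data frame (the image table) with columns `image_id`,
#'   `true_semantic`, `true_spatial`, `difficulty`, `ambiguity_semantic`,
#'   `ambiguity_spatial`.
#' @examples
#' m <- build_joint_model(6, 4, 0.8, "sem_to_spat")
#' img <- sample_image_set(m, 100, seed = 1)
#' table(img$true_semantic, img$true_spatial)
#' @export
sample_image_set <- function(model, n_images = 708L, seed = 1L,
                             ambiguity = list(semantic = c(1.5, 6),
                                              spatial = c(2.5, 4.5)),
                             difficulty_rate = 0) {
  stopifnot(inherits(model, "joint_category_model"))
  if (!is.numeric(n_images) || n_images < 1) stop_param("n_images must be >= 1")
  n_images <- as.integer(n_images)
  root_labels <- names(model$marginal)
  dep_labels <- colnames(model$coupling)
  n_dep <- length(dep_labels)

  with_seed(child_seed(seed, "image_set"), {
    root <- sample.int(length(root_labels), n_images, replace = TRUE,
                       prob = model$marginal)
    dep <- integer(n_images)
    if (model$direction == "independent") {
      dep <- sample.int(n_dep, n_images, replace = TRUE)
    } else {
      for (r in unique(root)) {
        idx <- which(root == r)
        dep[idx] <- sample.int(n_dep, length(idx), replace = TRUE,
                               prob = model$coupling[r, ])
      }
    }
    draw_amb <- function(spec) {
      if (length(spec) == 1L) rep(as.numeric(spec), n_images)
      else stats::rbeta(n_images, spec[1], spec[2])
    }
    amb_sem <- draw_amb(ambiguity$semantic)
    amb_spat <- draw_amb(ambiguity$spatial)
    difficulty <- if (difficulty_rate > 0)
      stats::rexp(n_images, difficulty_rate) else rep(0, n_images)

    df <- data.frame(image_id = seq_len(n_images), stringsAsFactors = FALSE)
    df[[paste0("true_", model$root_task)]] <- root_labels[root]
    df[[paste0("true_", model$dep_task)]] <- dep_labels[dep]
    df$difficulty <- difficulty
    df$ambiguity_semantic <- amb_sem
    df$ambiguity_spatial <- amb_spat
    df[, c("image_id", "true_semantic", "true_spatial", "difficulty",
           "ambiguity_semantic", "ambiguity_spatial")]
  })
}
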
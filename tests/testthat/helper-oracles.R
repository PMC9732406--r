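# Independent oracles and small builders shared across tests.

# Monte-Carlo max-rule m-AFC observer: proportion of trials on which the
# target's evidence (mean dprime) exceeds m - 1 standard-normal draws.
# Independent of the quadrature implementation under test.
mc_pc_mafc <- function(dprime, m, n = 1e6, seed = 1, chunk = 1e6) {
  set.seed(seed)
  hits <- 0
  left <- n
  while (left > 0) {
    k <- min(chunk, left)
    target <- rnorm(k, mean = dprime)
    mx <- rnorm(k)
    for (j in seq_len(m - 2)) mx <- pmax(mx, rnorm(k))
    hits <- hits + sum(target > mx)
    left <- left - k
  }
  hits / n
}

# Builds a label table from a named list observer -> character vector of
# per-image labels (images 1..n in order).
label_table_from <- function(votes, task = "semantic") {
  do.call(rbind, lapply(names(votes), function(o) {
    data.frame(task = task, observer_id = o,
               image_id = seq_along(votes[[o]]), category = votes[[o]],
               stringsAsFactors = FALSE)
  }))
}

# Minimal ground-truth table where the modal label is the generative label.
truth_from_images <- function(images, task, n_voters = 20L) {
  data.frame(image_id = images$image_id,
             modal_category = images[[paste0("true_", task)]],
             agreement = 1, n_voters = n_voters, tie = FALSE,
             stringsAsFactors = FALSE)
}

# Homogeneous image set (no ambiguity, no difficulty) over given labels.
homogeneous_images <- function(n, labels, seed = 1) {
  set.seed(seed)
  data.frame(image_id = seq_len(n),
             true_semantic = sample(labels, n, replace = TRUE),
             true_spatial = sample(labels, n, replace = TRUE),
             difficulty = 0, ambiguity_semantic = 0, ambiguity_spatial = 0,
             stringsAsFactors = FALSE)
}

# Single-cell design: every image at one duration/viewing, both colors.
flat_design <- function(duration = 106.7, colors = c("color", "grayscale")) {
  design_spec(durations_ms = duration, colors = colors, viewing = "mono",
              presentations_per_image = length(colors),
              blocks_per_session = 1L, sessions = length(colors))
}
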
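cpt_2x2 <- function() {
  # per-image modal votes realizing counts {x1: y1 3, y2 1; x2: y1 1, y2 3}
  x <- rep(c("x1", "x2"), each = 4)
  y <- c("y1", "y1", "y1", "y2", "y1", "y2", "y2", "y2")
  lp <- data.frame(task = "spatial", observer_id = "P1", image_id = 1:8,
                   category = x, stringsAsFactors = FALSE)
  lt <- data.frame(task = "semantic", observer_id = "T1", image_id = 1:8,
                   category = y, stringsAsFactors = FALSE)
  conditional_probability_table(lp, lt, alpha = 0)
}

test_that("hand-built 2x2 counts normalize row-wise", {
  cpt <- cpt_2x2()
  expect_equal(unname(cpt$p),
               matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE))
  expect_equal(unname(rowSums(cpt$p)), c(1, 1))
  expect_equal(cpt$predictor_task, "spatial")
  expect_equal(cpt$target_task, "semantic")
})

test_that("deterministic label maps give one-hot rows", {
  img <- 1:60
  x <- rep(c("x1", "x2", "x3"), 20)
  y <- c(x1 = "u", x2 = "v", x3 = "w")[x]
  lp <- data.frame(task = "spatial", observer_id = "P1", image_id = img,
                   category = x, stringsAsFactors = FALSE)
  lt <- data.frame(task = "semantic", observer_id = "T1", image_id = img,
                   category = y, stringsAsFactors = FALSE)
  cpt <- conditional_probability_table(lp, lt, alpha = 0)
  expect_true(all(apply(cpt$p, 1, max) == 1))
})

test_that("independent labels give rows near the target marginal", {
  m <- build_joint_model(6, 4, 0.8, "independent", seed = 2)
  img <- sample_image_set(m, 50000, seed = 2,
                          ambiguity = list(semantic = 0, spatial = 0))
  lp <- data.frame(task = "spatial", observer_id = "P1",
                   image_id = img$image_id, category = img$true_spatial,
                   stringsAsFactors = FALSE)
  lt <- data.frame(task = "semantic", observer_id = "T1",
                   image_id = img$image_id, category = img$true_semantic,
                   stringsAsFactors = FALSE)
  cpt <- conditional_probability_table(lp, lt, alpha = 0)
  marg <- table(lt$category)[colnames(cpt$p)] / nrow(lt)
  for (r in seq_len(nrow(cpt$p)))
    expect_lt(sum(abs(cpt$p[r, ] - as.numeric(marg))) / 2, 0.02)
})

test_that("outer pairing accumulates all vote pairs per image", {
  # one image, 2 predictor votes (x1, x2), 2 target votes (y1, y1):
  # each row of the CPT must be fully concentrated on y1
  lp <- data.frame(task = "spatial",
                   observer_id = c("P1", "P2"), image_id = 1,
                   category = c("x1", "x2"), stringsAsFactors = FALSE)
  lt <- data.frame(task = "semantic",
                   observer_id = c("T1", "T2"), image_id = 1,
                   category = c("y1", "y1"), stringsAsFactors = FALSE)
  cpt <- conditional_probability_table(lp, lt, alpha = 0,
    predictor_system = category_system("spatial", c("x1", "x2")),
    target_system = category_system("semantic", c("y1", "y2")))
  expect_equal(unname(cpt$p[, "y1"]), c(1, 1))
  # total accumulated weight is one per image
  expect_equal(sum(cpt$counts), 1)
})

test_that("Eq.-style scoring reproduces the hand example and its invariances", {
  cpt <- structure(list(
    p = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE,
               dimnames = list(c("open", "closed"), c("beach", "road"))),
    predictor_labels = c("open", "closed"), target_labels = c("beach", "road"),
    predictor_task = "spatial", target_task = "semantic",
    alpha = 0, pairing = "outer"), class = "cond_prob_table")
  pr <- predict_category(cpt, c("open", "open", "closed"))
  expect_equal(unname(pr$scores), c(1.6, 1.4))
  expect_equal(pr$category, "beach")
  expect_false(pr$tie)

  # order invariance and duplication scaling
  pr2 <- predict_category(cpt, c("closed", "open", "open"))
  expect_equal(pr2$scores, pr$scores)
  pr3 <- predict_category(cpt, rep(c("open", "open", "closed"), 3))
  expect_equal(pr3$scores, 3 * pr$scores)
  expect_equal(pr3$category, pr$category)

  # n = 1: mode of the conditional row
  expect_equal(predict_category(cpt, "closed")$category, "road")
  expect_error(predict_category(cpt, character(0)), "empty")
  expect_error(predict_category(cpt, "lake"), "alphabet")
})

test_that("one-hot tables reduce prediction to majority mapping", {
  cpt <- structure(list(
    p = matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(c("x1", "x2"), c("u", "v"))),
    predictor_labels = c("x1", "x2"), target_labels = c("u", "v"),
    predictor_task = "spatial", target_task = "semantic",
    alpha = 0, pairing = "outer"), class = "cond_prob_table")
  expect_equal(predict_category(cpt, c("x1", "x1", "x2"))$category, "u")
  expect_equal(predict_category(cpt, c("x1", "x2", "x2"))$category, "v")
  even <- predict_category(cpt, c("x1", "x2"))
  expect_true(even$tie)
  expect_equal(even$category, "u")  # lexicographic tie-break
})

test_that("zero-support predictor rows are unusable at alpha = 0 but smoothed otherwise", {
  lp <- data.frame(task = "spatial", observer_id = "P1", image_id = 1:4,
                   category = "x1", stringsAsFactors = FALSE)
  lt <- data.frame(task = "semantic", observer_id = "T1", image_id = 1:4,
                   category = c("u", "u", "v", "v"), stringsAsFactors = FALSE)
  psys <- category_system("spatial", c("x1", "x2"))
  tsys <- category_system("semantic", c("u", "v"))
  cpt0 <- conditional_probability_table(lp, lt, alpha = 0,
                                        predictor_system = psys,
                                        target_system = tsys)
  expect_true(all(is.na(cpt0$p["x2", ])))
  expect_error(predict_category(cpt0, "x2"), "zero support")
  cpt1 <- conditional_probability_table(lp, lt, alpha = 1,
                                        predictor_system = psys,
                                        target_system = tsys)
  expect_equal(unname(cpt1$p["x2", ]), c(0.5, 0.5))
})

test_that("model_predictions scores every (image, duration) cell", {
  labels <- c("A", "B", "C", "D")
  images <- homogeneous_images(24, labels, seed = 6)
  trials <- enumerate_design(flat_design(c(25, 100)), 24, seed = 2)
  pop <- observer_population(3, d_asym = 50, tau = 0.1, lapse = 0, seed = 3)
  sys <- category_system("spatial", labels)
  resp <- simulate_timed_experiment(images, trials, pop, sys, seed = 4)
  cpt <- structure(list(
    p = diag(4), predictor_labels = labels, target_labels = labels,
    predictor_task = "spatial", target_task = "semantic",
    alpha = 0, pairing = "outer"), class = "cond_prob_table")
  dimnames(cpt$p) <- list(labels, labels)
  preds <- model_predictions(cpt, resp)
  # one row per observed (image, duration) cell; images whose two color
  # presentations fell at different durations contribute two cells
  cells <- unique(trials[, c("image_id", "duration_ms")])
  expect_equal(nrow(preds), nrow(cells))
  expect_equal(sort(unique(preds$duration_ms)), c(25, 100))
  # identity CPT + error-free observers: prediction = true label
  expect_equal(preds$predicted_category,
               images$true_spatial[preds$image_id])
  # all 3 observers contribute each of the cell's 1 or 2 presentations
  expect_setequal(unique(preds$n_observers_used), c(3L, 6L))
})

test_that("model_performance spans chance to ceiling", {
  labels <- c("A", "B", "C", "D", "E", "F")
  images <- homogeneous_images(120, labels, seed = 7)
  truth <- truth_from_images(images, "semantic")
  perfect <- data.frame(image_id = rep(images$image_id, 2),
                        duration_ms = rep(c(25, 100), each = 120),
                        predicted_category = rep(images$true_semantic, 2),
                        stringsAsFactors = FALSE)
  class(perfect) <- c("model_prediction", "data.frame")
  mp <- model_performance(perfect, truth, m = 6, n_boot = 30, seed = 1)
  expect_equal(mp$series$mean, rep(dprime_mafc(1 - 1 / 240, 6), 2))

  set.seed(9)
  rand <- perfect
  rand$predicted_category <- sample(labels, nrow(rand), replace = TRUE)
  mr <- model_performance(rand, truth, m = 6, n_boot = 30, seed = 1)
  expect_true(all(abs(mr$series$mean) < 0.45))
})
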
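test_that("observer population validates its parameters", {
  expect_error(observer_population(10, lapse = 0.5), "lapse")
  expect_error(observer_population(10, shared_noise_weight = 1.5), "shared_noise_weight")
  expect_error(observer_population(10, tau = 0), "tau")
})

test_that("zero ambiguity gives unanimous unlimited pools", {
  m <- build_joint_model(6, 4, 0.5, "sem_to_spat", seed = 1)
  img <- sample_image_set(m, 60, seed = 1,
                          ambiguity = list(semantic = 0, spatial = 0))
  pool <- simulate_unlimited_pool(img, category_system("semantic"), 20, seed = 2)
  expect_equal(nrow(pool), 60 * 20)
  gt <- ground_truth_table(pool)
  expect_true(all(gt$agreement == 1))
  expect_equal(gt$modal_category, img$true_semantic)
})

test_that("full ambiguity reproduces the uniform-vote mode statistic", {
  m <- build_joint_model(4, 4, 0, "sem_to_spat", seed = 1)
  img <- sample_image_set(m, 400, seed = 3,
                          ambiguity = list(semantic = 1, spatial = 1))
  pool <- simulate_unlimited_pool(img, category_system("spatial"), 20, seed = 4)
  gt <- ground_truth_table(pool)
  # oracle: expected mode proportion of 20 uniform draws over 4 labels
  set.seed(99)
  oracle <- mean(replicate(4000, max(tabulate(sample.int(4, 20, TRUE), 4)) / 20))
  expect_lt(abs(mean(gt$agreement) - oracle), 0.01)
})

test_that("timed responses are bit-identical under a fixed seed", {
  m <- build_joint_model(6, 4, 0.8, "sem_to_spat", seed = 5)
  img <- sample_image_set(m, 36, seed = 5)
  tr <- enumerate_design(flat_design(c(25, 100)), 36, seed = 5)
  pop <- observer_population(3, seed = 5)
  sys <- category_system("semantic")
  a <- simulate_timed_experiment(img, tr, pop, sys, seed = 6, joint_model = m)
  b <- simulate_timed_experiment(img, tr, pop, sys, seed = 6, joint_model = m)
  expect_identical(a, b)
  expect_equal(nrow(a), 36 * 2 * 3)
})

test_that("flat evidence yields chance accuracy; saturated evidence yields ceiling", {
  labels <- c("A", "B", "C", "D")
  images <- homogeneous_images(1500, labels, seed = 7)
  truth <- truth_from_images(images, "spatial")
  trials <- enumerate_design(flat_design(), 1500, seed = 7)
  sys <- category_system("spatial", labels)

  flat <- observer_population(1, d_asym = 0, color_boost = 0,
                              stereo_boost = 0, lapse = 0)
  r0 <- simulate_timed_experiment(images, trials, flat, sys, seed = 8)
  acc0 <- mean(r0$response == truth$modal_category[match(r0$image_id, truth$image_id)])
  expect_lt(abs(acc0 - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(r0)))

  sat <- observer_population(1, d_asym = 50, tau = 1e-3, lapse = 0)
  r1 <- simulate_timed_experiment(images, trials, sat, sys, seed = 9)
  expect_gt(mean(r1$response == truth$modal_category[match(r1$image_id, truth$image_id)]),
            0.999)
})

test_that("mean accuracy increases with presentation duration", {
  m <- build_joint_model(6, 4, 0.6, "sem_to_spat", seed = 1)
  sys <- category_system("semantic")
  increasing <- 0L
  for (s in 1:5) {
    img <- sample_image_set(m, 120, seed = 20 + s)
    tr <- enumerate_design(design_spec(), 120, seed = 20 + s)
    pop <- observer_population(6, seed = s)
    resp <- simulate_timed_experiment(img, tr, pop, sys, seed = 30 + s)
    truth <- truth_from_images(img, "semantic")
    acc <- tapply(resp$response == truth$modal_category[
      match(resp$image_id, truth$image_id)], resp$duration_ms, mean)
    increasing <- increasing + all(diff(acc[order(as.numeric(names(acc)))]) > 0)
  }
  expect_gte(increasing, 4L)
})

test_that("shared noise streams coincide across pools and drive correlation", {
  labels <- c("A", "B", "C", "D")
  images <- homogeneous_images(1200, labels, seed = 9)
  trials <- enumerate_design(flat_design(), 1200, seed = 9)
  sys <- category_system("semantic", labels)
  truth <- truth_from_images(images, "semantic")
  pop <- observer_population(1, d_asym = 1, tau = 1e-3, lapse = 0,
                             shared_noise_weight = 0.6)
  # two separately simulated "pools" with the same shared-noise seed
  a <- simulate_timed_experiment(images, trials, pop, sys, seed = 100,
                                 shared_noise_seed = 55)
  b <- simulate_timed_experiment(images, trials, pop, sys, seed = 200,
                                 shared_noise_seed = 55)
  expect_gt(dvc(a, b, truth)$value, 0.1)
  # different shared-noise seeds decorrelate them
  c2 <- simulate_timed_experiment(images, trials, pop, sys, seed = 200,
                                  shared_noise_seed = 56)
  expect_lt(abs(dvc(a, c2, truth)$value), 0.08)
})

test_that("routed responses track the coupling map in the dependent task", {
  m <- build_joint_model(6, 4, 1, "sem_to_spat", seed = 2)
  img <- sample_image_set(m, 240, seed = 11,
                          ambiguity = list(semantic = 0, spatial = 0))
  tr <- enumerate_design(flat_design(), 240, seed = 11)
  sys_dep <- category_system("spatial")
  # spatial evidence is flat: only the routed channel carries information
  pop <- observer_population(1, d_asym = 50, tau = 1e-3, lapse = 0,
                             route_weight = 1)
  img$scale_spatial <- 0
  resp <- simulate_timed_experiment(img, tr, pop, sys_dep, seed = 12,
                                    joint_model = m)
  # deterministic coupling + perfect root percepts => perfect spatial responses
  expect_equal(mean(resp$response == img$true_spatial[
    match(resp$image_id, img$image_id)]), 1)
  # without routing the same observer is at chance
  pop0 <- observer_population(1, d_asym = 50, tau = 1e-3, lapse = 0,
                              route_weight = 0)
  resp0 <- simulate_timed_experiment(img, tr, pop0, sys_dep, seed = 12,
                                     joint_model = m)
  acc0 <- mean(resp0$response == img$true_spatial[
    match(resp0$image_id, img$image_id)])
  expect_lt(abs(acc0 - 0.25), 0.06)
})

test_that("viewing-condition report is far less sensitive than categorization", {
  m <- build_joint_model(6, 4, 0.8, "sem_to_spat", seed = 3)
  img <- sample_image_set(m, 708, seed = 13,
                          ambiguity = list(semantic = 0.1, spatial = 0.2))
  tr <- enumerate_design(design_spec(), 708, seed = 13)
  pop <- observer_population(3, seed = 13)
  resp <- simulate_timed_experiment(img, tr, pop, category_system("semantic"),
                                    seed = 14)
  rep_truth <- c(mono = "2D", stereo = "3D", reverse_stereo = "3D-reversed")
  acc_rep <- mean(resp$report == rep_truth[resp$viewing])
  acc_cat <- mean(resp$response == img$true_semantic[match(resp$image_id, img$image_id)])
  expect_gt(acc_cat, acc_rep + 0.05)
  expect_gt(acc_rep, 1 / 3)  # above chance, but weak
})
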
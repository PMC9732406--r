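make_truth <- function(agreement, modal = "A", n_voters = 20L) {
  data.frame(image_id = seq_along(agreement), modal_category = modal,
             agreement = agreement, n_voters = n_voters, tie = FALSE,
             stringsAsFactors = FALSE)
}

test_that("binning assigns each image once and respects (0, 1]", {
  tr <- make_truth(c(0.25, 0.5, 0.75, 1, 1, 0.5))
  b <- bin_by_agreement(tr, c(0, 0.5, 1))
  expect_equal(b$assignment$bin, c(1, 1, 2, 2, 2, 1))
  expect_equal(b$counts, c(3, 3))
  expect_equal(b$proportions, c(0.5, 0.5))
  expect_error(bin_by_agreement(make_truth(c(0.5, 1.2)), c(0, 1)), "0, 1")
  expect_error(bin_by_agreement(make_truth(c(0, 0.5)), c(0, 1)), "0, 1")
})

test_that("unanimous agreement occupies a single top bin", {
  tr <- make_truth(rep(1, 30))
  b <- bin_by_agreement(tr, c(0, 0.5, 1))
  expect_equal(b$proportions, c(0, 1))
})

test_that("20-voter agreements land on the attainable grid with one bin each", {
  # attainable values k/20 for k = 1..20; per-value edges separate them all
  tr <- make_truth(rep(seq_len(20) / 20, each = 25))
  edges <- agreement_bin_edges(tr, n_voters = 20, min_images = 20)
  expect_equal(edges, c(0, seq_len(20) / 20))
  b <- bin_by_agreement(tr, edges)
  expect_equal(b$counts, rep(25, 20))
})

test_that("bin edges merge upward until every task reaches the minimum count", {
  skewed <- make_truth(c(rep(0.05, 3), rep(0.5, 30), rep(1, 30)))
  edges <- agreement_bin_edges(skewed, n_voters = 20, min_images = 20)
  b <- bin_by_agreement(skewed, edges)
  expect_true(all(b$counts[b$counts > 0] >= 20))
  # identical agreement vectors in two tasks give identical proportions
  e2 <- agreement_bin_edges(list(skewed, skewed), n_voters = 20)
  expect_equal(bin_by_agreement(skewed, e2)$proportions,
               bin_by_agreement(skewed, e2)$proportions)
})

test_that("shared weights average the two histograms over joint bins", {
  tr_a <- make_truth(rep(c(0.25, 0.75), c(40, 0)))
  tr_b <- make_truth(rep(c(0.25, 0.75), c(20, 20)))
  edges <- c(0, 0.5, 1)
  ba <- bin_by_agreement(tr_a, edges)
  bb <- bin_by_agreement(tr_b, edges)
  # prop_a = (1, 0), prop_b = (0.5, 0.5): only bin 1 jointly occupied
  expect_equal(shared_bin_weights(ba, bb), c(1, 0))

  tr_a2 <- make_truth(rep(c(0.25, 0.75), c(40, 1)))
  ba2 <- bin_by_agreement(tr_a2, edges)
  w <- shared_bin_weights(ba2, bb)
  avg <- (ba2$proportions + bb$proportions) / 2
  expect_equal(w, avg / sum(avg))

  # identical distributions reproduce themselves
  expect_equal(shared_bin_weights(bb, bb), bb$proportions)

  # disjoint occupancy errors
  bc <- bin_by_agreement(make_truth(rep(0.75, 10)), edges)
  bd <- bin_by_agreement(make_truth(rep(0.25, 10)), edges)
  expect_error(shared_bin_weights(bc, bd), "no agreement bin")
})

sim_norm_fixture <- function(seed = 1) {
  labels <- c("A", "B", "C", "D")
  images <- homogeneous_images(96, labels, seed = seed)
  images$ambiguity_semantic <- rep(c(0.1, 0.6), each = 48)
  truth <- truth_from_images(images, "semantic")
  truth$agreement <- rep(c(0.9, 0.45), each = 48)
  trials <- enumerate_design(flat_design(c(25, 100)), 96, seed = seed)
  pop <- observer_population(5, lapse = 0, seed = seed)
  resp <- simulate_timed_experiment(images, trials, pop,
                                    category_system("semantic", labels),
                                    seed = seed)
  list(resp = resp, truth = truth, m = 4)
}

test_that("a single bin reproduces the unnormalized series exactly", {
  fx <- sim_norm_fixture()
  b <- bin_by_agreement(fx$truth, c(0, 1))
  ns <- normalized_dprime(fx$resp, fx$truth, b, 1, fx$m)
  us <- dprime_series(fx$resp, fx$truth, fx$m)
  expect_equal(ns$series$mean, us$series$mean)
  expect_equal(ns$series$se, us$series$se)
})

test_that("weights concentrated on one bin recover that bin's d'", {
  fx <- sim_norm_fixture(2)
  b <- bin_by_agreement(fx$truth, c(0, 0.5, 1))
  ns_top <- normalized_dprime(fx$resp, fx$truth, b, c(0, 1), fx$m)
  easy <- fx$resp[fx$resp$image_id <= 48, ]
  us <- dprime_series(easy, fx$truth, fx$m)
  expect_equal(ns_top$series$mean, us$series$mean)
})

test_that("normalized d' is a convex combination of per-bin values", {
  fx <- sim_norm_fixture(3)
  b <- bin_by_agreement(fx$truth, c(0, 0.5, 1))
  w <- c(0.5, 0.5)
  ns <- normalized_dprime(fx$resp, fx$truth, b, w, fx$m)
  lo <- normalized_dprime(fx$resp, fx$truth, b, c(1, 0), fx$m)
  hi <- normalized_dprime(fx$resp, fx$truth, b, c(0, 1), fx$m)
  per <- merge(merge(ns$per_observer, lo$per_observer,
                     by = c("observer_id", "duration_ms")),
               hi$per_observer, by = c("observer_id", "duration_ms"))
  expect_true(all(per$value.x >= pmin(per$value.y, per$value) - 1e-12))
  expect_true(all(per$value.x <= pmax(per$value.y, per$value) + 1e-12))
})

test_that("normalized d' is invariant to duplicating all trials", {
  fx <- sim_norm_fixture(4)
  b <- bin_by_agreement(fx$truth, c(0, 0.5, 1))
  w <- c(0.4, 0.6)
  base <- normalized_dprime(fx$resp, fx$truth, b, w, fx$m)
  doubled <- rbind(fx$resp, fx$resp)
  dup <- normalized_dprime(doubled, fx$truth, b, w, fx$m)
  expect_equal(dup$series$mean, base$series$mean, tolerance = 1e-10)
})

test_that("bootstrap equalization is deterministic and consistent with the analytic estimate", {
  fx <- sim_norm_fixture(5)
  b <- bin_by_agreement(fx$truth, c(0, 0.5, 1))
  bo <- bootstrap_equalize(fx$resp, fx$truth, b, fx$m, n_boot = 60, seed = 9)
  expect_equal(dim(bo$replicates), c(60L, 2L))
  bo2 <- bootstrap_equalize(fx$resp, fx$truth, b, fx$m, n_boot = 60, seed = 9)
  expect_identical(bo$replicates, bo2$replicates)
  expect_error(bootstrap_equalize(fx$resp, fx$truth, b, fx$m, n_boot = 1), "n_boot")

  # equal-count resampling with uniform weights matches the uniform-weight
  # analytic estimate within bootstrap error
  ns <- normalized_dprime(fx$resp, fx$truth, b, c(0.5, 0.5), fx$m)
  for (i in seq_along(bo$cells)) {
    se_b <- stats::sd(bo$replicates[, i])
    expect_lt(abs(bo$mean[i] - ns$series$mean[i]), 3 * se_b)
  }
})
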
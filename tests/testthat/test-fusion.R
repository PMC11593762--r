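test_that("shannon_entropy reproduces reference values in both conventions", {
  expect_equal(shannon_entropy(rep(1, 4), "raw_bits"), 2)
  expect_equal(shannon_entropy(rep(1, 4), "normalized"), 1)
  expect_equal(shannon_entropy(c(1, 0, 0, 0), "raw_bits"), 0)
  expect_equal(shannon_entropy(c(1, 0, 0, 0), "normalized"), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25), "raw_bits"), 1.5)
  expect_error(shannon_entropy(c(0, 0, 0)), "all-zero")
  expect_error(shannon_entropy(c(0.5, -0.1)), "negative")
})

test_that("shannon_entropy is scale- and permutation-invariant", {
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(2:8, 1))
    c <- runif(1, 0.1, 50)
    expect_equal(shannon_entropy(v), shannon_entropy(c * v), tolerance = 1e-12)
    expect_equal(shannon_entropy(v), shannon_entropy(sample(v)),
                 tolerance = 1e-12)
  }
})

test_that("entropy_weights matches Eq-style hand arithmetic and normalizes", {
  w <- entropy_weights(c(m1 = 0.4, m2 = 0.8))
  expect_equal(w$raw_weight, c(0.75, 0.25))
  expect_equal(w$normalized_weight, c(0.75, 0.25))
  expect_false(attr(w, "degenerate"))

  w2 <- entropy_weights(c(a = 0.6, b = 0.6))
  expect_equal(w2$normalized_weight, c(0.5, 0.5))

  # fully uninformative ensemble: uniform fallback, flagged
  w3 <- entropy_weights(c(a = 1, b = 1))
  expect_true(attr(w3, "degenerate"))
  expect_equal(w3$normalized_weight, c(0.5, 0.5))

  expect_error(entropy_weights(c(a = 0.5)), "ensemble_size_error")
  expect_error(entropy_weights(c(a = 0.5, b = NaN)), "non-finite")
})

test_that("normalized weights sum to 1 and two-model normalization is the identity", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    H <- runif(n, 0, 0.95)
    w <- entropy_weights(stats::setNames(H, paste0("m", 1:n)))
    expect_equal(sum(w$normalized_weight), 1, tolerance = 1e-12)
    if (n == 2) expect_identical(w$raw_weight, w$normalized_weight)
  }
})

test_that("decreasing one model's entropy never decreases its weight", {
  set.seed(9)
  for (i in 1:30) {
    H <- runif(3, 0, 0.9)
    w1 <- entropy_weights(stats::setNames(H, c("a", "b", "c")))
    H2 <- H; H2[1] <- H[1] - runif(1, 0, H[1])
    w2 <- entropy_weights(stats::setNames(H2, c("a", "b", "c")))
    expect_gte(w2$normalized_weight[1] + 1e-12, w1$normalized_weight[1])
  }
})

test_that("fuse is a voxelwise convex combination with exact reference points", {
  p1 <- model_prediction("a", array(1, c(1, 1, 2)))
  p2 <- model_prediction("b", array(c(0, 1), c(1, 1, 2)))
  w <- entropy_weights(c(a = 0.4, b = 0.8))   # 0.75 / 0.25
  f <- fuse(list(p1, p2), w)
  expect_equal(as.vector(f$data), c(0.75, 1))

  # identical predictions are a fixed point for any weights
  same <- array(runif(8), c(2, 2, 2))
  f2 <- fuse(list(model_prediction("a", voxel_grid(same, "score")),
                  model_prediction("b", voxel_grid(same, "score"))), w)
  expect_equal(f2$data, same, tolerance = 1e-12)

  expect_error(fuse(list(p1, model_prediction("c", array(0, c(1, 1, 2)))), w),
               "model_id_mismatch_error")
  expect_error(
    fuse(list(p1, model_prediction("b", array(0, c(1, 2, 1)))), w),
    "shape_mismatch_error")
})

test_that("fused scores stay inside the voxelwise min/max envelope", {
  set.seed(15)
  for (i in 1:20) {
    shape <- c(3, 6, 6)
    n <- sample(2:4, 1)
    preds <- lapply(seq_len(n), function(j)
      model_prediction(paste0("m", j),
                       voxel_grid(array(runif(prod(shape)), shape), "score")))
    w <- entropy_weights(stats::setNames(runif(n, 0, 0.9), paste0("m", 1:n)))
    f <- fuse(preds, w)$data
    lo <- Reduce(pmin, lapply(preds, grid_data))
    hi <- Reduce(pmax, lapply(preds, grid_data))
    expect_true(all(f >= lo - 1e-12) && all(f <= hi + 1e-12))
  }
})

test_that("binary-input fusion lies between intersection and union", {
  set.seed(21)
  for (thr in c(0.25, 0.5, 0.75, 1)) {
    shape <- c(3, 6, 6)
    masks <- lapply(1:3, function(j) random_mask(shape, 0.4))
    preds <- lapply(1:3, function(j) model_prediction(paste0("m", j), masks[[j]]))
    w <- entropy_weights(stats::setNames(runif(3, 0, 0.9), paste0("m", 1:3)))
    fm <- binarize(fuse(preds, w), thr)$data
    inter <- Reduce(function(a, b) a * b, masks)
    un <- Reduce(function(a, b) pmax(a, b), masks)
    expect_true(all(fm >= inter))
    expect_true(all(fm <= un))
  }
})

test_that("binarize applies the inclusive threshold rule", {
  s <- voxel_grid(array(c(0.75, 0.5, 0.49, 0), c(1, 2, 2)), "score")
  expect_equal(as.vector(binarize(s, 0.5)$data), c(1, 1, 0, 0))
  expect_error(binarize(s, 0), "threshold_error")
  expect_error(binarize(s, 1.2), "threshold_error")
})

test_that("calibrate_and_fuse: full symmetry gives 0.5/0.5 and reproduces shared target", {
  set.seed(25)
  target <- random_mask(c(3, 8, 8), 0.3)
  calib_pred <- random_mask(c(3, 8, 8), 0.3)
  truth <- ground_truth(random_mask(c(3, 8, 8), 0.3))
  calibration <- list(
    m1 = list(pred = model_prediction("m1", calib_pred), truth = truth),
    m2 = list(pred = model_prediction("m2", calib_pred), truth = truth))
  targets <- list(model_prediction("m1", target), model_prediction("m2", target))
  res <- calibrate_and_fuse(calibration, targets)
  expect_equal(res$weights$normalized_weight, c(0.5, 0.5))
  expect_identical(res$fused_mask$data, target)
})

test_that("weights follow the entropy of the calibration metric profile", {
  # A perfect calibration gives the all-ones metric vector, i.e. a uniform
  # distribution over the panel: maximal entropy. An all-zero prediction
  # produces a spread-out vector with strictly lower entropy, so under
  # lower-entropy-earns-more weighting it receives the larger weight. The
  # weights track profile dispersion, not segmentation quality per se.
  set.seed(37)
  truth_arr <- random_mask(c(3, 8, 8), 0.3)
  truth <- ground_truth(truth_arr)
  mv_perfect <- metric_vector(model_prediction("p", truth_arr), truth)
  mv_zero <- metric_vector(model_prediction("z", array(0, dim(truth_arr))),
                           truth)
  H_perfect <- shannon_entropy(mv_perfect)
  H_zero <- shannon_entropy(mv_zero)
  expect_equal(H_perfect, 1)          # uniform all-ones panel
  expect_lt(H_zero, 1)
  w <- entropy_weights(c(p = H_perfect, z = H_zero))
  expect_gt(w$normalized_weight[w$model_id == "z"],
            w$normalized_weight[w$model_id == "p"])
  # the end-to-end path agrees with the hand-assembled weights
  calibration <- list(
    p = list(pred = model_prediction("p", truth_arr), truth = truth),
    z = list(pred = model_prediction("z", array(0, dim(truth_arr))),
             truth = truth))
  targets <- list(model_prediction("p", truth_arr),
                  model_prediction("z", array(0, dim(truth_arr))))
  res <- calibrate_and_fuse(calibration, targets)
  expect_equal(res$weights$normalized_weight,
               w$normalized_weight[match(res$weights$model_id, w$model_id)],
               tolerance = 1e-12)
})

test_that("complementary-miss fusion recovers the union at threshold 0.5", {
  set.seed(31)
  gt <- generate_ground_truth(phantom_spec(shape = c(24, 48, 48),
                                           n_objects = 4, seed = 31))
  sc <- scenario_complementary_fn(gt, 1, seed = 31)
  calib <- degrade(gt, degradation_spec(boundary_radius = -1, seed = 31))
  calibration <- list(
    m1 = list(pred = model_prediction("m1", grid_data(calib)), truth = gt),
    m2 = list(pred = model_prediction("m2", grid_data(calib)), truth = gt))
  res <- calibrate_and_fuse(calibration, sc)
  expect_identical(res$fused_mask$data, grid_data(gt))
  expect_lt(dice(confusion_counts(sc[[1]], gt)), 1)
  expect_lt(dice(confusion_counts(sc[[2]], gt)), 1)
  expect_equal(dice(confusion_counts(res$fused_mask, gt)), 1)
})

test_that("equal-weight fusion dominates individual Dice on complementary misses", {
  set.seed(33)
  for (i in 1:5) {
    gt <- generate_ground_truth(phantom_spec(shape = c(20, 40, 40),
                                             n_objects = 4, seed = 100 + i))
    sc <- scenario_complementary_fn(gt, 1, seed = i)
    w <- entropy_weights(c(m1 = 0.5, m2 = 0.5))
    fm <- binarize(fuse(sc, w), 0.5)
    d_f <- dice(confusion_counts(fm, gt))
    d1 <- dice(confusion_counts(sc[[1]], gt))
    d2 <- dice(confusion_counts(sc[[2]], gt))
    expect_gte(d_f, max(d1, d2))
  }
})

test_that("weight report serializes entropies, weights and the degenerate flag", {
  dir <- withr::local_tempdir()
  w <- entropy_weights(c(m1 = 0.4, m2 = 0.8))
  p <- file.path(dir, "w.json")
  write_weight_report(w, p)
  back <- jsonlite::read_json(p)
  expect_false(back$degenerate)
  expect_equal(back$models[[1]]$normalized_weight, 0.75)
  expect_equal(back$models[[2]]$model_id, "m2")
})
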
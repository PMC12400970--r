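# a tiny trained model + data reused across attribution tests
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      es <- make_separable_epochs(n_trials = 120, amplitude = 8, sd = 0.5,
                                  seed = 12)
      fit <- train_classifier(build_model(tiny_model_config(seed = 3)),
                              es, NULL, quick_train_config(), "label")
      cache <<- list(es = es, fit = fit)
    }
    cache
  }
})

test_that("per-trial maps are rectified, normalized and input-shaped", {
  fx <- trained_fixture()
  gs <- grad_cam(fx$fit, fx$es)
  expect_equal(dim(gs$maps), c(120, 8, 64))
  expect_gte(min(gs$maps), 0)
  expect_lte(max(gs$maps), 1)
  per_trial_max <- apply(gs$maps, 1, max)
  expect_true(all(per_trial_max %in% c(0, 1)))  # minmax or all-zero
})

test_that("grand-mean attribution concentrates on the planted window", {
  fx <- trained_fixture()
  gm <- aggregate_maps(grad_cam(fx$fit, fx$es), "grand_mean")
  # planted effect: channels 1-2, Gaussian bump around sample 21 of 64
  t_window <- c(21 - 8, 21 + 8) / 250 * 1000
  ratio <- window_mass_ratio(gm, c("ch1", "ch2"), t_window[1],
                             t_window[2])
  expect_gt(ratio, 1.5)
})

test_that("constant-in-time block-2 activations give a temporally flat map", {
  fx <- trained_fixture()
  m <- fx$fit
  # block 1's batch norm swallows its input (scale 0, positive shift), so
  # block 2 receives time-constant activations whatever the epoch contains
  m$weights$g1[] <- 0
  m$weights$b1[] <- 3
  m$weights$Wd[] <- 0.1      # positive readout -> positive map weights
  gs <- grad_cam(m, fx$es[1:5])
  interior <- 9:56           # away from convolution edge effects
  for (i in 1:5) {
    mp <- gs$maps[i, , interior]
    expect_gt(max(mp), 0)
    expect_lt(max(apply(mp, 1, function(r) diff(range(r)))), 1e-8)
  }
})

test_that("a model with zero readout yields all-zero maps and a warning", {
  fx <- trained_fixture()
  m <- fx$fit
  m$weights$Wd[] <- 0
  expect_warning(gs <- grad_cam(m, fx$es[1:4]), "all zero")
  expect_true(all(gs$maps == 0))
})

test_that("aggregation averages, renormalizes and ignores order", {
  m1 <- matrix(stats::runif(12), 3, 4)
  m1[1, 1] <- 0                      # maps carry true zeros (post-ReLU)
  m1 <- m1 / max(m1)
  same <- aggregate_maps(list(m1, m1, m1))
  expect_equal(same$importance, m1, tolerance = 1e-12)
  zero <- matrix(0, 3, 4)
  half <- aggregate_maps(list(m1, zero))
  expect_equal(half$importance, (m1 / 2) / max(m1 / 2), tolerance = 1e-12)
  m2 <- matrix(stats::runif(12), 3, 4)
  expect_equal(aggregate_maps(list(m1, m2))$importance,
               aggregate_maps(list(m2, m1))$importance)
  expect_error(aggregate_maps(list()), "empty")
  expect_error(aggregate_maps(list(m1, matrix(0, 2, 2))), "shape")
})

test_that("subject-level aggregation returns one map per participant", {
  fx <- trained_fixture()
  gs <- grad_cam(fx$fit, fx$es)
  subj <- aggregate_maps(gs, "subject_mean")
  expect_length(subj, 2)
  expect_s3_class(subj[[1]], "attribution_map")
})

test_that("run median is the element-wise median across repetitions", {
  base <- matrix(0, 2, 3)
  ones <- base + 1
  med <- run_median(list(base, base, ones, ones, ones))
  expect_equal(med$importance, ones)
  m1 <- matrix(stats::runif(6), 2, 3)
  expect_equal(run_median(list(m1, m1, m1, m1, m1))$importance, m1)
  expect_equal(run_median(list(m1))$importance, m1)
  expect_error(run_median(list(m1, matrix(0, 3, 3))), "shape")
})

test_that("window mass is exact on uniform and concentrated maps", {
  imp <- matrix(1, 10, 100)
  map <- eegdecode:::new_attribution_map(
    imp, paste0("ch", 1:10), seq(0, 0.99, by = 0.01), "grand-mean", 1)
  # one channel x 10% of the samples = 1% of the cells
  expect_equal(window_mass(map, "ch1", 0, 99), 0.01, tolerance = 1e-12)
  expect_equal(window_mass_ratio(map, "ch1", 0, 99), 1, tolerance = 1e-6)
  conc <- imp * 0
  conc[3, 40:49] <- 1
  map2 <- eegdecode:::new_attribution_map(
    conc, paste0("ch", 1:10), seq(0, 0.99, by = 0.01), "grand-mean", 1)
  expect_equal(window_mass(map2, "ch3", 390, 490), 1)
  expect_error(window_mass(map, "ch1", 2000, 3000), "empty time window")
  expect_error(window_mass(map, "nope", 0, 99), "unknown channel")
})

test_that("min-max normalization is idempotent", {
  m <- matrix(stats::runif(20, 2, 7), 4, 5)
  once <- eegdecode:::minmax_norm(m)
  expect_equal(eegdecode:::minmax_norm(once), once)
  expect_equal(range(once), c(0, 1))
  expect_equal(eegdecode:::minmax_norm(matrix(3, 2, 2)),
               matrix(0, 2, 2))
})
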
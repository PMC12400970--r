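test_that("parameter count matches the layer-by-layer arithmetic", {
  cfg <- model_config(n_classes = 2, n_channels = 61, n_samples = 251,
                      F1 = 8, temporal_kernel_len = 64, D = 2, F2 = 16,
                      pool_sizes = c(4, 8), sep_kernel_len = 16)
  m <- build_model(cfg)
  # hand computation: temporal 8*64; depthwise spatial 16*61; pointwise
  # 16*16; BN 2*16; separable depthwise 16*16 + pointwise 16*16 + BN 2*16;
  # dense 2*(16*7)+2 with pooled lengths 251 %/% 4 = 62, 62 %/% 8 = 7
  by_hand <- 8 * 64 + (8 * 2) * 61 + 16 * (8 * 2) + 2 * 16 +
    16 * 16 + 16 * 16 + 2 * 16 + 2 * (16 * 7) + 2
  expect_equal(param_count(m), by_hand)
})

test_that("model config validates pooled lengths and class count", {
  expect_error(model_config(2, n_samples = 16, pool_sizes = c(8, 8)),
               "below 1")
  expect_error(model_config(1), "n_classes")
  cfg3 <- model_config(3, n_blocks = 3, pool_sizes = c(2, 2, 2),
                       n_samples = 64, n_channels = 4)
  expect_equal(cfg3$n_blocks, 3L)
})

test_that("class weights follow w_k = N/(K N_k) and sum back to N", {
  y <- c(rep(0L, 30), rep(1L, 10))
  w <- class_weights(y, 2)
  expect_equal(w, c(2 / 3, 2), tolerance = 1e-12)
  expect_equal(sum(tabulate(y + 1L, 2) * w), length(y))
  expect_error(class_weights(rep(0L, 5), 2), "empty class")
})

test_that("prediction breaks ties toward the lowest class index and is
          order-equivariant", {
  es <- make_separable_epochs(n_trials = 40)
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  m$label_map <- c("a", "b")
  m$trained <- TRUE
  m$weights$Wd[] <- 0
  m$weights$bd[] <- 0
  pr <- predict(m, es)
  expect_true(all(pr$labels == "a"))              # equal logits -> index 1
  expect_true(all(pr$logits[, 1] == pr$logits[, 2]))
  # order equivariance with nontrivial weights
  m2 <- build_model(tiny_model_config(seed = 9))
  m2$label_map <- c("a", "b"); m2$trained <- TRUE
  set.seed(1)
  perm <- sample(seq_len(n_trials(es)))
  p_all <- predict(m2, es)
  p_perm <- predict(m2, es[perm])
  expect_equal(p_perm$labels, p_all$labels[perm])
})

test_that("pooled split is stratified, disjoint, exhaustive and seeded", {
  es <- make_separable_epochs(n_trials = 1000, n_subjects = 4)
  sp <- pooled_split(es, "label", 0.8, seed = 3)
  expect_equal(n_trials(sp$train), 800)
  expect_equal(n_trials(sp$holdout), 200)
  expect_length(intersect(sp$train$metadata$trial_id,
                          sp$holdout$metadata$trial_id), 0)
  expect_setequal(c(sp$train$metadata$trial_id,
                    sp$holdout$metadata$trial_id), es$metadata$trial_id)
  # per-stratum proportions within 1 trial of the fraction
  tab <- table(sp$train$metadata$participant_id, sp$train$metadata$label)
  full <- table(es$metadata$participant_id, es$metadata$label)
  expect_true(all(abs(tab - 0.8 * full) <= 1))
  sp2 <- pooled_split(es, "label", 0.8, seed = 3)
  expect_identical(sp$train$metadata$trial_id,
                   sp2$train$metadata$trial_id)
  expect_error(pooled_split(es, "label", 1.2), "0, 1")
})

test_that("training learns a noiseless two-class separation", {
  es <- make_separable_epochs(n_trials = 160, amplitude = 10, sd = 1e-3,
                              seed = 3)
  fit <- train_classifier(build_model(tiny_model_config(seed = 2)), es,
                          NULL, quick_train_config(max_epochs = 50,
                                                   patience = 10),
                          "label")
  expect_gte(max(fit$history$val_acc), 0.95)
  expect_true(fit$trained)
  expect_equal(fit$label_map, c("a", "b"))
})

test_that("the network can memorize 64 random-label trials", {
  set.seed(11)
  es <- make_separable_epochs(n_trials = 64, amplitude = 0)
  es$metadata$label <- sample(c("a", "b"), 64, replace = TRUE)
  cfg <- tiny_model_config(seed = 4)
  cfg$dropout_rate <- 0
  fit <- train_classifier(build_model(cfg), es, es,
                          train_config(max_epochs = 150, patience = 149,
                                       batch_size = 16,
                                       learning_rate = 3e-3,
                                       dense_max_norm = Inf, seed = 2),
                          "label")
  pr <- predict(fit, es)
  expect_gte(mean(pr$labels == es$metadata$label), 0.99)
})

test_that("early stopping restores the best validation epoch", {
  es <- make_separable_epochs(n_trials = 120, amplitude = 1, seed = 5)
  tc <- quick_train_config(max_epochs = 30, patience = 3)
  fit <- train_classifier(build_model(tiny_model_config(seed = 3)), es,
                          NULL, tc, "label")
  h <- fit$history
  expect_equal(h$epoch, seq_len(nrow(h)))         # monotone history
  best <- which.min(h$val_loss)
  expect_equal(fit$best_epoch, best)
  if (nrow(h) < tc$max_epochs)                    # stopped early
    expect_equal(nrow(h), best + tc$patience)
})

test_that("per-subject cross-validation scores without refitting", {
  es <- make_separable_epochs(n_trials = 100, n_subjects = 3,
                              amplitude = 10, sd = 1e-3, seed = 6)
  fit <- train_classifier(build_model(tiny_model_config(seed = 2)), es,
                          NULL, quick_train_config(), "label")
  cv <- evaluate_per_subject_cv(fit, es, "label", k = 5, seed = 1)
  expect_equal(nrow(cv$per_subject), 3)
  expect_true(all(cv$per_fold$n %in% c(6, 7)))    # fold sizes differ <= 1
  # k = 1 degenerates to plain per-subject accuracy
  cv1 <- evaluate_per_subject_cv(fit, es, "label", k = 1, seed = 1)
  pr <- predict(fit, es)
  for (i in seq_len(3)) {
    idx <- es$metadata$participant_id == cv1$per_subject$participant_id[i]
    expect_equal(cv1$per_subject$accuracy[i],
                 mean(pr$labels[idx] == es$metadata$label[idx]))
  }
  # a perfect separation yields accuracy 1 everywhere
  expect_true(all(cv$per_subject$accuracy == 1))
  # subjects with too few trials are skipped with a warning
  es_small <- es[c(which(es$metadata$participant_id == 1),
                   which(es$metadata$participant_id == 2)[1:3])]
  expect_warning(cv2 <- evaluate_per_subject_cv(fit, es_small, "label",
                                                k = 5, seed = 1),
                 "fewer than")
  expect_equal(nrow(cv2$per_subject), 1)
})

test_that("random search with successive halving finds the trainable
          configuration", {
  es <- make_separable_epochs(n_trials = 140, amplitude = 10, sd = 0.1,
                              seed = 8)
  sp <- pooled_split(es, "label", 0.7, seed = 1)
  space <- list(learning_rate = c(3e-3, 1e3), F2 = c(4))
  res <- hyperparameter_search(space, sp$train, sp$holdout, "label",
                               n_classes = 2, budget = 4, seed = 5,
                               initial_epochs = 3)
  expect_equal(res$train_config$learning_rate, 3e-3)
  expect_true(nrow(res$log) >= 4)
  res2 <- hyperparameter_search(space, sp$train, sp$holdout, "label",
                                n_classes = 2, budget = 4, seed = 5,
                                initial_epochs = 3)
  expect_identical(res$log$val_acc, res2$log$val_acc)
  # budget 1 returns the single sampled configuration
  res1 <- hyperparameter_search(space, sp$train, sp$holdout, "label",
                                n_classes = 2, budget = 1, seed = 2,
                                initial_epochs = 2)
  expect_s3_class(res1$model_config, "model_config")
  expect_error(hyperparameter_search(list(), sp$train, sp$holdout,
                                     "label", 2, 3), "empty")
  expect_error(hyperparameter_search(list(bogus = 1), sp$train,
                                     sp$holdout, "label", 2, 3),
               "unknown search-space")
})

test_that("analytic gradients match finite differences on a 3-block net", {
  cfg <- model_config(n_classes = 3, n_channels = 5, n_samples = 32,
                      F1 = 2, temporal_kernel_len = 7, D = 2, F2 = 3,
                      n_blocks = 3, pool_sizes = c(2, 2, 2),
                      sep_kernel_len = 5, dropout_rate = 0, seed = 7)
  m <- build_model(cfg)
  set.seed(42)
  B <- 6
  X <- array(rnorm(32 * 5 * B), c(32, 5, B))
  y <- sample(0:2, B, replace = TRUE)
  cw <- rep(1, 3)
  masks <- lapply(1:3, function(b) matrix(1, 3, B))
  nn <- function(w) eegdecode:::nn_train_batch(X, y, w, cfg, cw, masks,
                                               1e-5)
  out <- nn(m$weights)
  get_leaf <- function(w, path) { for (p in path) w <- w[[p]]; w }
  set_leaf <- function(w, path, v) {
    if (length(path) == 1) { w[[path[[1]]]] <- v; return(w) }
    w[[path[[1]]]] <- set_leaf(w[[path[[1]]]], path[-1], v)
    w
  }
  paths <- list("Wt", "Wdw", "Wpw1", "g1", "b1",
                list("sep", 1, "Wdt"), list("sep", 1, "Wpw"),
                list("sep", 2, "Wdt"), list("sep", 2, "Wpw"),
                list("sep", 2, "g"), list("sep", 2, "b"), "Wd", "bd")
  eps <- 1e-6
  for (p in paths) {
    p <- as.list(p)
    leaf <- get_leaf(m$weights, p)
    gleaf <- get_leaf(out$grads, p)
    for (i in sample(length(leaf), min(3, length(leaf)))) {
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      num <- (nn(set_leaf(m$weights, p, lp))$loss -
                nn(set_leaf(m$weights, p, lm))$loss) / (2 * eps)
      rel <- abs(num - gleaf[i]) / max(1e-8, abs(num) + abs(gleaf[i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("a three-block model trains and predicts", {
  es <- make_separable_epochs(n_trials = 120, amplitude = 8, sd = 0.5,
                              seed = 13)
  cfg <- model_config(2, n_channels = 8, n_samples = 64, F1 = 2,
                      temporal_kernel_len = 9, D = 1, F2 = 4,
                      n_blocks = 3, pool_sizes = c(2, 2, 2),
                      sep_kernel_len = 5, dropout_rate = 0.1, seed = 2)
  fit <- train_classifier(build_model(cfg), es, NULL,
                          quick_train_config(max_epochs = 15), "label")
  pr <- predict(fit, es)
  expect_equal(dim(pr$logits), c(120, 2))
  expect_gt(mean(pr$labels == es$metadata$label), 0.8)
  gm <- aggregate_maps(grad_cam(fit, es), "grand_mean")
  expect_equal(dim(gm$importance), c(8, 64))
})
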
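# micro cohort shared by the experiment-driver tests (smoke-profile scale)
micro_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- report_config("smoke", seed = 21)
      cache <<- build_cohort(cfg)$epochs
    }
    cache
  }
})
smoke_args <- function() {
  cfg <- report_config("smoke")
  list(model_args = cfg$model, train_args = cfg$train,
       n_iter = cfg$stats$n_iter)
}

test_that("task classification report carries n_runs complete entries", {
  data <- micro_cohort()
  a <- smoke_args()
  rep2 <- run_task_classification(data, n_runs = 2, seed = 31,
                                  model_args = a$model_args,
                                  train_args = a$train_args,
                                  n_iter = a$n_iter, cv_k = 2)
  expect_s3_class(rep2, "experiment_report")
  expect_equal(rep2$n_runs, 2)
  expect_length(rep2$runs, 2)
  expect_length(rep2$run_accuracies, 2)
  # run median lies between the per-run extremes
  expect_gte(rep2$median_accuracy, min(rep2$run_accuracies))
  expect_lte(rep2$median_accuracy, max(rep2$run_accuracies))
  expect_s3_class(rep2$median_map, "attribution_map")
  td <- tidy(rep2)
  expect_equal(nrow(td), 2)
  expect_true(all(c("p.value", "conf.low", "significant") %in% names(td)))
  expect_s3_class(glance(rep2), "tbl_df")
  expect_s3_class(ggplot2::autoplot(rep2), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep2$median_map), "ggplot")
})

test_that("experiment preconditions are enforced", {
  data <- micro_cohort()
  scene_only <- data[data$metadata$task == "scene_memory"]
  expect_error(run_task_classification(scene_only), "both tasks")
  one_color <- data[data$metadata$wall_color == 1]
  expect_error(run_color_generalization(one_color), "at least two colors")
  expect_error(run_affordance_generalization(
    data, train_task = "scene_memory", test_task = "scene_memory"),
    "must differ")
})

test_that("goal filtering keeps correct two-door spatial trials", {
  data <- micro_cohort()
  filt <- eegdecode:::filter_trials(data, task = "spatial_memory",
                                    n_doors = 2, correct_only = TRUE)
  md <- filt$metadata
  expect_true(all(md$task == "spatial_memory"))
  expect_true(all(md$n_doors == 2))
  expect_true(all(md$response_correct))
  # roughly behavioral_accuracy of the eligible trials survive
  elig <- eegdecode:::filter_trials(data, task = "spatial_memory",
                                    n_doors = 2)
  frac <- n_trials(filt) / n_trials(elig)
  expect_gt(frac, 0.85)
  expect_lt(frac, 0.99)
})

test_that("generalization runs report both same-task and cross-task", {
  data <- micro_cohort()
  a <- smoke_args()
  rep1 <- run_color_generalization(data, n_runs = 1, seed = 41,
                                   model_args = a$model_args,
                                   train_args = a$train_args,
                                   n_iter = a$n_iter, cv_k = 2)
  r <- rep1$runs[[1]]
  expect_named(r$cross, "spatial_memory")
  expect_s3_class(r$cross$spatial_memory$chance_test, "chance_test")
  expect_false(is.null(rep1$cross_summary))
  expect_equal(rep1$cross_summary$test_task, "spatial_memory")
  # the within-task chance test is also present
  expect_s3_class(r$chance_test, "chance_test")
})

test_that("null-scenario task decoding stays at chance", {
  straddles <- logical(6)
  for (i in seq_along(straddles)) {
    sched <- make_trial_schedule(2, seed = 100 + i, trials_per_task = 28,
                                 n_colors = 8)
    cfg <- simulation_config(n_subjects = 2, epoch_window = c(-0.3, 1.1),
                             artifact_rate = 0, seed = 100 + i)
    es <- simulate_epochs(sched, cfg, "null")
    pp <- preprocess_epochs(es)$epochs
    a <- smoke_args()
    rep1 <- run_task_classification(pp, n_runs = 1, seed = 100 + i,
                                    model_args = a$model_args,
                                    train_args = a$train_args,
                                    n_iter = 2000, cv_k = 2)
    ci <- rep1$runs[[1]]$chance_test$ci95
    straddles[i] <- ci[1] <= 0 && ci[2] >= 0
  }
  expect_gte(sum(straddles), 5)
})

test_that("the full report runs all four experiments and writes outputs", {
  cfg <- report_config("smoke", seed = 77)
  out_dir <- file.path(withr::local_tempdir(), "report")
  fr1 <- run_full_report(cfg, out_dir = out_dir)
  expect_length(fr1$errors, 0)
  expect_equal(sort(names(fr1$reports)),
               sort(c("task_classification", "goal_decoding",
                      "affordance_generalization",
                      "color_generalization")))
  expect_equal(nrow(fr1$summary), 4)
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir,
                                    "task_classification.json")))
})
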
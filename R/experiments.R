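#' @keywords internal
filter_trials <- function(epochs, task = NULL, n_doors = NULL,
                          correct_only = FALSE) {
  md <- epochs$metadata
  keep <- rep(TRUE, nrow(md))
  if (!is.null(task)) keep <- keep & md$task %in% task
  if (!is.null(n_doors)) keep <- keep & md$n_doors %in% n_doors
  if (correct_only) keep <- keep & md$response_correct
  if (!any(keep)) stop("trial filter removed every trial", call. = FALSE)
  epochs[keep]
}

assert_disjoint <- function(a, b, what) {
  ov <- intersect(a$metadata$trial_id, b$metadata$trial_id)
  if (length(ov))
    stop("leakage audit failed: ", what, " share ", length(ov),
         " trial(s)", call. = FALSE)
  invisible(TRUE)
}

# one seeded run of the generic decoding chain:
# balance -> 80/20 pooled split -> normalize (train-fit stats) -> train ->
# per-subject k-fold holdout accuracies -> binomial bootstrap -> Grad-CAM,
# plus optional cross-task scoring with the training-set normalization
run_one_decoding <- function(data, label_field, k_classes, run_seed,
                             train_task = NULL, cross_tasks = character(0),
                             n_doors = NULL, correct_only = FALSE,
                             model_args = list(), train_args = list(),
                             n_iter = 10000, cv_k = 5,
                             compute_gradcam = TRUE) {
  pool <- filter_trials(data, task = train_task, n_doors = n_doors,
                        correct_only = correct_only)
  labs <- unique(as.character(pool$metadata[[label_field]]))
  if (length(labs) < 2)
    stop("label field '", label_field, "' has fewer than two classes ",
         "after filtering", call. = FALSE)
  pool <- balance_classes(pool, label_field, seed = run_seed)
  sp <- pooled_split(pool, label_field, 0.8, seed = run_seed)
  norm <- normalize_subject(sp$train)
  train_es <- norm$epochs
  holdout_es <- apply_normalization(sp$holdout, norm$stats)
  assert_disjoint(train_es, holdout_es, "train and holdout")

  mc <- do.call(model_config, c(
    list(n_classes = k_classes, n_channels = n_channels(train_es),
         n_samples = n_samples(train_es),
         seed = derive_seed(run_seed, "model")),
    model_args))
  tc <- do.call(train_config, c(
    list(seed = derive_seed(run_seed, "train")), train_args))
  fitted <- train_classifier(build_model(mc), train_es, NULL, tc,
                             label_field)

  cv <- evaluate_per_subject_cv(fitted, holdout_es, label_field,
                                k = cv_k, seed = run_seed)
  accs <- cv$per_subject$accuracy
  n_pred <- round(mean(cv$per_subject$n_trials))
  cm <- chance_model(k_classes, n_pred)
  chance <- bootstrap_vs_chance(accs, cm, n_iter = n_iter,
                                seed = run_seed)
  threshold <- binomial_chance_threshold(cm)
  gmap <- NULL
  if (compute_gradcam)
    gmap <- aggregate_maps(grad_cam(fitted, holdout_es), "grand_mean")

  cross <- list()
  for (ctask in cross_tasks) {
    ces <- filter_trials(data, task = ctask, n_doors = n_doors,
                         correct_only = correct_only)
    assert_disjoint(train_es, ces, "train and cross-task test")
    ces <- apply_normalization(ces, norm$stats)
    pred <- predict(fitted, ces)
    ok <- pred$labels == as.character(ces$metadata[[label_field]])
    per_sub <- tibble::tibble(
      participant_id = ces$metadata$participant_id, correct = ok) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(accuracy = mean(.data$correct),
                       n_trials = dplyr::n(), .groups = "drop")
    ccm <- chance_model(k_classes, round(mean(per_sub$n_trials)))
    cross[[ctask]] <- list(
      per_subject = per_sub,
      chance_test = bootstrap_vs_chance(per_sub$accuracy, ccm,
                                        n_iter = n_iter,
                                        seed = derive_seed(run_seed,
                                                           ctask)))
  }

  list(per_subject = cv$per_subject, per_fold = cv$per_fold,
       mean_accuracy = mean(accs), chance_test = chance,
       threshold = threshold, gradcam = gmap, cross = cross,
       history = fitted$history, seed = run_seed)
}

new_experiment_report <- function(name, label_field, k_classes, runs,
                                  seed, spec = list()) {
  run_acc <- vapply(runs, function(r) r$mean_accuracy, numeric(1))
  maps <- purrr::compact(lapply(runs, function(r) r$gradcam))
  median_map <- if (length(maps)) run_median(maps) else NULL
  cross_summary <- NULL
  if (length(runs[[1]]$cross)) {
    cross_summary <- purrr::map_dfr(names(runs[[1]]$cross), function(tk) {
      accs <- vapply(runs, function(r)
        mean(r$cross[[tk]]$per_subject$accuracy), numeric(1))
      sig <- vapply(runs, function(r)
        r$cross[[tk]]$chance_test$significant, logical(1))
      tibble::tibble(test_task = tk, median_accuracy = stats::median(accs),
                     n_significant = sum(sig), n_runs = length(runs))
    })
  }
  structure(
    list(name = name, label_field = label_field, k_classes = k_classes,
         runs = runs, n_runs = length(runs),
         run_accuracies = run_acc,
         median_accuracy = stats::median(run_acc),
         median_map = median_map, cross_summary = cross_summary,
         seed = seed, spec = spec),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "<experiment_report> %s (%d classes, %d run%s): median accuracy %.1f%% vs %.2f%% chance\n",
    x$name, x$k_classes, x$n_runs, if (x$n_runs > 1) "s" else "",
    100 * x$median_accuracy, chance_level(x$k_classes)))
  if (!is.null(x$cross_summary)) {
    for (i in seq_len(nrow(x$cross_summary)))
      cat(sprintf("  cross-task %s: median accuracy %.1f%%, above chance in %d/%d runs\n",
                  x$cross_summary$test_task[i],
                  100 * x$cross_summary$median_accuracy[i],
                  x$cross_summary$n_significant[i],
                  x$cross_summary$n_runs[i]))
  }
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) {
  purrr::map_dfr(seq_along(x$runs), function(i) {
    r <- x$runs[[i]]
    tibble::tibble(
      run = i, mean_accuracy = r$mean_accuracy,
      diff_from_chance = r$chance_test$mean_difference_from_chance,
      conf.low = r$chance_test$ci95[1], conf.high = r$chance_test$ci95[2],
      p.value = r$chance_test$p_value,
      significant = r$chance_test$significant)
  })
}

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(name = x$name, k_classes = x$k_classes,
                 n_runs = x$n_runs,
                 median_accuracy = x$median_accuracy,
                 chance_pct = chance_level(x$k_classes))
}

#' Task-classification experiment
#'
#' Trains the classifier to decode which task (scene memory vs spatial
#' memory) each balanced trial came from, evaluates per-subject five-fold
#' holdout accuracies against the two-class binomial null, and computes
#' the grand-mean Grad-CAM map; the whole chain is repeated `n_runs`
#' times and medians are reported.
#'
#' @param data A preprocessed `epoch_set` containing both tasks.
#' @param n_runs Repetitions of the full chain (default 5).
#' @param seed Master seed; run seeds derive from it.
#' @param model_args,train_args Named overrides for [model_config()] /
#'   [train_config()].
#' @param n_iter Bootstrap iterations per chance test.
#' @param cv_k Per-subject fold count.
#' @return An `experiment_report`.
#' @export
run_task_classification <- function(data, n_runs = 5, seed = 1,
                                    model_args = list(),
                                    train_args = list(), n_iter = 10000,
                                    cv_k = 5) {
  tasks <- unique(data$metadata$task)
  if (!all(c("scene_memory", "spatial_memory") %in% tasks))
    stop("both tasks must be present for task classification",
         call. = FALSE)
  runs <- lapply(seq_len(n_runs), function(r)
    run_one_decoding(data, "task", 2L, derive_seed(seed, paste0("run", r)),
                     model_args = model_args, train_args = train_args,
                     n_iter = n_iter, cv_k = cv_k))
  new_experiment_report("task_classification", "task", 2L, runs, seed)
}

#' Goal-direction decoding in the spatial memory task
#'
#' Restricts to spatial-memory trials with the requested door count and a
#' correct response, then decodes the remembered goal direction
#' (left/center/right) with the standard chain.
#'
#' @param data A preprocessed `epoch_set`.
#' @param n_doors Door-count condition, 2 or 3.
#' @inheritParams run_task_classification
#' @return An `experiment_report`.
#' @export
run_goal_decoding <- function(data, n_doors = 2, n_runs = 5, seed = 1,
                              model_args = list(), train_args = list(),
                              n_iter = 10000, cv_k = 5) {
  stopifnot(n_doors %in% c(2, 3))
  runs <- lapply(seq_len(n_runs), function(r)
    run_one_decoding(data, "goal_direction", 3L,
                     derive_seed(seed, paste0("run", r)),
                     train_task = "spatial_memory", n_doors = n_doors,
                     correct_only = TRUE, model_args = model_args,
                     train_args = train_args, n_iter = n_iter,
                     cv_k = cv_k))
  new_experiment_report(paste0("goal_decoding_", n_doors, "door"),
                        "goal_direction", 3L, runs, seed,
                        spec = list(n_doors = n_doors))
}

#' Affordance decoding and cross-task generalization
#'
#' Trains the door-configuration decoder (7 classes) on one task only,
#' reports held-out same-task accuracy plus its chance test, and applies
#' the same trained model to every trial of the other task (normalized
#' with the training-set statistics), testing that cross-task accuracy
#' against the same binomial null. Train and cross-test trial sets are
#' disjoint by construction and audited.
#'
#' @param data A preprocessed `epoch_set` with both tasks.
#' @param train_task Task used for training (default scene memory).
#' @param test_task Task used for the generalization test.
#' @inheritParams run_task_classification
#' @return An `experiment_report` with a `cross_summary`.
#' @export
run_affordance_generalization <- function(data,
                                          train_task = "scene_memory",
                                          test_task = "spatial_memory",
                                          n_runs = 5, seed = 1,
                                          model_args = list(),
                                          train_args = list(),
                                          n_iter = 10000, cv_k = 5) {
  if (identical(train_task, test_task))
    stop("train and test tasks must differ", call. = FALSE)
  runs <- lapply(seq_len(n_runs), function(r)
    run_one_decoding(data, "door_configuration", 7L,
                     derive_seed(seed, paste0("run", r)),
                     train_task = train_task, cross_tasks = test_task,
                     model_args = model_args, train_args = train_args,
                     n_iter = n_iter, cv_k = cv_k))
  new_experiment_report("affordance_generalization",
                        "door_configuration", 7L, runs, seed,
                        spec = list(train_task = train_task,
                                    test_task = test_task))
}

#' Wall-color decoding and cross-task generalization control
#'
#' Same structure as [run_affordance_generalization()] but decoding the
#' wall color, a scene feature whose planted pattern is shared between
#' tasks in the presets, so generalization is expected to survive.
#'
#' @inheritParams run_affordance_generalization
#' @export
run_color_generalization <- function(data, train_task = "scene_memory",
                                     test_task = "spatial_memory",
                                     n_runs = 5, seed = 1,
                                     model_args = list(),
                                     train_args = list(), n_iter = 10000,
                                     cv_k = 5) {
  k <- length(unique(data$metadata$wall_color))
  if (k < 2)
    stop("wall-color decoding needs at least two colors", call. = FALSE)
  runs <- lapply(seq_len(n_runs), function(r)
    run_one_decoding(data, "wall_color", as.integer(k),
                     derive_seed(seed, paste0("run", r)),
                     train_task = train_task, cross_tasks = test_task,
                     model_args = model_args, train_args = train_args,
                     n_iter = n_iter, cv_k = cv_k))
  new_experiment_report("color_generalization", "wall_color",
                        as.integer(k), runs, seed,
                        spec = list(train_task = train_task,
                                    test_task = test_task))
}

#' Scale profiles for the full experiment report
#'
#' `"desk"` is the package's reduced default scale (5 subjects, 400
#' trials/task, 8 colors, F1 = 4, 10,000 bootstrap iterations); `"smoke"`
#' is a minutes-scale profile for end-to-end checks; `"full"` mirrors the
#' study scale (30 subjects, 770 trials/task, 100,000 iterations) and is
#' only practical on generous hardware.
#'
#' @param profile One of `"smoke"`, `"desk"`, `"full"`.
#' @param seed Master seed.
#' @return A nested config list of class `report_config`.
#' @export
report_config <- function(profile = c("desk", "smoke", "full"), seed = 1) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile, master_seed = as.integer(seed),
    simulate = list(n_subjects = 5, trials_per_task = 200, n_colors = 8,
                    scenario = "cohort", epoch_window = c(-0.3, 1.1),
                    amplitude = 4, noise_sd = 10, artifact_rate = 0.02),
    preprocess = list(),
    model = list(F1 = 4, temporal_kernel_len = 32, D = 4, F2 = 16,
                 pool_sizes = c(4, 8), sep_kernel_len = 8,
                 dropout_rate = 0.1),
    train = list(max_epochs = 15, batch_size = 64, learning_rate = 5e-3,
                 patience = 3),
    stats = list(n_iter = 10000),
    experiments = list(n_runs = 5, cv_k = 5)
  )
  if (profile == "smoke") {
    base$simulate$n_subjects <- 2
    base$simulate$trials_per_task <- 56
    base$model <- list(F1 = 2, temporal_kernel_len = 16, D = 1, F2 = 4,
                       pool_sizes = c(4, 8), sep_kernel_len = 8,
                       dropout_rate = 0.25)
    base$train <- list(max_epochs = 4, batch_size = 32,
                       learning_rate = 3e-3, patience = 3)
    base$stats$n_iter <- 500
    base$experiments <- list(n_runs = 1, cv_k = 2)
  }
  if (profile == "full") {
    base$simulate$n_subjects <- 30
    base$simulate$trials_per_task <- 770
    base$simulate$n_colors <- 8
    base$model <- list(F1 = 8, temporal_kernel_len = 64, D = 2, F2 = 16,
                       pool_sizes = c(4, 8), dropout_rate = 0.25)
    base$train <- list(max_epochs = 50, batch_size = 64,
                       learning_rate = 1e-3, patience = 5)
    base$stats$n_iter <- 100000
  }
  structure(base, class = c("report_config", "list"))
}

#' Simulate and preprocess one experimental cohort
#'
#' Builds the trial schedule, simulates the requested scenario (the
#' `"cohort"` scenario plants task, goal, affordance and color components
#' together, with the spatial-task affordance patterns remapped), and
#' runs the deterministic conditioning pipeline.
#'
#' @param cfg A [report_config()].
#' @return A list with `epochs` (ready for the experiment drivers) and
#'   `preprocess_report`.
#' @export
build_cohort <- function(cfg) {
  sim <- cfg$simulate
  schedule <- make_trial_schedule(
    sim$n_subjects, n_colors = sim$n_colors, seed = cfg$master_seed,
    trials_per_task = sim$trials_per_task)
  scfg <- simulation_config(
    n_subjects = sim$n_subjects, n_colors = sim$n_colors,
    epoch_window = sim$epoch_window, amplitude = sim$amplitude,
    noise_sd = sim$noise_sd, artifact_rate = sim$artifact_rate,
    seed = cfg$master_seed)
  if (sim$scenario %in% c("cohort", "dissociation"))
    scfg <- remap_condition_patterns(scfg, sim$scenario,
                                     seed = cfg$master_seed)
  epochs <- simulate_epochs(schedule, scfg, sim$scenario)
  pp <- preprocess_epochs(epochs)
  list(epochs = pp$epochs, preprocess_report = pp$report)
}

#' Run all four experiments on one simulated cohort
#'
#' Executes task classification, goal decoding, affordance generalization
#' and color generalization on a single simulated and preprocessed
#' cohort. Individual experiment failures are recorded and do not abort
#' the remaining experiments. With `out_dir` set, JSON reports, the
#' summary table and heatmap figures are written there.
#'
#' @param cfg A [report_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `full_report`: `reports` (per experiment),
#'   `summary` (tibble), `errors`, `config`, and `summary_json` (a
#'   deterministic serialization given the master seed).
#' @export
run_full_report <- function(cfg = report_config(), out_dir = NULL) {
  cohort <- build_cohort(cfg)
  data <- cohort$epochs
  nr <- cfg$experiments$n_runs
  cvk <- cfg$experiments$cv_k
  ni <- cfg$stats$n_iter
  seed <- cfg$master_seed
  margs <- cfg$model; targs <- cfg$train

  runners <- list(
    task_classification = function()
      run_task_classification(data, n_runs = nr, seed = derive_seed(seed,
        "exp_task"), model_args = margs, train_args = targs,
        n_iter = ni, cv_k = cvk),
    goal_decoding = function()
      run_goal_decoding(data, n_doors = 2, n_runs = nr,
        seed = derive_seed(seed, "exp_goal"), model_args = margs,
        train_args = targs, n_iter = ni, cv_k = cvk),
    affordance_generalization = function()
      run_affordance_generalization(data, n_runs = nr,
        seed = derive_seed(seed, "exp_afford"), model_args = margs,
        train_args = targs, n_iter = ni, cv_k = cvk),
    color_generalization = function()
      run_color_generalization(data, n_runs = nr,
        seed = derive_seed(seed, "exp_color"), model_args = margs,
        train_args = targs, n_iter = ni, cv_k = cvk)
  )
  reports <- list(); errors <- list()
  for (nm in names(runners)) {
    res <- tryCatch(runners[[nm]](), error = function(e) e)
    if (inherits(res, "error")) errors[[nm]] <- conditionMessage(res)
    else reports[[nm]] <- res
  }
  summary_tbl <- purrr::map_dfr(reports, function(r) {
    row <- glance(r)
    if (!is.null(r$cross_summary)) {
      row$cross_median_accuracy <- r$cross_summary$median_accuracy[1]
      row$cross_above_chance <-
        r$cross_summary$n_significant[1] > r$cross_summary$n_runs[1] / 2
    } else {
      row$cross_median_accuracy <- NA_real_
      row$cross_above_chance <- NA
    }
    row$p_value_median <- stats::median(
      vapply(r$runs, function(x) x$chance_test$p_value, numeric(1)))
    row
  })
  summary_json <- jsonlite::toJSON(
    list(master_seed = seed, profile = cfg$profile,
         n_trials_after_preprocess = n_trials(data),
         summary = summary_tbl, errors = errors),
    auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(summary_json, file.path(out_dir, "summary.json"))
    for (nm in names(reports)) {
      jsonlite::write_json(tidy(reports[[nm]]),
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
      map <- reports[[nm]]$median_map
      if (!is.null(map)) {
        ok <- tryCatch({
          p <- ggplot2::autoplot(map)
          suppressMessages(ggplot2::ggsave(
            file.path(out_dir, paste0(nm, "_gradcam.png")), p,
            width = 7, height = 5, dpi = 120))
          TRUE
        }, error = function(e) FALSE)
        if (!ok) message("could not render heatmap for ", nm)
      }
    }
  }
  structure(list(reports = reports, summary = summary_tbl,
                 errors = errors, config = cfg,
                 summary_json = as.character(summary_json)),
            class = "full_report")
}

#' @export
print.full_report <- function(x, ...) {
  cat("<full_report> profile", x$config$profile, "seed",
      x$config$master_seed, "\n")
  print(x$summary)
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n")
  }
  invisible(x)
}
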
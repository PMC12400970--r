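sine_epochs <- function(freqs, fs = 250, T_len = 751, amp = 10) {
  x <- array(0, c(length(freqs), 1, T_len))
  t <- (seq_len(T_len) - 1) / fs
  for (i in seq_along(freqs))
    x[i, 1, ] <- if (freqs[i] == 0) amp else amp * sin(2 * pi * freqs[i] * t)
  epoch_set(x, tibble::tibble(participant_id = seq_along(freqs),
                              trial_id = as.character(seq_along(freqs))),
            test_montage(1), fs, 251)
}

mid_rms <- function(v) {
  n <- length(v)
  sqrt(mean(v[round(n / 3):round(2 * n / 3)]^2))
}

test_that("band-pass removes DC, keeps 10 Hz, attenuates 80 Hz", {
  es <- sine_epochs(c(0, 10, 80))
  out <- bandpass_filter(es, 0.3, 50)
  expect_lt(max(abs(out$data[1, 1, ])), 1e-8)               # DC -> ~0
  g10 <- mid_rms(out$data[2, 1, ]) / mid_rms(es$data[2, 1, ])
  expect_lt(abs(g10 - 1), 0.05)                              # in band
  g80 <- mid_rms(out$data[3, 1, ]) / mid_rms(es$data[3, 1, ])
  expect_lte(g80, 0.10)                                      # >= 90% cut
  expect_equal(dim(out$data), dim(es$data))
  expect_error(bandpass_filter(es, 0.3, 130), "Nyquist")
  expect_error(bandpass_filter(es, 50, 10), "low < high")
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  es <- sine_epochs(0, T_len = 501)   # constant 10
  out <- baseline_correct(es, c(-200, 0))
  expect_true(all(abs(out$data) < 1e-12))
  # trace equal to 0 in baseline and 3 afterwards is unchanged
  es2 <- sine_epochs(0, T_len = 501)
  es2$data[1, 1, ] <- c(rep(0, 251), rep(3, 250))
  out2 <- baseline_correct(es2, c(-200, 0))
  expect_equal(out2$data, es2$data)
  # corrected output has exactly zero baseline mean for any input
  es3 <- sine_epochs(7.3, T_len = 501)
  es3$data[] <- stats::rnorm(length(es3$data))
  out3 <- baseline_correct(es3, c(-200, 0))
  i <- 201:251   # the (-200, 0) ms window at 250 Hz
  expect_lt(abs(mean(out3$data[1, 1, i])), 1e-12)
  expect_error(baseline_correct(es3, c(-3000, -2500)), "outside")
})

test_that("model-window cropping is endpoint inclusive", {
  es <- sine_epochs(5, fs = 250, T_len = 751)   # window (-1, 2) s
  out <- crop_model_window(es, c(0, 1000))
  expect_equal(n_samples(out), 251)
  expect_equal(out$time_zero_index, 1L)
  out0 <- crop_model_window(es, c(0, 0))
  expect_equal(n_samples(out0), 1)
  es100 <- sine_epochs(5, fs = 100, T_len = 301)
  es100$time_zero_index <- 101L
  out100 <- crop_model_window(es100, c(0, 1000))
  expect_equal(n_samples(out100), 101)
  expect_error(crop_model_window(es, c(0, 5000)), "exceeds")
})

test_that("amplitude rejection drops exactly the offending trials", {
  x <- array(stats::rnorm(20 * 3 * 50, sd = 5), c(20, 3, 50))
  x[x > 99] <- 99; x[x < -99] <- -99
  x[7, 2, 13] <- 101
  es <- epoch_set(x, tibble::tibble(trial_id = as.character(1:20)),
                  test_montage(3), 250, 1)
  out <- reject_artifacts(es, 100)
  expect_equal(out$rejected_indices, 7)
  expect_equal(n_trials(out$epochs), 19)
  expect_equal(out$epochs$metadata$trial_id, as.character(c(1:6, 8:20)))
  # nothing dropped when all |x| <= threshold
  x[7, 2, 13] <- 50
  es2 <- epoch_set(x, es$metadata, test_montage(3), 250, 1)
  expect_length(reject_artifacts(es2, 100)$rejected_indices, 0)
  es3 <- es
  es3$data[] <- 200
  expect_error(reject_artifacts(es3, 100), "all trials")
  expect_error(reject_artifacts(es, -1), "> 0")
})

test_that("channel dropping removes mastoids with set semantics", {
  x <- array(stats::rnorm(4 * 63 * 20), c(4, 63, 20))
  es <- epoch_set(x, tibble::tibble(trial_id = as.character(1:4)),
                  default_montage(), 250, 1)
  out <- drop_channels(es, c("M1", "M2"))
  expect_equal(n_channels(out), 61)
  expect_false(any(c("M1", "M2") %in% out$montage$channels))
  out2 <- drop_channels(es, c("M1", "M1", "M2"))
  expect_equal(out2$data, out$data)
  expect_equal(drop_channels(es, character(0))$data, es$data)
  expect_error(drop_channels(es, "XX"), "unknown channel")
})

test_that("subject-level normalization is fit/apply separable", {
  es <- make_separable_epochs(n_trials = 80, seed = 2)
  es$data[es$metadata$participant_id == 2, , ] <-
    es$data[es$metadata$participant_id == 2, , ] * 10 + 4
  out <- normalize_subject(es)
  for (pid in 1:2) {
    sub <- out$epochs$data[out$epochs$metadata$participant_id == pid, , ]
    mu <- apply(sub, 2, mean); sdv <- apply(sub, 2, stats::sd)
    expect_lt(max(abs(mu)), 1e-10)
    expect_lt(max(abs(sdv - 1)), 1e-10)
  }
  # statistics fitted on a subset do not adapt to shifted held-out data
  fitted <- normalize_subject(es, fit_mask = 1:40)
  held <- es[41:80]
  held$data <- held$data + 5
  applied <- apply_normalization(held, fitted$stats)
  expect_gt(abs(mean(applied$data)), 0.3)
})

test_that("zero-variance channels get an epsilon with a warning", {
  es <- make_separable_epochs(n_trials = 20, n_subjects = 1)
  es$data[, 3, ] <- 2
  expect_warning(out <- normalize_subject(es), "epsilon")
  expect_true(all(is.finite(out$epochs$data)))
})

test_that("class balancing undersamples to the minority count", {
  es <- make_separable_epochs(n_trials = 90)
  es$metadata$label <- rep(c("A", "B", "C"), times = c(40, 20, 30))
  out <- balance_classes(es, "label", seed = 4)
  expect_equal(unname(table(out$metadata$label)), rep(20L, 3),
               ignore_attr = TRUE)
  out2 <- balance_classes(es, "label", seed = 4)
  expect_identical(out$metadata$trial_id, out2$metadata$trial_id)
  # already balanced input comes back as a permutation
  es$metadata$label <- rep(c("A", "B"), each = 45)
  outp <- balance_classes(es, "label", seed = 1)
  expect_setequal(outp$metadata$trial_id, es$metadata$trial_id)
  es$metadata$label <- "A"
  expect_error(balance_classes(es, "label"), "two classes")
})

test_that("pipeline keeps trials and metadata aligned", {
  sched <- make_trial_schedule(2, seed = 6, trials_per_task = 28)
  cfg <- simulation_config(n_subjects = 2, epoch_window = c(-0.3, 1.1),
                           artifact_rate = 0.15, seed = 6)
  es <- simulate_epochs(sched, cfg, "task")
  out <- preprocess_epochs(es)
  pp <- out$epochs
  expect_equal(n_channels(pp), 61)
  expect_equal(n_samples(pp), 251)
  expect_equal(nrow(pp$metadata), n_trials(pp))
  kept <- setdiff(seq_len(n_trials(es)), out$report$rejected_indices)
  expect_equal(pp$metadata$trial_id, es$metadata$trial_id[kept])
  expect_equal(out$report$n_in, n_trials(es))
  expect_equal(out$report$n_out, n_trials(pp))
})
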
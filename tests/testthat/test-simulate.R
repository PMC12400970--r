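# reduced simulation settings used throughout this file
small_config <- function(..., seed = 1) {
  simulation_config(n_subjects = 2, epoch_window = c(-0.2, 1),
                    seed = seed, ...)
}
small_schedule <- function(n_subjects = 2, seed = 1, tpt = 28, ...) {
  make_trial_schedule(n_subjects, seed = seed, trials_per_task = tpt, ...)
}

test_that("identical schedule, config and seed give bit-identical epochs", {
  sched <- small_schedule()
  cfg <- small_config(artifact_rate = 0.1)
  a <- simulate_epochs(sched, cfg, "task")
  b <- simulate_epochs(sched, cfg, "task")
  expect_identical(a$data, b$data)
  cfg2 <- small_config(seed = 2, artifact_rate = 0.1)
  c <- simulate_epochs(sched, cfg2, "task")
  expect_false(identical(a$data, c$data))
})

test_that("noiseless single component equals its closed-form bump", {
  sched <- small_schedule(1, tpt = 14)
  comp <- component_spec("probe", c(POz = 1, Oz = 0.5), 200, 30,
                         c(scene_memory = 5, spatial_memory = 0), "task",
                         subject_gain_sd = 0, subject_latency_jitter_sd = 0)
  cfg <- small_config(noise_sd = 0, artifact_rate = 0,
                      components = list(probe = list(comp)))
  es <- simulate_epochs(sched, cfg, "probe")
  tms <- epoch_times(es)
  expected <- 5 * outer(c(1, 0.5), exp(-(tms - 0.2)^2 / (2 * 0.03^2)))
  ch <- match(c("POz", "Oz"), es$montage$channels)
  scene <- which(es$metadata$task == "scene_memory")
  for (i in scene[1:3])
    expect_equal(es$data[i, ch, ], expected, tolerance = 1e-12,
                 ignore_attr = TRUE)
  spatial <- which(es$metadata$task == "spatial_memory")
  expect_true(all(es$data[spatial, , ] == 0))
})

test_that("null scenario has no class-conditional structure", {
  sched <- small_schedule(2, tpt = 140)
  cfg <- small_config(artifact_rate = 0, spatial_mixing = 0)
  es <- simulate_epochs(sched, cfg, "null")
  ch <- match("POz", es$montage$channels)
  t_idx <- which(abs(epoch_times(es) - 0.15) < 0.02)
  v <- rowMeans(es$data[, ch, t_idx])
  scene <- es$metadata$task == "scene_memory"
  diff <- mean(v[scene]) - mean(v[!scene])
  se <- sqrt(stats::var(v[scene]) / sum(scene) +
               stats::var(v[!scene]) / sum(!scene))
  expect_lt(abs(diff), 4 * se)
})

test_that("background periodogram slope recovers the 1/f exponent", {
  for (beta in c(0.5, 1)) {
    x <- pink_noise(2^14, beta = beta, seed = 42, fs = 250)
    n <- length(x)
    p <- Mod(stats::fft(x))^2 / n
    f <- 250 * (seq_len(n) - 1) / n
    keep <- f > 0.5 & f < 100
    slope <- stats::coef(stats::lm(log(p[keep]) ~ log(f[keep])))[2]
    expect_lt(abs(slope + beta), 0.3)
  }
})

test_that("the maximal class difference sits on the peak-weight channel", {
  sched <- small_schedule(1, tpt = 14)
  comp <- component_spec("probe", op_topography(), 150, 30,
                         c(scene_memory = 0, spatial_memory = 4), "task",
                         subject_gain_sd = 0, subject_latency_jitter_sd = 0)
  cfg <- small_config(noise_sd = 0, artifact_rate = 0,
                      components = list(probe = list(comp)))
  es <- simulate_epochs(sched, cfg, "probe")
  scene <- es$metadata$task == "scene_memory"
  diff <- apply(es$data[!scene, , , drop = FALSE], c(2, 3), mean) -
    apply(es$data[scene, , , drop = FALSE], c(2, 3), mean)
  peak_chan <- es$montage$channels[which.max(apply(abs(diff), 1, max))]
  expect_equal(peak_chan, "POz")  # weight 1.0 in the topography
})

test_that("task preset evoked difference peaks occipitoparietally in 50-250 ms", {
  cfg <- small_config()
  # independent closed form, computed from the component fields directly
  comps <- cfg$components$task
  tms <- seq(-0.2, 1, by = 1 / 250)
  chans <- cfg$montage$channels
  diff <- matrix(0, length(chans), length(tms))
  for (cp in comps) {
    if (cp$label_field != "task") next
    a <- cp$amplitude_by_class[["spatial_memory"]] -
      cp$amplitude_by_class[["scene_memory"]]
    w <- stats::setNames(numeric(length(chans)), chans)
    w[names(cp$topography)] <- cp$topography
    diff <- diff + a * outer(w, exp(-(tms - cp$latency_center / 1000)^2 /
                                      (2 * (cp$latency_width / 1000)^2)))
  }
  op <- cfg$montage$groups$occipitoparietal
  sub <- diff[match(op, chans), ]
  peak_t <- tms[which.max(apply(abs(sub), 2, max))] * 1000
  expect_gte(peak_t, 50)
  expect_lte(peak_t, 250)
  # and the generator's noiseless class means match the same closed form
  cfg0 <- small_config(noise_sd = 0, artifact_rate = 0,
                       subject_gain_sd = 0,
                       subject_latency_jitter_sd = 0)
  sched <- small_schedule(1, tpt = 14)
  es <- simulate_epochs(sched, cfg0, "task")
  scene <- es$metadata$task == "scene_memory"
  got <- apply(es$data[!scene, , , drop = FALSE], c(2, 3), mean) -
    apply(es$data[scene, , , drop = FALSE], c(2, 3), mean)
  expect_equal(got, diff, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("artifact injection matches the configured rate", {
  sched <- small_schedule(2, tpt = 140)
  cfg <- small_config(artifact_rate = 0.1)
  es <- simulate_epochs(sched, cfg, "null")
  n_bad <- length(reject_artifacts(es, 100)$rejected_indices)
  expect_gte(n_bad, stats::qbinom(0.0005, n_trials(es), 0.1))
  expect_lte(n_bad, stats::qbinom(0.9995, n_trials(es), 0.1))
  cfg0 <- small_config(artifact_rate = 0)
  es0 <- simulate_epochs(sched, cfg0, "null")
  expect_length(reject_artifacts(es0, 100)$rejected_indices, 0)
})

test_that("component latency outside the epoch is rejected", {
  sched <- small_schedule(1, tpt = 14)
  comp <- component_spec("late", c(POz = 1), 1500, 30, c(any = 1))
  cfg <- small_config(components = list(bad = list(comp)))
  expect_error(simulate_epochs(sched, cfg, "bad"), "outside the epoch")
  expect_error(simulate_epochs(sched, cfg, "nope"), "unknown scenario")
})

test_that("remapping permutes class patterns in the spatial task only", {
  cfg <- small_config()
  # identity permutation leaves the config untouched
  cfgs7 <- sort(unique(make_stimulus_catalog(1)$door_configuration))
  ident <- stats::setNames(cfgs7, cfgs7)
  expect_identical(remap_condition_patterns(cfg, "affordance",
                                            permutation = ident), cfg)
  # a two-class swap exchanges the class-conditional means
  swap <- ident
  swap[c("L", "R")] <- c("R", "L")
  rc <- remap_condition_patterns(cfg, "affordance", permutation = swap)
  em_scene_L <- expected_evoked(rc, "affordance",
                                list(task = "scene_memory",
                                     door_configuration = "L"))
  em_spat_L <- expected_evoked(rc, "affordance",
                               list(task = "spatial_memory",
                                    door_configuration = "L"))
  em_scene_R <- expected_evoked(rc, "affordance",
                                list(task = "scene_memory",
                                     door_configuration = "R"))
  expect_false(isTRUE(all.equal(em_scene_L, em_spat_L)))
  expect_equal(em_spat_L, em_scene_R, tolerance = 1e-12)
  # seeded default draw is a derangement, marginals preserved
  rd <- remap_condition_patterns(cfg, "affordance", seed = 3)
  perm <- rd$remap$permutation
  expect_true(all(perm != names(perm)))
  expect_setequal(perm, names(perm))
  expect_error(remap_condition_patterns(cfg, "null"), "no components")
})
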
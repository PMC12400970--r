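#' Specify a planted evoked component
#'
#' A component is a Gaussian-in-time bump with a fixed spatial topography
#' whose amplitude depends on a trial label (task, goal direction, door
#' configuration or wall color), optionally restricted to one task. Per
#' subject, the amplitude is scaled by a lognormal gain and the latency
#' shifted by Gaussian jitter.
#'
#' @param name Component name.
#' @param topography Named numeric vector of per-channel weights (names are
#'   montage labels); rescaled so that `max(abs(w)) == 1`.
#' @param latency_center Peak latency in ms post stimulus.
#' @param latency_width Gaussian SD of the bump in ms.
#' @param amplitude_by_class Named numeric vector, class label -> amplitude
#'   in microvolts. Labels absent from the map get amplitude 0.
#' @param label_field Metadata column the amplitudes are keyed on
#'   (`"task"`, `"goal_direction"`, `"door_configuration"`, `"wall_color"`)
#'   or `"none"` for a class-independent component.
#' @param task_filter Optional task name restricting the component to one
#'   task.
#' @param subject_gain_sd SD of the per-subject lognormal amplitude gain.
#' @param subject_latency_jitter_sd SD in ms of the per-subject latency
#'   jitter.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, topography, latency_center, latency_width,
                           amplitude_by_class, label_field = "none",
                           task_filter = NULL, subject_gain_sd = 0.2,
                           subject_latency_jitter_sd = 10) {
  stopifnot(is.numeric(topography), !is.null(names(topography)),
            all(is.finite(topography)), all(is.finite(amplitude_by_class)),
            latency_width > 0)
  mx <- max(abs(topography))
  if (mx == 0) stop("topography must not be all zero", call. = FALSE)
  structure(
    list(name = name, topography = topography / mx,
         latency_center = latency_center, latency_width = latency_width,
         amplitude_by_class = amplitude_by_class,
         label_field = label_field, task_filter = task_filter,
         subject_gain_sd = subject_gain_sd,
         subject_latency_jitter_sd = subject_latency_jitter_sd),
    class = "component_spec"
  )
}

op_topography <- function() {
  c(P8 = 0.6, POz = 1.0, O1 = 0.8, O2 = 0.8, P6 = 0.5, PO4 = 0.7,
    PO6 = 0.6, PO7 = 0.6, PO8 = 0.6, Oz = 0.9)
}

frontal_topography <- function() {
  c(Fz = 1.0, FCz = 0.8, F1 = 0.7, F2 = 0.7, F3 = 0.5, F4 = 0.5, Fpz = 0.4)
}

central_topography <- function() {
  c(Cz = 1.0, C1 = 0.8, C2 = 0.8, C3 = 0.6, C4 = 0.6)
}

# fixed per-color topographies: mutually orthogonal signed patterns (DCT
# basis rows) over the 16-channel parieto-occipital pool, so every color
# has a distinct distributed scalp pattern of equal energy
color_topography <- function(color) {
  pool <- c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
            "PO3", "POz", "PO4", "O1", "Oz", "O2", "PO7", "PO8")
  i <- seq_along(pool)
  stats::setNames(cos(pi * color * (i - 0.5) / length(pool)), pool)
}

# lateralized multi-channel patterns, one per door position; a door
# configuration's evoked pattern is the sum over its open doors
door_topographies <- function() {
  list(left = c(P7 = 0.9, P5 = 0.7, P3 = 0.5, PO7 = 1, PO5 = 0.8,
                O1 = 0.6),
       center = c(POz = 1, Oz = 0.9, Pz = 0.6, PO3 = 0.5, PO4 = 0.5),
       right = c(P8 = 0.9, P6 = 0.7, P4 = 0.5, PO8 = 1, PO6 = 0.8,
                 O2 = 0.6))
}

# preset component lists per scenario; amplitudes in microvolts
scenario_components <- function(scenario, n_colors = 7, amplitude = 4,
                                subject_gain_sd = 0.2,
                                subject_latency_jitter_sd = 10) {
  cs <- function(...) component_spec(..., subject_gain_sd = subject_gain_sd,
                                     subject_latency_jitter_sd =
                                       subject_latency_jitter_sd)
  evoked <- cs("visual_evoked", op_topography(), 100, 20,
               c(any = 5), label_field = "none")
  # the task-discriminative effect is purely occipitoparietal within
  # 50-250 ms; frontal attention and response-related motor activity are
  # present but class-independent (both tasks require key presses)
  task_comps <- list(
    cs("task_op_early", op_topography(), 150, 30,
       c(scene_memory = 0, spatial_memory = amplitude), "task"),
    cs("task_op_late", op_topography(), 220, 25,
       c(scene_memory = 0, spatial_memory = amplitude * 0.6), "task"),
    cs("frontal_attention", frontal_topography(), 190, 25,
       c(any = amplitude * 0.5), label_field = "none"),
    cs("response_motor", central_topography(), 700, 60,
       c(any = amplitude * 0.75), label_field = "none")
  )
  # goal retrieval: a frontal transient near 190-200 ms plus sustained
  # direction-specific frontal activity while the goal is held in mind
  goal_topos <- list(
    left = c(F3 = 1, F5 = 0.9, F7 = 0.7, FC5 = 0.8, FC3 = 0.8,
             C5 = 0.6, C3 = 0.6, AF7 = 0.5, AF3 = 0.6, F1 = 0.4),
    center = c(Fz = 1, FCz = 0.9, Cz = 0.7, F1 = 0.7, F2 = 0.7,
               FC1 = 0.6, FC2 = 0.6, Fpz = 0.5, C1 = 0.4, C2 = 0.4),
    right = c(F4 = 1, F6 = 0.9, F8 = 0.7, FC6 = 0.8, FC4 = 0.8,
              C6 = 0.6, C4 = 0.6, AF8 = 0.5, AF4 = 0.6, F2 = 0.4))
  goal_comps <- c(
    purrr::imap(goal_topos, function(w, dir)
      cs(paste0("goal_", dir), w, 195, 25,
         stats::setNames(amplitude, dir), "goal_direction")),
    purrr::imap(goal_topos, function(w, dir)
      cs(paste0("goal_", dir, "_sustained"), w, 500, 200,
         stats::setNames(amplitude * 0.5, dir), "goal_direction")))
  goal_comps <- unname(goal_comps)
  # door configurations evoke a layout transient near 200 ms plus a weaker
  # sustained response while the doors remain visible; wall color drives a
  # sustained chromatic response throughout the 1 s presentation
  cfgs <- door_configurations()
  dt <- door_topographies()
  door_comp <- function(pos, latency, width, amp, tag) {
    amps <- stats::setNames(
      ifelse(config_has_door(cfgs, pos), amp, 0), cfgs)
    cs(paste0("door_", pos, tag), dt[[pos]], latency, width, amps,
       "door_configuration")
  }
  affordance_comps <- c(
    lapply(DOOR_POSITIONS, door_comp, latency = 200, width = 25,
           amp = amplitude, tag = ""),
    lapply(DOOR_POSITIONS, door_comp, latency = 500, width = 200,
           amp = amplitude * 0.5, tag = "_sustained"))
  color_comps <- lapply(seq_len(n_colors), function(i) {
    cs(paste0("color_", i), color_topography(i), 500, 200,
       stats::setNames(amplitude, as.character(i)), "wall_color")
  })
  switch(
    scenario,
    null = list(evoked),
    task = c(list(evoked), task_comps),
    goal = c(list(evoked), goal_comps),
    affordance = c(list(evoked), affordance_comps),
    color = c(list(evoked), color_comps),
    dissociation = c(list(evoked), affordance_comps, color_comps),
    cohort = c(list(evoked), task_comps, goal_comps, affordance_comps,
               color_comps),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' Configure the synthetic EEG generator
#'
#' Bundles the montage, the noise model (1/f^beta background with uniform
#' spatial correlation), the planted component presets for every scenario,
#' behavioral accuracy, artifact injection and the epoch geometry.
#'
#' @param n_subjects Number of participants the config is intended for.
#' @param montage Montage (defaults to the full 63-channel cap including
#'   mastoids).
#' @param noise_sd Background noise SD per channel, microvolts.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param spatial_mixing Uniform channel-correlation strength in `[0, 1)`.
#' @param behavioral_accuracy Probability a spatial-memory response is
#'   correct.
#' @param artifact_rate Fraction of epochs receiving a 150 microvolt
#'   rectangular excursion on two random channels (exercises the 100
#'   microvolt rejection rule).
#' @param sampling_rate Hz.
#' @param epoch_window Two-element numeric, seconds relative to onset. Must
#'   contain the baseline window (-0.2, 0) and the model window (0, 1).
#' @param seed Master seed; all generator randomness derives from it via
#'   named sub-streams.
#' @param n_colors Wall-color count used by the color-keyed presets.
#' @param amplitude Base planted amplitude in microvolts.
#' @param subject_gain_sd,subject_latency_jitter_sd Between-subject
#'   variability of the planted components.
#' @param components Optional named list (by scenario) of
#'   [component_spec()] lists overriding the presets.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 5, montage = default_montage(),
                              noise_sd = 10, noise_exponent = 1,
                              spatial_mixing = 0.3,
                              behavioral_accuracy = 0.93,
                              artifact_rate = 0.05, sampling_rate = 250,
                              epoch_window = c(-1, 2), seed = 1,
                              n_colors = 7, amplitude = 4,
                              subject_gain_sd = 0.2,
                              subject_latency_jitter_sd = 10,
                              components = NULL) {
  stopifnot(behavioral_accuracy >= 0, behavioral_accuracy <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            spatial_mixing >= 0, spatial_mixing < 1,
            sampling_rate > 0, length(epoch_window) == 2L,
            epoch_window[1] < epoch_window[2])
  if (epoch_window[1] > -0.2 || epoch_window[2] < 1)
    stop("epoch_window must contain the baseline window (-0.2, 0) and the ",
         "model window (0, 1)", call. = FALSE)
  if (is.null(components)) {
    scen <- c("null", "task", "goal", "affordance", "color",
              "dissociation", "cohort")
    components <- stats::setNames(lapply(scen, function(s)
      scenario_components(s, n_colors = n_colors, amplitude = amplitude,
                          subject_gain_sd = subject_gain_sd,
                          subject_latency_jitter_sd =
                            subject_latency_jitter_sd)), scen)
  }
  structure(
    list(n_subjects = n_subjects, montage = montage, noise_sd = noise_sd,
         noise_exponent = noise_exponent, spatial_mixing = spatial_mixing,
         behavioral_accuracy = behavioral_accuracy,
         artifact_rate = artifact_rate, sampling_rate = sampling_rate,
         epoch_window = epoch_window, seed = seed, n_colors = n_colors,
         components = components),
    class = "simulation_config"
  )
}

#' Generate 1/f^beta ("pink") Gaussian noise
#'
#' Spectrally shaped Gaussian noise with power spectral density
#' proportional to `f^(-beta)` and unit variance (in expectation). The DC
#' component is zeroed.
#'
#' @param n Number of samples.
#' @param beta Spectral exponent (1 = classic pink noise).
#' @param seed Optional seed.
#' @param fs Sampling rate (only sets the frequency axis scale; the shape
#'   is scale free).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, beta = 1, seed = NULL, fs = 1) {
  w <- if (is.null(seed)) matrix(stats::rnorm(n), n, 1)
       else with_seed(seed, matrix(stats::rnorm(n), n, 1))
  drop(shape_pink(w, beta, fs))
}

# multiply the FFT of each column of w (n x m) by a symmetric f^(-beta/2)
# amplitude profile, unit-RMS normalized; returns real time series
shape_pink <- function(w, beta, fs) {
  n <- nrow(w)
  f <- fs * (seq_len(n) - 1) / n
  f <- pmin(f, fs - f)               # two-sided, symmetric
  s <- ifelse(f == 0, 0, f^(-beta / 2))
  s <- s / sqrt(mean(s^2))
  fft_shape(w, s)
}

#' Simulate an EpochSet from a schedule and a scenario
#'
#' Each epoch is `background + sum_k gain_s(k) * amplitude_k(label) *
#' w_k(c) * exp(-(t - tau_k - jitter_s(k))^2 / (2 sigma_k^2))`, plus an
#' optional artifact excursion. The background is per-channel 1/f^beta
#' Gaussian noise mixed with a shared per-trial 1/f^beta trace so that all
#' channel pairs share correlation `spatial_mixing`. Fully reproducible
#' from the config seed.
#'
#' @param schedule A [make_trial_schedule()] tibble.
#' @param config A [simulation_config()].
#' @param scenario One of `"null"`, `"task"`, `"goal"`, `"affordance"`,
#'   `"color"`, `"dissociation"` (or any scenario added to
#'   `config$components`).
#' @return An [epoch_set()].
#' @export
simulate_epochs <- function(schedule, config, scenario = "task") {
  if (!scenario %in% names(config$components))
    stop("unknown scenario '", scenario, "'; config defines: ",
         paste(names(config$components), collapse = ", "), call. = FALSE)
  comps <- config$components[[scenario]]
  fs <- config$sampling_rate
  w0 <- config$epoch_window[1]; w1 <- config$epoch_window[2]
  T_len <- as.integer(round((w1 - w0) * fs)) + 1L
  tzi <- as.integer(round(-w0 * fs)) + 1L
  times <- (seq_len(T_len) - tzi) / fs
  chans <- config$montage$channels
  C <- length(chans)
  N <- nrow(schedule)
  for (cp in comps) {
    if (cp$latency_center / 1000 < w0 || cp$latency_center / 1000 > w1)
      stop("component '", cp$name, "' latency ", cp$latency_center,
           " ms lies outside the epoch window", call. = FALSE)
    unknown <- setdiff(names(cp$topography), chans)
    if (length(unknown))
      stop("component '", cp$name, "' references unknown channels: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  data <- array(0, dim = c(N, C, T_len))

  # --- background noise, per subject, fixed 128-trial chunks -------------
  lam <- config$spatial_mixing
  for (pid in if (config$noise_sd > 0) sort(unique(schedule$participant_id))
       else integer(0)) {
    idx <- which(schedule$participant_id == pid)
    with_seed(derive_seed(config$seed, paste0("noise_s", pid)), {
      for (start in seq(1L, length(idx), by = 128L)) {
        ch_idx <- idx[start:min(start + 127L, length(idx))]
        m <- length(ch_idx)
        iid <- shape_pink(matrix(stats::rnorm(T_len * C * m), T_len),
                          config$noise_exponent, fs)
        shared <- shape_pink(matrix(stats::rnorm(T_len * m), T_len),
                             config$noise_exponent, fs)
        # iid columns are ordered channel-fastest within trial
        dim(iid) <- c(T_len, C, m)
        noise <- sqrt(1 - lam) * iid +
          sqrt(lam) * aperm(array(shared, c(T_len, m, C)), c(1, 3, 2))
        # data is still zero here: assign rather than accumulate
        data[ch_idx, , ] <- config$noise_sd * aperm(noise, c(3, 2, 1))
      }
    })
  }

  # --- planted components ------------------------------------------------
  for (pid in sort(unique(schedule$participant_id))) {
    sub_rows <- schedule$participant_id == pid
    draws <- with_seed(derive_seed(config$seed, paste0("gains_s", pid)), {
      lapply(comps, function(cp)
        list(gain = exp(stats::rnorm(1, 0, cp$subject_gain_sd)),
             jitter = stats::rnorm(1, 0, cp$subject_latency_jitter_sd)))
    })
    for (k in seq_along(comps)) {
      cp <- comps[[k]]
      tau <- (cp$latency_center + draws[[k]]$jitter) / 1000
      sig <- cp$latency_width / 1000
      bump <- exp(-(times - tau)^2 / (2 * sig^2))
      w <- stats::setNames(numeric(C), chans)
      w[names(cp$topography)] <- cp$topography
      sel <- sub_rows
      if (!is.null(cp$task_filter)) sel <- sel & schedule$task == cp$task_filter
      if (cp$label_field == "none") {
        amp <- rep(cp$amplitude_by_class[[1L]], N)
      } else {
        amp <- cp$amplitude_by_class[as.character(schedule[[cp$label_field]])]
        amp[is.na(amp)] <- 0
      }
      amp[!sel] <- 0
      nz <- which(w != 0)   # only touch supported channels
      for (a in setdiff(unique(amp), 0)) {
        idx <- which(amp == a)
        slab <- (draws[[k]]$gain * a) * outer(w[nz], bump)
        data[idx, nz, ] <- data[idx, nz, ] +
          array(rep(slab, each = length(idx)),
                c(length(idx), length(nz), T_len))
      }
    }
  }

  # --- artifact excursions ----------------------------------------------
  if (config$artifact_rate > 0) {
    with_seed(derive_seed(config$seed, "artifacts"), {
      hit <- which(stats::runif(N) < config$artifact_rate)
      wlen <- max(1L, as.integer(round(0.1 * fs)))
      for (i in hit) {
        ch <- sample.int(C, 2L)
        s0 <- sample.int(max(1L, T_len - wlen + 1L), 1L)
        data[i, ch, s0:(s0 + wlen - 1L)] <-
          data[i, ch, s0:(s0 + wlen - 1L)] + 150
      }
    })
  }

  epoch_set(data, schedule, config$montage, fs, tzi,
            provenance = list(seed = config$seed, scenario = scenario))
}

#' Remap class-conditional patterns in one task
#'
#' Returns a config in which spatial-memory trials use a permuted class ->
#' component assignment while scene-memory trials are unchanged, modeling a
#' change of the discriminative neural pattern after spatial learning. The
#' marginal amplitude distribution is preserved (it is a permutation of the
#' class labels inside each component's amplitude map).
#'
#' @param config A [simulation_config()].
#' @param scenario Scenario whose components to remap.
#' @param seed Seed for the default permutation draw.
#' @param label_field Metadata field whose classes are permuted (default
#'   door configurations).
#' @param permutation Optional named character vector `new_label ->
#'   source_label`. Defaults to a seeded derangement. The identity
#'   permutation returns the config unchanged.
#' @return A modified `simulation_config`.
#' @export
remap_condition_patterns <- function(config, scenario, seed = config$seed,
                                     label_field = "door_configuration",
                                     permutation = NULL) {
  comps <- config$components[[scenario]]
  if (is.null(comps))
    stop("config has no components for scenario '", scenario, "'",
         call. = FALSE)
  target <- vapply(comps, function(cp) cp$label_field == label_field,
                   logical(1))
  if (!any(target))
    stop("scenario '", scenario, "' has no components keyed on '",
         label_field, "'", call. = FALSE)
  classes <- sort(unique(unlist(
    lapply(comps[target], function(cp) names(cp$amplitude_by_class)))))
  if (length(classes) < 2L)
    stop("cannot remap a single-class scenario", call. = FALSE)
  if (is.null(permutation)) {
    permutation <- with_seed(derive_seed(seed, "remap"), {
      p <- sample(classes)
      while (any(p == classes)) p <- sample(classes)  # derangement
      stats::setNames(p, classes)
    })
  } else {
    stopifnot(setequal(names(permutation), classes),
              setequal(permutation, classes))
    permutation <- permutation[classes]
  }
  if (all(permutation == classes)) return(config)

  new_comps <- list()
  for (cp in comps) {
    if (!cp$label_field == label_field ||
        identical(cp$task_filter, "scene_memory")) {
      new_comps <- c(new_comps, list(cp))
      next
    }
    amp <- cp$amplitude_by_class
    full <- stats::setNames(rep(0, length(classes)), classes)
    full[names(amp)] <- amp
    remapped <- stats::setNames(full[permutation], classes)
    if (identical(cp$task_filter, "spatial_memory")) {
      cp$amplitude_by_class <- remapped
      new_comps <- c(new_comps, list(cp))
    } else {
      scene_cp <- cp; scene_cp$task_filter <- "scene_memory"
      spat_cp <- cp
      spat_cp$task_filter <- "spatial_memory"
      spat_cp$amplitude_by_class <- remapped
      spat_cp$name <- paste0(cp$name, "_remapped")
      new_comps <- c(new_comps, list(scene_cp, spat_cp))
    }
  }
  config$components[[scenario]] <- new_comps
  config$remap <- list(scenario = scenario, label_field = label_field,
                       permutation = permutation)
  config
}

#' Noise-free expected class-conditional mean of a scenario
#'
#' Evaluates the planted components analytically (unit subject gain, zero
#' jitter) for one class labeling, returning the channels x samples
#' expectation. Used for closed-form checks of the generator.
#'
#' @param config A [simulation_config()].
#' @param scenario Scenario name.
#' @param labels Named list of metadata values identifying the class (e.g.
#'   `list(task = "spatial_memory")`).
#' @return A channels x samples matrix on the config's epoch grid.
#' @export
expected_evoked <- function(config, scenario, labels) {
  comps <- config$components[[scenario]]
  fs <- config$sampling_rate
  w0 <- config$epoch_window[1]
  T_len <- as.integer(round((config$epoch_window[2] - w0) * fs)) + 1L
  tzi <- as.integer(round(-w0 * fs)) + 1L
  times <- (seq_len(T_len) - tzi) / fs
  chans <- config$montage$channels
  out <- matrix(0, length(chans), T_len,
                dimnames = list(chans, NULL))
  for (cp in comps) {
    if (!is.null(cp$task_filter) &&
        !identical(labels[["task"]], cp$task_filter)) next
    a <- if (cp$label_field == "none") cp$amplitude_by_class[[1L]]
         else {
           lab <- labels[[cp$label_field]]
           if (is.null(lab)) 0
           else {
             v <- cp$amplitude_by_class[as.character(lab)]
             if (is.na(v)) 0 else v
           }
         }
    if (a == 0) next
    w <- stats::setNames(numeric(length(chans)), chans)
    w[names(cp$topography)] <- cp$topography
    bump <- exp(-(times - cp$latency_center / 1000)^2 /
                  (2 * (cp$latency_width / 1000)^2))
    out <- out + a * outer(w, bump)
  }
  out
}
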
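DOOR_POSITIONS <- c("left", "center", "right")

# 7 non-empty subsets of {left, center, right}, ordered by subset bitmask
# (left = 1, center = 2, right = 4)
door_configurations <- function() {
  labs <- character(7)
  for (mask in 1:7) {
    doors <- DOOR_POSITIONS[bitwAnd(mask, c(1L, 2L, 4L)) != 0L]
    labs[mask] <- paste(substr(toupper(doors), 1, 1), collapse = "")
  }
  labs
}

config_n_doors <- function(config) nchar(config)

config_has_door <- function(config, position) {
  grepl(substr(toupper(position), 1, 1), config, fixed = TRUE)
}

#' Enumerate the stimulus catalog
#'
#' Crosses the 7 door configurations (the non-empty subsets of the three
#' wall positions left/center/right) with `n_colors` wall colors, in
#' deterministic order: configurations by subset bitmask, then color index.
#'
#' @param n_colors Number of wall color variations (>= 1).
#' @return A tibble with one row per unique stimulus: `door_configuration`
#'   (e.g. `"LC"`), `n_doors`, `wall_color`.
#' @export
#' @examples
#' nrow(make_stimulus_catalog(7))  # 49 unique stimuli
make_stimulus_catalog <- function(n_colors) {
  if (!is.numeric(n_colors) || length(n_colors) != 1L || n_colors < 1 ||
      n_colors != round(n_colors))
    stop("`n_colors` must be a positive integer", call. = FALSE)
  n_colors <- as.integer(n_colors)
  cfgs <- door_configurations()
  tibble::tibble(
    door_configuration = rep(cfgs, each = n_colors),
    n_doors = config_n_doors(rep(cfgs, each = n_colors)),
    wall_color = rep(seq_len(n_colors), times = length(cfgs))
  )
}

# split n as evenly as possible into k parts; remainder spread over the
# first parts (never dropped)
split_evenly <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  r <- n %% k
  if (r > 0) out[seq_len(r)] <- out[seq_len(r)] + 1L
  as.integer(out)
}

#' Build a per-participant trial schedule
#'
#' Emulates the study design: six blocks, each containing a scene-memory
#' phase followed by a spatial-memory phase on the same stimuli; each of the
#' 7 door configurations repeated equally often within each task (110 times
#' for the default 770 trials/task); each wall color deterministically
#' associated with a goal direction within a participant; responses in the
#' spatial task correct with probability `behavioral_accuracy`.
#'
#' When `trials_per_task` is not divisible by 7 (or by the block count) the
#' remainder is distributed across the first configurations/blocks, never
#' dropped.
#'
#' @param n_subjects Number of participants.
#' @param n_colors Wall color count (default 7 reproduces the 49-stimulus
#'   catalog arithmetic).
#' @param behavioral_accuracy Probability a spatial-memory response is
#'   correct (default 0.93).
#' @param seed Master seed; sub-streams are derived per participant.
#' @param trials_per_task Trials per task per participant (default 770).
#' @param n_blocks Number of blocks (default 6).
#' @return A tibble with one row per trial: `participant_id`, `block`,
#'   `task`, `door_configuration`, `n_doors`, `wall_color`,
#'   `goal_direction`, `response_correct`, `trial_index`, `trial_id`.
#' @export
#' @examples
#' sched <- make_trial_schedule(1, seed = 1)
#' nrow(sched)                                   # 1540
#' table(sched$task)                             # 770 per task
make_trial_schedule <- function(n_subjects, n_colors = 7,
                                behavioral_accuracy = 0.93, seed = 1,
                                trials_per_task = 770, n_blocks = 6) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("`n_subjects` must be >= 1", call. = FALSE)
  if (behavioral_accuracy < 0 || behavioral_accuracy > 1)
    stop("`behavioral_accuracy` must be in [0, 1]", call. = FALSE)
  if (n_colors < 1) stop("`n_colors` must be >= 1", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  cfgs <- door_configurations()

  one_subject <- function(pid) {
    sseed <- derive_seed(seed, paste0("schedule_s", pid))
    with_seed(sseed, {
      # color -> goal direction mapping, fixed for the participant
      perm <- sample(DOOR_POSITIONS)
      goal_of_color <- function(color) perm[(color - 1L) %% 3L + 1L]

      per_cfg <- split_evenly(trials_per_task, length(cfgs))
      make_task <- function(task) {
        rows <- purrr::map2_dfr(cfgs, per_cfg, function(cf, nrep) {
          cols <- rep_len(seq_len(n_colors), nrep)
          tibble::tibble(door_configuration = cf,
                         wall_color = sample(cols))
        })
        rows$task <- task
        rows <- rows[sample.int(nrow(rows)), ]  # spread configs over blocks
        rows$block <- unlist(purrr::map2(
          seq_len(n_blocks), split_evenly(nrow(rows), n_blocks), rep_len))
        # pseudorandom presentation order within each block
        rows <- rows[order(rows$block, sample.int(nrow(rows))), ]
        rows
      }
      scene <- make_task("scene_memory")
      spatial <- make_task("spatial_memory")
      # re-distribute block labels independently drawn above; interleave so
      # that within each block scene trials precede spatial trials
      all_rows <- dplyr::bind_rows(scene, spatial)
      all_rows <- all_rows[order(all_rows$block,
                                 all_rows$task != "scene_memory"), ]
      all_rows$n_doors <- config_n_doors(all_rows$door_configuration)
      all_rows$goal_direction <- ifelse(
        all_rows$task == "scene_memory", "none",
        goal_of_color(all_rows$wall_color))
      bseed <- derive_seed(seed, paste0("behavior_s", pid))
      all_rows$response_correct <- TRUE
      sp <- all_rows$task == "spatial_memory"
      all_rows$response_correct[sp] <- with_seed(
        bseed, stats::runif(sum(sp)) < behavioral_accuracy)
      all_rows$participant_id <- pid
      all_rows$trial_index <- seq_len(nrow(all_rows))
      all_rows$trial_id <- sprintf("s%02d_t%04d", pid, all_rows$trial_index)
      all_rows
    })
  }

  out <- purrr::map_dfr(seq_len(n_subjects), one_subject)
  dplyr::select(out, "participant_id", "block", "task",
                "door_configuration", "n_doors", "wall_color",
                "goal_direction", "response_correct", "trial_index",
                "trial_id")
}
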
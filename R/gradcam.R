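new_attribution_map <- function(importance, channels, times,
                                aggregation, n_trials) {
  structure(list(importance = importance, channels = channels,
                 times = times, aggregation = aggregation,
                 n_trials_contributing = n_trials),
            class = "attribution_map")
}

minmax_norm <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(m * 0)
  (m - lo) / (hi - lo)
}

#' Grad-CAM attribution over the second convolutional block
#'
#' For every trial: a forward pass, a backward pass from the logit of the
#' trial's predicted class (optionally the true class), per-feature-map
#' weights equal to the temporal mean of the gradient, a rectified
#' weighted sum of the feature maps, linear upsampling of the pooled time
#' axis to the input grid, and min-max normalization to `[0, 1]`.
#'
#' The second block's feature maps carry no channel axis (the depthwise
#' spatial convolution collapses it), so the electrode dimension is
#' re-projected through the energy (squared weights) of the
#' depthwise-spatial filters, chained through the pointwise layers and
#' weighted by the per-map Grad-CAM weights. The per-trial map is the
#' outer product of this channel profile with the rectified temporal map.
#'
#' @param model A trained `classifier_model` (2 or 3 blocks; attribution
#'   always targets block 2).
#' @param epochs An `epoch_set` matching the model geometry.
#' @param use_true_labels If `TRUE`, backpropagate from the true-class
#'   logit given in `label_field` instead of the predicted class.
#' @param label_field Metadata column with true labels (only used when
#'   `use_true_labels = TRUE`).
#' @return An object of class `attribution_set`: per-trial maps
#'   (`maps[n, channel, sample]`, each in `[0, 1]`), channels, times and
#'   the per-trial participant ids.
#' @export
grad_cam <- function(model, epochs, use_true_labels = FALSE,
                     label_field = NULL) {
  if (!model$trained)
    warning("model is untrained; attribution maps may be all zero")
  cube <- epochs_to_cube(epochs, model$config)
  N <- n_trials(epochs)
  pred <- predict(model, epochs)
  if (use_true_labels) {
    if (is.null(label_field))
      stop("label_field is required with use_true_labels", call. = FALSE)
    cls <- labels_to_index(epochs$metadata[[label_field]],
                           model$label_map)
  } else {
    cls <- labels_to_index(pred$labels, model$label_map)
  }

  C <- model$config$n_channels
  T_len <- model$config$n_samples
  p1 <- model$config$pool_sizes[1]
  w <- model$weights
  # energy (squared-weight) channel re-projection through the pointwise
  # and depthwise-spatial layers
  sq_wdw <- w$Wdw^2                          # (F1*D) x C
  sq_wpw1 <- w$Wpw1^2                        # F2 x (F1*D)
  sq_wpw2 <- w$sep[[1]]$Wpw^2                # F2 x F2
  kappa <- rowSums(w$sep[[1]]$Wdt^2)         # F2

  maps <- array(0, c(N, C, T_len))
  all_zero <- 0L
  chunk <- 512L
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    fg <- nn_feature_grad(cube[, , idx, drop = FALSE], w, model$config,
                          model$bn_state, 1e-5, cls[idx])
    T1 <- dim(fg$features)[1]
    centers <- (seq_len(T1) - 0.5) * p1 + 0.5
    for (j in seq_along(idx)) {
      alpha <- colMeans(fg$grads[, , j, drop = FALSE][, , 1])
      lt <- pmax(0, as.vector(fg$features[, , j] %*% alpha))
      lt_up <- stats::approx(centers, lt, xout = seq_len(T_len),
                             rule = 2)$y
      rel <- kappa * as.vector(t(sq_wpw2) %*% abs(alpha))
      rho <- as.vector(t(sq_wpw1) %*% rel)
      chanw <- as.vector(t(sq_wdw) %*% rho)
      m <- outer(chanw, lt_up)
      if (max(m) <= 0) all_zero <- all_zero + 1L else m <- minmax_norm(m)
      maps[idx[j], , ] <- m
    }
  }
  if (all_zero > 0L)
    warning(all_zero, " trial map(s) were all zero (no positive ",
            "class-aligned activation)")
  structure(
    list(maps = maps, channels = epochs$montage$channels,
         times = epoch_times(epochs),
         participant_id = epochs$metadata$participant_id,
         predicted = pred$labels, target_layer = "block2"),
    class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("<attribution_set> %d trial maps, %d channels x %d samples\n",
              dim(x$maps)[1], dim(x$maps)[2], dim(x$maps)[3]))
  invisible(x)
}

as_map_list <- function(x) {
  if (inherits(x, "attribution_set")) {
    lapply(seq_len(dim(x$maps)[1]), function(i) x$maps[i, , ])
  } else if (inherits(x, "attribution_map")) {
    list(x$importance)
  } else if (is.list(x)) {
    lapply(x, function(m) if (inherits(m, "attribution_map")) m$importance
           else m)
  } else stop("cannot interpret attribution input", call. = FALSE)
}

map_axes <- function(x) {
  if (inherits(x, "attribution_set"))
    list(channels = x$channels, times = x$times)
  else if (inherits(x, "attribution_map"))
    list(channels = x$channels, times = x$times)
  else if (is.list(x) && inherits(x[[1]], "attribution_map"))
    list(channels = x[[1]]$channels, times = x[[1]]$times)
  else list(channels = NULL, times = NULL)
}

#' Aggregate attribution maps
#'
#' Element-wise mean of normalized per-trial maps, re-normalized to
#' `[0, 1]`. `"subject_mean"` first averages within each participant and
#' `"grand_mean"` averages those subject means with equal weight (plain
#' mean if no participant information is available). Aggregation is
#' permutation-invariant.
#'
#' @param x An `attribution_set`, an `attribution_map` list, or a list of
#'   matrices sharing one shape.
#' @param level `"grand_mean"` (default) or `"subject_mean"` (returns one
#'   map per participant).
#' @return An `attribution_map`, or a named list of them for
#'   `"subject_mean"`.
#' @export
aggregate_maps <- function(x, level = c("grand_mean", "subject_mean")) {
  level <- match.arg(level)
  if (is.list(x) && !inherits(x, c("attribution_set", "attribution_map")) &&
      length(x) == 0L)
    stop("empty map list", call. = FALSE)
  ax <- map_axes(x)
  if (inherits(x, "attribution_set")) {
    pids <- x$participant_id
    if (is.null(pids)) pids <- rep(1L, dim(x$maps)[1])
    sub_means <- lapply(sort(unique(pids)), function(p) {
      sel <- which(pids == p)
      apply(x$maps[sel, , , drop = FALSE], c(2, 3), mean)
    })
    names(sub_means) <- sort(unique(pids))
    if (level == "subject_mean") {
      return(lapply(sub_means, function(m)
        new_attribution_map(minmax_norm(m), ax$channels, ax$times,
                            "per-subject-mean", NA_integer_)))
    }
    m <- Reduce(`+`, sub_means) / length(sub_means)
    return(new_attribution_map(minmax_norm(m), ax$channels, ax$times,
                               "grand-mean", dim(x$maps)[1]))
  }
  maps <- as_map_list(x)
  if (length(maps) == 0L) stop("empty map list", call. = FALSE)
  dims <- lapply(maps, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
    stop("maps do not share one shape", call. = FALSE)
  m <- Reduce(`+`, maps) / length(maps)
  new_attribution_map(minmax_norm(m), ax$channels, ax$times,
                      level, length(maps))
}

#' Element-wise median of attribution maps across repeated runs
#'
#' @param maps List of `attribution_map` objects (or matrices) from
#'   repeated analysis runs.
#' @return An `attribution_map`.
#' @export
run_median <- function(maps) {
  ms <- as_map_list(maps)
  if (length(ms) == 0L) stop("need at least one map", call. = FALSE)
  dims <- lapply(ms, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
    stop("maps do not share one shape", call. = FALSE)
  arr <- array(unlist(ms), c(dim(ms[[1]]), length(ms)))
  med <- apply(arr, c(1, 2), stats::median)
  ax <- map_axes(maps)
  new_attribution_map(med, ax$channels, ax$times, "run-median",
                      length(ms))
}

#' Fraction of attribution mass inside a channel x time window
#'
#' Sum of importance inside the given channels and time window divided by
#' the total importance; exact.
#'
#' @param map An `attribution_map`.
#' @param channels Channel labels defining the window rows.
#' @param t0,t1 Window bounds in ms post stimulus (inclusive).
#' @return A fraction in `[0, 1]`.
#' @export
window_mass <- function(map, channels, t0, t1) {
  ch_idx <- match(channels, map$channels)
  if (anyNA(ch_idx))
    stop("unknown channel(s): ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  tms <- map$times * 1000
  t_idx <- which(tms >= t0 & tms <= t1)
  if (length(t_idx) == 0L) stop("empty time window", call. = FALSE)
  tot <- sum(map$importance)
  if (tot == 0) return(0)
  sum(map$importance[ch_idx, t_idx]) / tot
}

#' Ratio of window mass to the uniform expectation
#'
#' A value of 1 means the window carries exactly its area share of the
#' attribution mass; 2 means twice the uniform expectation.
#'
#' @inheritParams window_mass
#' @export
window_mass_ratio <- function(map, channels, t0, t1) {
  frac <- window_mass(map, channels, t0, t1)
  tms <- map$times * 1000
  area <- (length(match(channels, map$channels)) / nrow(map$importance)) *
    (sum(tms >= t0 & tms <= t1) / ncol(map$importance))
  frac / area
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %d channels x %d samples (%s, max %.3f)\n",
              nrow(x$importance), ncol(x$importance),
              x$aggregation, max(x$importance)))
  invisible(x)
}
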
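#' Preprocessing configuration
#'
#' Defaults mirror standard ERP conditioning: 0.3-50 Hz zero-phase
#' band-pass, baseline correction over (-200, 0) ms, model window
#' (0, 1000) ms, 100 microvolt amplitude rejection, mastoid removal,
#' per-subject z-scoring and class balancing.
#'
#' @param bandpass Two-element numeric, Hz.
#' @param baseline_window Two-element numeric, ms.
#' @param model_window Two-element numeric, ms.
#' @param reject_threshold Microvolts.
#' @param drop_channels Channel labels removed before modeling.
#' @param balance Balance classes after conditioning?
#' @param seed Seed for the balancing draw.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass = c(0.3, 50),
                              baseline_window = c(-200, 0),
                              model_window = c(0, 1000),
                              reject_threshold = 100,
                              drop_channels = c("M1", "M2"),
                              balance = TRUE, seed = 1) {
  stopifnot(bandpass[1] > 0, bandpass[1] < bandpass[2],
            reject_threshold > 0,
            baseline_window[2] <= model_window[1])
  structure(list(bandpass = bandpass, baseline_window = baseline_window,
                 model_window = model_window,
                 reject_threshold = reject_threshold,
                 drop_channels = drop_channels, balance = balance,
                 seed = seed),
            class = "preprocess_config")
}

# smallest 5-smooth integer >= n (fast FFT length)
next_fast_len <- function(n) {
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# squared Butterworth magnitude response of the zero-phase band-pass
# (order-4 low-pass, order-2 high-pass, applied forward-backward in the
# spectral domain)
bandpass_gain <- function(f, low, high, n_lp = 4, n_hp = 2) {
  g <- ifelse(f == 0, 0,
              1 / (1 + (f / high)^(2 * n_lp)) /
                (1 + (low / pmax(f, .Machine$double.eps))^(2 * n_hp)))
  g
}

#' Zero-phase band-pass filter
#'
#' Spectral zero-phase filter: each channel trace is reflection-padded,
#' transformed, multiplied by the squared magnitude response of a
#' Butterworth band-pass (order 4 low-pass at `high`, order 2 high-pass at
#' `low` -- the forward-backward equivalent), and inverse transformed. DC
#' is removed exactly.
#'
#' @param epochs An [epoch_set()].
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @return The filtered `epoch_set`.
#' @export
bandpass_filter <- function(epochs, low = 0.3, high = 50) {
  fs <- epochs$sampling_rate
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  if (high >= fs / 2)
    stop("`high` must be below the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  d <- dim(epochs$data)
  N <- d[1L]; C <- d[2L]; T_len <- d[3L]
  P0 <- min(T_len - 1L, as.integer(round(fs)))  # ~1 s reflection padding
  L <- next_fast_len(T_len + 2L * P0)           # 5-smooth FFT length
  Pl <- (L - T_len) %/% 2L
  Pr <- L - T_len - Pl
  Pl <- min(Pl, T_len - 1L); Pr <- min(Pr, T_len - 1L)
  L <- T_len + Pl + Pr
  f <- fs * (seq_len(L) - 1) / L
  f <- pmin(f, fs - f)
  H <- bandpass_gain(f, low, high)

  X <- aperm(epochs$data, c(3, 2, 1))
  dim(X) <- c(T_len, C * N)
  out <- fft_filter(X, H, Pl, Pr)
  rm(X)
  dim(out) <- c(T_len, C, N)
  epochs$data <- aperm(out, c(3, 2, 1))
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from the whole trace.
#'
#' @param epochs An [epoch_set()].
#' @param window Two-element numeric, ms relative to onset.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  i0 <- ms_to_sample(epochs, window[1])
  i1 <- ms_to_sample(epochs, window[2])
  if (i1 < i0) stop("empty baseline window", call. = FALSE)
  if (i0 < 1 || i1 > n_samples(epochs))
    stop("baseline window outside the epoch extent", call. = FALSE)
  bl <- rowMeans(epochs$data[, , i0:i1, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over samples
  epochs
}

#' Crop epochs to the model window
#'
#' Keeps samples from `window[1]` to `window[2]` ms, inclusive at both
#' ends: at 250 Hz the default (0, 1000) ms window yields 251 samples.
#'
#' @param epochs An [epoch_set()].
#' @param window Two-element numeric, ms relative to onset.
#' @return The cropped `epoch_set`.
#' @export
crop_model_window <- function(epochs, window = c(0, 1000)) {
  i0 <- ms_to_sample(epochs, window[1])
  i1 <- ms_to_sample(epochs, window[2])
  if (i0 < 1 || i1 > n_samples(epochs) || i1 < i0)
    stop("model window exceeds the epoch extent", call. = FALSE)
  epochs$data <- epochs$data[, , i0:i1, drop = FALSE]
  epochs$time_zero_index <- epochs$time_zero_index - i0 + 1L
  epochs
}

#' Reject epochs containing large-amplitude artifacts
#'
#' Drops any trial whose absolute amplitude exceeds `threshold` at any
#' channel or sample; metadata is pruned in lockstep.
#'
#' @param epochs An [epoch_set()].
#' @param threshold Microvolts (> 0).
#' @return A list with `epochs` (the retained trials) and
#'   `rejected_indices` (original trial indices that were dropped).
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  bad <- which(as.vector(trial_absmax(epochs$data)) > threshold)
  if (length(bad) == n_trials(epochs))
    stop("all trials exceeded the rejection threshold", call. = FALSE)
  keep <- setdiff(seq_len(n_trials(epochs)), bad)
  list(epochs = epochs[keep], rejected_indices = bad)
}

#' Remove named channels from an EpochSet
#'
#' @param epochs An [epoch_set()].
#' @param labels Channel labels to drop (set semantics; dropping a label
#'   twice equals once).
#' @return The reduced `epoch_set` with its montage updated.
#' @export
drop_channels <- function(epochs, labels) {
  labels <- unique(labels)
  if (length(labels) == 0L) return(epochs)
  unknown <- setdiff(labels, epochs$montage$channels)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- !(epochs$montage$channels %in% labels)
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$montage <- montage_drop(epochs$montage, labels)
  epochs
}

#' Subject-level z-score normalization
#'
#' Per subject and channel, z-scores the data using mean/SD estimated on
#' the `fit_mask` trials only (all trials by default). The statistics are
#' returned so held-out or cross-task data can be normalized with
#' training-set statistics, preventing leakage (see
#' [apply_normalization()]).
#'
#' @param epochs An [epoch_set()].
#' @param fit_mask Logical or integer trial subset used to estimate the
#'   statistics; must cover every subject present.
#' @return A list with `epochs` (normalized) and `stats` (tibble:
#'   `participant_id`, `channel`, `mean`, `sd`).
#' @export
normalize_subject <- function(epochs, fit_mask = NULL) {
  N <- n_trials(epochs)
  if (is.null(fit_mask)) fit_mask <- seq_len(N)
  fit_idx <- seq_len(N)[fit_mask]
  subs <- sort(unique(epochs$metadata$participant_id))
  stats_list <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    fidx <- intersect(fit_idx,
                      which(epochs$metadata$participant_id == subs[i]))
    if (length(fidx) == 0L)
      stop("fit_mask contains no trials for subject ", subs[i],
           call. = FALSE)
    sub <- epochs$data[fidx, , , drop = FALSE]
    dim(sub) <- c(length(fidx), n_channels(epochs), n_samples(epochs))
    mu <- apply(sub, 2, mean)
    sdv <- apply(sub, 2, stats::sd)
    if (any(sdv == 0)) {
      warning("zero-variance channel(s) for subject ", subs[i],
              "; adding epsilon 1e-8 to the SD")
      sdv[sdv == 0] <- 1e-8
    }
    stats_list[[i]] <- tibble::tibble(
      participant_id = subs[i], channel = epochs$montage$channels,
      mean = mu, sd = sdv)
  }
  stats_tbl <- dplyr::bind_rows(stats_list)
  list(epochs = apply_normalization(epochs, stats_tbl), stats = stats_tbl)
}

#' Apply previously fitted normalization statistics
#'
#' @param epochs An [epoch_set()].
#' @param stats The `stats` tibble returned by [normalize_subject()].
#' @return The normalized `epoch_set`.
#' @export
apply_normalization <- function(epochs, stats) {
  for (pid in sort(unique(epochs$metadata$participant_id))) {
    st <- stats[stats$participant_id == pid, ]
    if (nrow(st) == 0L)
      stop("no normalization statistics for subject ", pid, call. = FALSE)
    st <- st[match(epochs$montage$channels, st$channel), ]
    idx <- which(epochs$metadata$participant_id == pid)
    sub <- epochs$data[idx, , , drop = FALSE]
    sub <- sweep(sub, 2, st$mean, "-")
    sub <- sweep(sub, 2, st$sd, "/")
    epochs$data[idx, , ] <- sub
  }
  epochs
}

#' Balance classes by seeded random undersampling
#'
#' Undersamples every class to the minority-class count and shuffles the
#' retained trials, deterministically given `seed`.
#'
#' @param epochs An [epoch_set()].
#' @param label_field Metadata column holding the class labels.
#' @param seed Seed for the undersampling draw.
#' @return The balanced `epoch_set`.
#' @export
balance_classes <- function(epochs, label_field, seed = 1) {
  labels <- as.character(epochs$metadata[[label_field]])
  if (is.null(epochs$metadata[[label_field]]))
    stop("unknown label field '", label_field, "'", call. = FALSE)
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("need at least two classes to balance", call. = FALSE)
  m <- min(counts)
  with_seed(derive_seed(seed, paste0("balance_", label_field)), {
    keep <- unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sample(idx, m) else idx
    }))
    keep <- sample(keep)
  })
  epochs[keep]
}

#' Run the deterministic conditioning pipeline
#'
#' Applies, in order: band-pass filter, baseline correction (before
#' cropping, so the pre-stimulus window is available), crop to the model
#' window, amplitude rejection, channel dropping. Normalization and
#' balancing are split-dependent and are applied by the experiment
#' drivers (or explicitly by the caller).
#'
#' @param epochs An [epoch_set()].
#' @param config A [preprocess_config()].
#' @return A list with `epochs` and a `report` list (counts in/out,
#'   rejected indices, channels dropped).
#' @export
preprocess_epochs <- function(epochs, config = preprocess_config()) {
  n_in <- n_trials(epochs)
  epochs <- bandpass_filter(epochs, config$bandpass[1], config$bandpass[2])
  epochs <- baseline_correct(epochs, config$baseline_window)
  epochs <- crop_model_window(epochs, config$model_window)
  rej <- reject_artifacts(epochs, config$reject_threshold)
  epochs <- rej$epochs
  dropped <- intersect(config$drop_channels, epochs$montage$channels)
  if (length(dropped)) epochs <- drop_channels(epochs, dropped)
  list(epochs = epochs,
       report = list(n_in = n_in, n_out = n_trials(epochs),
                     rejected_indices = rej$rejected_indices,
                     channels_dropped = dropped))
}
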
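#' Construct an EpochSet
#'
#' The package's core container: a trials x channels x samples amplitude
#' array (microvolts) plus per-trial metadata, the montage, the sampling
#' rate and the sample index of stimulus onset.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]`.
#' @param metadata Tibble with one row per trial (a trial-schedule slice).
#' @param montage A [default_montage()]-style montage whose channel count
#'   matches `dim(data)[2]`.
#' @param sampling_rate Sampling rate in Hz.
#' @param time_zero_index 1-based sample index of stimulus onset.
#' @param provenance Optional named list (seed, scenario, config hash ...).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, metadata, montage, sampling_rate,
                      time_zero_index, provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  es <- structure(
    list(data = data, metadata = tibble::as_tibble(metadata),
         montage = montage, sampling_rate = sampling_rate,
         time_zero_index = as.integer(time_zero_index),
         provenance = provenance),
    class = "epoch_set"
  )
  validate_epoch_set(es)
}

validate_epoch_set <- function(es) {
  d <- dim(es$data)
  if (nrow(es$metadata) != d[1L])
    stop("metadata rows (", nrow(es$metadata), ") != trial count (", d[1L],
         ")", call. = FALSE)
  if (length(es$montage$channels) != d[2L])
    stop("montage channel count (", length(es$montage$channels),
         ") != data channels (", d[2L], ")", call. = FALSE)
  if (es$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (es$time_zero_index < 1 || es$time_zero_index > d[3L])
    stop("time_zero_index outside the sample axis", call. = FALSE)
  es
}

#' Number of trials / channels / samples of an EpochSet
#' @param es An `epoch_set`.
#' @export
n_trials <- function(es) dim(es$data)[1L]

#' @rdname n_trials
#' @export
n_channels <- function(es) dim(es$data)[2L]

#' @rdname n_trials
#' @export
n_samples <- function(es) dim(es$data)[3L]

#' Time axis of an EpochSet, in seconds relative to stimulus onset
#' @param es An `epoch_set`.
#' @export
epoch_times <- function(es) {
  (seq_len(n_samples(es)) - es$time_zero_index) / es$sampling_rate
}

#' Subset trials of an EpochSet
#'
#' @param x An `epoch_set`.
#' @param i Trial index vector (integer or logical).
#' @param ... Unused.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  i <- seq_len(n_trials(x))[i]
  x$data <- x$data[i, , , drop = FALSE]
  x$metadata <- x$metadata[i, , drop = FALSE]
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  tr <- epoch_times(x)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%.3f, %.3f] s\n",
    n_trials(x), n_channels(x), n_samples(x), x$sampling_rate,
    tr[1L], tr[length(tr)]))
  if (nrow(x$metadata) > 0 && "task" %in% names(x$metadata)) {
    tb <- table(x$metadata$task)
    cat("  tasks:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# convert a ms value to the nearest sample index relative to onset
ms_to_sample <- function(es, ms) {
  es$time_zero_index + as.integer(round(ms / 1000 * es$sampling_rate))
}
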
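EPOCHSET_SCHEMA_VERSION <- "1.0"

#' Write an EpochSet to disk
#'
#' Writes a pair of files: `<path>.bin` (raw little-endian float64, trial
#' fastest, then channel, then sample) and `<path>.json` (schema version,
#' dimensions, sampling rate, onset index, montage, per-trial metadata and
#' provenance). The round trip is bit exact.
#'
#' @param es An `epoch_set`.
#' @param path Base path (without extension).
#' @return `path`, invisibly.
#' @export
write_epochset <- function(es, path) {
  meta <- list(
    schema_version = EPOCHSET_SCHEMA_VERSION,
    dims = dim(es$data), dtype = "float64", byte_order = "little",
    sampling_rate = es$sampling_rate,
    time_zero_index = es$time_zero_index,
    montage = list(channels = es$montage$channels,
                   reference = es$montage$reference,
                   mastoids = es$montage$mastoids,
                   groups = es$montage$groups),
    metadata = es$metadata,
    provenance = es$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(es$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an EpochSet written by [write_epochset()]
#'
#' @param path Base path (without extension).
#' @return An `epoch_set`.
#' @export
read_epochset <- function(path) {
  jf <- paste0(path, ".json"); bf <- paste0(path, ".bin")
  if (!file.exists(jf) || !file.exists(bf))
    stop("missing container file(s) at ", path, call. = FALSE)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(meta$schema_version, EPOCHSET_SCHEMA_VERSION))
    stop("schema version mismatch: file has '", meta$schema_version,
         "', reader expects '", EPOCHSET_SCHEMA_VERSION, "'",
         call. = FALSE)
  dims <- as.integer(meta$dims)
  expected <- prod(dims) * 8
  if (file.info(bf)$size != expected)
    stop("array file is truncated or corrupt: expected ", expected,
         " bytes, found ", file.info(bf)$size, call. = FALSE)
  con <- file(bf, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = prod(dims), size = 8,
                  endian = "little")
  montage <- structure(
    list(channels = as.character(meta$montage$channels),
         reference = meta$montage$reference,
         mastoids = as.character(meta$montage$mastoids),
         groups = lapply(meta$montage$groups, as.character)),
    class = "montage")
  md <- tibble::as_tibble(meta$metadata)
  if (prod(dims) == 0 && nrow(md) == 0 && length(md) == 0)
    md <- tibble::tibble(.rows = 0)
  epoch_set(array(vals, dims), md, montage, meta$sampling_rate,
            meta$time_zero_index,
            provenance = as.list(meta$provenance))
}

# ---------------------------------------------------------------------------
# Minimal European Data Format (EDF) writer/reader: continuous recording,
# 16-bit samples, 1-second data records, plus an integer "EVENTS" signal
# carrying a nonzero code at each stimulus-onset sample. No installed R
# package reads EDF, and the format is simple enough to support directly.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a continuous recording to EDF
#'
#' @param data Samples x channels numeric matrix (microvolts).
#' @param fs Sampling rate in Hz (integer).
#' @param labels Channel labels.
#' @param events Tibble/data frame with `sample` (1-based) and integer
#'   `code`; stored as an extra `EVENTS` signal.
#' @param path Output file.
#' @export
write_edf <- function(data, fs, labels, events, path) {
  stopifnot(is.matrix(data), ncol(data) == length(labels),
            fs == round(fs))
  ns <- length(labels) + 1L  # + events channel
  n_rec <- ceiling(nrow(data) / fs)
  total <- n_rec * fs
  if (total > nrow(data))
    data <- rbind(data, matrix(0, total - nrow(data), ncol(data)))
  ev <- integer(total)
  if (nrow(events) > 0) ev[events$sample] <- as.integer(events$code)

  pmax_ <- max(abs(data), 1)
  dig <- round(data / pmax_ * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80),
    pad_field("eegdecode export", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  all_labels <- c(labels, "EVENTS")
  fields <- list(
    lab = vapply(all_labels, pad_field, "", width = 16),
    trans = rep(pad_field("", 80), ns),
    dim = c(rep(pad_field("uV", 8), ns - 1), pad_field("", 8)),
    pmin = c(rep(pad_field(-pmax_, 8), ns - 1), pad_field(-32768, 8)),
    pmax = c(rep(pad_field(pmax_, 8), ns - 1), pad_field(32767, 8)),
    dmin = rep(pad_field(-32768, 8), ns),
    dmax = rep(pad_field(32767, 8), ns),
    pre = rep(pad_field("", 80), ns),
    spr = rep(pad_field(fs, 8), ns),
    res = rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_along(labels))
      writeBin(as.integer(dig[rows, ch]), con, size = 2,
               endian = "little")
    writeBin(ev[rows], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF)
#'
#' @param path EDF file.
#' @return A list: `data` (samples x channels, physical units), `fs`,
#'   `labels`, `events` (tibble with `sample`, `code`; taken from an
#'   `EVENTS` signal when present).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns)
  rd(8 * ns)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)

  out <- lapply(seq_len(ns), function(i)
    matrix(0L, spr[i], n_rec))
  for (r in seq_len(n_rec))
    for (ch in seq_len(ns))
      out[[ch]][, r] <- readBin(con, "integer", n = spr[ch], size = 2,
                                endian = "little", signed = TRUE)
  ev_ix <- which(labels == "EVENTS")
  fs <- spr[if (length(ev_ix)) setdiff(seq_len(ns), ev_ix)[1] else 1] /
    rec_dur
  keep <- setdiff(seq_len(ns), ev_ix)
  data <- vapply(keep, function(ch) {
    dg <- as.vector(out[[ch]])
    pmin[ch] + (dg - dmin[ch]) * (pmax[ch] - pmin[ch]) /
      (dmax[ch] - dmin[ch])
  }, numeric(spr[keep[1]] * n_rec))
  events <- tibble::tibble(sample = integer(0), code = integer(0))
  if (length(ev_ix)) {
    ev <- as.vector(out[[ev_ix]])
    nz <- which(ev != 0)
    events <- tibble::tibble(sample = nz, code = ev[nz])
  }
  list(data = data, fs = fs, labels = labels[keep], events = events)
}

#' Import epochs from an EDF recording
#'
#' Cuts fixed-length epochs around the event markers of an EDF file
#' (adapter for real recordings). Recordings whose sampling rate differs
#' from `target_fs` are linearly resampled with a warning; overlapping
#' epochs are allowed and flagged.
#'
#' @param path EDF file with an `EVENTS` signal (see [write_edf()]).
#' @param epoch_window Two-element numeric, seconds around each marker.
#' @param metadata Optional sidecar tibble with one row per event
#'   (merged into the epoch metadata).
#' @param target_fs Target sampling rate (default 250 Hz).
#' @return An `epoch_set`.
#' @export
import_edf <- function(path, epoch_window = c(-0.2, 1.0), metadata = NULL,
                       target_fs = 250) {
  rec <- read_edf(path)
  if (nrow(rec$events) == 0)
    stop("EDF file contains no event markers", call. = FALSE)
  data <- rec$data; fs <- rec$fs
  ev_samples <- rec$events$sample
  if (fs != target_fs) {
    warning("resampling from ", fs, " Hz to ", target_fs, " Hz")
    n_new <- round(nrow(data) * target_fs / fs)
    data <- apply(data, 2, function(x)
      stats::approx(seq_along(x), x, n = n_new)$y)
    ev_samples <- pmax(1L, round(ev_samples * target_fs / fs))
    fs <- target_fs
  }
  pre <- as.integer(round(-epoch_window[1] * fs))
  post <- as.integer(round(epoch_window[2] * fs))
  T_len <- pre + post + 1L
  ok <- ev_samples - pre >= 1 & ev_samples + post <= nrow(data)
  if (!all(ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  ev_samples <- ev_samples[ok]
  if (length(ev_samples) == 0)
    stop("no event leaves room for a full epoch", call. = FALSE)
  if (any(diff(sort(ev_samples)) < T_len))
    warning("epochs overlap")
  arr <- array(0, c(length(ev_samples), ncol(data), T_len))
  for (i in seq_along(ev_samples)) {
    rng <- (ev_samples[i] - pre):(ev_samples[i] + post)
    arr[i, , ] <- t(data[rng, ])
  }
  md <- tibble::tibble(trial_index = seq_along(ev_samples),
                       onset_sample = ev_samples,
                       code = rec$events$code[ok])
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)[ok, , drop = FALSE]
    md <- dplyr::bind_cols(md, metadata)
  }
  montage <- structure(list(channels = rec$labels, reference = NA,
                            mastoids = character(0),
                            groups = list()), class = "montage")
  epoch_set(arr, md, montage, fs, pre + 1L,
            provenance = list(source = path))
}

# ---------------------------------------------------------------------------

fnv_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) h <- ((bitwXor(as.integer(h %% 2^31), b)) *
                                  16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Load and validate a run configuration file
#'
#' Reads a YAML or JSON configuration mirroring the [report_config()]
#' schema, rejects unknown keys (naming the offending key), fills
#' defaults from the named profile, and records a content hash for
#' provenance.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `report_config` with `config_hash` attached.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- raw$profile %||% "desk"
  seed <- raw$master_seed %||% 1
  if (!is.numeric(seed))
    stop("type mismatch at master_seed: expected numeric", call. = FALSE)
  base <- report_config(profile, seed = seed)
  merge_checked <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k, call. = FALSE)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_checked(base[[k]], upd[[k]],
                                   paste0(prefix, k, "."))
      else {
        if (is.numeric(base[[k]]) && !is.numeric(upd[[k]]))
          stop("type mismatch at ", prefix, k, ": expected numeric",
               call. = FALSE)
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  cfg <- merge_checked(unclass(base), raw)
  cfg <- structure(cfg, class = c("report_config", "list"))
  canon <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                         digits = NA))
  cfg$config_hash <- fnv_hash(canon)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
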
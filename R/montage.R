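#' Default 64-electrode 10-10 montage
#'
#' Channel layout of a 64-electrode waveguard-style cap referenced at CPz
#' (the reference is not a data channel), leaving 63 recorded channels of
#' which the two mastoids `M1`/`M2` are flagged as removable, so that 61
#' data channels remain after mastoid removal.
#'
#' Region groups give the named channel subsets used to place simulated
#' components and to quantify attribution mass:
#' * `occipitoparietal`: P8, POz, O1, O2, P6, PO4, PO6, PO7, PO8, Oz
#' * `frontal`: prefrontal and frontal rows
#' * `central`: central strip
#'
#' @param drop_mastoids If `TRUE`, return the montage without M1/M2.
#' @return An object of class `montage`: a list with `channels` (ordered
#'   labels, roughly anterior to posterior), `reference`, `mastoids` and
#'   `groups`.
#' @export
#' @examples
#' m <- default_montage()
#' length(m$channels)       # 63 recorded channels
#' length(default_montage(drop_mastoids = TRUE)$channels)  # 61
default_montage <- function(drop_mastoids = FALSE) {
  # anterior -> posterior ordering (used for plotting and channel indexing)
  channels <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "M1", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "M2",
    "TP7", "CP5", "CP3", "CP1", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2"
  )
  groups <- list(
    occipitoparietal = c("P8", "POz", "O1", "O2", "P6", "PO4", "PO6",
                         "PO7", "PO8", "Oz"),
    frontal = c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
                "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    central = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                "FC3", "FC1", "FCz", "FC2", "FC4")
  )
  m <- structure(
    list(channels = channels, reference = "CPz",
         mastoids = c("M1", "M2"), groups = groups),
    class = "montage"
  )
  validate_montage(m)
  if (drop_mastoids) m <- montage_drop(m, m$mastoids)
  m
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  if (anyDuplicated(m$channels) > 0L)
    stop("montage channel labels must be unique", call. = FALSE)
  for (g in names(m$groups)) {
    extra <- setdiff(m$groups[[g]], m$channels)
    if (length(extra))
      stop("region group '", g, "' contains labels not in the montage: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

montage_drop <- function(m, labels) {
  unknown <- setdiff(labels, m$channels)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m$channels <- setdiff(m$channels, labels)
  m$groups <- lapply(m$groups, setdiff, y = labels)
  m$mastoids <- setdiff(m$mastoids, labels)
  m
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channels), " channels (reference ",
      x$reference, ")\n", sep = "")
  cat("  groups:", paste(sprintf("%s[%d]", names(x$groups),
                                 lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}
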
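#' Derive a named sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams (e.g. `"schedule"`, `"noise_s3"`, `"run2"`), so individual
#' stages can be re-run independently and still reproduce bit-identically.
#' The derivation is a small polynomial rolling hash of the stream name,
#' folded with the master seed modulo 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character scalar naming the sub-stream.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "schedule")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(stream)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
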
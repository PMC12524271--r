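# Internal helpers shared across modules.

FISH_KEYPOINTS <- c("head", "tail", "top", "bottom")

stopf <- function(fmt, ..., class = "stereofish_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "stereofish_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("%s must be finite", what, class = "domain_error")
  invisible(x)
}

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one user-supplied seed; named
#' substreams (e.g. "population", "pose", "noise") are derived from it so
#' that each stage is independently reproducible.
#'
#' @param seed master integer seed.
#' @param name substream name.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
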
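## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves always rounded up (the
#' convention used for all reported percentages), unlike [base::round()]'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(94.45, 1)  # 94.5, where round() would give 94.4
#' @export
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  # tiny nudge guards against 94.45 being represented as 94.4499999...
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

## structured condition constructors; callers can test inherits(e, class)
soyStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "soyOriginError")))
}

inputError   <- function(msg) soyStop("soyInputError", msg)
formatError  <- function(msg) soyStop("soyFormatError", msg)
notSoybeanError <- function(msg) soyStop("soyNotSoybeanError", msg)
undefinedMetricError <- function(msg) soyStop("soyUndefinedMetricError", msg)

## evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## derive an independent sub-stream seed from one master seed, so each named
## generator has its own stream and adding one does not shift another's
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
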
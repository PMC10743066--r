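#' Probability of catching a contaminant grain in a lot sample
#'
#' For a lot in which a fraction `p` of grains is of the other origin, the
#' probability that a random sample of `n` single grains contains at least
#' one such grain. With independent draws (the default, appropriate when
#' the lot is large relative to `n`) this is 1 - (1-p)^n; for small finite
#' lots pass `lotSize` to use the hypergeometric tail instead.
#'
#' @param n number of grains sampled (>= 1).
#' @param p contaminant grain fraction in \[0, 1\].
#' @param lotSize total grains in the lot, or `Inf` (default) for
#'   independent draws. Finite lots round `p * lotSize` to the nearest
#'   whole grain.
#' @return detection probability in \[0, 1\].
#' @examples
#' detectionPower(24, 0.1175)  # ~0.95: 24 grains suffice at ~12% admixture
#' @export
detectionPower <- function(n, p, lotSize = Inf) {
  if (any(n < 1) || any(n != as.integer(n))) inputError("n must be a positive integer")
  if (any(p < 0 | p > 1)) inputError("p must be in [0, 1]")
  if (is.infinite(lotSize)) return(1 - (1 - p)^n)
  K <- round(p * lotSize)
  if (any(n > lotSize)) inputError("cannot sample more grains than the lot holds")
  1 - stats::phyper(0, K, lotSize - K, n)
}

#' Minimum grains for a target detection confidence
#'
#' Smallest n with `detectionPower(n, p) >= confidence`, i.e.
#' ceiling(log(1-confidence) / log(1-p)) under independent draws. At an
#' admixture fraction of about 11.75%, 24 grains give 95% confidence — the
#' basis of the standard 24-grain lot sample.
#'
#' @param p contaminant fraction (0 < p <= 1).
#' @param confidence target detection probability (0 < confidence < 1).
#' @return integer number of grains.
#' @examples
#' minGrains(0.1175, 0.95)  # 24
#' @export
minGrains <- function(p, confidence = 0.95) {
  if (p <= 0 || p > 1) inputError("p must be in (0, 1]: p = 0 has no finite n")
  if (confidence <= 0 || confidence >= 1)
    inputError("confidence must be in (0, 1)")
  if (p == 1) return(1L)
  n <- as.integer(ceiling(log(1 - confidence) / log(1 - p)))
  # guard the closed form against floating-point edge cases
  while (detectionPower(n, p) < confidence) n <- n + 1L
  while (n > 1L && detectionPower(n - 1L, p) >= confidence) n <- n - 1L
  n
}

#' Aggregate grain verdicts into a lot verdict
#'
#' Default rule: consider only informative grains (verdicts domestic or
#' foreign; undetermined/unknown/invalid grains are ignored). All
#' informative grains domestic gives `domestic`; all foreign gives
#' `foreign`; both present gives `mixed`; no informative grain gives
#' `undetermined`. The rule is order-invariant.
#'
#' @param verdicts character vector of per-grain verdicts as produced by
#'   [classifyProfiles()] (length >= 1).
#' @return one of "domestic", "foreign", "mixed", "undetermined".
#' @export
aggregateLot <- function(verdicts) {
  if (length(verdicts) == 0L) inputError("need at least one grain verdict")
  hasD <- any(verdicts == "domestic")
  hasF <- any(verdicts == "foreign")
  if (hasD && hasF) return("mixed")
  if (hasD) return("domestic")
  if (hasF) return("foreign")
  "undetermined"
}

#' Classify grain lots
#'
#' Groups profile rows by `lot_id`, classifies each grain against the
#' table, and aggregates with [aggregateLot()].
#'
#' @param profiles profile data.frame with a `lot_id` column.
#' @param table a [DiscriminationTable-class].
#' @param panel a [MarkerPanel-class].
#' @return data.frame: lot_id, n grains, informative grain counts per side,
#'   and the lot verdict.
#' @export
classifyLots <- function(profiles, table, panel = soyPanel()) {
  if (!"lot_id" %in% names(profiles))
    inputError("profiles must have a lot_id column")
  res <- classifyProfiles(profiles, table, panel)
  res$lot_id <- profiles$lot_id
  do.call(rbind, lapply(split(res, res$lot_id), function(g)
    data.frame(lot_id = g$lot_id[1L], nGrains = nrow(g),
               nDomestic = sum(g$verdict == "domestic"),
               nForeign = sum(g$verdict == "foreign"),
               nUninformative = sum(!g$verdict %in% c("domestic", "foreign")),
               verdict = aggregateLot(g$verdict))))
}
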
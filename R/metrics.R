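#' Confusion tallies of a discrimination table
#'
#' Scores the table against itself: every sample at a value observed only
#' in its own origin (or at a resolved overlap, where external morphology
#' recovers the call on both sides) counts as correctly classified; samples
#' at unresolved overlapping values are classification failures on their
#' true side. This yields TD/FD over the domestic samples and TF/FF over
#' the foreign ones.
#'
#' @param x a [DiscriminationTable-class].
#' @param ... unused.
#' @name confusionCounts
#' @return a [ConfusionCounts-class].
#' @examples
#' confusionCounts(soyDiscriminationTable())  # TD 595 FD 35 TF 446 FF 20
#' @export
setMethod("confusionCounts", "DiscriminationTable", function(x, ...) {
  ov <- overlappingValues(x)   # unresolved only
  d <- domesticEntries(x); f <- foreignEntries(x)
  new("ConfusionCounts",
      TD = sum(d$count[!d$value %in% ov]),
      FD = sum(d$count[d$value %in% ov]),
      TF = sum(f$count[!f$value %in% ov]),
      FF = sum(f$count[f$value %in% ov]))
})

#' @rdname confusionCounts
#' @param TD,FD,TF,FF non-negative integer tallies.
#' @export
ConfusionCounts <- function(TD, FD, TF, FF) {
  new("ConfusionCounts", TD = as.integer(TD), FD = as.integer(FD),
      TF = as.integer(TF), FF = as.integer(FF))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TD %d, FD %d (domestic n=%d); TF %d, FF %d (foreign n=%d)\n",
              object@TD, object@FD, object@TD + object@FD,
              object@TF, object@FF, object@TF + object@FF))
})

#' Qualitative performance metrics
#'
#' Percentages reported to one decimal (half-up): sensitivity
#' 100*TD/(TD+FD) is the rate at which domestic samples are recovered as
#' domestic; selectivity 100*TF/(TF+FF) the same for foreign samples;
#' efficiency 100*(TD+TF)/(TD+FD+TF+FF) is their count-weighted mean. A
#' zero denominator raises `soyUndefinedMetricError`.
#'
#' @param x a [ConfusionCounts-class].
#' @param rounded logical; round half-up to 1 decimal (default) or return
#'   the raw ratio times 100.
#' @param ... unused.
#' @name performance-metrics
#' @return a percentage in \[0, 100\].
#' @examples
#' cc <- ConfusionCounts(595, 35, 446, 20)
#' sensitivity(cc)  # 94.4
#' selectivity(cc)  # 95.7
#' efficiency(cc)   # 95.0
#' @export
setMethod("sensitivity", "ConfusionCounts", function(x, rounded = TRUE, ...)
  pct(x@TD, x@TD + x@FD, rounded, "sensitivity"))

#' @rdname performance-metrics
#' @export
setMethod("selectivity", "ConfusionCounts", function(x, rounded = TRUE, ...)
  pct(x@TF, x@TF + x@FF, rounded, "selectivity"))

#' @rdname performance-metrics
#' @export
setMethod("efficiency", "ConfusionCounts", function(x, rounded = TRUE, ...)
  pct(x@TD + x@TF, x@TD + x@FD + x@TF + x@FF, rounded, "efficiency"))

pct <- function(num, den, rounded, what) {
  if (den == 0)
    undefinedMetricError(paste(what, "undefined: zero denominator"))
  p <- 100 * num / den
  if (rounded) roundHalfUp(p, 1L) else p
}

#' All three metrics at once
#'
#' @param x a [ConfusionCounts-class].
#' @param rounded see [sensitivity()].
#' @return named list with sensitivity, selectivity and efficiency.
#' @export
performanceSummary <- function(x, rounded = TRUE) {
  list(sensitivity = sensitivity(x, rounded),
       selectivity = selectivity(x, rounded),
       efficiency = efficiency(x, rounded))
}

#' Predictive rates on a validation set
#'
#' For an independent validation collection, the domestic predictive rate
#' is the percentage of true-domestic samples whose table verdict is
#' domestic; the foreign predictive rate is the same for foreign samples;
#' overall pools both sides.
#'
#' @param domesticCorrect,domesticTotal domestic samples verdicted
#'   domestic, and domestic samples tested.
#' @param foreignCorrect,foreignTotal same for foreign samples.
#' @param rounded see [sensitivity()].
#' @return named list (domestic, foreign, overall), percentages.
#' @examples
#' predictiveRates(29, 30, 30, 30)  # 96.7 / 100.0 / 98.3
#' @export
predictiveRates <- function(domesticCorrect, domesticTotal,
                            foreignCorrect, foreignTotal, rounded = TRUE) {
  if (domesticTotal <= 0 || foreignTotal <= 0)
    undefinedMetricError("predictive rates undefined: zero totals")
  if (domesticCorrect > domesticTotal || foreignCorrect > foreignTotal)
    inputError("correct counts cannot exceed totals")
  list(domestic = pct(domesticCorrect, domesticTotal, rounded, "rate"),
       foreign = pct(foreignCorrect, foreignTotal, rounded, "rate"),
       overall = pct(domesticCorrect + foreignCorrect,
                     domesticTotal + foreignTotal, rounded, "rate"))
}

#' Overlap summary of a discrimination table
#'
#' Quantifies how much of the table the unresolved overlapping values
#' spoil: `valueFraction` is their share of the union of distinct judgment
#' values across both origins; `sampleFraction` is the share of all
#' reference samples sitting at such values (and hence undeterminable by
#' the genetic assay).
#'
#' @param x a [DiscriminationTable-class].
#' @param rounded round percentages half-up to 1 decimal (default).
#' @param ... unused.
#' @name overlapStats
#' @return named list: nOverlapValues, valueFraction (%),
#'   nUndeterminedSamples, sampleFraction (%).
#' @examples
#' overlapStats(soyDiscriminationTable())  # 4 values, 3.4%, 55 samples, 5.0%
#' @export
setMethod("overlapStats", "DiscriminationTable",
          function(x, rounded = TRUE, ...) {
  ov <- overlappingValues(x)
  uni <- union(domesticEntries(x)$value, foreignEntries(x)$value)
  e <- tableEntries(x)
  und <- sum(e$count[e$value %in% ov])
  tot <- sum(e$count)
  vf <- if (length(uni) == 0L) 0 else 100 * length(ov) / length(uni)
  sf <- if (tot == 0L) 0 else 100 * und / tot
  if (rounded) { vf <- roundHalfUp(vf, 1L); sf <- roundHalfUp(sf, 1L) }
  list(nOverlapValues = length(ov), valueFraction = vf,
       nUndeterminedSamples = und, sampleFraction = sf)
})
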
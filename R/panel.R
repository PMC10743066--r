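#' Construct a MarkerPanel
#'
#' Builds a panel from a marker definition table. Scores are always derived
#' from marker index (marker k scores 2^(k-1)); they are never stored in the
#' input so the definition file cannot disagree with the encoding.
#'
#' @param markers data.frame with columns `marker` (index 1..n), `set`
#'   (multiplex set label), `final_conc`, `forward`, `reverse`, `size` (bp).
#'   Rows may appear in any order (definition files group by multiplex set).
#' @return a [MarkerPanel-class] object.
#' @examples
#' pan <- soyPanel()
#' nMarkers(pan)
#' @export
markerPanel <- function(markers) {
  need <- c("set", "marker", "final_conc", "forward", "reverse", "size")
  if (!all(need %in% names(markers)))
    formatError(paste("panel definition needs columns:",
                      paste(need, collapse = ", ")))
  m <- markers[order(markers$marker), , drop = FALSE]
  if (!identical(as.integer(m$marker), seq_len(nrow(m))))
    formatError("marker indices must be a permutation of 1..n")
  df <- data.frame(index = as.integer(m$marker),
                   score = as.numeric(2^(as.integer(m$marker) - 1L)),
                   ampliconSize = as.numeric(m$size),
                   multiplexSet = as.character(m$set),
                   forward = as.character(m$forward),
                   reverse = as.character(m$reverse),
                   finalConc = as.numeric(m$final_conc))
  new("MarkerPanel", markers = df)
}

#' Read a marker panel definition file
#'
#' @param path tab-separated file with the columns described in
#'   [markerPanel()].
#' @return a [MarkerPanel-class].
#' @export
readMarkerPanel <- function(path) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  markerPanel(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' The packaged eleven-marker soybean origin panel
#'
#' Loads the reference panel used throughout: eleven allele-specific InDel
#' markers (marker 1 the endogenous soybean control) in six multiplex sets
#' A-F, with amplicon sizes 102, 238, 473, 138, 107, 459, 246, 112, 324,
#' 872 and 112 bp for markers 1..11.
#'
#' @return a [MarkerPanel-class] with 11 markers.
#' @export
soyPanel <- function() {
  readMarkerPanel(system.file("extdata", "marker_panel.tsv",
                              package = "soyOrigin", mustWork = TRUE))
}

#' @describeIn MarkerPanel-accessors number of markers in the panel
#' @export
setMethod("nMarkers", "MarkerPanel", function(x) nrow(x@markers))

#' Accessors for MarkerPanel
#'
#' @param x a [MarkerPanel-class].
#' @name MarkerPanel-accessors
#' @return `nMarkers`: integer; `markerScores`, `ampliconSizes`: numeric
#'   vectors named by marker index; `multiplexSets`: list of marker-index
#'   vectors named by set label; `markers`: the full definition data.frame.
NULL

#' @describeIn MarkerPanel-accessors per-marker scores (2^(k-1))
#' @export
setMethod("markerScores", "MarkerPanel", function(x)
  stats::setNames(x@markers$score, x@markers$index))

#' @describeIn MarkerPanel-accessors per-marker amplicon sizes in bp
#' @export
setMethod("ampliconSizes", "MarkerPanel", function(x)
  stats::setNames(x@markers$ampliconSize, x@markers$index))

#' @describeIn MarkerPanel-accessors multiplex set label -> marker indices
#' @export
setMethod("multiplexSets", "MarkerPanel", function(x)
  split(x@markers$index, x@markers$multiplexSet))

#' @describeIn MarkerPanel-accessors the marker definition data.frame
#' @export
setMethod("markers", "MarkerPanel", function(x) x@markers)

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat(sprintf("MarkerPanel with %d markers in %d multiplex sets (%s)\n",
              nrow(m), length(unique(m$multiplexSet)),
              paste(sort(unique(m$multiplexSet)), collapse = ",")))
  cat(sprintf("  scores %s..%s; pattern capacity %d\n",
              format(min(m$score), scientific = FALSE),
              format(max(m$score), scientific = FALSE),
              patternCapacity(object)))
})

#' Encode an amplification profile as a judgment value
#'
#' A grain's genotype fingerprint is the sum of the scores of all amplified
#' markers. Marker 1 (the endogenous soybean control) must amplify for a
#' sample to be scoreable at all: a marker-1-negative profile means the
#' sample is not soybean and raises an error of class `soyNotSoybeanError`
#' rather than silently scoring 0. Every scoreable value is therefore odd.
#'
#' @param calls logical (or 0/1) vector of length `nMarkers(panel)`, a
#'   matrix with one row per sample, or a profile data.frame with columns
#'   `m1`..`m<n>` as produced by [readProfiles()].
#' @param panel a [MarkerPanel-class] (default the packaged panel).
#' @return integer judgment value(s); for the full panel an odd integer in
#'   \[1, 2047\].
#' @examples
#' pan <- soyPanel()
#' encodeJudgmentValue(rep(TRUE, 11), pan)                   # 2047
#' encodeJudgmentValue(c(1, 0, 1, 1, 1, 1, 0, 1, 0, 0, 0), pan)  # 189
#' @export
encodeJudgmentValue <- function(calls, panel = soyPanel()) {
  mat <- callMatrix(calls, panel)
  if (any(!mat[, 1L]))
    notSoybeanError(paste(
      "endogenous control (marker 1) did not amplify; sample is not",
      "scoreable as soybean"))
  as.integer(mat %*% markerScores(panel))
}

## normalize calls input to a logical matrix with nMarkers(panel) columns
callMatrix <- function(calls, panel) {
  n <- nMarkers(panel)
  if (is.data.frame(calls)) {
    cols <- paste0("m", seq_len(n))
    if (!all(cols %in% names(calls)))
      inputError(paste("profile data.frame must have columns",
                       cols[1], "..", cols[n]))
    calls <- as.matrix(calls[cols])
  }
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1L)
  if (ncol(calls) != n)
    inputError(sprintf("expected %d marker calls per profile, got %d",
                       n, ncol(calls)))
  if (!all(calls %in% c(0, 1)))
    inputError("marker calls must be logical or 0/1")
  storage.mode(calls) <- "logical"
  calls
}

#' Decode a judgment value into its amplified marker set
#'
#' Inverts the encoding: because scores are distinct powers of two, every
#' valid judgment value has a unique decomposition into marker scores.
#'
#' @param value a single judgment value (odd, in \[1, sum of panel scores\]).
#' @param panel a [MarkerPanel-class].
#' @return integer vector of amplified marker indices (always contains 1).
#' @examples
#' decodeJudgmentValue(189)   # 1 3 4 5 6 8
#' decodeJudgmentValue(2047)  # 1..11
#' @export
decodeJudgmentValue <- function(value, panel = soyPanel()) {
  if (length(value) != 1L || is.na(value) || value != as.integer(value))
    inputError("value must be a single integer")
  value <- as.integer(value)
  sc <- markerScores(panel)
  if (value < 1L || value > sum(sc))
    inputError(sprintf("judgment value %d outside [1, %d]",
                       value, as.integer(sum(sc))))
  if (value %% 2L == 0L)
    inputError(paste("even judgment value", value,
                     "is invalid: the control marker (score 1) is missing"))
  rest <- value
  taken <- logical(length(sc))
  for (k in rev(seq_along(sc))) {     # greedy works: scores are powers of 2
    if (rest >= sc[k]) { taken[k] <- TRUE; rest <- rest - sc[k] }
  }
  if (rest != 0L)
    inputError(sprintf("value %d cannot be decomposed over this panel", value))
  which(taken)
}

#' Theoretical pattern capacity of a panel
#'
#' Number of distinct genetic patterns the binary scoring scheme can
#' distinguish: 2^n for an n-marker panel (2048 for the packaged 11-marker
#' panel). Half of these (the odd values) are scoreable soybean patterns;
#' the even half encodes control failure.
#'
#' @param x a [MarkerPanel-class].
#' @name patternCapacity
#' @return integer count of distinct patterns.
#' @examples
#' patternCapacity(soyPanel())  # 2048
#' @export
setMethod("patternCapacity", "MarkerPanel",
          function(x) as.integer(2^nMarkers(x)))

#' Check amplicon-size separation within multiplex sets
#'
#' Markers co-amplified in one multiplex PCR must yield products whose
#' sizes are distinguishable on a gel. Flags every within-set marker pair
#' closer than `margin` bp (default 20; the smallest gap in the packaged
#' panel is 26 bp, markers 4 vs 11 in set B).
#'
#' @param panel a [MarkerPanel-class].
#' @param margin minimum acceptable within-set size difference in bp (> 0).
#' @return data.frame of violations (set, markerA, markerB, sizeA, sizeB,
#'   gap); zero rows when the panel is separable at `margin`.
#' @export
validateMultiplex <- function(panel, margin = 20) {
  if (!is.numeric(margin) || margin <= 0) inputError("margin must be > 0")
  sizes <- ampliconSizes(panel)
  out <- list()
  for (set in names(multiplexSets(panel))) {
    idx <- multiplexSets(panel)[[set]]
    if (length(idx) < 2L) next
    pairs <- utils::combn(idx, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      gap <- abs(sizes[[a]] - sizes[[b]])
      if (gap < margin)
        out[[length(out) + 1L]] <- data.frame(
          set = set, markerA = a, markerB = b,
          sizeA = sizes[[a]], sizeB = sizes[[b]], gap = gap)
    }
  }
  if (length(out) == 0L)
    return(data.frame(set = character(), markerA = integer(),
                      markerB = integer(), sizeA = numeric(),
                      sizeB = numeric(), gap = numeric()))
  do.call(rbind, out)
}

#' Drop markers from a panel
#'
#' Returns the panel restricted to the remaining markers, re-indexed 1..m
#' in the original order (so scores are again 2^(k-1)). Used by the panel
#' reduction experiment; the control marker cannot be dropped. Note that
#' [reducePanel()] on a [DiscriminationTable-class] keeps the original
#' score basis instead, so its reduced values stay comparable to the full
#' table; this function is for building genuinely smaller assays.
#'
#' @param panel a [MarkerPanel-class].
#' @param drop integer indices of markers to remove (must not include 1).
#' @return a [MarkerPanel-class] with `nMarkers(panel) - length(drop)`
#'   markers.
#' @export
dropMarkers <- function(panel, drop) {
  drop <- as.integer(drop)
  if (1L %in% drop)
    inputError("marker 1 is the mandatory endogenous control; cannot drop it")
  if (!all(drop %in% markers(panel)$index))
    inputError("drop indices outside the panel")
  keep <- markers(panel)$index[!markers(panel)$index %in% drop]
  m <- markers(panel)[keep, , drop = FALSE]
  df <- data.frame(set = m$multiplexSet, marker = seq_len(nrow(m)),
                   final_conc = m$finalConc, forward = m$forward,
                   reverse = m$reverse, size = m$ampliconSize)
  markerPanel(df)
}
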
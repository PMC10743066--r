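#' MarkerPanel: an ordered allele-specific PCR marker panel
#'
#' Holds the ordered marker definitions of a binary-scored InDel panel.
#' Marker 1 is the endogenous soybean control (score 1); marker k carries
#' score 2^(k-1), so a sample's amplification profile encodes to a unique
#' integer judgment value. Each marker belongs to a multiplex set whose
#' amplicon sizes must be separable on a gel.
#'
#' @slot markers data.frame with one row per marker and columns
#'   `index` (1..n), `score` (2^(index-1)), `ampliconSize` (bp),
#'   `multiplexSet` (single-letter label), `forward`, `reverse`
#'   (A/C/G/T primer sequences) and `finalConc` (ng/uL).
#'
#' @seealso [markerPanel()], [soyPanel()], [encodeJudgmentValue()]
#' @export
setClass("MarkerPanel", representation(markers = "data.frame"))

setValidity("MarkerPanel", function(object) {
  m <- object@markers
  need <- c("index", "score", "ampliconSize", "multiplexSet",
            "forward", "reverse", "finalConc")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) < 1L) return("panel must contain at least the control marker")
  if (!identical(m$index, seq_len(nrow(m))))
    return("marker indices must be 1..n in order")
  if (!identical(as.double(m$score), 2^(m$index - 1)))
    return("score of marker k must be 2^(k-1) (marker 1 scores 1)")
  if (any(diff(m$score) <= 0)) return("scores must be strictly increasing")
  if (any(m$ampliconSize <= 0)) return("amplicon sizes must be positive")
  bad <- !grepl("^[ACGT]+$", m$forward) | !grepl("^[ACGT]+$", m$reverse)
  if (any(bad)) return("primers must be nonempty A/C/G/T strings")
  TRUE
})

#' DiscriminationTable: origin-labeled judgment values with sample counts
#'
#' The lookup table at the heart of origin classification: each entry is a
#' judgment value observed among labeled reference samples of one origin
#' (domestic or foreign), with the number of samples observed at that value
#' and an optional variety note. Values present in both origins are
#' "overlapping" and cannot be resolved by the genetic assay alone;
#' `resolvedValues` marks those that external evidence (seed morphology)
#' disambiguates.
#'
#' @slot entries data.frame with columns `value` (odd integer judgment
#'   value), `origin` ("domestic" or "foreign"), `count` (samples observed,
#'   >= 0) and `note` (character).
#' @slot resolvedValues integer vector of overlap values resolved by
#'   external evidence (empty by default).
#' @slot maxValue integer, the largest judgment value the generating panel
#'   can produce (2047 for the full 11-marker panel).
#'
#' @seealso [buildDiscriminationTable()], [soyDiscriminationTable()],
#'   [classifyValue()], [overlappingValues()]
#' @export
setClass("DiscriminationTable",
         representation(entries = "data.frame",
                        resolvedValues = "integer",
                        maxValue = "integer"),
         prototype(entries = data.frame(value = integer(),
                                        origin = character(),
                                        count = integer(),
                                        note = character()),
                   resolvedValues = integer(),
                   maxValue = 2047L))

setValidity("DiscriminationTable", function(object) {
  e <- object@entries
  need <- c("value", "origin", "count", "note")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(e$origin %in% c("domestic", "foreign")))
    return("origin must be 'domestic' or 'foreign'")
  if (any(e$value %% 2 != 1))
    return("judgment values must be odd (control marker always scores 1)")
  if (any(e$value < 1 | e$value > object@maxValue))
    return(sprintf("judgment values must lie in [1, %d]", object@maxValue))
  if (anyDuplicated(e[c("value", "origin")]))
    return("judgment values must be unique within each origin")
  if (any(e$count < 0)) return("duplicate counts must be non-negative")
  TRUE
})

#' ConfusionCounts: tallies for the qualitative performance metrics
#'
#' Confusion tallies of an origin discrimination table or validation run:
#' TD (true domestic) and FD (domestic samples not recovered as domestic)
#' partition the domestic samples; TF (true foreign) and FF (foreign
#' samples not recovered as foreign) partition the foreign ones. They feed
#' sensitivity = TD/(TD+FD), selectivity = TF/(TF+FF) and
#' efficiency = (TD+TF)/(TD+FD+TF+FF), each times 100.
#'
#' @slot TD,FD,TF,FF non-negative integer tallies.
#' @seealso [confusionCounts()], [sensitivity()], [efficiency()]
#' @export
setClass("ConfusionCounts",
         representation(TD = "integer", FD = "integer",
                        TF = "integer", FF = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TD, object@FD, object@TF, object@FF)
  if (any(is.na(v)) || any(v < 0)) return("tallies must be non-negative")
  TRUE
})
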
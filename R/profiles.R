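#' Read per-grain amplification profiles
#'
#' Profile files are tab-separated with one row per grain: `sample_id`,
#' `origin` (domestic/imported/foreign/unknown, optional), `variety`
#' (optional), then `m1`..`m<n>` amplification calls as 0/1. Extra columns
#' (e.g. `lot_id`, or an expected `judgment_value`) are preserved.
#'
#' @param path path to a tab-separated profile file.
#' @param panel panel the calls refer to (checks the column count).
#' @return data.frame of profiles.
#' @seealso [writeProfiles()], [encodeJudgmentValue()]
#' @export
readProfiles <- function(path, panel = soyPanel()) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- paste0("m", seq_len(nMarkers(panel)))
  if (!all(cols %in% names(df)))
    formatError(paste("profile file must have call columns",
                      cols[1], "..", cols[length(cols)]))
  if (!"sample_id" %in% names(df))
    formatError("profile file must have a sample_id column")
  bad <- !as.matrix(df[cols]) %in% c(0, 1)
  if (any(bad)) formatError("marker calls must be 0 or 1")
  df
}

#' Write per-grain amplification profiles
#'
#' @param profiles data.frame as returned by [readProfiles()] or the
#'   synthetic generators.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Judgment values for a set of profiles
#'
#' Vectorized encoding with per-sample control handling: rows whose
#' endogenous control (marker 1) did not amplify get `NA` and are listed in
#' the `invalid` attribute instead of aborting the whole batch (use
#' [encodeJudgmentValue()] for strict single-profile scoring).
#'
#' @param profiles profile data.frame (see [readProfiles()]).
#' @param panel a [MarkerPanel-class].
#' @return integer vector of judgment values, `NA` for marker-1-negative
#'   rows, with attribute `invalid` holding their sample ids.
#' @export
judgmentValues <- function(profiles, panel = soyPanel()) {
  mat <- callMatrix(profiles, panel)
  ok <- mat[, 1L]
  vals <- as.integer(mat %*% markerScores(panel))
  vals[!ok] <- NA_integer_
  ids <- if ("sample_id" %in% names(profiles)) profiles$sample_id
         else as.character(seq_len(nrow(mat)))
  structure(vals, invalid = ids[!ok])
}

#' The packaged standard-sample profiles
#'
#' Sixteen reference cultivars (15 Korean and the Williams 82 reference)
#' with their amplification profiles over the packaged panel and their
#' printed judgment values (column `judgment_value`). Two Korean cultivars,
#' Seonyu and Hwangkeumol, share value 665 and are therefore not
#' distinguishable by the assay.
#'
#' @return profile data.frame with 16 rows.
#' @export
soyStandards <- function() {
  readProfiles(system.file("extdata", "standard_samples.tsv",
                           package = "soyOrigin", mustWork = TRUE))
}
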
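#' Construct a DiscriminationTable from entry data
#'
#' @param entries data.frame with columns `value`, `origin` ("domestic" /
#'   "foreign"; "imported" is accepted and mapped to "foreign"), `count`
#'   and optionally `note`.
#' @param resolvedValues judgment values whose domestic/foreign overlap is
#'   resolved by external (morphological) evidence.
#' @param maxValue largest value the generating panel can produce.
#' @return a [DiscriminationTable-class].
#' @export
discriminationTable <- function(entries, resolvedValues = integer(),
                                maxValue = 2047L) {
  if (!"note" %in% names(entries)) entries$note <- rep("", nrow(entries))
  entries$origin <- ifelse(entries$origin == "imported", "foreign",
                           entries$origin)
  e <- data.frame(value = as.integer(entries$value),
                  origin = as.character(entries$origin),
                  count = as.integer(entries$count),
                  note = as.character(entries$note))
  e <- e[order(e$origin, e$value), , drop = FALSE]
  rownames(e) <- NULL
  new("DiscriminationTable", entries = e,
      resolvedValues = as.integer(resolvedValues),
      maxValue = as.integer(maxValue))
}

#' Build a discrimination table from labeled profiles
#'
#' Encodes every profile and tallies the distinct judgment values per
#' origin: entry counts are the observed sample multiplicities, so counts
#' per origin always sum to the number of input samples of that origin.
#'
#' @param profiles profile data.frame with an `origin` column (domestic /
#'   imported / foreign) and call columns (see [readProfiles()]).
#' @param panel a [MarkerPanel-class].
#' @param resolvedValues see [discriminationTable()].
#' @return a [DiscriminationTable-class].
#' @examples
#' tab <- buildDiscriminationTable(soyStandards())
#' totalSamples(tab)
#' @export
buildDiscriminationTable <- function(profiles, panel = soyPanel(),
                                     resolvedValues = integer()) {
  if (nrow(profiles) == 0L)
    return(discriminationTable(
      data.frame(value = integer(), origin = character(), count = integer()),
      resolvedValues, sum(markerScores(panel))))
  if (!"origin" %in% names(profiles) || anyNA(profiles$origin))
    inputError("every profile must carry an origin label")
  org <- ifelse(profiles$origin == "imported", "foreign", profiles$origin)
  if (!all(org %in% c("domestic", "foreign")))
    inputError("origin labels must be domestic, imported or foreign")
  vals <- judgmentValues(profiles, panel)
  if (length(attr(vals, "invalid")) > 0L)
    notSoybeanError(paste(
      "marker-1-negative (non-soybean) profiles cannot enter the table:",
      paste(attr(vals, "invalid"), collapse = ", ")))
  agg <- stats::aggregate(list(count = rep(1L, length(vals))),
                          by = list(value = as.integer(vals), origin = org),
                          FUN = sum)
  vnote <- if ("variety" %in% names(profiles)) profiles$variety else NULL
  agg$note <- ""
  if (!is.null(vnote)) {
    key <- paste(vals, org)
    notes <- tapply(vnote, key, function(v)
      paste(sort(unique(v[!is.na(v) & nzchar(v)])), collapse = "/"))
    agg$note <- as.character(notes[paste(agg$value, agg$origin)])
  }
  discriminationTable(agg, resolvedValues, sum(markerScores(panel)))
}

#' Accessors for DiscriminationTable
#'
#' @param x a [DiscriminationTable-class].
#' @param value replacement integer vector (for `resolvedValues<-`).
#' @param origin for `totalSamples`: "domestic", "foreign" or "both".
#' @param ... unused.
#' @name DiscriminationTable-accessors
NULL

#' @describeIn DiscriminationTable-accessors all entries as a data.frame
#' @export
setMethod("tableEntries", "DiscriminationTable", function(x) x@entries)

#' @describeIn DiscriminationTable-accessors domestic entries
#' @export
setMethod("domesticEntries", "DiscriminationTable", function(x)
  x@entries[x@entries$origin == "domestic", , drop = FALSE])

#' @describeIn DiscriminationTable-accessors foreign entries
#' @export
setMethod("foreignEntries", "DiscriminationTable", function(x)
  x@entries[x@entries$origin == "foreign", , drop = FALSE])

#' @describeIn DiscriminationTable-accessors values resolved by morphology
#' @export
setMethod("resolvedValues", "DiscriminationTable", function(x)
  x@resolvedValues)

#' @describeIn DiscriminationTable-accessors set the resolved values
#' @export
setReplaceMethod("resolvedValues", "DiscriminationTable", function(x, value) {
  x@resolvedValues <- as.integer(value)
  methods::validObject(x)
  x
})

#' @describeIn DiscriminationTable-accessors total observed samples
#' @export
setMethod("totalSamples", "DiscriminationTable",
          function(x, origin = c("both", "domestic", "foreign")) {
  origin <- match.arg(origin)
  e <- x@entries
  if (origin != "both") e <- e[e$origin == origin, , drop = FALSE]
  sum(e$count)
})

setMethod("show", "DiscriminationTable", function(object) {
  d <- domesticEntries(object); f <- foreignEntries(object)
  ov <- overlappingValues(object)
  cat(sprintf(paste0(
    "DiscriminationTable: %d domestic values (%d samples), ",
    "%d foreign values (%d samples)\n"),
    nrow(d), sum(d$count), nrow(f), sum(f$count)))
  cat(sprintf("  unresolved overlapping values: %s\n",
              if (length(ov)) paste(ov, collapse = ", ") else "none"))
  if (length(object@resolvedValues))
    cat(sprintf("  resolved by external evidence: %s\n",
                paste(object@resolvedValues, collapse = ", ")))
})

#' Judgment values observed in both origins
#'
#' Overlapping values defeat the genetic assay: a sample at such a value
#' cannot be assigned an origin by table lookup. Values marked as resolved
#' (morphological disambiguation) are excluded.
#'
#' @param x a [DiscriminationTable-class].
#' @param ... unused.
#' @name overlappingValues
#' @return sorted integer vector of unresolved overlapping values.
#' @export
setMethod("overlappingValues", "DiscriminationTable", function(x, ...) {
  ov <- intersect(domesticEntries(x)$value, foreignEntries(x)$value)
  sort(setdiff(ov, x@resolvedValues))
})

#' Classify a judgment value against a discrimination table
#'
#' Membership lookup: `domestic` if the value occurs only among domestic
#' entries, `foreign` if only among foreign ones, `undetermined_overlap` if
#' it occurs in both and is unresolved, and `unknown_value` if the table
#' has never seen it. A resolved overlapping value still needs the external
#' (morphological) call for the individual sample, passed as `sideHint`;
#' without a hint the sample stays `undetermined_overlap`.
#'
#' @param value a judgment value (odd integer within the table's range).
#' @param table a [DiscriminationTable-class].
#' @param sideHint optional "domestic" or "foreign": the morphology call
#'   used only when `value` is a resolved overlap.
#' @return one of "domestic", "foreign", "undetermined_overlap",
#'   "unknown_value".
#' @examples
#' tab <- soyDiscriminationTable()
#' classifyValue(189, tab)   # domestic (Sinhwa)
#' classifyValue(2047, tab)  # foreign (Williams82)
#' classifyValue(671, tab)   # undetermined_overlap
#' @export
classifyValue <- function(value, table, sideHint = NULL) {
  if (length(value) != 1L || is.na(value) || value != as.integer(value))
    inputError("value must be a single integer")
  value <- as.integer(value)
  if (value %% 2L != 1L || value < 1L || value > table@maxValue)
    inputError(sprintf("invalid judgment value %d (odd, in [1, %d])",
                       value, table@maxValue))
  inDom <- value %in% domesticEntries(table)$value
  inFor <- value %in% foreignEntries(table)$value
  if (inDom && inFor) {
    if (value %in% table@resolvedValues && !is.null(sideHint)) {
      sideHint <- match.arg(sideHint, c("domestic", "foreign"))
      return(sideHint)
    }
    return("undetermined_overlap")
  }
  if (inDom) return("domestic")
  if (inFor) return("foreign")
  "unknown_value"
}

#' Classify a batch of profiles
#'
#' Encodes each profile and looks it up in the table. Marker-1-negative
#' profiles get verdict `invalid_sample` (the assay says "not soybean")
#' instead of aborting the batch.
#'
#' @param profiles profile data.frame (see [readProfiles()]).
#' @param table a [DiscriminationTable-class].
#' @param panel a [MarkerPanel-class].
#' @return data.frame with sample_id, judgment_value and verdict.
#' @export
classifyProfiles <- function(profiles, table, panel = soyPanel()) {
  vals <- judgmentValues(profiles, panel)
  verdict <- vapply(seq_along(vals), function(i) {
    if (is.na(vals[i])) "invalid_sample"
    else classifyValue(vals[i], table)
  }, character(1))
  ids <- if ("sample_id" %in% names(profiles)) profiles$sample_id
         else as.character(seq_along(vals))
  data.frame(sample_id = ids, judgment_value = as.integer(vals),
             verdict = verdict)
}

#' Collapse a discrimination table onto a reduced marker panel
#'
#' Simulates running the assay without some markers: each judgment value is
#' mapped to itself minus the scores of the dropped markers present in its
#' decomposition; entries that collapse onto the same value merge, their
#' sample counts summing and variety notes concatenating. Total counts per
#' origin are conserved; the number of distinct values can only shrink, so
#' discrimination can only degrade.
#'
#' @param table a [DiscriminationTable-class] built on `panel`.
#' @param drop integer marker indices to remove (never 1, the control).
#' @param panel the full [MarkerPanel-class] the table was built on.
#' @return a [DiscriminationTable-class] over the reduced score basis.
#' @examples
#' tab10 <- reducePanel(soyDiscriminationTable(), drop = 11)
#' @export
reducePanel <- function(table, drop, panel = soyPanel()) {
  drop <- as.integer(drop)
  if (length(drop) == 0L) return(table)
  if (1L %in% drop)
    inputError("marker 1 is the mandatory endogenous control; cannot drop it")
  sc <- markerScores(panel)
  if (!all(drop %in% markers(panel)$index))
    inputError("drop indices outside the panel")
  e <- tableEntries(table)
  dropSum <- vapply(e$value, function(v) {
    idx <- decodeJudgmentValue(v, panel)
    sum(sc[idx[idx %in% drop]])
  }, numeric(1))
  e$value <- as.integer(e$value - dropSum)
  merged <- do.call(rbind, lapply(split(e, list(e$origin, e$value),
                                        drop = TRUE), function(g)
    data.frame(value = g$value[1L], origin = g$origin[1L],
               count = sum(g$count),
               note = paste(unique(g$note[nzchar(g$note)]),
                            collapse = "/"))))
  discriminationTable(merged, resolvedValues = integer(),
                      maxValue = as.integer(sum(sc[-drop])))
}

#' Read / write discrimination tables
#'
#' Table files are tab-separated with one row per judgment value:
#' `judgment_value`, per-marker score columns `m1`..`m<n>` (the score when
#' amplified, empty otherwise), `duplicate_count`, `origin`, `note`.
#' Comment lines `# resolved_values:` and `# max_value:` carry the
#' remaining state, making write-then-read lossless. On reading, each
#' row's marker score columns must re-sum to its judgment value and values
#' must be unique within an origin; violations raise `soyFormatError`.
#'
#' @param path one or more file paths; entries are pooled (the packaged
#'   reference is shipped as one domestic and one foreign file).
#' @param table a [DiscriminationTable-class] to write.
#' @param panel panel whose scores define the per-marker columns.
#' @return `readDiscriminationTable`: a [DiscriminationTable-class];
#'   `writeDiscriminationTable`: `path`, invisibly.
#' @export
readDiscriminationTable <- function(path, panel = soyPanel()) {
  parts <- lapply(path, readOneTableFile, panel = panel)
  entries <- do.call(rbind, lapply(parts, `[[`, "entries"))
  resolved <- sort(unique(unlist(lapply(parts, `[[`, "resolved"))))
  maxv <- max(c(sum(markerScores(panel)),
                unlist(lapply(parts, `[[`, "maxValue"))))
  if (anyDuplicated(entries[c("value", "origin")]))
    formatError("duplicate judgment value within one origin")
  discriminationTable(entries, as.integer(resolved), as.integer(maxv))
}

readOneTableFile <- function(path, panel) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getMeta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(ln) == 0L) return(integer())
    txt <- sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1L])
    if (!nzchar(trimws(txt))) integer()
    else as.integer(strsplit(trimws(txt), "\\s*,\\s*")[[1L]])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  need <- c("judgment_value", "duplicate_count", "origin")
  if (!all(need %in% names(df)))
    formatError(paste("table file must have columns:",
                      paste(need, collapse = ", ")))
  mcols <- paste0("m", seq_len(nMarkers(panel)))
  if (all(mcols %in% names(df))) {
    bits <- as.matrix(df[mcols])
    bits[is.na(bits)] <- 0
    bad <- rowSums(bits) != df$judgment_value
    if (any(bad))
      formatError(paste(
        "marker score columns do not re-sum to the judgment value in rows:",
        paste(which(bad), collapse = ", ")))
  }
  if (!"note" %in% names(df)) df$note <- ""
  df$note[is.na(df$note)] <- ""
  list(entries = data.frame(value = df$judgment_value, origin = df$origin,
                            count = df$duplicate_count, note = df$note),
       resolved = getMeta("resolved_values"),
       maxValue = getMeta("max_value"))
}

#' @rdname readDiscriminationTable
#' @export
writeDiscriminationTable <- function(table, path, panel = soyPanel()) {
  e <- tableEntries(table)
  sc <- markerScores(panel)
  bits <- t(vapply(e$value, function(v) {
    idx <- decodeJudgmentValue(v, panel)
    out <- rep(NA_real_, length(sc)); out[idx] <- sc[idx]; out
  }, numeric(length(sc))))
  colnames(bits) <- paste0("m", seq_along(sc))
  out <- data.frame(judgment_value = e$value, bits,
                    duplicate_count = e$count, origin = e$origin,
                    note = e$note, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolved_values: %s",
                     paste(table@resolvedValues, collapse = ",")), con)
  writeLines(sprintf("# max_value: %d", table@maxValue), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged origin discrimination table
#'
#' The reference table built from 1096 labeled soybean samples (630
#' domestic, 466 foreign): 53 distinct domestic and 70 distinct foreign
#' judgment values. Four values (671, 1183, 1215, 1695) occur in both
#' origins; 1215 (domestic Pungsannamul vs Chinese varieties) is the one
#' resolvable by seed morphology, enabled via `resolve1215`.
#'
#' @param resolve1215 logical; mark value 1215 as morphologically resolved
#'   (default FALSE: the genetic assay alone).
#' @return a [DiscriminationTable-class].
#' @examples
#' tab <- soyDiscriminationTable()
#' overlappingValues(tab)
#' @export
soyDiscriminationTable <- function(resolve1215 = FALSE) {
  files <- system.file("extdata",
                       c("discrimination_domestic.tsv",
                         "discrimination_foreign.tsv"),
                       package = "soyOrigin", mustWork = TRUE)
  tab <- readDiscriminationTable(files)
  if (resolve1215) resolvedValues(tab) <- 1215L
  tab
}
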
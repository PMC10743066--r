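# Shared fixtures built in code.

# a minimal two-origin toy table: disjoint values unless overlap requested
toyTable <- function(domestic = c(25, 189), foreign = c(247, 2047),
                     domesticCounts = rep(2L, length(domestic)),
                     foreignCounts = rep(3L, length(foreign)),
                     resolved = integer()) {
  discriminationTable(
    data.frame(value = c(domestic, foreign),
               origin = rep(c("domestic", "foreign"),
                            c(length(domestic), length(foreign))),
               count = c(domesticCounts, foreignCounts)),
    resolvedValues = resolved)
}

# profile data.frame from a list of amplified-marker index sets
profilesFromSets <- function(sets, origin = "domestic", n = 11L) {
  calls <- t(vapply(sets, function(s) as.integer(seq_len(n) %in% s),
                    integer(n)))
  colnames(calls) <- paste0("m", seq_len(n))
  cbind(data.frame(sample_id = sprintf("S%02d", seq_along(sets)),
                   origin = rep(origin, length.out = length(sets))),
        as.data.frame(calls))
}

# a tiny panel of m markers with separable dummy amplicon sizes
toyPanel <- function(m, sizes = 100 + 50 * seq_len(m)) {
  markerPanel(data.frame(set = LETTERS[seq_len(m)], marker = seq_len(m),
                         final_conc = 1, forward = "ACGTACGT",
                         reverse = "TTGGCCAA", size = sizes))
}
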
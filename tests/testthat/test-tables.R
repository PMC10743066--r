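test_that("packaged discrimination table has the reference structure", {
  tab <- soyDiscriminationTable()
  d <- domesticEntries(tab); f <- foreignEntries(tab)
  expect_equal(nrow(d), 53L)
  expect_equal(sum(d$count), 630L)
  expect_equal(nrow(f), 70L)
  expect_equal(sum(f$count), 466L)
  # every packaged row's marker decomposition re-encodes to its value
  pan <- soyPanel()
  sc <- markerScores(pan)
  for (v in tableEntries(tab)$value)
    expect_equal(sum(sc[decodeJudgmentValue(v, pan)]), v)
})

test_that("building a table from profiles tallies multiplicities", {
  # three varieties, uneven multiplicities, two origins
  profs <- rbind(
    profilesFromSets(rep(list(c(1, 4, 5), c(1, 2)), c(3, 2)), "domestic"),
    profilesFromSets(rep(list(c(1, 11)), 4), "imported"))
  profs$sample_id <- sprintf("S%02d", seq_len(nrow(profs)))
  tab <- buildDiscriminationTable(profs)
  expect_equal(totalSamples(tab, "domestic"), 5L)
  expect_equal(totalSamples(tab, "foreign"), 4L)
  d <- domesticEntries(tab)
  expect_equal(d$value, c(3L, 25L))          # 1+2, 1+8+16
  expect_equal(d$count, c(2L, 3L))
  expect_equal(foreignEntries(tab)$value, 1025L)
  # empty input gives an empty table
  expect_equal(totalSamples(buildDiscriminationTable(profs[0, ])), 0L)
})

test_that("table construction rejects unlabeled and non-soybean profiles", {
  profs <- profilesFromSets(list(c(1, 2), c(2, 3)))
  expect_error(buildDiscriminationTable(transform(profs, origin = NA)),
               class = "soyInputError")
  err <- tryCatch(buildDiscriminationTable(profs),
                  soyNotSoybeanError = identity)
  expect_s3_class(err, "soyNotSoybeanError")
  expect_match(conditionMessage(err), "S02")  # offending id is reported
})

test_that("overlapping values are found and respect resolutions", {
  tab <- soyDiscriminationTable()
  expect_identical(overlappingValues(tab), c(671L, 1183L, 1215L, 1695L))
  expect_identical(overlappingValues(soyDiscriminationTable(resolve1215 = TRUE)),
                   c(671L, 1183L, 1695L))
  expect_length(overlappingValues(toyTable()), 0L)
})

test_that("classification is a total function with one verdict per value", {
  tab <- soyDiscriminationTable()
  expect_equal(classifyValue(189, tab), "domestic")    # Sinhwa's value
  expect_equal(classifyValue(2047, tab), "foreign")    # Williams82's value
  expect_equal(classifyValue(671, tab), "undetermined_overlap")
  expect_equal(classifyValue(5, tab), "unknown_value")
  expect_error(classifyValue(188, tab), class = "soyInputError")
  expect_error(classifyValue(2049, tab), class = "soyInputError")
  # partition property: every scoreable value gets exactly one verdict
  verdicts <- vapply(seq(1L, 2047L, by = 2L),
                     function(v) classifyValue(v, tab), character(1))
  expect_true(all(verdicts %in% c("domestic", "foreign",
                                  "undetermined_overlap", "unknown_value")))
  dom <- domesticEntries(tab)$value; forv <- foreignEntries(tab)$value
  expect_equal(sum(verdicts == "domestic"), length(setdiff(dom, forv)))
  expect_equal(sum(verdicts == "foreign"), length(setdiff(forv, dom)))
  expect_equal(sum(verdicts == "undetermined_overlap"),
               length(intersect(dom, forv)))
})

test_that("resolved overlaps classify only with a per-sample morphology call", {
  tab <- soyDiscriminationTable(resolve1215 = TRUE)
  expect_equal(classifyValue(1215, tab), "undetermined_overlap")  # no hint
  expect_equal(classifyValue(1215, tab, sideHint = "domestic"), "domestic")
  expect_equal(classifyValue(1215, tab, sideHint = "foreign"), "foreign")
  # hints are ignored at unresolved overlaps
  expect_equal(classifyValue(671, tab, sideHint = "domestic"),
               "undetermined_overlap")
})

test_that("batch classification flags non-soybean grains instead of failing", {
  tab <- soyDiscriminationTable()
  profs <- profilesFromSets(list(c(1, 3, 4, 5, 6, 8), c(2, 3), 1:11))
  res <- classifyProfiles(profs, tab)
  expect_equal(res$verdict, c("domestic", "invalid_sample", "foreign"))
  expect_true(is.na(res$judgment_value[2]))
})

test_that("panel reduction maps, merges and conserves counts", {
  # dropping nothing is the identity
  tab <- soyDiscriminationTable()
  expect_equal(tableEntries(reducePanel(tab, integer())), tableEntries(tab))
  # toy case: 1563 contains score 1024, so dropping marker 11 gives 539
  toy <- discriminationTable(data.frame(value = 1563, origin = "domestic",
                                        count = 2))
  red <- reducePanel(toy, 11L)
  expect_equal(tableEntries(red)$value, 539L)
  expect_equal(tableEntries(red)$count, 2L)
  # oracle: re-encode the decoded marker set without the dropped marker
  idx <- setdiff(decodeJudgmentValue(1563), 11L)
  expect_equal(sum(markerScores(soyPanel())[idx]), 539)
  expect_error(reducePanel(tab, 1L), class = "soyInputError")
})

test_that("reduction conserves counts and merges monotonically", {
  tab <- soyDiscriminationTable()
  pan <- soyPanel()
  sc <- markerScores(pan)
  for (drop in list(11L, 10L, c(10L, 11L), 2L)) {
    red <- reducePanel(tab, drop, pan)
    # conservation per origin
    expect_equal(totalSamples(red, "domestic"), 630L)
    expect_equal(totalSamples(red, "foreign"), 466L)
    # distinct values never increase
    expect_lte(nrow(domesticEntries(red)), nrow(domesticEntries(tab)))
    expect_lte(nrow(foreignEntries(red)), nrow(foreignEntries(tab)))
    # the image of the old overlap set is contained in the new overlap set
    mapped <- vapply(overlappingValues(tab), function(v) {
      idx <- decodeJudgmentValue(v, pan)
      as.integer(v - sum(sc[idx[idx %in% drop]]))
    }, integer(1))
    expect_true(all(mapped %in% overlappingValues(red)))
    # merged counts equal the sum of their preimages' counts (brute force)
    e <- tableEntries(tab); r <- tableEntries(red)
    eMap <- vapply(e$value, function(v) {
      idx <- decodeJudgmentValue(v, pan)
      as.integer(v - sum(sc[idx[idx %in% drop]]))
    }, integer(1))
    for (i in seq_len(nrow(r))) {
      pre <- e$count[eMap == r$value[i] & e$origin == r$origin[i]]
      expect_equal(sum(pre), r$count[i])
    }
  }
})

test_that("table files round-trip losslessly and reject inconsistent rows", {
  tab <- soyDiscriminationTable(resolve1215 = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  writeDiscriminationTable(tab, tmp)
  back <- readDiscriminationTable(tmp)
  expect_equal(tableEntries(back), tableEntries(tab))
  expect_equal(resolvedValues(back), resolvedValues(tab))
  # a row whose marker columns do not re-sum to its value is rejected
  lines <- readLines(tmp)
  i <- grep("^25\t", lines)  # claim marker 2 amplified without updating 25
  lines[i] <- sub("^25\t1\t\t", "25\t1\t2\t", lines[i])
  writeLines(lines, tmp)
  expect_error(readDiscriminationTable(tmp), class = "soyFormatError")
  # duplicate value within one origin is rejected
  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(c("judgment_value\tduplicate_count\torigin",
               "25\t1\tdomestic", "25\t2\tdomestic"), tmp2)
  expect_error(readDiscriminationTable(tmp2), class = "soyFormatError")
})
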
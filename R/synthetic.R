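#' Simulation configuration
#'
#' Bundles the knobs of the synthetic data generator. Defaults mirror the
#' reference collection behind the packaged table: 53 domestic and 70
#' foreign varieties (its distinct judgment values), about 12 grains per
#' variety (630/53), a low per-marker assay error (allele-specific PCR is
#' near-binary once optimized), 24-grain lots, and a mixed-lot admixture of
#' 11.75% — the fraction that a 24-grain sample detects with 95%
#' confidence.
#'
#' @param seed master integer seed; every generator derives its own
#'   sub-stream from it, so outputs are reproducible and independent.
#' @param nDomesticVarieties,nForeignVarieties fingerprint counts.
#' @param samplesPerVariety grains drawn per variety.
#' @param dropoutRate probability a truly present marker fails to amplify.
#' @param falseAmpRate probability an absent marker amplifies.
#' @param lotSize grains per lot.
#' @param mixtureFraction foreign-grain fraction in a mixed lot.
#' @param markerPresenceProb per-marker presence probability for fingerprint
#'   draws; scalar or one value per non-control marker.
#' @param forceSeparable draw domestic and foreign fingerprints with
#'   disjoint judgment values (no overlaps by construction).
#' @return a list of class `soySimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nDomesticVarieties = 53L, nForeignVarieties = 70L,
                      samplesPerVariety = 12L,
                      dropoutRate = 0.01, falseAmpRate = 0.01,
                      lotSize = 24L, mixtureFraction = 0.1175,
                      markerPresenceProb = 0.5,
                      forceSeparable = FALSE) {
  stopifnot(dropoutRate >= 0, dropoutRate <= 1,
            falseAmpRate >= 0, falseAmpRate <= 1,
            mixtureFraction >= 0, mixtureFraction <= 1)
  structure(list(seed = as.integer(seed),
                 nDomesticVarieties = as.integer(nDomesticVarieties),
                 nForeignVarieties = as.integer(nForeignVarieties),
                 samplesPerVariety = as.integer(samplesPerVariety),
                 dropoutRate = dropoutRate, falseAmpRate = falseAmpRate,
                 lotSize = as.integer(lotSize),
                 mixtureFraction = mixtureFraction,
                 markerPresenceProb = markerPresenceProb,
                 forceSeparable = forceSeparable),
            class = "soySimConfig")
}

#' Generate variety fingerprints
#'
#' One amplification fingerprint per variety: marker 1 (the control) is
#' always present; markers 2..n are drawn independently with
#' `markerPresenceProb`. With `forceSeparable`, fingerprints are instead
#' drawn as distinct judgment values split disjointly between origins, so
#' the resulting table has zero overlapping values by construction — only
#' 2^(n-1) distinct fingerprints exist (1024 for the 11-marker panel), so
#' requesting more errors out.
#'
#' @param config a [simConfig()].
#' @param panel a [MarkerPanel-class].
#' @return profile data.frame, one row per variety.
#' @export
generateVarieties <- function(config, panel = soyPanel()) {
  n <- nMarkers(panel)
  nD <- config$nDomesticVarieties; nF <- config$nForeignVarieties
  withSeed(subSeed(config$seed, "varieties"), {
    if (config$forceSeparable) {
      cap <- 2^(n - 1L)
      if (nD + nF > cap)
        inputError(sprintf(
          "cannot draw %d distinct fingerprints: only %d exist (marker 1 fixed)",
          nD + nF, cap))
      vals <- sample.int(cap, nD + nF) * 2L - 1L
      calls <- t(vapply(vals, function(v)
        seq_len(n) %in% decodeJudgmentValue(v, panel), logical(n)))
    } else {
      p <- rep(config$markerPresenceProb, length.out = n - 1L)
      calls <- cbind(TRUE,
                     matrix(stats::rbinom((nD + nF) * (n - 1L), 1L,
                                          rep(p, each = nD + nF)) == 1L,
                            nrow = nD + nF))
    }
    ids <- c(sprintf("DOM_V%03d", seq_len(nD)),
             sprintf("FOR_V%03d", seq_len(nF)))
    df <- data.frame(sample_id = ids,
                     origin = rep(c("domestic", "foreign"), c(nD, nF)),
                     variety = ids)
    calls <- matrix(as.integer(calls), nrow = nD + nF)
    colnames(calls) <- paste0("m", seq_len(n))
    cbind(df, as.data.frame(calls))
  })
}

## apply per-grain assay noise to a call matrix (marker 1 never flips)
applyNoise <- function(calls, dropoutRate, falseAmpRate) {
  flips <- matrix(stats::runif(length(calls)), nrow = nrow(calls))
  noisy <- (calls == 1L & flips >= dropoutRate) |
           (calls == 0L & flips < falseAmpRate)
  noisy[, 1L] <- TRUE
  matrix(as.integer(noisy), nrow = nrow(calls),
         dimnames = dimnames(calls))
}

#' Generate a noisy grain population from variety fingerprints
#'
#' Draws `samplesPerVariety` grains per variety: each grain copies its
#' variety fingerprint, then every non-control marker independently drops
#' out (present -> absent) with `dropoutRate` or falsely amplifies
#' (absent -> present) with `falseAmpRate`. The control never flips. True
#' variety and origin labels are retained.
#'
#' @param varieties profile data.frame from [generateVarieties()].
#' @param config a [simConfig()].
#' @param panel a [MarkerPanel-class].
#' @return profile data.frame, `samplesPerVariety * nrow(varieties)` rows.
#' @export
generatePopulation <- function(varieties, config, panel = soyPanel()) {
  n <- nMarkers(panel)
  cols <- paste0("m", seq_len(n))
  idx <- rep(seq_len(nrow(varieties)), each = config$samplesPerVariety)
  calls <- as.matrix(varieties[idx, cols])
  withSeed(subSeed(config$seed, "population"), {
    noisy <- applyNoise(calls, config$dropoutRate, config$falseAmpRate)
    df <- data.frame(sample_id = sprintf("G%05d", seq_along(idx)),
                     origin = varieties$origin[idx],
                     variety = varieties$variety[idx])
    rownames(noisy) <- NULL
    cbind(df, as.data.frame(noisy))
  })
}

#' Generate grain lots
#'
#' Pure lots draw every grain from varieties of one origin; mixed lots
#' draw each grain from a foreign variety with probability
#' `mixtureFraction`, else a domestic one. Grains carry the same assay
#' noise as [generatePopulation()]; the true lot label is retained in
#' `true_lot_label`.
#'
#' @param varieties profile data.frame from [generateVarieties()].
#' @param config a [simConfig()].
#' @param nDomesticLots,nForeignLots,nMixedLots lot counts per type.
#' @param panel a [MarkerPanel-class].
#' @return profile data.frame with `lot_id` and `true_lot_label` columns,
#'   `lotSize` rows per lot.
#' @export
generateLots <- function(varieties, config, nDomesticLots = 1L,
                         nForeignLots = 1L, nMixedLots = 1L,
                         panel = soyPanel()) {
  n <- nMarkers(panel)
  cols <- paste0("m", seq_len(n))
  domIdx <- which(varieties$origin == "domestic")
  forIdx <- which(varieties$origin == "foreign")
  types <- rep(c("domestic", "foreign", "mixed"),
               c(nDomesticLots, nForeignLots, nMixedLots))
  withSeed(subSeed(config$seed, "lots"), {
    out <- lapply(seq_along(types), function(i) {
      isFor <- switch(types[i],
        domestic = rep(FALSE, config$lotSize),
        foreign = rep(TRUE, config$lotSize),
        mixed = stats::runif(config$lotSize) < config$mixtureFraction)
      pick <- ifelse(isFor,
                     sample(forIdx, config$lotSize, replace = TRUE),
                     sample(domIdx, config$lotSize, replace = TRUE))
      calls <- applyNoise(as.matrix(varieties[pick, cols]),
                          config$dropoutRate, config$falseAmpRate)
      rownames(calls) <- NULL
      cbind(data.frame(lot_id = sprintf("LOT%03d", i),
                       true_lot_label = types[i],
                       sample_id = sprintf("LOT%03d_g%02d", i,
                                           seq_len(config$lotSize)),
                       origin = varieties$origin[pick],
                       variety = varieties$variety[pick]),
            as.data.frame(calls))
    })
    do.call(rbind, out)
  })
}

#' Generate a block-structured VCF with recorded ground truth
#'
#' Emulates a variant-discovery input: SNPs are placed by a Poisson process
#' at a high density inside the designated dense variation blocks (dVBs)
#' and a low density elsewhere, and a fixed number of qualifying InDels is
#' planted inside each dVB. The returned truth record holds the planted
#' block layout and InDel positions, so segmentation and candidate
#' selection can be scored against it. A fixed seed gives a byte-identical
#' file.
#'
#' @param chromLength chromosome length in bp.
#' @param dvbRanges 2-column matrix of 1-based inclusive (start, end) dVB
#'   intervals.
#' @param snpDensityDvb,snpDensitySvb SNP densities in SNPs/kb inside and
#'   outside dVBs.
#' @param indelsPerDvb qualifying InDels planted per dVB.
#' @param indelSizeRange length-2 range of planted InDel sizes in bp.
#' @param seed integer seed.
#' @param path output VCF path (default a tempfile).
#' @param chrom chromosome name.
#' @return list with `path`, the variant data.frame, and `truth`
#'   (`blocks`: GRanges tiling the chromosome with the planted classes;
#'   `indels`: data.frame of planted InDels).
#' @export
generateVcf <- function(chromLength = 1e6,
                        dvbRanges = rbind(c(200001, 300000),
                                          c(600001, 700000)),
                        snpDensityDvb = 5, snpDensitySvb = 0.5,
                        indelsPerDvb = 2L, indelSizeRange = c(5L, 20L),
                        seed = 1L, path = tempfile(fileext = ".vcf"),
                        chrom = "chr1") {
  dvbRanges <- matrix(as.numeric(dvbRanges), ncol = 2L)
  if (any(dvbRanges[, 2L] <= dvbRanges[, 1L]) ||
      any(dvbRanges > chromLength) || any(dvbRanges < 1))
    inputError("dvbRanges must be 1-based intervals within the chromosome")
  o <- order(dvbRanges[, 1L])
  dvbRanges <- dvbRanges[o, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  ## full tiling: sVB segments are the complement of the dVBs
  bounds <- rbind(cbind(start = dvbRanges[, 1L], end = dvbRanges[, 2L],
                        dvb = 1),
                  cbind(start = c(1, dvbRanges[, 2L] + 1),
                        end = c(dvbRanges[, 1L] - 1, chromLength), dvb = 0))
  bounds <- bounds[bounds[, "end"] >= bounds[, "start"], , drop = FALSE]
  bounds <- bounds[order(bounds[, "start"]), , drop = FALSE]
  withSeed(subSeed(seed, "vcf"), {
    recs <- list()
    indels <- list()
    for (i in seq_len(nrow(bounds))) {
      s <- bounds[i, "start"]; e <- bounds[i, "end"]
      dens <- if (bounds[i, "dvb"] == 1) snpDensityDvb else snpDensitySvb
      nSnp <- stats::rpois(1L, dens * (e - s + 1) / 1000)
      nSnp <- min(nSnp, e - s + 1)
      pos <- sort(sample.int(e - s + 1, nSnp)) + s - 1
      ref <- sample(bases, nSnp, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      recs[[length(recs) + 1L]] <-
        data.frame(pos = pos, ref = ref, alt = alt)
      if (bounds[i, "dvb"] == 1 && indelsPerDvb > 0L) {
        size <- sample(seq(indelSizeRange[1L], indelSizeRange[2L]),
                       indelsPerDvb, replace = TRUE)
        ip <- sort(sample.int(e - s + 1 - max(size), indelsPerDvb)) + s - 1
        iref <- vapply(size, function(k)
          paste(sample(bases, k + 1L, replace = TRUE), collapse = ""),
          character(1))
        recs[[length(recs) + 1L]] <-
          data.frame(pos = ip, ref = iref, alt = substr(iref, 1L, 1L))
        indels[[length(indels) + 1L]] <-
          data.frame(chrom = chrom, pos = ip, size = size)
      }
    }
    v <- do.call(rbind, recs)
    v <- v[order(v$pos), , drop = FALSE]
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom,
                     as.integer(chromLength)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom,
                    as.integer(v$pos), v$ref, v$alt)
    writeLines(c(hdr, body), path)
    truthBlocks <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = bounds[, "start"],
                              end = bounds[, "end"]),
      class = ifelse(bounds[, "dvb"] == 1, "dVB", "sVB"))
    list(path = path,
         variants = data.frame(chrom = chrom, pos = as.integer(v$pos),
                               ref = v$ref, alt = v$alt,
                               type = ifelse(nchar(v$ref) != nchar(v$alt),
                                             "InDel", "SNP")),
         truth = list(blocks = truthBlocks,
                      indels = if (length(indels)) do.call(rbind, indels)
                               else data.frame(chrom = character(),
                                               pos = integer(),
                                               size = integer())))
  })
}

#' Estimate per-marker presence frequencies from a table
#'
#' Decodes every entry of a discrimination table and returns the
#' count-weighted frequency with which each marker is present, per origin.
#' Useful for parameterizing [simConfig()]'s `markerPresenceProb` to mimic
#' the uneven marker frequencies of real collections.
#'
#' @param table a [DiscriminationTable-class].
#' @param panel a [MarkerPanel-class].
#' @return matrix (2 x nMarkers) of presence frequencies by origin.
#' @export
fitMarkerFrequencies <- function(table, panel = soyPanel()) {
  e <- tableEntries(table)
  n <- nMarkers(panel)
  bits <- t(vapply(e$value, function(v) seq_len(n) %in%
                     decodeJudgmentValue(v, panel), logical(n)))
  out <- rbind(
    domestic = colSums(bits * e$count * (e$origin == "domestic")) /
      sum(e$count[e$origin == "domestic"]),
    foreign = colSums(bits * e$count * (e$origin == "foreign")) /
      sum(e$count[e$origin == "foreign"]))
  colnames(out) <- paste0("m", seq_len(n))
  out
}
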
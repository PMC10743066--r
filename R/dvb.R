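#' Read biallelic variants from a VCF
#'
#' Loads a VCF (plain or bgzipped) and returns the biallelic records with a
#' SNP/InDel type call (InDel iff REF and ALT lengths differ). Multiallelic
#' records are skipped with a message; split them upstream (e.g. with
#' `bcftools norm -m-`) if they matter.
#'
#' @param path VCF file path.
#' @return data.frame with chrom, pos (1-based), ref, alt, type; attribute
#'   `multiallelicSkipped` holds the skipped-record count.
#' @export
readVariants <- function(path) {
  if (!file.exists(path)) inputError(paste("no such file:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi))
    message(sum(multi), " multiallelic/altless records skipped")
  fix <- fix[!multi, , drop = FALSE]
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    type = ifelse(nchar(fix$REF) != nchar(fix$ALT),
                                  "InDel", "SNP"))
  structure(out, multiallelicSkipped = sum(multi))
}

#' Windowed SNP density along a chromosome
#'
#' Tiles each chromosome into consecutive non-overlapping windows (the
#' last may be short) and computes the SNP density of each in variants
#' per kb. Windows are returned as a [GenomicRanges::GRanges] (1-based
#' closed intervals, the Bioconductor convention); a variant at position p
#' falls in window `floor((p-1)/window) + 1`.
#'
#' @param variants data.frame as from [readVariants()].
#' @param chromLength named numeric vector of chromosome lengths in bp
#'   (a single unnamed length is accepted for single-chromosome input).
#' @param window window size in bp (default 100 kb, the scale at which
#'   dense variation blocks occur).
#' @return `GRanges` with metadata columns `nSnps` and `density` (SNPs/kb).
#' @export
windowDensity <- function(variants, chromLength, window = 1e5) {
  if (window <= 0) inputError("window must be positive")
  chroms <- unique(variants$chrom)
  if (is.null(names(chromLength))) {
    if (length(chromLength) == 1L && length(chroms) <= 1L)
      names(chromLength) <- if (length(chroms)) chroms else "chr1"
    else inputError("chromLength must be named by chromosome")
  }
  if (!all(chroms %in% names(chromLength)))
    inputError("variants on chromosomes absent from chromLength")
  grl <- lapply(names(chromLength), function(ch) {
    len <- chromLength[[ch]]
    v <- variants[variants$chrom == ch & variants$type == "SNP", , drop = FALSE]
    if (any(variants$pos[variants$chrom == ch] > len) ||
        any(variants$pos[variants$chrom == ch] < 1))
      inputError(paste("variant position outside chromosome", ch))
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    counts <- tabulate(floor((v$pos - 1) / window) + 1L,
                       nbins = length(starts))
    gr <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = starts, end = ends),
      nSnps = counts,
      density = counts / ((ends - starts + 1) / 1000))
    gr
  })
  ans <- do.call(c, grl)
  GenomeInfoDb::seqlengths(ans) <- chromLength[GenomeInfoDb::seqlevels(ans)]
  ans
}

#' Segment density windows into variation blocks
#'
#' Classifies each window as dVB (dense variation block, density >=
#' threshold) or sVB (sparse), then merges adjacent windows of the same
#' class per chromosome. Block density is recomputed over the merged
#' extent, so it is the count-weighted mean of its windows. Blocks tile
#' each chromosome without gaps or overlaps.
#'
#' @param windows `GRanges` from [windowDensity()].
#' @param threshold SNPs/kb; windows at or above it are dVB. No universal
#'   value exists — it depends on sequencing depth and the cultivar set —
#'   so it is a required parameter; see [densityThreshold()] for a
#'   data-driven choice.
#' @return `GRanges` of blocks with `class` ("dVB"/"sVB"), `nSnps`, and
#'   `density` columns.
#' @export
segmentBlocks <- function(windows, threshold) {
  if (threshold < 0) inputError("threshold must be >= 0")
  cls <- ifelse(windows$density >= threshold, "dVB", "sVB")
  grl <- lapply(GenomeInfoDb::seqlevels(windows), function(ch) {
    w <- windows[GenomicRanges::seqnames(windows) == ch]
    if (length(w) == 0L) return(GenomicRanges::GRanges())
    w <- GenomicRanges::sort(w)
    k <- cls[as.logical(GenomicRanges::seqnames(windows) == ch)]
    r <- rle(k)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    GenomicRanges::GRanges(
      ch,
      IRanges::IRanges(start = GenomicRanges::start(w)[lo],
                       end = GenomicRanges::end(w)[hi]),
      class = r$values,
      nSnps = vapply(seq_along(lo), function(i)
        sum(w$nSnps[lo[i]:hi[i]]), numeric(1)))
  })
  ans <- do.call(c, grl)
  ans$density <- ans$nSnps / (GenomicRanges::width(ans) / 1000)
  ans
}

#' Data-driven dVB density threshold
#'
#' The dVB/sVB dichotomy implies a bimodal density distribution. This
#' splits the log-densities into two clusters with an exact 1-D two-means
#' (every split point of the sorted values is tried; deterministic, no
#' random starts) and returns the midpoint of the two cluster means,
#' back-transformed to SNPs/kb. A pseudo-count of half a SNP per window
#' keeps empty windows on the log scale.
#'
#' @param windows `GRanges` from [windowDensity()].
#' @return threshold in SNPs/kb.
#' @export
densityThreshold <- function(windows) {
  d <- windows$density
  if (length(d) < 2L || diff(range(d)) == 0)
    inputError("densities are degenerate: no two-cluster structure")
  kb <- stats::median(GenomicRanges::width(windows)) / 1000
  eps <- 0.5 / kb
  x <- sort(log(d + eps))
  n <- length(x)
  css <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  wss <- vapply(1:(n - 1L), function(k)
    css(x[1:k]) + css(x[(k + 1L):n]), numeric(1))
  k <- which.min(wss)
  mid <- (mean(x[1:k]) + mean(x[(k + 1L):n])) / 2
  exp(mid) - eps
}

#' Select InDel marker candidates inside dense variation blocks
#'
#' Markers are sought where varieties differ most: InDels located in dVBs,
#' with an allele length difference large enough for allele-specific PCR
#' discrimination.
#'
#' @param blocks `GRanges` from [segmentBlocks()].
#' @param variants data.frame as from [readVariants()].
#' @param minLen,maxLen allowed REF/ALT length difference in bp
#'   (default 1 to Inf).
#' @return data.frame of candidate InDels sorted by chrom, pos, with a
#'   `lenDiff` column.
#' @export
selectIndelCandidates <- function(blocks, variants, minLen = 1,
                                  maxLen = Inf) {
  if (minLen < 1) inputError("minLen must be >= 1")
  ind <- variants[variants$type == "InDel", , drop = FALSE]
  ind$lenDiff <- abs(nchar(ind$ref) - nchar(ind$alt))
  ind <- ind[ind$lenDiff >= minLen & ind$lenDiff <= maxLen, , drop = FALSE]
  if (nrow(ind) == 0L) return(ind)
  dvb <- blocks[blocks$class == "dVB"]
  gr <- GenomicRanges::GRanges(ind$chrom,
                               IRanges::IRanges(ind$pos, width = 1L))
  hit <- IRanges::overlapsAny(gr, dvb)
  out <- ind[hit, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variation blocks as BED
#'
#' BED is 0-based half-open: a block covering bases 1..100000 (1-based)
#' is written as start 0, end 100000. Columns: chrom, start, end, class,
#' density.
#'
#' @param blocks `GRanges` from [segmentBlocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlocksBed <- function(blocks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(blocks)),
                   start = GenomicRanges::start(blocks) - 1L,
                   end = GenomicRanges::end(blocks),
                   class = blocks$class,
                   density = if (is.null(blocks$density)) NA
                             else blocks$density)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
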
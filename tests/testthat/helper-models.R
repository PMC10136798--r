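# small in-code model builders shared across test files

# one gene with the given exon (start,end) pairs
toyGene <- function(..., strand = "+", chrom = "chrT", id = "g1") {
  ex <- do.call(rbind, list(...))
  grl <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(ex[, 1], ex[, 2]), strand))
  names(grl) <- id
  GeneModelSet(grl)
}

# n equal genes: 5 exons of width exon_w separated by introns of intron_w
toyCohort <- function(n, exon_w = 100L, intron_w = 300L, gap = 500L,
                      strand = "+", chrom = "chrT") {
  exl <- vector("list", n)
  at <- 1L
  for (i in seq_len(n)) {
    starts <- at + (0:4) * (exon_w + intron_w)
    exl[[i]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, starts + exon_w - 1L), strand)
    names(exl)[i] <- sprintf("tg%03d", i)
    at <- at + 5L * (exon_w + intron_w) + gap
  }
  GeneModelSet(GenomicRanges::GRangesList(exl))
}

junction <- function(start, end, strand = "+", chrom = "chrT",
                     condition = "WT") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
  S4Vectors::mcols(gr)$condition <- condition
  gr
}

# uniform-coverage track over given ranges
uniformTrack <- function(regions, depth = 10, chrom_len = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(regions))[1]
  if (is.null(chrom_len)) chrom_len <- max(GenomicRanges::end(regions)) + 100L
  vp <- numeric(chrom_len); vm <- numeric(chrom_len)
  for (i in seq_along(regions)) {
    idx <- GenomicRanges::start(regions)[i]:GenomicRanges::end(regions)[i]
    if (as.character(GenomicRanges::strand(regions))[i] == "-")
      vm[idx] <- depth else vp[idx] <- depth
  }
  lp <- list(S4Vectors::Rle(vp)); names(lp) <- chrom
  lm <- list(S4Vectors::Rle(vm)); names(lm) <- chrom
  CoverageTrack(plus = methods::as(lp, "RleList"),
                minus = methods::as(lm, "RleList"))
}

# naive regex oracle for the G4 scanner (independent of the run-chaining
# implementation): greedy PCRE over the same pattern definition
g4RegexOracle <- function(s, r = 3, l = 7, k = 4) {
  hits <- list()
  for (spec in list(c("G", "[ACTN]", "+"), c("C", "[AGTN]", "-"))) {
    pat <- sprintf("%s{%d,}(?:%s{1,%d}%s{%d,}){%d,}",
                   spec[1], r, spec[2], l, spec[1], r, k - 1)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] != -1L)
      hits[[length(hits) + 1L]] <- data.frame(
        start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L,
        strand = spec[3], stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
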
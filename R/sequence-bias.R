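#' Scan sequences for G-quadruplex motifs
#'
#' Detects the canonical quadruplex-forming pattern of `k` runs of at
#' least `r` guanines separated by loops of 1 to `l` non-G bases
#' (defaults r = 3, l = 7, k = 4: the "R4" class). Matching is maximal,
#' non-overlapping and left-greedy per strand; `N` never contributes to
#' a run. With `both_strands`, minus-strand motifs are detected as the
#' mirrored C-run pattern on the reference sequence. Loops are defined
#' over the non-G (respectively non-C) alphabet, which makes run/loop
#' boundaries unambiguous and the scan bit-reproducible.
#'
#' @param sequences a `DNAStringSet`, or named character vector over
#'   `{A,C,G,T,N}`.
#' @param r minimum run length (>= 2).
#' @param l maximum loop length.
#' @param k minimum number of runs (>= 2).
#' @param both_strands also scan for the complementary pattern.
#' @return `GRanges` (seqnames from `names(sequences)`) with `strand` and
#'   an `n_runs` mcol.
#' @examples
#' scanG4(c(s1 = "GGGAGGGTGGGCGGG"))
#' @export
scanG4 <- function(sequences, r = 3L, l = 7L, k = 4L, both_strands = TRUE) {
  if (r < 2 || k < 2) stop("G4 scan requires r >= 2 and k >= 2")
  if (methods::is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
  } else seqs <- sequences
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- list()
  for (nm in names(seqs)) {
    s <- toupper(seqs[[nm]])
    out[[length(out) + 1L]] <- .chainRuns(s, nm, "G", "+", r, l, k)
    if (both_strands)
      out[[length(out) + 1L]] <- .chainRuns(s, nm, "C", "-", r, l, k)
  }
  out <- out[lengths(out) > 0]
  if (!length(out)) {
    res <- GRanges()
    mcols(res)$n_runs <- integer(0)
    return(res)
  }
  res <- do.call(c, out)
  BiocGenerics::sort(res, ignore.strand = TRUE)
}

# left-greedy maximal chaining of base runs: a motif is >=k consecutive
# maximal `base`-runs of length >=r whose inter-run gaps (which contain no
# `base` by construction of maximal runs of length >= 1) are <= l
.chainRuns <- function(s, nm, base, strd, r, l, k) {
  m <- gregexpr(paste0(base, "+"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(GRanges())
  rs <- as.integer(m); rw <- attr(m, "match.length")
  elig <- rw >= r
  starts <- integer(0); ends <- integer(0); nrun <- integer(0)
  i <- 1L; nr <- length(rs)
  while (i <= nr) {
    if (!elig[i]) { i <- i + 1L; next }
    j <- i
    while (j < nr && elig[j + 1L] &&
           (rs[j + 1L] - (rs[j] + rw[j])) <= l) j <- j + 1L
    if (j - i + 1L >= k) {
      starts <- c(starts, rs[i]); ends <- c(ends, rs[j] + rw[j] - 1L)
      nrun <- c(nrun, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(starts)) return(GRanges())
  GRanges(nm, IRanges(starts, ends), strand = strd, n_runs = nrun)
}

#' G-quadruplex density over a region set
#'
#' @param motifs `GRanges` from [scanG4()].
#' @param regions `GRanges`; a motif counts when fully contained in a
#'   region (strand ignored: quadruplexes act on DNA).
#' @return motifs per kilobase of total region length.
#' @export
g4Density <- function(motifs, regions) {
  total_kb <- sum(as.numeric(width(regions))) / 1000
  if (total_kb == 0) stop("zero-length region set")
  if (!length(motifs)) return(0)
  n <- sum(IRanges::overlapsAny(motifs, regions, type = "within",
                                ignore.strand = TRUE))
  n / total_kb
}

#' Windowed nucleotide composition
#'
#' Tiles each sequence into windows (last window clipped at the sequence
#' boundary, flagged) and reports per-window A/C/G/T fractions and GC
#' content. `N` bases are excluded from the denominator; an all-N window
#' yields NA fractions with the `undefined` flag set.
#'
#' @param sequences `DNAStringSet` or named character vector.
#' @param window window size in bp (default 500, the intronic window
#'   around backsplice sites).
#' @return data.frame: `seq`, `window`, `start`, `end`, `A`, `C`, `G`,
#'   `T`, `GC`, `n_used`, `clipped`, `undefined`.
#' @export
baseComposition <- function(sequences, window = 500L) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  rows <- list()
  for (nm in names(sequences)) {
    len <- Biostrings::width(sequences[nm])
    starts <- seq(1L, len, by = window)
    for (wi in seq_along(starts)) {
      s0 <- starts[wi]; e0 <- min(s0 + window - 1L, len)
      sub <- Biostrings::subseq(sequences[[nm]], s0, e0)
      cnt <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
      used <- sum(cnt)
      frac <- if (used > 0) cnt / used else rep(NA_real_, 4)
      rows[[length(rows) + 1L]] <- data.frame(
        seq = nm, window = wi, start = s0, end = e0,
        A = unname(frac[1]), C = unname(frac[2]),
        G = unname(frac[3]), T = unname(frac[4]),
        GC = unname(frac[2] + frac[3]),
        n_used = used, clipped = (e0 - s0 + 1L) < window,
        undefined = used == 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fixed windows flanking backsplice sites
#'
#' Returns the intronic windows immediately upstream of the acceptor and
#' downstream of the donor backsplice site (transcript orientation),
#' clipped to the flanking intron when it is shorter than `width`.
#'
#' @param circs a [CircRNASet-class] (exonic records used).
#' @param genes a [GeneModelSet-class].
#' @param width window width in bp (default 500).
#' @return `GRanges` with mcols `host_gene`, `condition`, `side`
#'   (upstream/downstream), `clipped`.
#' @export
flankWindows <- function(circs, genes, width = 500L) {
  keep <- which(mcols(circs)$circ_class %in% c("exonic_single", "exonic_multi"))
  out <- GRanges()
  strd <- geneStrand(genes)
  for (i in keep) {
    fl <- flankingIntrons(circs[i], genes)
    gid <- mcols(circs[i])$host_gene
    plus <- strd[[gid]] == "+"
    for (side in c("upstream", "downstream")) {
      intr <- fl[[side]]
      if (is.null(intr)) next
      w <- min(width, BiocGenerics::width(intr))
      # the window abuts the backsplice-site exon boundary, inside the intron
      at_end <- (side == "upstream") == plus
      win <- if (at_end)
        GRanges(seqnames(intr), IRanges(end(intr) - w + 1L, end(intr)),
                strand = strand(intr))
      else
        GRanges(seqnames(intr), IRanges(start(intr), start(intr) + w - 1L),
                strand = strand(intr))
      mcols(win)$host_gene <- gid
      mcols(win)$condition <- mcols(circs[i])$condition
      mcols(win)$side <- side
      mcols(win)$clipped <- w < width
      out <- c(out, win)
    }
  }
  out
}

#' Repeat-class enrichment in flanking introns
#'
#' Base-pair overlap fractions per repeat class in a target intron set
#' versus a background intron set, with fold = target / background and a
#' seeded bootstrap CI over target introns (measuring in bp fractions is
#' robust to fragmented repeat annotations). Classes absent from the
#' background get `fold = NA` (flagged), never infinity.
#'
#' @param target,background `GRanges` of introns.
#' @param repeats `GRanges` with the repeat class in the `name` mcol.
#' @param B bootstrap resamples over target introns (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return data.frame: `class`, `target_fraction`, `background_fraction`,
#'   `fold`, `ci_lo`, `ci_hi`, `fold_defined`.
#' @export
repeatEnrichment <- function(target, background, repeats, B = 1000L,
                             seed = 1L, conf = 0.95) {
  classes <- sort(unique(mcols(repeats)$name))
  tfrac <- vapply(classes, function(cl)
    .bpFraction(target, repeats[mcols(repeats)$name == cl]), 0)
  bfrac <- vapply(classes, function(cl)
    .bpFraction(background, repeats[mcols(repeats)$name == cl]), 0)
  fold <- ifelse(bfrac > 0, tfrac / bfrac, NA_real_)
  ci <- matrix(NA_real_, length(classes), 2)
  if (length(target) && B > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, B, length(classes))
    for (b in seq_len(B)) {
      samp <- target[sample(length(target), replace = TRUE)]
      boots[b, ] <- vapply(seq_along(classes), function(ci_)
        .bpFraction(samp, repeats[mcols(repeats)$name == classes[ci_]]), 0)
    }
    for (j in seq_along(classes)) {
      if (is.na(fold[j])) next
      q <- stats::quantile(boots[, j] / bfrac[j],
                           c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
      ci[j, ] <- q
    }
  }
  data.frame(class = classes, target_fraction = unname(tfrac),
             background_fraction = unname(bfrac), fold = unname(fold),
             ci_lo = ci[, 1], ci_hi = ci[, 2],
             fold_defined = !is.na(fold), stringsAsFactors = FALSE,
             row.names = NULL)
}

# fraction of interval bp covered by (possibly duplicated) repeat bp;
# intervals kept as given so bootstrap resamples weight repeated introns
.bpFraction <- function(intervals, feats) {
  tot <- sum(as.numeric(width(intervals)))
  if (tot == 0 || !length(feats)) return(0)
  feats <- GenomicRanges::reduce(feats, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(intervals, feats, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  ov <- GenomicRanges::pintersect(
    intervals[S4Vectors::queryHits(hits)], feats[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  sum(as.numeric(width(ov))) / tot
}

#' Symmetric RNA-binding-protein motif enrichment in flanking introns
#'
#' Counts IUPAC motif occurrences in the transcript-5' and transcript-3'
#' flanking regions and tests each flank against the background per-base
#' occurrence rate with a one-sided binomial test, Benjamini-Hochberg
#' corrected across motifs within each flank. A motif is called
#' *symmetric* when it is significantly enriched in both flanks at
#' `alpha` (after correction) — motifs acting on both sides of the
#' backsplice site, the hallmark the analysis looks for.
#'
#' @param motifs named character vector of IUPAC patterns.
#' @param flank5,flank3,background `DNAStringSet` of region sequences
#'   (sense strand).
#' @param alpha significance level for the symmetric call.
#' @return data.frame: `motif`, `pattern`, `count_5p`, `count_3p`,
#'   `bp_5p`, `bp_3p`, `background_rate`, `p_5p`, `p_3p`, `q_5p`,
#'   `q_3p`, `symmetric`.
#' @export
motifEnrichment <- function(motifs, flank5, flank3, background, alpha = 0.05) {
  stopifnot(!is.null(names(motifs)))
  bp5 <- sum(Biostrings::width(flank5))
  bp3 <- sum(Biostrings::width(flank3))
  bpb <- sum(Biostrings::width(background))
  cnt <- function(pat, seqs) {
    if (!length(seqs)) return(0L)
    sum(Biostrings::vcountPattern(pat, seqs, fixed = FALSE))
  }
  rows <- lapply(names(motifs), function(id) {
    pat <- motifs[[id]]
    c5 <- cnt(pat, flank5); c3 <- cnt(pat, flank3); cb <- cnt(pat, background)
    rate <- max(cb / max(bpb, 1), .Machine$double.xmin)
    rate <- min(rate, 1 - 1e-12)
    p5 <- stats::binom.test(c5, bp5, rate, alternative = "greater")$p.value
    p3 <- stats::binom.test(c3, bp3, rate, alternative = "greater")$p.value
    data.frame(motif = id, pattern = pat, count_5p = c5, count_3p = c3,
               bp_5p = bp5, bp_3p = bp3, background_rate = cb / max(bpb, 1),
               p_5p = p5, p_3p = p3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_5p <- stats::p.adjust(out$p_5p, "BH")
  out$q_3p <- stats::p.adjust(out$p_3p, "BH")
  out$symmetric <- out$q_5p < alpha & out$q_3p < alpha
  out
}
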
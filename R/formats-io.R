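#' File readers and writers for the pipeline's flat formats
#'
#' FASTA via Biostrings; BED6 and bedGraph via rtracklayer (0-based
#' half-open on disk, 1-based `GRanges` in memory); backsplice-junction
#' calls and probe counts as headered TSV. All writers are deterministic:
#' identical objects produce identical bytes.
#'
#' @name circArch-io
NULL

#' @describeIn circArch-io read a FASTA file into a `DNAStringSet`.
#' @param path file path.
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @describeIn circArch-io write a `DNAStringSet` (60-column wrap).
#' @param x object to write (see individual writers).
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @describeIn circArch-io read a BED6 file (e.g. repeat annotation; the
#'   repeat class is carried in the name column) into a `GRanges`.
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gr
}

#' @describeIn circArch-io write a `GRanges` with a `name` mcol as BED6.
#' @export
writeBed <- function(x, path) {
  nm <- if ("name" %in% colnames(mcols(x))) mcols(x)$name else "."
  sc <- if ("score" %in% colnames(mcols(x))) mcols(x)$score else 0
  std <- as.character(strand(x)); std[std == "*"] <- "."
  writeLines(paste(as.character(seqnames(x)), start(x) - 1L, end(x),
                   nm, sc, std, sep = "\t"), path)
  invisible(path)
}

#' Read / write strand-paired bedGraph coverage
#'
#' Coverage is stored on disk as two bedGraph files,
#' `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph`. Intervals must
#' be non-overlapping within a file; gaps read back as zero signal.
#'
#' @param prefix path prefix (without the `.plus.bedgraph` suffix).
#' @return `readBedGraphPair`: a [CoverageTrack-class].
#' @export
readBedGraphPair <- function(prefix) {
  CoverageTrack(plus = .readBedGraph(paste0(prefix, ".plus.bedgraph")),
                minus = .readBedGraph(paste0(prefix, ".minus.bedgraph")))
}

.readBedGraph <- function(path) {
  if (!file.size(path)) return(IRanges::RleList(compress = FALSE))
  gr <- rtracklayer::import(path, format = "bedGraph")
  bad <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(bad))
    stop("bedGraph parse error in ", basename(path),
         ": overlapping intervals (e.g. records ",
         S4Vectors::queryHits(bad)[1], " and ", S4Vectors::subjectHits(bad)[1], ")")
  GenomicRanges::coverage(gr, weight = gr$score)
}

#' @rdname readBedGraphPair
#' @param x a [CoverageTrack-class].
#' @return `writeBedGraphPair`: `prefix`, invisibly.
#' @export
writeBedGraphPair <- function(x, prefix) {
  .writeBedGraph(x@plus, paste0(prefix, ".plus.bedgraph"))
  .writeBedGraph(x@minus, paste0(prefix, ".minus.bedgraph"))
  invisible(prefix)
}

.writeBedGraph <- function(rl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in sort(names(rl))) {
    r <- rl[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (any(keep))
      writeLines(paste(chrom, starts[keep], ends[keep],
                       format(vals[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write backsplice-junction call tables
#'
#' The junction TSV dialect is a headered table with columns `chrom`,
#' `start`, `end`, `strand`, `condition`, `n_reads` and optionally
#' `circ_type` and `gene` (a superset mappable from seekCRIT output;
#' unknown extra columns are ignored). `start`/`end` are the 1-based
#' inclusive genomic span of the backspliced segment, so `start < end` on
#' either strand.
#'
#' @param path file path.
#' @return `readJunctions`: a `GRanges` with mcols `condition`, `n_reads`
#'   and, when present, `gene` and `circ_type`.
#' @export
readJunctions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "strand", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("junction TSV parse error: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop("junction TSV coordinate error at data row ", bad[1],
         ": start must be < end (acceptor genomically left of donor)")
  if (!all(df$strand %in% c("+", "-")))
    stop("junction TSV parse error: strand must be + or -")
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$condition <- as.character(df$condition)
  mcols(gr)$n_reads <- if ("n_reads" %in% colnames(df)) df$n_reads else NA_integer_
  if ("gene" %in% colnames(df)) mcols(gr)$gene <- df$gene
  if ("circ_type" %in% colnames(df)) mcols(gr)$circ_type <- df$circ_type
  gr
}

#' @rdname readJunctions
#' @param x a `GRanges` of junction calls (or a [CircRNASet-class]).
#' @export
writeJunctions <- function(x, path) {
  df <- data.frame(chrom = as.character(seqnames(x)), start = start(x),
                   end = end(x), strand = as.character(strand(x)),
                   stringsAsFactors = FALSE)
  for (col in intersect(c("circ_type", "gene", "condition", "n_reads",
                          "circ_class", "host_gene", "acceptor_exon",
                          "donor_exon"),
                        colnames(mcols(x))))
    df[[col]] <- mcols(x)[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write probe-count tables
#'
#' TSV with columns `probe_id`, `gene_id`, `probe_type`, then one integer
#' column per sample named `<condition>_<replicate>`.
#'
#' @param path file path.
#' @return `readProbeCounts`: a [ProbeCountMatrix-class].
#' @export
readProbeCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("probe_id", "gene_id", "probe_type")
  if (!all(meta %in% colnames(df)))
    stop("probe-count TSV parse error: need probe_id, gene_id, probe_type")
  samp <- setdiff(colnames(df), meta)
  cnt <- as.matrix(df[, samp, drop = FALSE])
  rownames(cnt) <- df$probe_id
  parts <- regmatches(samp, regexpr("_[^_]+$", samp))
  cond <- substr(samp, 1L, nchar(samp) - nchar(parts))
  rep <- substring(parts, 2L)
  ProbeCountMatrix(cnt, gene_id = df$gene_id, probe_type = df$probe_type,
                   condition = cond, replicate = rep)
}

#' @rdname readProbeCounts
#' @param x a [ProbeCountMatrix-class].
#' @export
writeProbeCounts <- function(x, path) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  rd <- SummarizedExperiment::rowData(x)
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(probe_id = rownames(x), gene_id = rd$gene_id,
                   probe_type = rd$probe_type, stringsAsFactors = FALSE)
  cols <- paste(cd$condition, cd$replicate, sep = "_")
  for (j in seq_len(ncol(cnt))) df[[cols[j]]] <- cnt[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean and total coverage of regions in a CoverageTrack
#'
#' Strand-aware per-region statistics; positions beyond the stored signal
#' (or chromosomes absent from the track) read as zero.
#'
#' @param track a [CoverageTrack-class].
#' @param regions a `GRanges`; each region is looked up on its own strand
#'   (`*` sums both strands).
#' @return numeric vector of per-region means (`regionMean`) or sums
#'   (`regionSum`), parallel to `regions`.
#' @export
regionMean <- function(track, regions) regionSum(track, regions) / width(regions)

#' @rdname regionMean
#' @export
regionSum <- function(track, regions) {
  out <- numeric(length(regions))
  std <- as.character(strand(regions))
  for (s in c("+", "-")) {
    idx <- which(std == s | std == "*")
    if (!length(idx)) next
    rl <- if (s == "+") track@plus else track@minus
    add <- vapply(idx, function(i) {
      chrom <- as.character(seqnames(regions))[i]
      if (!chrom %in% names(rl)) return(0)
      r <- rl[[chrom]]
      lo <- start(regions)[i]; hi <- min(end(regions)[i], length(r))
      if (lo > length(r)) return(0)
      sum(as.numeric(S4Vectors::window(r, lo, hi)))
    }, 0)
    out[idx] <- out[idx] + add
  }
  out
}
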
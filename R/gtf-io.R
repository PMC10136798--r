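#' Read a GTF annotation into a GeneModelSet
#'
#' Parses gene/transcript/exon features and keeps one representative
#' transcript per gene: the transcript with the longest genomic span
#' (ties broken by lexicographically smallest `transcript_id`). GTF
#' coordinates (1-based inclusive) are carried into the `GRanges`-based
#' model unchanged.
#'
#' @param path path to a GTF file.
#' @return a [GeneModelSet-class] with genes ordered by (seqname, start,
#'   gene_id).
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "circArch")
#' if (nzchar(gtf)) readGtf(gtf)
#' @export
readGtf <- function(path) {
  raw <- readLines(path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  fields <- strsplit(raw[body], "\t", fixed = TRUE)
  lineno <- which(body)
  bad <- which(vapply(fields, function(f) length(f) < 9 || !(f[7] %in% c("+", "-")), TRUE))
  if (length(bad))
    stop("GTF parse error at line ", lineno[bad[1]],
         ": expected 9 fields with strand '+' or '-'")
  gr <- rtracklayer::import(path, format = "gtf")
  if (!all(c("type", "gene_id") %in% colnames(mcols(gr))))
    stop("GTF parse error: missing type/gene_id attributes")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("GTF parse error: no exon features")
  if (any(is.na(ex$transcript_id)))
    stop("GTF parse error: exon without transcript_id")

  tx <- gr[gr$type == "transcript"]
  if (length(tx)) {
    txspan <- split(granges(tx), tx$transcript_id)
    byTx <- split(granges(ex), ex$transcript_id)
    common <- intersect(names(txspan), names(byTx))
    for (t in common) {
      sp <- range(byTx[[t]])
      if (start(sp) < start(txspan[[t]]) || end(sp) > end(txspan[[t]])) {
        off <- byTx[[t]][start(byTx[[t]]) < start(txspan[[t]]) |
                         end(byTx[[t]]) > end(txspan[[t]])][1]
        ln <- .gtfLineOf(fields, lineno, "exon", off)
        stop("GTF parse error at line ", ln,
             ": exon outside transcript span for ", t)
      }
    }
  }

  # representative transcript per gene: longest genomic span, tie -> lexicographic
  perTx <- split(seq_along(ex), ex$transcript_id)
  txGene <- vapply(perTx, function(i) ex$gene_id[i[1]], "")
  txSpan <- vapply(perTx, function(i) {
    max(end(ex)[i]) - min(start(ex)[i]) + 1L
  }, 1L)
  keepTx <- vapply(split(names(perTx), txGene), function(ts) {
    sp <- txSpan[ts]
    cand <- ts[sp == max(sp)]
    sort(cand)[1]
  }, "")
  ex <- ex[ex$transcript_id %in% keepTx]

  exl <- split(granges(ex), ex$gene_id)
  exl <- GenomicRanges::GRangesList(lapply(exl, BiocGenerics::sort))
  txOf <- stats::setNames(names(keepTx), keepTx)  # tx -> gene
  txPerGene <- stats::setNames(keepTx, names(keepTx))[names(exl)]
  ord <- order(as.character(unlist(seqnames(range(exl)), use.names = FALSE)),
               vapply(BiocGenerics::start(range(exl)), `[`, 1L, 1),
               names(exl))
  GeneModelSet(exl[ord], transcript_id = unname(txPerGene[ord]))
}

.gtfLineOf <- function(fields, lineno, type, gr1) {
  hit <- which(vapply(fields, function(f) {
    f[3] == type && f[1] == as.character(seqnames(gr1))[1] &&
      as.integer(f[4]) == start(gr1)[1] && as.integer(f[5]) == end(gr1)[1]
  }, TRUE))
  if (length(hit)) lineno[hit[1]] else NA_integer_
}

#' Write a GeneModelSet as GTF
#'
#' Emits gene, transcript and exon features (1-based inclusive) with
#' deterministic formatting, genes ordered by (seqname, start, gene_id),
#' exons numbered in transcript orientation. `writeGtf(readGtf(f))`
#' reproduces generator output byte-for-byte.
#'
#' @param x a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(x, path) {
  exl <- exonRanges(x)
  sp <- geneRanges(x)
  ord <- order(as.character(seqnames(sp)), start(sp), names(exl))
  tx <- transcriptIds(x)
  lines <- character(0)
  for (i in ord) {
    gid <- names(exl)[i]
    ex <- exl[[i]]
    chrom <- as.character(seqnames(ex))[1]
    strd <- as.character(strand(ex))[1]
    gs <- min(start(ex)); ge <- max(end(ex))
    attr_g <- sprintf('gene_id "%s";', gid)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tx[[gid]])
    # exon_number in transcript (5'->3') orientation
    idx <- if (strd == "+") seq_along(ex) else rev(seq_along(ex))
    attr_e <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                      gid, tx[[gid]], idx)
    lines <- c(lines,
      paste(chrom, "circArch", "gene", gs, ge, ".", strd, ".", attr_g, sep = "\t"),
      paste(chrom, "circArch", "transcript", gs, ge, ".", strd, ".", attr_t, sep = "\t"),
      paste(chrom, "circArch", "exon", start(ex), end(ex), ".", strd, ".", attr_e,
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
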
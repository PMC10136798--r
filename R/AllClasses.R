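#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle runValue
#' @importFrom IRanges IRanges RleList Views viewMeans viewSums psetdiff
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames strand strand<-
#'   start end width findOverlaps pintersect reduce shift
#' @importFrom BiocGenerics unlist relist sort
NULL

## ---------------------------------------------------------------------------
## GeneModelSet: one representative transcript per protein-coding gene
## ---------------------------------------------------------------------------

#' Gene models with one representative transcript per gene
#'
#' A `GeneModelSet` stores, for each gene, the exons of a single
#' representative transcript as a named [GenomicRanges::GRangesList]
#' (genomic order; one chromosome and one strand per gene). Introns are
#' derived, never stored. All downstream analyses (junction
#' classification, flanking-intron architecture, pausing region schemas)
#' are defined against this representative structure.
#'
#' @slot exons named `GRangesList`, one element per gene, exons sorted by
#'   genomic start and mutually disjoint.
#' @slot geneData `DataFrame` with one row per gene: `transcript_id`.
#'
#' @seealso [readGtf()], [intronRanges()], [flankingIntrons()]
#' @export
setClass("GeneModelSet",
  slots = c(exons = "CompressedGRangesList", geneData = "DataFrame"))

setValidity("GeneModelSet", function(object) {
  ex <- object@exons
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("exons must be a named GRangesList with unique gene ids")
  if (length(ex) != nrow(object@geneData))
    return("geneData must have one row per gene")
  if (!identical(names(ex), rownames(object@geneData)))
    return("geneData rownames must match gene ids")
  if (!"transcript_id" %in% colnames(object@geneData))
    return("geneData must carry a transcript_id column")
  nstr <- vapply(ex, function(g) length(unique(as.character(strand(g)))), 1L)
  if (any(nstr != 1L)) return("each gene must lie on a single strand")
  if (any(as.character(unlist(strand(ex), use.names = FALSE)) == "*"))
    return("gene strand must be + or -")
  if (!all(vapply(ex, function(g) IRanges::isDisjoint(ranges(g)), TRUE)))
    return("exons within a gene must be disjoint")
  TRUE
})

#' Construct a GeneModelSet
#'
#' @param exons named `GRangesList` of exons (one element per gene).
#' @param transcript_id character vector of representative transcript ids,
#'   parallel to `exons` (defaults to `<gene_id>.t1`).
#' @return a [GeneModelSet-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("chrS", IRanges::IRanges(c(101, 301), c(200, 400)), "+"))
#' gm <- GeneModelSet(ex)
#' intronRanges(gm)
#' @export
GeneModelSet <- function(exons, transcript_id = NULL) {
  exons <- GenomicRanges::GRangesList(lapply(exons, BiocGenerics::sort))
  if (is.null(transcript_id)) transcript_id <- paste0(names(exons), ".t1")
  gd <- S4Vectors::DataFrame(transcript_id = transcript_id,
                             row.names = names(exons))
  new("GeneModelSet", exons = exons, geneData = gd)
}

setMethod("show", "GeneModelSet", function(object) {
  n <- length(object@exons)
  nex <- sum(lengths(object@exons))
  cat("GeneModelSet with", n, "genes /", nex, "exons on",
      length(unique(as.character(unlist(seqnames(object@exons), use.names = FALSE)))),
      "sequence(s)\n")
  if (n) {
    sp <- geneRanges(object)
    cat("  gene span: ", min(width(sp)), "-", max(width(sp)), " bp\n", sep = "")
  }
})

#' @describeIn GeneModelSet-class number of genes
#' @param x,object a `GeneModelSet`
#' @export
setMethod("length", "GeneModelSet", function(x) length(x@exons))

## ---------------------------------------------------------------------------
## CircRNASet: classified backsplice junctions
## ---------------------------------------------------------------------------

.CIRC_CLASSES <- c("intronic", "exonic_single", "exonic_multi", "unassigned")

#' Classified backsplice junctions
#'
#' Extends `GRanges`; each range is the genomic span of one backsplice
#' junction (leftmost backspliced base to rightmost, 1-based inclusive).
#' Metadata columns: `condition`, `n_reads`, `circ_class` (one of
#' intronic, exonic_single, exonic_multi, unassigned), `host_gene`,
#' `acceptor_exon` and `donor_exon` (1-based transcript-orientation exon
#' indices, NA when not exonic).
#'
#' @seealso [classifyJunctions()]
#' @export
setClass("CircRNASet", contains = "GRanges")

setValidity("CircRNASet", function(object) {
  need <- c("condition", "circ_class", "host_gene", "acceptor_exon", "donor_exon")
  miss <- setdiff(need, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing mcols:", paste(miss, collapse = ", ")))
  cls <- mcols(object)$circ_class
  if (!all(cls %in% .CIRC_CLASSES))
    return("circ_class outside the allowed set")
  ex <- cls %in% c("exonic_single", "exonic_multi")
  a <- mcols(object)$acceptor_exon[ex]; d <- mcols(object)$donor_exon[ex]
  if (any(is.na(a)) || any(is.na(d)) || any(a > d))
    return("exonic junctions need acceptor_exon <= donor_exon")
  if (any(cls == "exonic_single" & !is.na(a <- mcols(object)$acceptor_exon) &
          !is.na(d <- mcols(object)$donor_exon) & a != d))
    return("exonic_single requires acceptor_exon == donor_exon")
  TRUE
})

setMethod("show", "CircRNASet", function(object) {
  cat("CircRNASet with", length(object), "junction calls\n")
  if (length(object)) {
    tab <- table(factor(mcols(object)$circ_class, levels = .CIRC_CLASSES))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  conditions:", paste(sort(unique(mcols(object)$condition)),
                               collapse = ", "), "\n")
  }
})

## ---------------------------------------------------------------------------
## CoverageTrack: strand-resolved per-base nascent-RNA signal
## ---------------------------------------------------------------------------

#' Strand-resolved per-base coverage
#'
#' Holds one non-negative run-length-encoded signal vector per chromosome
#' and strand (nascent-RNA / NET-seq style occupancy). Positions outside
#' the stored vectors read as zero.
#'
#' @slot plus,minus `RleList` keyed by chromosome.
#' @seealso [readBedGraphPair()], [pausingIndex()]
#' @export
setClass("CoverageTrack", slots = c(plus = "RleList", minus = "RleList"))

setValidity("CoverageTrack", function(object) {
  for (s in c("plus", "minus")) {
    rl <- slot(object, s)
    if (length(rl) && any(vapply(rl, function(r) any(runValue(r) < 0), TRUE)))
      return("coverage values must be >= 0")
  }
  TRUE
})

#' Construct a CoverageTrack
#' @param plus,minus `RleList` (or coercible list) of per-base signal per
#'   chromosome for the plus and minus strand.
#' @return a [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(plus = IRanges::RleList(), minus = IRanges::RleList()) {
  new("CoverageTrack", plus = methods::as(plus, "RleList"),
      minus = methods::as(minus, "RleList"))
}

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:",
      length(object@plus), "plus-strand and",
      length(object@minus), "minus-strand sequence(s)\n")
  tot <- sum(vapply(object@plus, function(r) sum(as.numeric(r)), 0)) +
         sum(vapply(object@minus, function(r) sum(as.numeric(r)), 0))
  cat("  total signal:", format(tot, big.mark = ","), "\n")
})

## ---------------------------------------------------------------------------
## ProbeCountMatrix: circular/linear junction probe counts
## ---------------------------------------------------------------------------

#' Probe-count matrix for circular and linear junction probes
#'
#' Extends `SummarizedExperiment`. Rows are probes (`rowData`: `gene_id`,
#' `probe_type` in circ / linear / housekeeping), columns are samples
#' (`colData`: `condition`, `replicate`), and the `counts` assay holds
#' non-negative digital counts, one capture/reporter probe pair per
#' backsplice or linear splice junction.
#'
#' @seealso [normalizeCounts()], [probeLog2FC()], [clRatioClass()]
#' @export
setClass("ProbeCountMatrix",
  contains = "SummarizedExperiment")

setValidity("ProbeCountMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("need a 'counts' assay")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene_id", "probe_type") %in% colnames(rd)))
    return("rowData needs gene_id and probe_type")
  if (!all(rd$probe_type %in% c("circ", "linear", "housekeeping")))
    return("probe_type must be circ, linear or housekeeping")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd)))
    return("colData needs condition and replicate")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) return("counts must be >= 0")
  TRUE
})

#' Construct a ProbeCountMatrix
#'
#' @param counts numeric matrix, probes x samples; rownames are probe ids.
#' @param gene_id,probe_type character vectors parallel to rows.
#' @param condition,replicate vectors parallel to columns.
#' @return a [ProbeCountMatrix-class] object.
#' @export
ProbeCountMatrix <- function(counts, gene_id, probe_type, condition, replicate) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste(condition, replicate, sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = gene_id, probe_type = probe_type),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.character(replicate)))
  new("ProbeCountMatrix", se)
}

setMethod("show", "ProbeCountMatrix", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  cat("ProbeCountMatrix:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  probe types:", paste(names(table(rd$probe_type)),
                              table(rd$probe_type), sep = "=", collapse = " "), "\n")
  cat("  conditions:", paste(sort(unique(cd$condition)), collapse = ", "), "\n")
})
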
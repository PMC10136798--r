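#' @include AllClasses.R
NULL

#' Accessors for GeneModelSet
#'
#' `geneIds()` returns gene identifiers; `exonRanges()` the exon
#' `GRangesList` (genomic order); `intronRanges()` the derived introns
#' (gaps between adjacent exons, genomic order); `geneRanges()` the gene
#' spans as a `GRanges` named by gene; `geneStrand()` the per-gene strand.
#'
#' @param x a [GeneModelSet-class]
#' @return see individual descriptions.
#' @name GeneModelSet-accessors
NULL

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@exons))

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("intronRanges", "GeneModelSet", function(x) {
  spans <- unlist(range(x@exons), use.names = FALSE)
  names(spans) <- names(x@exons)
  psetdiff(spans, x@exons)
})

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) {
  sp <- unlist(range(x@exons), use.names = FALSE)
  names(sp) <- names(x@exons)
  sp
})

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneStrand", "GeneModelSet", function(x) {
  all_s <- as.character(unlist(strand(x@exons), use.names = FALSE))
  first <- cumsum(c(1L, utils::head(lengths(x@exons), -1L)))
  stats::setNames(all_s[first], names(x@exons))
})

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("transcriptIds", "GeneModelSet", function(x)
  stats::setNames(x@geneData$transcript_id, rownames(x@geneData)))

#' Subset a GeneModelSet by gene id or index
#' @param x a `GeneModelSet`; @param i gene ids or indices;
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneModelSet", function(x, i, j, ..., drop = FALSE) {
  new("GeneModelSet", exons = x@exons[i], geneData = x@geneData[i, , drop = FALSE])
})
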
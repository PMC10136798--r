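#' Classify backsplice junctions against gene models
#'
#' A junction call is *exonic* when its genomic start coincides with an
#' annotated exon start and its end with an annotated exon end of the
#' same representative transcript (within `tolerance` bp, default 0 —
#' exact, as annotation-aware callers report annotated boundaries);
#' exonic calls split into single-exon and multi-exon circRNAs by the
#' acceptor/donor exon indices (transcript orientation). A call is
#' *intronic* (ciRNA) when its whole span lies inside a single intron.
#' Anything else, including calls overlapping no gene, is *unassigned*.
#' When several genes match, the gene with the smallest genomic span
#' wins, deterministically; strand must agree.
#'
#' @param junctions `GRanges` of junction calls (see [readJunctions()]);
#'   each range spans the backspliced segment, `condition` in mcols.
#' @param genes a [GeneModelSet-class].
#' @param tolerance non-negative integer, boundary-match slack in bp.
#' @return a [CircRNASet-class] parallel to `junctions`.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   g1 = GenomicRanges::GRanges("chrS",
#'     IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)), "+"))
#' gm <- GeneModelSet(ex)
#' j <- GenomicRanges::GRanges("chrS", IRanges::IRanges(201, 300), "+",
#'                             condition = "WT")
#' classifyJunctions(j, gm)
#' @export
classifyJunctions <- function(junctions, genes, tolerance = 0L) {
  stopifnot(tolerance >= 0)
  n <- length(junctions)
  circ_class <- rep("unassigned", n)
  host <- rep(NA_character_, n)
  acc <- rep(NA_integer_, n); don <- rep(NA_integer_, n)

  exl <- exonRanges(genes)
  inl <- intronRanges(genes)
  spans <- geneRanges(genes)
  strd <- geneStrand(genes)
  hits <- GenomicRanges::findOverlaps(junctions, spans, ignore.strand = TRUE)
  jstrand <- as.character(strand(junctions))

  for (i in seq_len(n)) {
    gidx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    gidx <- gidx[strd[gidx] == jstrand[i]]
    if (!length(gidx)) next
    s <- start(junctions)[i]; e <- end(junctions)[i]
    best_ex <- NULL; best_in <- NULL
    for (g in gidx) {
      ex <- exl[[g]]
      ia <- which(abs(start(ex) - s) <= tolerance)
      id <- which(abs(end(ex) - e) <= tolerance)
      if (length(ia) && length(id)) {
        ia <- ia[which.min(abs(start(ex)[ia] - s))]
        id <- id[which.min(abs(end(ex)[id] - e))]
        if (ia <= id) {
          w <- width(spans)[g]
          if (is.null(best_ex) || w < best_ex$w)
            best_ex <- list(g = g, ia = ia, id = id, w = w)
        }
      }
      if (is.null(best_ex)) {
        ins <- inl[[g]]
        if (length(ins)) {
          contained <- which(start(ins) <= s & e <= end(ins))
          if (length(contained)) {
            w <- width(spans)[g]
            if (is.null(best_in) || w < best_in$w) best_in <- list(g = g, w = w)
          }
        }
      }
    }
    if (!is.null(best_ex)) {
      g <- best_ex$g
      nex <- length(exl[[g]])
      # genomic exon index -> transcript-orientation index
      if (strd[g] == "+") { a <- best_ex$ia; d <- best_ex$id }
      else { a <- nex - best_ex$id + 1L; d <- nex - best_ex$ia + 1L }
      circ_class[i] <- if (a == d) "exonic_single" else "exonic_multi"
      host[i] <- names(exl)[g]; acc[i] <- a; don[i] <- d
    } else if (!is.null(best_in)) {
      circ_class[i] <- "intronic"
      host[i] <- names(exl)[best_in$g]
    }
  }

  out <- granges(junctions)
  mcols(out)$condition <- mcols(junctions)$condition
  mcols(out)$n_reads <- if ("n_reads" %in% colnames(mcols(junctions)))
    mcols(junctions)$n_reads else NA_integer_
  mcols(out)$circ_class <- circ_class
  mcols(out)$host_gene <- host
  mcols(out)$acceptor_exon <- acc
  mcols(out)$donor_exon <- don
  new("CircRNASet", out)
}

#' Venn partition of labeled identifier sets
#'
#' Counts every region of the 2- or 3-set Venn partition. Reusable for
#' junction identities, host genes, differential-expression gene lists or
#' alternative-splicing gene lists. Duplicates within one set are
#' deduplicated with a warning.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return data.frame with columns `region` (membership signature, e.g.
#'   `"WT"`, `"WT&KD"`) and `count` (elements belonging to exactly that
#'   combination), plus attribute `total` = number of distinct
#'   identifiers.
#' @examples
#' conditionOverlap(list(A = c("x", "y"), B = c("y", "z")))
#' @export
conditionOverlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3 ||
      is.null(names(sets)))
    stop("sets must be a named list of 2 or 3 identifier vectors")
  if (any(vapply(sets, anyDuplicated, 0L) > 0)) {
    warning("duplicate identifiers within a set; deduplicating")
    sets <- lapply(sets, unique)
  }
  labels <- names(sets)
  all_ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, labels))
  sig <- apply(member, 1L, function(m) paste(labels[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&")), use.names = FALSE)
  counts <- vapply(combos, function(cb) sum(sig == cb), 0L)
  out <- data.frame(region = combos, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(all_ids)
  out
}

#' Overlap of skipped-exon events with circRNA spans
#'
#' Asks how often a circRNA coincides with an annotated skipped-exon
#' alternative-splicing event in the same gene: an event counts as a
#' match when its exon interval is identical to the genomic span of a
#' classified circRNA. Percentages are reported over the
#' alternatively-spliced gene set, to one decimal.
#'
#' @param as_genes character vector of alternatively spliced gene ids.
#' @param host_genes character vector of circRNA-producing gene ids.
#' @param skipped_exon_events data.frame with columns `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive exon interval).
#' @param circs a [CircRNASet-class].
#' @return list: `n_as`, `n_host`, `n_as_and_host` (genes both AS and
#'   circRNA-producing), `n_skipped_match` (AS genes with an event
#'   identical to a circRNA span), `pct_skipped_match` (over `n_as`, one
#'   decimal).
#' @export
spliceOverlapReport <- function(as_genes, host_genes, skipped_exon_events, circs) {
  as_genes <- unique(as_genes); host_genes <- unique(host_genes)
  n_as <- length(as_genes)
  circ_key <- paste(as.character(seqnames(circs)), start(circs), end(circs),
                    mcols(circs)$host_gene, sep = ":")
  matched <- character(0)
  if (NROW(skipped_exon_events)) {
    ev <- skipped_exon_events
    ev_key <- paste(ev$chrom, ev$start, ev$end, ev$gene, sep = ":")
    matched <- unique(ev$gene[ev_key %in% circ_key & ev$gene %in% as_genes])
  }
  list(n_as = n_as,
       n_host = length(host_genes),
       n_as_and_host = length(intersect(as_genes, host_genes)),
       n_skipped_match = length(matched),
       pct_skipped_match = if (n_as) round(100 * length(matched) / n_as, 1) else 0.0)
}
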
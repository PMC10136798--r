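.SCHEMA_LABELS <- c("E1", "A", "I", "D", "dsE", "AD")

#' circRNA-anchored region schema for pausing analysis
#'
#' Labels the host gene of an exonic circRNA into: E1 (first exon of the
#' gene, when it lies transcript-upstream of the circRNA), A (acceptor
#' exon), I (circRNA-internal exons), D (donor exon), dsE (first exon
#' downstream of the donor), plus a `flank` window of `flank` bp on each
#' side of every labeled exon (transcript orientation suffixes `_up` /
#' `_dn`). For a single-exon circRNA the acceptor and donor coincide and
#' are emitted as the combined label `AD`. E1 is omitted (flagged) when
#' the acceptor is the first exon; dsE when the donor is the last. Flank
#' windows are clipped to the gene span and trimmed against every
#' exon-labeled region and previously assigned flank, so labels never
#' overlap within a gene.
#'
#' @param circ a single-element exonic [CircRNASet-class].
#' @param genes a [GeneModelSet-class].
#' @param flank flank width in bp (default 300).
#' @return `GRanges` with mcols `label` (e.g. `"A"`, `"A_up"`) and
#'   `gene`; attribute `omitted` lists dropped labels.
#' @export
defineRegions <- function(circ, genes, flank = 300L) {
  stopifnot(length(circ) == 1L)
  cls <- mcols(circ)$circ_class
  if (!cls %in% c("exonic_single", "exonic_multi"))
    stop("region schema applies to exonic circRNAs, got ", cls)
  gid <- mcols(circ)$host_gene
  ex <- exonRanges(genes)[[gid]]
  nex <- length(ex)
  es <- start(ex); ee <- end(ex)
  chrom <- as.character(seqnames(ex))[1]
  std <- as.character(strand(ex))[1]
  span_lo <- min(es); span_hi <- max(ee)
  a <- mcols(circ)$acceptor_exon; d <- mcols(circ)$donor_exon
  gix <- function(t) if (std == "+") t else nex - t + 1L  # transcript -> genomic

  omitted <- character(0)
  core <- list()                      # label -> genomic exon indices
  if (a > 1L) core$E1 <- gix(1L) else omitted <- c(omitted, "E1")
  if (a == d) {
    core$AD <- gix(a)
  } else {
    core$A <- gix(a)
    if (d > a + 1L) core$I <- sort(vapply((a + 1L):(d - 1L), gix, 1L))
    core$D <- gix(d)
  }
  if (d < nex) core$dsE <- gix(d + 1L) else omitted <- c(omitted, "dsE")

  # assemble in plain integers; one GRanges at the end
  seg_s <- integer(0); seg_e <- integer(0); seg_lab <- character(0)
  for (lab in names(core)) {
    idx <- core[[lab]]
    seg_s <- c(seg_s, es[idx]); seg_e <- c(seg_e, ee[idx])
    seg_lab <- c(seg_lab, rep(lab, length(idx)))
  }
  if (flank > 0) {
    subtract <- function(s, e, ss, ee_) {
      # remove [ss,ee_] intervals from [s,e]; returns matrix of segments
      segs <- matrix(c(s, e), ncol = 2)
      for (j in seq_along(ss)) {
        keep <- matrix(integer(0), ncol = 2)
        for (r in seq_len(nrow(segs))) {
          lo <- segs[r, 1]; hi <- segs[r, 2]
          if (ss[j] > hi || ee_[j] < lo) { keep <- rbind(keep, c(lo, hi)); next }
          if (ss[j] > lo) keep <- rbind(keep, c(lo, ss[j] - 1L))
          if (ee_[j] < hi) keep <- rbind(keep, c(ee_[j] + 1L, hi))
        }
        segs <- keep
        if (!nrow(segs)) break
      }
      segs
    }
    for (lab in names(core)) {
      idx <- core[[lab]]
      blk_lo <- min(es[idx]); blk_hi <- max(ee[idx])
      left <- c(max(blk_lo - flank, span_lo), blk_lo - 1L)
      right <- c(blk_hi + 1L, min(blk_hi + flank, span_hi))
      up <- if (std == "+") left else right
      dn <- if (std == "+") right else left
      for (fl in list(list(paste0(lab, "_up"), up),
                      list(paste0(lab, "_dn"), dn))) {
        w <- fl[[2]]
        if (w[1] > w[2]) next
        segs <- subtract(w[1], w[2], seg_s, seg_e)
        if (nrow(segs)) {
          seg_s <- c(seg_s, segs[, 1]); seg_e <- c(seg_e, segs[, 2])
          seg_lab <- c(seg_lab, rep(fl[[1]], nrow(segs)))
        }
      }
    }
  }
  out <- GRanges(chrom, IRanges(seg_s, seg_e), strand = std)
  mcols(out)$label <- seg_lab
  mcols(out)$gene <- gid
  attr(out, "omitted") <- omitted
  out
}

#' Pausing index of a region
#'
#' Index = mean per-base coverage in the region divided by mean per-base
#' coverage over the gene body (the gene span), on the gene's strand.
#' Uniform coverage gives 1; values above 1 mark RNAPII accumulation.
#' Genes with zero gene-body coverage are excluded (NA with a warning),
#' never zero-filled.
#'
#' @param track a [CoverageTrack-class].
#' @param region `GRanges` (one or more ranges pooled into one region).
#' @param gene_body `GRanges` of the gene span (same strand as region).
#' @return a single numeric index, or NA when the gene body has no
#'   signal.
#' @export
pausingIndex <- function(track, region, gene_body) {
  body_mean <- sum(regionSum(track, gene_body)) /
    sum(as.numeric(width(gene_body)))
  if (body_mean == 0) {
    warning("gene body has zero coverage; excluded from pausing analysis")
    return(NA_real_)
  }
  reg_mean <- sum(regionSum(track, region)) / sum(as.numeric(width(region)))
  reg_mean / body_mean
}

#' Per-gene, per-region pausing profile of a circRNA cohort
#'
#' @param circs exonic [CircRNASet-class] records (one per host gene /
#'   circRNA).
#' @param genes a [GeneModelSet-class].
#' @param track a [CoverageTrack-class].
#' @param flank flank width for [defineRegions()].
#' @param collapse_flanks pool all `_up`/`_dn` windows into one `flank`
#'   label instead of keeping them per exon.
#' @return data.frame: `host_gene`, `condition`, `region`, `index`;
#'   genes with zero body coverage are dropped.
#' @export
pausingProfile <- function(circs, genes, track, flank = 300L,
                           collapse_flanks = FALSE) {
  keep <- which(mcols(circs)$circ_class %in% c("exonic_single", "exonic_multi"))
  rows <- list()
  for (i in keep) {
    gid <- mcols(circs[i])$host_gene
    schema <- defineRegions(circs[i], genes, flank = flank)
    body <- geneRanges(genes)[gid]
    if (sum(regionSum(track, body)) == 0) next
    labs <- mcols(schema)$label
    if (collapse_flanks)
      labs[grepl("_(up|dn)$", labs)] <- "flank"
    for (lab in unique(labs)) {
      idx <- pausingIndex(track, schema[labs == lab], body)
      rows[[length(rows) + 1L]] <- data.frame(
        host_gene = gid, condition = mcols(circs[i])$condition,
        region = lab, index = idx, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(host_gene = character(0), condition = character(0),
                      region = character(0), index = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cohort-level metaprofile of pausing indices
#'
#' @param profile data.frame from [pausingProfile()].
#' @return data.frame per region: `n`, `mean`, `sem`.
#' @export
metaprofile <- function(profile) {
  if (!nrow(profile)) stop("empty cohort")
  sp <- split(profile$index, profile$region)
  out <- do.call(rbind, lapply(names(sp), function(r) {
    x <- sp[[r]][!is.na(sp[[r]])]
    data.frame(region = r, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
               stringsAsFactors = FALSE)
  }))
  out[order(out$region), , drop = FALSE]
}

#' Welch comparison of two cohorts' pausing profiles per region
#'
#' @param profile_a,profile_b data.frames from [pausingProfile()].
#' @return data.frame per shared region: means and Welch p-value.
#' @export
compareProfiles <- function(profile_a, profile_b) {
  regions <- intersect(unique(profile_a$region), unique(profile_b$region))
  do.call(rbind, lapply(regions, function(r) {
    xa <- profile_a$index[profile_a$region == r]
    xb <- profile_b$index[profile_b$region == r]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    p <- if (length(xa) > 1 && length(xb) > 1 &&
             (stats::sd(xa) > 0 || stats::sd(xb) > 0))
      stats::t.test(xa, xb)$p.value else NA_real_
    data.frame(region = r, n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), mean_b = mean(xb), p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Change in pausing between two conditions
#'
#' Per gene and region: `log2((index_kd + eps) / (index_wt + eps))`.
#' Genes excluded (zero body coverage) in either condition are dropped
#' from the deltas.
#'
#' @param profile_wt,profile_kd data.frames from [pausingProfile()] (or
#'   [intronExonPausing()], long format) for the two conditions.
#' @param eps pseudo-index guarding the ratio (default 1e-6).
#' @param tau no-change threshold on |log2 ratio|, default `log2(1.5)`.
#' @return data.frame: `host_gene`, `region`, `index_wt`, `index_kd`,
#'   `log2_ratio`, `class` (increased / decreased / no_change).
#' @export
deltaPausing <- function(profile_wt, profile_kd, eps = 1e-6,
                         tau = log2(1.5)) {
  key <- c("host_gene", "region")
  m <- merge(profile_wt[, c(key, "index")], profile_kd[, c(key, "index")],
             by = key, suffixes = c("_wt", "_kd"))
  m <- m[!is.na(m$index_wt) & !is.na(m$index_kd), , drop = FALSE]
  m$log2_ratio <- log2((m$index_kd + eps) / (m$index_wt + eps))
  m$class <- classifyChange(m$log2_ratio, tau = tau)
  m[order(m$host_gene, m$region), , drop = FALSE]
}

#' Classify log2 pausing changes
#'
#' Thresholds are symmetric about zero: increased when `x > tau`,
#' decreased when `x < -tau`, no_change otherwise.
#'
#' @param x numeric vector of log2 ratios.
#' @param tau threshold, default `log2(1.5)`.
#' @return character vector in {increased, decreased, no_change}.
#' @export
classifyChange <- function(x, tau = log2(1.5)) {
  ifelse(x > tau, "increased", ifelse(x < -tau, "decreased", "no_change"))
}

#' Pooled exonic and intronic pausing indices of genes
#'
#' All exonic bp of the representative transcript pooled into one region
#' and all intronic bp into another, each normalized by the gene-body
#' mean. Intronless genes get an NA intron index (flagged); genes with
#' zero body coverage are dropped.
#'
#' With `normalize = "none"` the raw pooled coverage densities (reads
#' per bp) are returned instead: the form used to compare exon/intron
#' pausing *changes* between conditions, where per-gene body
#' normalization would cancel concerted shifts (tracks should then be
#' depth-matched).
#'
#' @param genes a [GeneModelSet-class].
#' @param track a [CoverageTrack-class].
#' @param gene_ids genes to profile (default all).
#' @param normalize `"gene"` (divide by gene-body mean) or `"none"`.
#' @return data.frame in long format: `host_gene`, `region`
#'   (exon/intron), `index`.
#' @export
intronExonPausing <- function(genes, track, gene_ids = geneIds(genes),
                              normalize = c("gene", "none")) {
  normalize <- match.arg(normalize)
  rows <- list()
  exl <- exonRanges(genes)
  inl <- intronRanges(genes)
  for (gid in gene_ids) {
    body <- geneRanges(genes)[gid]
    if (sum(regionSum(track, body)) == 0) next
    dens <- function(region) {
      if (normalize == "gene") pausingIndex(track, region, body)
      else sum(regionSum(track, region)) / sum(as.numeric(width(region)))
    }
    ei <- dens(exl[[gid]])
    ii <- if (length(inl[[gid]])) dens(inl[[gid]]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      host_gene = gid, region = c("exon", "intron"), index = c(ei, ii),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
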
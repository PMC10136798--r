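#' Flanking introns of an exonic circRNA
#'
#' The upstream flanking intron is the intron immediately transcript-5'
#' of the acceptor exon; the downstream flanking intron sits immediately
#' transcript-3' of the donor exon. Strand-aware: for a minus-strand
#' gene the upstream intron has the larger genomic coordinates. When the
#' acceptor is the first exon (or the donor the last), the corresponding
#' flank is undefined and returned as `NA` with the flag set.
#'
#' @param circ a single-element [CircRNASet-class] (exonic).
#' @param genes a [GeneModelSet-class] containing the host gene.
#' @return list with `upstream` and `downstream` (each a `GRanges` of
#'   length 1 or `NULL`), and logical flags `upstream_defined`,
#'   `downstream_defined`.
#' @export
flankingIntrons <- function(circ, genes) {
  stopifnot(length(circ) == 1L)
  cls <- mcols(circ)$circ_class
  if (!cls %in% c("exonic_single", "exonic_multi"))
    stop("flanking-intron analysis applies to exonic circRNAs, got ", cls)
  gid <- mcols(circ)$host_gene
  ins <- intronRanges(genes)[[gid]]
  nex <- length(exonRanges(genes)[[gid]])
  std <- geneStrand(genes)[[gid]]
  a <- mcols(circ)$acceptor_exon; d <- mcols(circ)$donor_exon
  # transcript intron j sits between transcript exons j and j+1;
  # genomic intron index = j on '+', nex - j on '-'
  up_t <- a - 1L; dn_t <- d
  up <- dn <- NULL
  if (up_t >= 1L) {
    gi <- if (std == "+") up_t else nex - up_t
    up <- ins[gi]
  }
  if (dn_t <= nex - 1L) {
    gi <- if (std == "+") dn_t else nex - dn_t
    dn <- ins[gi]
  }
  list(upstream = up, downstream = dn,
       upstream_defined = !is.null(up), downstream_defined = !is.null(dn))
}

#' Per-circRNA host-gene architecture records
#'
#' One record per exonic classified junction: host-gene length, flanking
#' intron lengths (NA when the acceptor/donor exon is terminal),
#' internal intron and circRNA exon lengths. Host genes with several
#' circRNAs contribute one record per distinct circRNA.
#'
#' @param circs a [CircRNASet-class].
#' @param genes a [GeneModelSet-class].
#' @return data.frame with one row per exonic circRNA: `host_gene`,
#'   `condition`, `circ_class`, `gene_length`, `upstream_length`,
#'   `downstream_length`, `internal_intron_lengths` and
#'   `circ_exon_lengths` (comma-joined), `internal_intron_mean`,
#'   `circ_exon_mean`.
#' @export
architectureRecords <- function(circs, genes) {
  keep <- which(mcols(circs)$circ_class %in% c("exonic_single", "exonic_multi"))
  exl <- exonRanges(genes)
  inl <- intronRanges(genes)
  spans <- geneRanges(genes)
  spanw <- stats::setNames(width(spans), names(spans))
  strd <- geneStrand(genes)
  rows <- lapply(keep, function(i) {
    ci <- circs[i]
    gid <- mcols(ci)$host_gene
    a <- mcols(ci)$acceptor_exon; d <- mcols(ci)$donor_exon
    nex <- length(exl[[gid]])
    fl <- flankingIntrons(ci, genes)
    # transcript exon index -> genomic index
    gix <- function(t) if (strd[[gid]] == "+") t else nex - t + 1L
    circ_ex <- vapply(a:d, function(t) width(exl[[gid]])[gix(t)], 1L)
    int_in <- if (d > a)
      vapply(a:(d - 1L), function(t) {
        gi <- if (strd[[gid]] == "+") t else nex - t
        width(inl[[gid]])[gi]
      }, 1L) else integer(0)
    data.frame(
      host_gene = gid,
      condition = mcols(ci)$condition,
      circ_class = mcols(ci)$circ_class,
      gene_length = spanw[[gid]],
      upstream_length = if (fl$upstream_defined) width(fl$upstream) else NA_integer_,
      downstream_length = if (fl$downstream_defined) width(fl$downstream) else NA_integer_,
      internal_intron_lengths = paste(int_in, collapse = ","),
      circ_exon_lengths = paste(circ_ex, collapse = ","),
      internal_intron_mean = if (length(int_in)) mean(int_in) else NA_real_,
      circ_exon_mean = mean(circ_ex),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.lenStats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  data.frame(n = n,
             mean = if (n) mean(x) else NA_real_,
             median = if (n) stats::median(x) else NA_real_,
             sem = if (n > 1) stats::sd(x) / sqrt(n) else if (n == 1) 0 else NA_real_)
}

.splitLens <- function(s) as.integer(unlist(strsplit(s[nzchar(s)], ","), use.names = FALSE))

#' Architecture summary per condition plus background
#'
#' Means, medians, n and SEM per condition for gene length, upstream /
#' downstream flanking introns, pooled internal introns, and pooled
#' circRNA exon lengths, next to the background gene cohort (all genes
#' not hosting any circRNA in any condition: their gene, intron, and
#' exon lengths).
#'
#' @param records output of [architectureRecords()].
#' @param genes a [GeneModelSet-class].
#' @param background_genes character vector of background gene ids;
#'   defaults to all genes in `genes` absent from `records$host_gene`.
#' @return data.frame with columns `group`, `metric`, `n`, `mean`,
#'   `median`, `sem`.
#' @export
summarizeArchitecture <- function(records, genes,
                                  background_genes = setdiff(geneIds(genes),
                                                             records$host_gene)) {
  out <- list()
  for (cond in sort(unique(records$condition))) {
    r <- records[records$condition == cond, , drop = FALSE]
    metrics <- list(
      gene_length = r$gene_length,
      upstream_intron = r$upstream_length,
      downstream_intron = r$downstream_length,
      internal_intron = .splitLens(r$internal_intron_lengths),
      circ_exon = .splitLens(r$circ_exon_lengths))
    for (m in names(metrics))
      out[[length(out) + 1L]] <- cbind(group = cond, metric = m,
                                       .lenStats(metrics[[m]]))
  }
  bg <- genes[intersect(background_genes, geneIds(genes))]
  if (length(bg)) {
    bmetrics <- list(
      gene_length = width(geneRanges(bg)),
      intron = unlist(width(intronRanges(bg)), use.names = FALSE),
      exon = unlist(width(exonRanges(bg)), use.names = FALSE))
    for (m in names(bmetrics))
      out[[length(out) + 1L]] <- cbind(group = "background", metric = m,
                                       .lenStats(bmetrics[[m]]))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-group length comparison
#'
#' Default is Welch's t on log-transformed lengths (intron and gene
#' lengths are heavy-tailed); `"student-raw"` applies Student's pooled t
#' on the raw scale. When both groups have zero variance the p-value is
#' 1 for equal means and 0 otherwise.
#'
#' @param a,b numeric length vectors (NAs dropped), each n >= 2.
#' @param test `"welch-log"` (default) or `"student-raw"`.
#' @param paired logical; requires equal lengths.
#' @return list with `p`, `statistic`, `method`.
#' @export
compareLengths <- function(a, b, test = c("welch-log", "student-raw"),
                           paired = FALSE) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 observations per group")
  if (test == "welch-log") { a <- log(a); b <- log(b) }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && !paired)
    return(list(p = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                statistic = NA_real_, method = test))
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = (test == "student-raw"), paired = paired),
    error = function(e)
      list(p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
           statistic = NA_real_))
  list(p = unname(ht$p.value), statistic = unname(ht$statistic), method = test)
}

#' Flanking-intron length asymmetry
#'
#' Ratio of mean upstream to mean downstream flanking-intron length over
#' records where both flanks are defined, with a paired test on the
#' per-circRNA (upstream - downstream) differences.
#'
#' @param records output of [architectureRecords()].
#' @param test passed to [compareLengths()] (`paired = TRUE`).
#' @return list: `n_pairs`, `mean_up`, `mean_down`, `ratio`, `p`
#'   (NA, flagged via `p_defined = FALSE`, when fewer than 2 complete
#'   pairs).
#' @export
intronAsymmetry <- function(records, test = "student-raw") {
  ok <- !is.na(records$upstream_length) & !is.na(records$downstream_length)
  if (!any(ok)) stop("no records with both flanking introns defined")
  up <- records$upstream_length[ok]; dn <- records$downstream_length[ok]
  res <- list(n_pairs = sum(ok), mean_up = mean(up), mean_down = mean(dn),
              ratio = mean(up) / mean(dn))
  if (sum(ok) >= 2 && stats::sd(up - dn) > 0) {
    res$p <- compareLengths(up, dn, test = test, paired = TRUE)$p
    res$p_defined <- TRUE
  } else {
    res$p <- NA_real_; res$p_defined <- FALSE
  }
  res
}
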
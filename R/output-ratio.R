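#' Housekeeping geometric-mean normalization of probe counts
#'
#' Standard digital-counting normalization: each sample is scaled by
#' (grand geometric mean of housekeeping counts) / (geometric mean of
#' that sample's housekeeping counts), so housekeeping geometric means
#' agree across samples afterwards. Housekeeping probes with a zero
#' count in any sample are dropped from the factor computation with a
#' warning; if none survive, an error is raised.
#'
#' @param x a [ProbeCountMatrix-class].
#' @return a [ProbeCountMatrix-class] with scaled counts; scale factors
#'   in `metadata(x)$size_factors`.
#' @export
normalizeCounts <- function(x) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  hk <- SummarizedExperiment::rowData(x)$probe_type == "housekeeping"
  if (!any(hk)) stop("no housekeeping probes present")
  hkc <- cnt[hk, , drop = FALSE]
  usable <- rowSums(hkc == 0) == 0
  if (!all(usable)) {
    warning(sum(!usable), " housekeeping probe(s) with zero counts dropped ",
            "from factor computation")
    hkc <- hkc[usable, , drop = FALSE]
  }
  if (!nrow(hkc)) stop("all housekeeping probes contain zeros")
  sample_gm <- exp(colMeans(log(hkc)))
  grand_gm <- exp(mean(log(hkc)))
  factors <- grand_gm / sample_gm
  out <- x
  SummarizedExperiment::assay(out, "counts") <- sweep(cnt, 2, factors, `*`)
  S4Vectors::metadata(out)$size_factors <- factors
  out
}

#' Per-probe log2 fold change and Welch test against a reference
#'
#' `log2FC = log2(mean_cond + c) - log2(mean_ref + c)` with pseudo-count
#' `c` (default 0.5) on normalized counts; the p-value is a two-sample
#' Welch t-test on `log2(count + c)` across replicates, BH-corrected
#' across the circular and linear probes. Probes with fewer than 2
#' replicates in either group get `p = NA` (flagged).
#'
#' @param x a normalized [ProbeCountMatrix-class].
#' @param condition condition to compare.
#' @param ref reference condition (default `"WT"`).
#' @param pseudo pseudo-count.
#' @return data.frame: `probe_id`, `gene_id`, `probe_type`, `condition`,
#'   `log2fc`, `p`, `q`, `p_defined`.
#' @export
probeLog2FC <- function(x, condition, ref = "WT", pseudo = 0.5) {
  cd <- SummarizedExperiment::colData(x)
  if (!condition %in% cd$condition) stop("condition ", condition, " absent")
  if (!ref %in% cd$condition) stop("reference condition ", ref, " absent")
  cnt <- SummarizedExperiment::assay(x, "counts")
  ic <- which(cd$condition == condition)
  ir <- which(cd$condition == ref)
  rd <- SummarizedExperiment::rowData(x)
  lfc <- log2(rowMeans(cnt[, ic, drop = FALSE]) + pseudo) -
         log2(rowMeans(cnt[, ir, drop = FALSE]) + pseudo)
  p <- rep(NA_real_, nrow(cnt))
  if (length(ic) >= 2 && length(ir) >= 2) {
    lg <- log2(cnt + pseudo)
    p <- vapply(seq_len(nrow(cnt)), function(i) {
      a <- lg[i, ic]; b <- lg[i, ir]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      stats::t.test(a, b)$p.value
    }, 0)
  }
  out <- data.frame(probe_id = rownames(cnt), gene_id = rd$gene_id,
                    probe_type = rd$probe_type, condition = condition,
                    log2fc = unname(lfc), p = p,
                    p_defined = !is.na(p), stringsAsFactors = FALSE)
  test_rows <- out$probe_type %in% c("circ", "linear")
  out$q <- NA_real_
  out$q[test_rows] <- stats::p.adjust(out$p[test_rows], "BH")
  out
}

#' Flag expression-altered probes and host genes
#'
#' A probe is altered when its p-value (or BH q-value with
#' `use = "q"`) is below `alpha` and `|log2FC|` exceeds
#' `lfc_threshold`; a gene is altered when either of its circular or
#' linear probes is. The altered-gene percentage is reported over the
#' profiled genes, rounded to the nearest integer.
#'
#' @param changes data.frame from [probeLog2FC()].
#' @param alpha significance level.
#' @param lfc_threshold absolute log2FC threshold (default 2).
#' @param use `"p"` (default, mirroring volcano-plot cutoffs) or `"q"`.
#' @return list: `probes` (with `altered` flag), `genes` (per-gene
#'   flag), `n_genes`, `n_altered`, `pct_altered`.
#' @export
classifyExpression <- function(changes, alpha = 0.05, lfc_threshold = 2,
                               use = c("p", "q")) {
  use <- match.arg(use)
  ch <- changes[changes$probe_type %in% c("circ", "linear"), , drop = FALSE]
  stat <- ch[[use]]
  ch$altered <- !is.na(stat) & stat < alpha & abs(ch$log2fc) > lfc_threshold
  per_gene <- tapply(ch$altered, ch$gene_id, any)
  genes <- data.frame(gene_id = names(per_gene),
                      altered = as.vector(per_gene),
                      stringsAsFactors = FALSE)
  n <- nrow(genes); n_alt <- sum(genes$altered)
  list(probes = ch, genes = genes, n_genes = n, n_altered = n_alt,
       pct_altered = if (n) round(100 * n_alt / n) else 0)
}

#' Circular-to-linear ratio change classes
#'
#' Per gene, the C:L ratio change is `delta_cl = log2FC_circ -
#' log2FC_linear`. A gene is *increased* when `delta_cl > delta` and the
#' circular change is significant, *decreased* when `delta_cl < -delta`
#' with a significant circular change, and *no_change* otherwise. Genes
#' missing either probe are excluded. Class percentages over analyzable
#' genes are rounded to the nearest integer.
#'
#' @param changes data.frame from [probeLog2FC()].
#' @param delta symmetric threshold on `delta_cl` (default 1, i.e.
#'   2-fold).
#' @param alpha significance level for the circular-probe change.
#' @param use `"p"` or `"q"` column for significance.
#' @return list: `genes` (per-gene `log2fc_circ`, `log2fc_linear`,
#'   `delta_cl`, `class`), `counts`, `percentages` (named increased /
#'   decreased / no_change).
#' @export
clRatioClass <- function(changes, delta = 1, alpha = 0.05, use = c("p", "q")) {
  use <- match.arg(use)
  circ <- changes[changes$probe_type == "circ", , drop = FALSE]
  lin <- changes[changes$probe_type == "linear", , drop = FALSE]
  m <- merge(circ[, c("gene_id", "log2fc", use)],
             lin[, c("gene_id", "log2fc")],
             by = "gene_id", suffixes = c("_circ", "_linear"))
  names(m)[names(m) == use] <- "stat_circ"
  m$delta_cl <- m$log2fc_circ - m$log2fc_linear
  sig <- !is.na(m$stat_circ) & m$stat_circ < alpha
  m$class <- ifelse(m$delta_cl > delta & sig, "increased",
             ifelse(m$delta_cl < -delta & sig, "decreased", "no_change"))
  counts <- table(factor(m$class, c("increased", "decreased", "no_change")))
  pct <- round(100 * counts / max(nrow(m), 1))
  list(genes = m[, c("gene_id", "log2fc_circ", "log2fc_linear",
                     "delta_cl", "class")],
       counts = as.vector(counts) |> stats::setNames(names(counts)),
       percentages = as.vector(pct) |> stats::setNames(names(pct)))
}

#' Cross-tabulate C:L ratio classes with pausing classes
#'
#' Builds, separately for exonic and intronic pausing, the contingency
#' table of pausing change class within each C:L ratio class, with row
#' percentages and a Fisher exact test for association.
#'
#' @param cl result of [clRatioClass()] (or its `genes` data.frame).
#' @param pausing data.frame with `host_gene`, `region` (exon/intron)
#'   and `class` (e.g. [deltaPausing()] on [intronExonPausing()]
#'   profiles).
#' @return list per region (`exon`, `intron`): `table`, `row_pct`,
#'   `fisher_p`.
#' @export
pausingCrosstab <- function(cl, pausing) {
  genes <- if (is.data.frame(cl)) cl else cl$genes
  lv_p <- c("increased", "decreased", "no_change")
  out <- list()
  for (reg in c("exon", "intron")) {
    pr <- pausing[pausing$region == reg, , drop = FALSE]
    m <- merge(genes[, c("gene_id", "class")], pr[, c("host_gene", "class")],
               by.x = "gene_id", by.y = "host_gene",
               suffixes = c("_cl", "_pausing"))
    if (!nrow(m)) stop("no shared genes between C:L and pausing classes (",
                       reg, ")")
    tab <- table(cl_class = factor(m$class_cl, lv_p),
                 pausing_class = factor(m$class_pausing, lv_p))
    keep <- rowSums(tab) > 0
    row_pct <- sweep(tab, 1, pmax(rowSums(tab), 1), `/`) * 100
    ft <- tab[keep, colSums(tab) > 0, drop = FALSE]
    fisher_p <- if (nrow(ft) >= 2 && ncol(ft) >= 2)
      stats::fisher.test(ft, workspace = 2e6)$p.value else NA_real_
    out[[reg]] <- list(table = tab, row_pct = row_pct, fisher_p = fisher_p)
  }
  out
}
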
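#' Packaged demonstration cohorts
#'
#' Deterministic, programmatically built cohorts with fixed, known
#' composition, used by the worked examples, the test suite and the
#' acceptance script. They emulate a three-condition (WT / PARPi / KD)
#' Drosophila S2 circRNA study at desk scale: a junction-call cohort
#' with a fixed intronic/exonic partition, an alternative-splicing
#' overlap cohort, a 26-gene probe panel with planted expression
#' effects, and a 26-gene pausing cohort with planted exon/intron
#' density changes.
#'
#' @name circArch-fixtures
NULL

#' @describeIn circArch-fixtures junction-call cohort: 284 distinct
#'   backsplice junctions (70 intronic: 26 WT / 21 PARPi / 23 KD;
#'   214 exonic: 67 WT / 87 PARPi / 60 KD, each junction exclusive to
#'   one condition) plus within-condition repeat calls bringing the
#'   total to 364 calls. Returns a list with `genes`
#'   ([GeneModelSet-class]) and `junctions` (`GRanges`).
#' @export
junctionCohortFixture <- function() {
  n_intronic <- c(WT = 26L, PARPi = 21L, KD = 23L)
  n_exonic <- c(WT = 67L, PARPi = 87L, KD = 60L)
  total_calls <- 364L
  exon_w <- 200L; intron_w <- 500L; gap <- 300L
  n_genes <- sum(n_intronic) + sum(n_exonic)
  exl <- vector("list", n_genes)
  jlist <- vector("list", n_genes)
  spec <- rbind(
    data.frame(condition = rep(names(n_intronic), n_intronic),
               kind = "intronic", stringsAsFactors = FALSE),
    data.frame(condition = rep(names(n_exonic), n_exonic),
               kind = "exonic", stringsAsFactors = FALSE))
  at <- 1L
  for (i in seq_len(n_genes)) {
    starts <- at + (0:4) * (exon_w + intron_w)
    ex <- GRanges("chrS", IRanges(starts, starts + exon_w - 1L), "+")
    gid <- sprintf("jg%03d", i)
    exl[[i]] <- ex
    names(exl)[i] <- gid
    if (spec$kind[i] == "intronic") {
      # strictly inside intron 2
      js <- end(ex)[2] + 10L; je <- start(ex)[3] - 10L
    } else if (i %% 2L == 0L) {
      js <- start(ex)[2]; je <- end(ex)[2]          # single exon
    } else {
      js <- start(ex)[2]; je <- end(ex)[4]          # multi exon
    }
    jr <- GRanges("chrS", IRanges(js, je), strand = "+")
    mcols(jr)$condition <- spec$condition[i]
    mcols(jr)$n_reads <- 2L + (i %% 7L)
    jlist[[i]] <- jr
    at <- max(end(ex)) + gap
  }
  junctions <- do.call(c, jlist)
  # repeat calls of existing junctions within their own condition
  extra <- total_calls - n_genes
  dup <- junctions[seq_len(extra)]
  list(genes = GeneModelSet(GenomicRanges::GRangesList(exl)),
       junctions = c(junctions, dup))
}

#' @describeIn circArch-fixtures alternative-splicing overlap cohort for
#'   one condition: `"KD"` gives 422 alternatively spliced genes, 52 of
#'   them circRNA-producing, and 38 with a skipped-exon event identical
#'   to a circRNA span; `"PARPi"` gives 471 / 56 / 42. Returns the
#'   arguments of [spliceOverlapReport()] as a list.
#' @param condition `"KD"` or `"PARPi"`.
#' @export
spliceOverlapFixture <- function(condition = c("KD", "PARPi")) {
  condition <- match.arg(condition)
  nums <- switch(condition,
                 KD = c(as = 422L, host = 52L, match = 38L),
                 PARPi = c(as = 471L, host = 56L, match = 42L))
  as_genes <- sprintf("%s_as%03d", condition, seq_len(nums[["as"]]))
  # circRNA-producing genes: the first `host` AS genes plus 64 hosts
  # outside the AS set (host genes need not be alternatively spliced)
  host_genes <- c(as_genes[seq_len(nums[["host"]])],
                  sprintf("%s_xh%03d", condition, seq_len(64L)))
  span_start <- 1000L + 900L * seq_along(host_genes)
  circ <- GRanges("chrS", IRanges(span_start, span_start + 400L), "+")
  mcols(circ)$condition <- condition
  mcols(circ)$n_reads <- 3L
  mcols(circ)$circ_class <- "exonic_single"
  mcols(circ)$host_gene <- host_genes
  mcols(circ)$acceptor_exon <- 2L
  mcols(circ)$donor_exon <- 2L
  circs <- new("CircRNASet", circ)
  # events: identical span for matching genes, shifted for the rest
  ev_gene <- as_genes
  ev_start <- ifelse(seq_along(as_genes) <= nums[["match"]],
                     span_start[seq_along(as_genes)], 5L)
  events <- data.frame(gene = ev_gene, chrom = "chrS", start = ev_start,
                       end = ev_start + 400L, stringsAsFactors = FALSE)
  list(as_genes = as_genes, host_genes = host_genes, events = events,
       circs = circs)
}

#' @describeIn circArch-fixtures 26-gene probe panel with planted
#'   expression effects: under KD, 5 genes carry a +3 log2 circular-only
#'   effect (increased C:L ratio), 13 a -3 circular-only effect
#'   (decreased), and 8 no effect; under PARPi, 7 genes carry a
#'   circular effect (4 up, 3 down) and 19 none. Counts are simulated
#'   with a low-dispersion negative binomial so planted effects dominate
#'   sampling noise. Returns the [simulateCounts()] result.
#' @param seed RNG seed for the count draw (panel composition is fixed).
#' @export
probePanelFixture <- function(seed = 1L) {
  genes <- sprintf("hg%03d", 1:26)
  eff <- rbind(
    data.frame(gene_id = genes[1:5], probe_type = "circ", condition = "KD",
               lfc = 3, stringsAsFactors = FALSE),
    data.frame(gene_id = genes[6:18], probe_type = "circ", condition = "KD",
               lfc = -3, stringsAsFactors = FALSE),
    data.frame(gene_id = genes[1:4], probe_type = "circ", condition = "PARPi",
               lfc = 3, stringsAsFactors = FALSE),
    data.frame(gene_id = genes[5:7], probe_type = "circ", condition = "PARPi",
               lfc = -3, stringsAsFactors = FALSE))
  params <- simParams(nb_mean = 1000, nb_dispersion = 0.005,
                      n_replicates = 3L, n_probe_genes = 26L,
                      condition_logfc = eff, seed = as.integer(seed))
  simulateCounts(params, gene_ids = genes)
}

#' @describeIn circArch-fixtures 26-gene pausing cohort: noise-free WT
#'   and KD coverage tracks over 26 four-exon genes in which KD changes
#'   pooled exon coverage density by 2x for 15 genes, 0.5x for 3 and 1x
#'   for 8, and pooled intron density by 2x for 14 genes, 0.5x for 9 and
#'   1x for 3. Returns a list with `genes`, `track_wt`, `track_kd`,
#'   `exon_mult`, `intron_mult`.
#' @export
pausingCohortFixture <- function() {
  n <- 26L
  exon_mult <- rep(c(2, 0.5, 1), c(15L, 3L, 8L))
  intron_mult <- rep(c(2, 0.5, 1), c(14L, 9L, 3L))
  exon_w <- 300L; intron_w <- 600L; gap <- 400L; depth <- 10
  exl <- vector("list", n)
  at <- 1L
  cov_wt <- cov_kd <- NULL
  chrom_parts_wt <- list(); chrom_parts_kd <- list()
  for (i in seq_len(n)) {
    starts <- at + (0:3) * (exon_w + intron_w)
    ex <- GRanges("chrS", IRanges(starts, starts + exon_w - 1L), "+")
    exl[[i]] <- ex
    names(exl)[i] <- sprintf("hg%03d", i)
    at <- max(end(ex)) + gap
  }
  genes <- GeneModelSet(GenomicRanges::GRangesList(exl))
  len <- at + 100L
  v_wt <- numeric(len); v_kd <- numeric(len)
  exlist <- exonRanges(genes); inlist <- intronRanges(genes)
  for (i in seq_len(n)) {
    gid <- sprintf("hg%03d", i)
    for (r in seq_along(exlist[[gid]])) {
      idx <- start(exlist[[gid]])[r]:end(exlist[[gid]])[r]
      v_wt[idx] <- depth; v_kd[idx] <- depth * exon_mult[i]
    }
    for (r in seq_along(inlist[[gid]])) {
      idx <- start(inlist[[gid]])[r]:end(inlist[[gid]])[r]
      v_wt[idx] <- depth; v_kd[idx] <- depth * intron_mult[i]
    }
  }
  list(genes = genes,
       track_wt = CoverageTrack(plus = methods::as(list(chrS = S4Vectors::Rle(v_wt)),
                                                   "RleList")),
       track_kd = CoverageTrack(plus = methods::as(list(chrS = S4Vectors::Rle(v_kd)),
                                                   "RleList")),
       exon_mult = exon_mult, intron_mult = intron_mult)
}
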
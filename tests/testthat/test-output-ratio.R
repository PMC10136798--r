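mkPanel <- function(counts, conditions, reps = 2L) {
  # counts: probes x samples matrix with rownames gene_type
  gene_id <- sub("_(circ|linear|housekeeping)$", "", rownames(counts))
  probe_type <- sub("^.*_", "", rownames(counts))
  ProbeCountMatrix(counts, gene_id = gene_id, probe_type = probe_type,
                   condition = rep(conditions, each = reps),
                   replicate = rep(seq_len(reps), length(conditions)))
}

test_that("housekeeping normalization equalizes geometric means", {
  cnt <- rbind(g1_circ = c(10, 10, 20, 20),
               g1_linear = c(50, 50, 100, 100),
               hk1_housekeeping = c(100, 100, 200, 200),
               hk2_housekeeping = c(400, 400, 800, 800),
               hk3_housekeeping = c(900, 900, 1800, 1800))
  pcm <- mkPanel(cnt, c("WT", "KD"))
  norm <- normalizeCounts(pcm)
  f <- S4Vectors::metadata(norm)$size_factors
  # samples 3-4 are doubled: factor 1/sqrt(2) relative to the grand mean
  expect_equal(unname(f[3] / f[1]), 0.5)
  hk <- SummarizedExperiment::assay(norm, "counts")[3:5, ]
  gm <- exp(colMeans(log(hk)))
  expect_equal(max(gm) / min(gm), 1, tolerance = 1e-12)
  # identical samples -> all factors 1
  cnt_same <- cnt[, c(1, 1, 1, 1)]
  expect_equal(unname(S4Vectors::metadata(
    normalizeCounts(mkPanel(cnt_same, c("WT", "KD"))))$size_factors),
    rep(1, 4))
  # zero housekeeping counts are dropped with a warning; all-zero errors
  cnt0 <- cnt; cnt0["hk1_housekeeping", 2] <- 0
  expect_warning(normalizeCounts(mkPanel(cnt0, c("WT", "KD"))), "dropped")
  cntz <- cnt; cntz[3:5, 1] <- 0
  expect_error(suppressWarnings(normalizeCounts(mkPanel(cntz, c("WT", "KD")))),
               "housekeeping")
})

test_that("log2 fold change and Welch test match a hand computation", {
  cnt <- rbind(g1_circ = c(100, 120, 110, 400, 420, 380),
               g1_linear = c(200, 210, 190, 200, 205, 195),
               hk1_housekeeping = rep(500, 6),
               hk2_housekeeping = rep(300, 6),
               hk3_housekeeping = rep(800, 6))
  pcm <- mkPanel(cnt, c("WT", "KD"), reps = 3L)
  ch <- probeLog2FC(pcm, "KD", ref = "WT")
  # matches direct computation with pseudo-count 0.5
  for (pr in c("g1_circ", "g1_linear")) {
    a <- cnt[pr, 4:6]; b <- cnt[pr, 1:3]
    expect_equal(ch$log2fc[ch$probe_id == pr],
                 log2(mean(a) + 0.5) - log2(mean(b) + 0.5))
    expect_equal(ch$p[ch$probe_id == pr],
                 t.test(log2(a + 0.5), log2(b + 0.5))$p.value)
  }
  expect_equal(ch$q[ch$probe_type != "housekeeping"],
               p.adjust(ch$p[ch$probe_type != "housekeeping"], "BH"))
  # identical conditions -> log2FC 0
  same <- mkPanel(cnt[, c(1:3, 1:3)], c("WT", "KD"), reps = 3L)
  ch0 <- probeLog2FC(same, "KD")
  expect_true(all(ch0$log2fc == 0))
  # missing condition errors; single replicate flags p undefined
  expect_error(probeLog2FC(pcm, "PARPi"), "absent")
  one <- mkPanel(cnt[, c(1, 4)], c("WT", "KD"), reps = 1L)
  ch1 <- probeLog2FC(one, "KD")
  expect_true(all(!ch1$p_defined))
})

test_that("planted probe effects are recovered and flagged as altered", {
  fx <- probePanelFixture(seed = 101L)
  pcm <- normalizeCounts(fx$counts)
  ch <- probeLog2FC(pcm, "KD")
  truth <- fx$truth[fx$truth$condition == "KD", ]
  m <- merge(ch, truth, by = c("gene_id", "probe_type"))
  planted <- m[m$lfc != 0, ]
  expect_equal(nrow(planted), 18L)
  expect_equal(planted$log2fc, planted$lfc, tolerance = 0.15)
  ce <- classifyExpression(ch)
  expect_equal(ce$n_genes, 26L)
  expect_equal(ce$n_altered, 18L)
  expect_equal(ce$pct_altered, 69)
  ce_pi <- classifyExpression(probeLog2FC(pcm, "PARPi"))
  expect_equal(ce_pi$pct_altered, 27)
  # nothing passes an impossible threshold
  expect_equal(classifyExpression(ch, lfc_threshold = 50)$pct_altered, 0)
})

test_that("C:L ratio classes partition the panel with the planted design", {
  fx <- probePanelFixture(seed = 103L)
  ch <- probeLog2FC(normalizeCounts(fx$counts), "KD")
  cl <- clRatioClass(ch)
  expect_equal(unname(cl$counts), c(5L, 13L, 8L))
  expect_equal(unname(cl$percentages), c(19, 50, 31))
  expect_equal(sum(cl$counts), 26L)
  # equal circular and linear change -> delta 0 -> no_change
  ch_eq <- ch
  ch_eq$log2fc[ch_eq$probe_type == "linear"] <-
    ch_eq$log2fc[match(paste0(ch_eq$gene_id[ch_eq$probe_type == "linear"], "_circ"),
                       ch_eq$probe_id)]
  cl_eq <- clRatioClass(ch_eq)
  expect_true(all(cl_eq$genes$class == "no_change"))
})

test_that("log2FC, classes and percentages are scale invariant", {
  fx <- probePanelFixture(seed = 107L)
  cnt <- SummarizedExperiment::assay(fx$counts, "counts")
  rd <- SummarizedExperiment::rowData(fx$counts)
  cd <- SummarizedExperiment::colData(fx$counts)
  scaled <- ProbeCountMatrix(cnt * 10, gene_id = rd$gene_id,
                             probe_type = rd$probe_type,
                             condition = cd$condition,
                             replicate = cd$replicate)
  ch1 <- probeLog2FC(normalizeCounts(fx$counts), "KD")
  ch2 <- probeLog2FC(normalizeCounts(scaled), "KD")
  expect_equal(ch2$log2fc, ch1$log2fc, tolerance = 0.02)
  expect_equal(clRatioClass(ch2)$percentages, clRatioClass(ch1)$percentages)
})

test_that("noise-free limit returns exact means", {
  p <- simParams(nb_dispersion = 0, n_probe_genes = 4L, seed = 109L)
  cc <- simulateCounts(p)
  cnt <- SummarizedExperiment::assay(cc$counts, "counts")
  # replicates identical within condition
  expect_equal(cnt[, 1], cnt[, 2])
  expect_equal(cnt[, 1], cnt[, 3])
})

test_that("crosstab margins, association and failure modes", {
  fx <- pausingCohortFixture()
  pw <- intronExonPausing(fx$genes, fx$track_wt, normalize = "none")
  pk <- intronExonPausing(fx$genes, fx$track_kd, normalize = "none")
  dp <- deltaPausing(pw, pk)
  cl_genes <- data.frame(
    gene_id = sprintf("hg%03d", 1:26),
    class = rep(c("increased", "decreased", "no_change"), c(5, 13, 8)),
    stringsAsFactors = FALSE)
  xt <- pausingCrosstab(cl_genes, dp)
  expect_equal(sum(xt$exon$table), 26)
  expect_equal(sum(xt$intron$table), 26)
  expect_equal(unname(rowSums(xt$exon$table)), c(5, 13, 8))
  expect_true(all(abs(rowSums(xt$exon$row_pct) - 100) < 1e-9 |
                  rowSums(xt$exon$table) == 0))
  # perfectly concordant labels associate strongly
  conc <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     class = rep(c("increased", "decreased"), each = 20))
  pconc <- data.frame(host_gene = conc$gene_id, region = "exon",
                      class = conc$class)
  pconc <- rbind(pconc, transform(pconc, region = "intron"))
  xt2 <- pausingCrosstab(conc, pconc)
  expect_lt(xt2$exon$fisher_p, 1e-6)
  # empty intersection errors
  expect_error(pausingCrosstab(conc, dp), "shared")
})

test_that("independent labels give uniform Fisher p-values under the null", {
  set.seed(113)
  ps <- replicate(200, {
    g <- sprintf("g%03d", 1:60)
    cl <- data.frame(gene_id = g,
                     class = sample(c("increased", "decreased"), 60, TRUE))
    pa <- data.frame(host_gene = g, region = "exon",
                     class = sample(c("increased", "decreased"), 60, TRUE))
    pa <- rbind(pa, transform(pa, region = "intron"))
    pausingCrosstab(cl, pa)$exon$fisher_p
  })
  # Fisher's exact test is conservative: at most the nominal rate rejects,
  # and the null p-value mass is not piled near zero
  expect_lte(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps > 0.2), 0.5)
})
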
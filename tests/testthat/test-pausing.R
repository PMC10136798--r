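test_that("region schema labels the circRNA anatomy", {
  gm <- toyCohort(1)
  ex <- exonRanges(gm)[[1]]
  # circ = exons 2..4 of a 5-exon gene
  cc <- classifyJunctions(junction(GenomicRanges::start(ex)[2],
                                   GenomicRanges::end(ex)[4]), gm)
  sc <- defineRegions(cc[1], gm)
  labs <- S4Vectors::mcols(sc)$label
  expect_setequal(setdiff(labs, labs[grepl("_(up|dn)$", labs)]),
                  c("E1", "A", "I", "D", "dsE"))
  expect_equal(GenomicRanges::start(sc[labs == "E1"]),
               GenomicRanges::start(ex)[1])
  expect_equal(GenomicRanges::start(sc[labs == "A"]),
               GenomicRanges::start(ex)[2])
  expect_equal(GenomicRanges::start(sc[labs == "I"]),
               GenomicRanges::start(ex)[3])
  expect_equal(GenomicRanges::start(sc[labs == "dsE"]),
               GenomicRanges::start(ex)[5])
  # labels never overlap
  expect_true(IRanges::isDisjoint(GenomicRanges::ranges(sc)))

  # single-exon circ: acceptor and donor coincide, no internal exons
  cc1 <- classifyJunctions(junction(GenomicRanges::start(ex)[2],
                                    GenomicRanges::end(ex)[2]), gm)
  sc1 <- defineRegions(cc1[1], gm)
  expect_true("AD" %in% S4Vectors::mcols(sc1)$label)
  expect_false(any(c("A", "I", "D") %in% S4Vectors::mcols(sc1)$label))

  # terminal donor: dsE omitted and flagged
  cc2 <- classifyJunctions(junction(GenomicRanges::start(ex)[2],
                                    GenomicRanges::end(ex)[5]), gm)
  sc2 <- defineRegions(cc2[1], gm)
  expect_true("dsE" %in% attr(sc2, "omitted"))

  # intronic circRNA is an error
  intr <- intronRanges(gm)[[1]]
  cci <- classifyJunctions(junction(GenomicRanges::start(intr)[1] + 5L,
                                    GenomicRanges::end(intr)[1] - 5L), gm)
  expect_error(defineRegions(cci[1], gm), "exonic")
})

test_that("minus-strand schema mirrors the plus-strand labels", {
  gm_p <- toyCohort(1)
  gm_m <- GeneModelSet(GenomicRanges::GRangesList(
    tg001 = `strand<-`(exonRanges(gm_p)[[1]], value = "-")))
  ex <- exonRanges(gm_p)[[1]]
  cc_p <- classifyJunctions(junction(GenomicRanges::start(ex)[2],
                                     GenomicRanges::end(ex)[4]), gm_p)
  cc_m <- classifyJunctions(junction(GenomicRanges::start(ex)[2],
                                     GenomicRanges::end(ex)[4], strand = "-"),
                            gm_m)
  sc_p <- defineRegions(cc_p[1], gm_p)
  sc_m <- defineRegions(cc_m[1], gm_m)
  # E1 flips to the genomically last exon; A and D swap genomic positions
  lab_p <- S4Vectors::mcols(sc_p)$label
  lab_m <- S4Vectors::mcols(sc_m)$label
  expect_setequal(lab_p, lab_m)
  expect_equal(GenomicRanges::start(sc_m[lab_m == "E1"]),
               GenomicRanges::start(ex)[5])
  expect_equal(GenomicRanges::start(sc_m[lab_m == "A"]),
               GenomicRanges::start(ex)[4])
  expect_equal(GenomicRanges::start(sc_m[lab_m == "D"]),
               GenomicRanges::start(ex)[2])
  # widths per label agree between the mirrored layouts
  wp <- tapply(GenomicRanges::width(sc_p), lab_p, sum)
  wm <- tapply(GenomicRanges::width(sc_m), lab_m, sum)
  expect_equal(wp[sort(names(wp))], wm[sort(names(wm))])
})

test_that("pausing index is region mean over body mean", {
  gm <- toyCohort(1)
  sp <- geneRanges(gm)
  tr <- uniformTrack(sp, depth = 10)
  ex <- exonRanges(gm)[[1]]
  expect_equal(pausingIndex(tr, ex, sp), 1)
  # region at 30/bp over body at 10/bp -> 3 (uniform body elsewhere)
  len <- GenomicRanges::end(sp) + 100L
  v <- numeric(len)
  v[GenomicRanges::start(sp):GenomicRanges::end(sp)] <- 10
  idx2 <- GenomicRanges::start(ex)[2]:GenomicRanges::end(ex)[2]
  v[idx2] <- 30
  lp <- list(chrT = S4Vectors::Rle(v))
  tr2 <- CoverageTrack(plus = methods::as(lp, "RleList"))
  body_mean <- mean(v[GenomicRanges::start(sp):GenomicRanges::end(sp)])
  expect_equal(pausingIndex(tr2, ex[2], sp), 30 / body_mean)
  # zero body coverage -> NA with a warning
  expect_warning(res <- pausingIndex(uniformTrack(sp, depth = 0), ex, sp),
                 "zero coverage")
  expect_true(is.na(res))
})

test_that("scaling a track leaves every pausing index unchanged", {
  p <- simParams(n_host_genes = 8L, n_background_genes = 4L, seed = 71L)
  sim <- simulateGenome(p, emit_sequence = FALSE)
  cov <- simulateCoverage(sim, p)
  cc <- classifyJunctions(sim$junctions, sim$genes)
  prof <- pausingProfile(cc, sim$genes, cov$WT, collapse_flanks = TRUE)
  scaled <- CoverageTrack(plus = cov$WT@plus * 7L, minus = cov$WT@minus * 7L)
  prof2 <- pausingProfile(cc, sim$genes, scaled, collapse_flanks = TRUE)
  expect_equal(prof2$index, prof$index)
})

test_that("planted pause multipliers are recovered from simulated coverage", {
  mult <- list(WT = c(E1 = 1, A = 3, AD = 3, I = 1, D = 1, dsE = 1,
                      flank = 1, body = 1))
  p <- simParams(n_host_genes = 250L, n_background_genes = 2L,
                 intronic_circ_fraction = 0, pause_multipliers = mult,
                 coverage_depth = 10, gene_rate_sdlog = 0, seed = 73L)
  sim <- simulateGenome(p, emit_sequence = FALSE)
  cov <- simulateCoverage(sim, p)
  cc <- classifyJunctions(sim$junctions, sim$genes)
  keep <- which(S4Vectors::mcols(cc)$circ_class == "exonic_multi")
  idx <- vapply(keep, function(i) {
    sc <- defineRegions(cc[i], sim$genes)
    labs <- S4Vectors::mcols(sc)$label
    if (!"A" %in% labs) return(NA_real_)
    gid <- S4Vectors::mcols(cc[i])$host_gene
    body <- BiocGenerics::setdiff(geneRanges(sim$genes)[gid],
                                  GenomicRanges::granges(sc),
                                  ignore.strand = TRUE)
    GenomicRanges::strand(body) <- as.character(GenomicRanges::strand(cc[i]))
    pausingIndex(cov$WT, sc[labs == "A"], body)
  }, 0)
  idx <- idx[!is.na(idx)]
  expect_gt(length(idx), 100)
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - 3), 2 * se + 0.05)
})

test_that("metaprofile summarizes and detects cohort differences", {
  fx <- pausingCohortFixture()
  cc <- classifyJunctions(
    do.call(c, lapply(1:26, function(i) {
      ex <- exonRanges(fx$genes)[[i]]
      junction(GenomicRanges::start(ex)[2], GenomicRanges::end(ex)[3],
               chrom = "chrS")
    })), fx$genes)
  prof_wt <- pausingProfile(cc, fx$genes, fx$track_wt, collapse_flanks = TRUE)
  meta <- metaprofile(prof_wt)
  # identical genes, noise-free track -> SEM 0 everywhere
  expect_true(all(meta$sem < 1e-12))
  expect_error(metaprofile(prof_wt[0, ]), "empty")
  prof_kd <- pausingProfile(cc, fx$genes, fx$track_kd, collapse_flanks = TRUE)
  cmpp <- compareProfiles(prof_wt, prof_kd)
  # circ = exons 2..3 of a 4-exon gene: no internal exons, so the schema
  # carries E1 / A / D / dsE
  expect_true(all(c("E1", "A", "D", "dsE") %in% cmpp$region))
  # mean equals brute-force recomputation
  for (r in meta$region)
    expect_equal(meta$mean[meta$region == r],
                 mean(prof_wt$index[prof_wt$region == r]))
})

test_that("delta pausing classifies exon/intron density changes", {
  fx <- pausingCohortFixture()
  pw <- intronExonPausing(fx$genes, fx$track_wt, normalize = "none")
  pk <- intronExonPausing(fx$genes, fx$track_kd, normalize = "none")
  dp <- deltaPausing(pw, pk)
  expect_equal(nrow(dp), 52L)  # 26 genes x {exon, intron}
  gene_i <- as.integer(sub("hg", "", dp$host_gene))
  want <- ifelse(dp$region == "exon",
                 c("increased", "decreased", "no_change")[
                   findInterval(gene_i, c(1, 16, 19))],
                 c("increased", "decreased", "no_change")[
                   findInterval(gene_i, c(1, 15, 24))])
  expect_equal(dp$class, want)
  # identical tracks -> all zero deltas, no_change
  dp0 <- deltaPausing(pw, pw)
  expect_true(all(dp0$log2_ratio == 0))
  expect_true(all(dp0$class == "no_change"))
})

test_that("pooled exon and intron indices behave at the limits", {
  gm <- toyCohort(2)
  sp <- geneRanges(gm)
  tr <- uniformTrack(sp, depth = 5)
  pe <- intronExonPausing(gm, tr)
  expect_true(all(abs(pe$index - 1) < 1e-12))
  # exon-only coverage -> intron index 0
  exv <- unlist(GenomicRanges::reduce(exonRanges(gm)))
  tr_ex <- uniformTrack(exv, depth = 5,
                        chrom_len = max(GenomicRanges::end(sp)) + 10L)
  pe2 <- intronExonPausing(gm, tr_ex)
  expect_true(all(pe2$index[pe2$region == "intron"] == 0))
  # intronless gene: intron index NA
  gm1 <- toyGene(c(1, 400))
  tr1 <- uniformTrack(geneRanges(gm1), depth = 3)
  pe3 <- intronExonPausing(gm1, tr1)
  expect_true(is.na(pe3$index[pe3$region == "intron"]))
  expect_equal(pe3$index[pe3$region == "exon"], 1)
})
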
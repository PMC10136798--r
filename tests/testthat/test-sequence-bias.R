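test_that("canonical quadruplexes are found on both strands", {
  m <- scanG4(c(s1 = "GGGAGGGTGGGCGGG"))
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 15L)
  expect_equal(as.character(GenomicRanges::strand(m)), "+")
  expect_equal(S4Vectors::mcols(m)$n_runs, 4L)

  m <- scanG4(c(s1 = "CCCACCCTCCCACCC"))
  expect_equal(length(m), 1L)
  expect_equal(as.character(GenomicRanges::strand(m)), "-")
  expect_equal(length(scanG4(c(s1 = "CCCACCCTCCCACCC"), both_strands = FALSE)),
               0L)

  # N breaks a run: the GGNG prefix cannot seed the motif, which starts
  # at the first clean GGG run instead
  m <- scanG4(c(s1 = "GGNGAGGGTGGGCGGGAGGG"))
  expect_equal(GenomicRanges::start(m), 6L)
  expect_equal(GenomicRanges::end(m), 20L)
  # loops longer than l break the chain
  expect_equal(length(scanG4(c(s1 = "GGGAAAAAAAAGGGTGGGCGGG"))), 0L)
  expect_error(scanG4(c(s1 = "GGG"), r = 1), "r >= 2")
})

test_that("run-chaining scanner agrees with the regex oracle", {
  set.seed(37)
  for (i in 1:200) {
    # G/C-rich alphabet so motifs actually occur, plus occasional Ns
    s <- randomSeq(2000, alphabet = c("A", "C", "G", "T", "G", "C", "N"))
    got <- scanG4(c(x = s))
    want <- g4RegexOracle(s)
    expect_equal(length(got), nrow(want))
    if (nrow(want)) {
      ord <- order(GenomicRanges::start(got), as.character(GenomicRanges::strand(got)))
      expect_equal(GenomicRanges::start(got)[ord], want$start)
      expect_equal(GenomicRanges::end(got)[ord], want$end)
      expect_equal(as.character(GenomicRanges::strand(got))[ord], want$strand)
    }
  }
})

test_that("strand duality: motifs mirror under reverse complement", {
  set.seed(41)
  s <- randomSeq(3000, alphabet = c("A", "C", "G", "T", "G", "C"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scanG4(c(x = s))
  rev <- scanG4(c(x = rc))
  L <- nchar(s)
  mirr_start <- sort(L - GenomicRanges::end(rev) + 1L)
  expect_equal(sort(GenomicRanges::start(fwd)), mirr_start)
  flip <- c("+" = "-", "-" = "+")
  expect_equal(table(as.character(GenomicRanges::strand(fwd)))[c("+", "-")],
               table(flip[as.character(GenomicRanges::strand(rev))])[c("+", "-")])
})

test_that("G4 density is count per kilobase of region", {
  regions <- GenomicRanges::GRanges("x", IRanges::IRanges(1, 10000))
  motifs <- GenomicRanges::GRanges("x", IRanges::IRanges(c(1, 2001, 4001, 6001, 8001),
                                                          width = 20), "+")
  expect_equal(g4Density(motifs, regions), 0.5)
  expect_equal(g4Density(motifs[0], regions), 0)
  expect_error(g4Density(motifs, regions[0]), "zero-length")
})

test_that("planted G4 motifs are re-detected at recorded coordinates", {
  p <- simParams(n_host_genes = 12L, n_background_genes = 10L,
                 g4_density_per_kb = 1, seed = 43L)
  sim <- plantSequenceFeatures(simulateGenome(p), p)
  tr <- sim$truth$g4
  expect_gt(nrow(tr), 10)
  found <- scanG4(sim$sequences)
  key <- paste(GenomicRanges::seqnames(found), GenomicRanges::start(found),
               GenomicRanges::end(found), GenomicRanges::strand(found))
  expect_true(all(paste(tr$chrom, tr$start, tr$end, tr$strand) %in% key))
  # planted density is recovered within Poisson-scale error
  flanks <- circArch:::.truthFlankIntrons(sim)
  dens <- g4Density(found, flanks)
  expect_equal(dens, 1, tolerance = 0.3)
  # zero density leaves the sequence untouched
  p0 <- simParams(n_host_genes = 5L, n_background_genes = 5L,
                  g4_density_per_kb = 0,
                  repeat_flank_densities = c(Satellite = 0),
                  repeat_background_densities = c(Satellite = 0), seed = 47L)
  sim0 <- simulateGenome(p0)
  planted0 <- plantSequenceFeatures(sim0, p0)
  expect_equal(as.character(planted0$sequences), as.character(sim0$sequences))
})

test_that("windowed composition matches a brute-force tally", {
  comp <- baseComposition(c(w = "GGCC"), window = 4)
  expect_equal(comp$GC, 1)
  expect_equal(baseComposition(c(w = "ATAT"), window = 4)$GC, 0)
  nn <- baseComposition(c(w = "NNNN"), window = 4)
  expect_true(nn$undefined)
  expect_true(is.na(nn$GC))

  set.seed(53)
  s <- randomSeq(1234, alphabet = c("A", "C", "G", "T", "N"))
  comp <- baseComposition(c(x = s), window = 500)
  expect_equal(nrow(comp), 3L)
  expect_true(comp$clipped[3])
  for (i in seq_len(nrow(comp))) {
    chars <- strsplit(substr(s, comp$start[i], comp$end[i]), "")[[1]]
    used <- sum(chars != "N")
    expect_equal(comp$A[i], sum(chars == "A") / used)
    expect_equal(comp$G[i], sum(chars == "G") / used)
    expect_equal(comp$GC[i], sum(chars %in% c("G", "C")) / used)
    expect_equal(comp$A[i] + comp$C[i] + comp$G[i] + comp$T[i], 1,
                 tolerance = 1e-9)
  }
})

test_that("repeat enrichment folds and overlaps match brute force", {
  set.seed(59)
  target <- GenomicRanges::GRanges("x", IRanges::IRanges(c(1, 5001), width = 2000))
  background <- GenomicRanges::GRanges("x", IRanges::IRanges(c(20001, 30001),
                                                             width = 4000))
  reps <- GenomicRanges::GRanges("x",
    IRanges::IRanges(c(100, 900, 5200, 20500, 30100), width = c(200, 100, 300, 200, 200)),
    name = c("LINE", "LINE", "Satellite", "LINE", "Satellite"))
  enr <- repeatEnrichment(target, background, reps, B = 50, seed = 1)
  # brute-force per-base overlap oracle
  bruteFrac <- function(ivs, feats) {
    pos <- unlist(lapply(seq_along(ivs), function(i)
      GenomicRanges::start(ivs)[i]:GenomicRanges::end(ivs)[i]))
    fpos <- unique(unlist(lapply(seq_along(feats), function(i)
      GenomicRanges::start(feats)[i]:GenomicRanges::end(feats)[i])))
    sum(pos %in% fpos) / length(pos)
  }
  for (cl in enr$class) {
    f <- reps[S4Vectors::mcols(reps)$name == cl]
    expect_equal(enr$target_fraction[enr$class == cl], bruteFrac(target, f))
    expect_equal(enr$background_fraction[enr$class == cl], bruteFrac(background, f))
  }
  # a set against itself gives fold 1 everywhere
  self <- repeatEnrichment(background, background, reps, B = 0)
  expect_true(all(abs(self$fold[self$fold_defined] - 1) < 1e-12))
  # class absent from background is flagged, not infinite
  reps2 <- c(reps, GenomicRanges::GRanges("x", IRanges::IRanges(300, 350),
                                          name = "LTR"))
  enr2 <- repeatEnrichment(target, background, reps2, B = 0)
  expect_false(enr2$fold_defined[enr2$class == "LTR"])
  expect_true(is.na(enr2$fold[enr2$class == "LTR"]))
})

test_that("planted repeat excess in flanks is recovered as fold change", {
  p <- simParams(n_host_genes = 25L, n_background_genes = 40L,
                 repeat_flank_densities = c(Satellite = 0.09),
                 repeat_background_densities = c(Satellite = 0.03),
                 g4_density_per_kb = 0, seed = 61L)
  sim <- plantSequenceFeatures(simulateGenome(p), p)
  flanks <- circArch:::.truthFlankIntrons(sim)
  bg_ids <- sim$truth$genes$gene_id[sim$truth$genes$role == "background"]
  bg <- unlist(intronRanges(sim$genes)[bg_ids], use.names = FALSE)
  enr <- repeatEnrichment(flanks, bg, sim$repeats, B = 200, seed = 2)
  row <- enr[enr$class == "Satellite", ]
  expect_equal(row$fold, 3, tolerance = 0.05)
  expect_true(row$ci_lo <= row$fold && row$fold <= row$ci_hi)
})

test_that("motif enrichment flags planted symmetric motifs and controls nulls", {
  set.seed(67)
  mkseqs <- function(n, len, plant = NULL, times = 0) {
    vapply(seq_len(n), function(i) {
      s <- randomSeq(len)
      if (!is.null(plant) && times > 0)
        for (k in seq_len(times)) {
          at <- sample(len - nchar(plant), 1)
          substr(s, at, at + nchar(plant) - 1) <- plant
        }
      s
    }, "")
  }
  flank5 <- Biostrings::DNAStringSet(mkseqs(20, 1000, "ACTAAC", 6))
  flank3 <- Biostrings::DNAStringSet(mkseqs(20, 1000, "ACTAAC", 6))
  background <- Biostrings::DNAStringSet(mkseqs(40, 1000))
  motifs <- c(branch = "ACTAAC", ctrl1 = "GTCGAC", ctrl2 = "TTAGGC",
              absent = "ACGCGCGCGT")
  res <- motifEnrichment(motifs, flank5, flank3, background)
  expect_true(res$symmetric[res$motif == "branch"])
  expect_lt(res$q_5p[res$motif == "branch"], 0.05)
  expect_equal(res$p_5p[res$motif == "absent"], 1)
  expect_false(res$symmetric[res$motif == "absent"])

  # null simulation: symmetric calls are rare after BH correction
  null_motifs <- setNames(
    vapply(1:20, function(i) randomSeq(6), ""),
    paste0("m", 1:20))
  n_sym <- 0L
  for (i in 1:20) {
    f5 <- Biostrings::DNAStringSet(mkseqs(10, 800))
    f3 <- Biostrings::DNAStringSet(mkseqs(10, 800))
    bg <- Biostrings::DNAStringSet(mkseqs(20, 800))
    n_sym <- n_sym + sum(motifEnrichment(null_motifs, f5, f3, bg)$symmetric)
  }
  expect_lte(n_sym / (20 * 20), 0.02)
})
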
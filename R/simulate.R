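#' Simulation parameters for the synthetic study generator
#'
#' Defines the conditions the generator emulates: a miniature genome in
#' which circRNA host genes carry long, possibly asymmetric flanking
#' introns around the backspliced exons while background genes follow
#' typical Drosophila gene architecture (background introns averaging
#' 1832 bp, exons 292 bp); planted repeat elements and G-quadruplexes in
#' flanking introns; region-specific RNAPII pause multipliers with
#' Poisson sampling noise; and negative-binomial probe counts with
#' planted condition effects. All length laws are lognormal,
#' parameterized by their mean and a log-scale dispersion (intron
#' lengths are heavy-tailed). The seed fully determines every emitted
#' byte.
#'
#' @param n_host_genes,n_background_genes gene counts.
#' @param exons_per_gene integer range (min, max) of exons per gene;
#'   minimum 4 when host genes are requested so every exonic circRNA has
#'   two flanking introns.
#' @param background_intron_mean,background_exon_mean mean lengths (bp)
#'   for background gene features.
#' @param host_flank_up_mean,host_flank_down_mean mean lengths (bp) of
#'   the introns flanking the backsplice acceptor and donor exons
#'   (transcript orientation).
#' @param host_internal_intron_mean,circ_exon_mean mean lengths (bp) of
#'   circRNA-internal introns and of backspliced exons.
#' @param dispersion lognormal log-scale sd shared by all length laws.
#' @param intergenic_mean mean intergenic gap (bp).
#' @param minus_strand_fraction probability a gene lies on the minus
#'   strand.
#' @param intronic_circ_fraction fraction of host genes whose planted
#'   junction is intronic (ciRNA) rather than exonic.
#' @param repeat_flank_densities,repeat_background_densities named
#'   numeric, expected bp fraction per repeat class in flanking introns
#'   of exonic hosts and in background-gene introns.
#' @param g4_density_per_kb planted G-quadruplex motifs per kb of
#'   flanking intron.
#' @param pause_multipliers named list (one element per coverage
#'   condition) of named numeric fold multipliers over the labels
#'   `E1, A, AD, I, D, dsE, flank, body`.
#' @param coverage_depth mean nascent-RNA reads per base in gene bodies.
#' @param gene_rate_sdlog lognormal sd of the per-gene expression rate
#'   (mean 1; shared across coverage conditions).
#' @param nb_mean,nb_dispersion negative-binomial probe-count baseline
#'   mean and dispersion (`dispersion = 0` gives exact means, the
#'   noise-free limit).
#' @param n_replicates probe-count replicates per condition.
#' @param n_probe_genes number of host genes on the probe panel.
#' @param n_housekeeping housekeeping probes (zero planted effect);
#'   at least 3.
#' @param conditions condition labels; `reference` must be among them.
#' @param reference reference condition for fold changes.
#' @param condition_logfc data.frame (`gene_id`, `probe_type`,
#'   `condition`, `lfc`) of planted probe log2 effects, or NULL.
#' @param n_chromosomes chromosomes to spread genes over (default 1).
#' @param gene_length_budget upper bound on a single expected gene
#'   length; exceeding it is a configuration error.
#' @param seed integer seed.
#' @return validated parameter list of class `simParams`.
#' @export
simParams <- function(n_host_genes = 30L,
                      n_background_genes = 120L,
                      exons_per_gene = c(4L, 9L),
                      background_intron_mean = 1832,
                      background_exon_mean = 292,
                      host_flank_up_mean = 9131,
                      host_flank_down_mean = 9355,
                      host_internal_intron_mean = 3683,
                      circ_exon_mean = 372,
                      dispersion = 0.5,
                      intergenic_mean = 2000,
                      minus_strand_fraction = 0.5,
                      intronic_circ_fraction = 0.25,
                      repeat_flank_densities = c(Satellite = 0.06, LINE = 0.05,
                                                 LTR = 0.04, Simple_repeat = 0.01,
                                                 Low_complexity = 0.01),
                      repeat_background_densities = c(Satellite = 0.02, LINE = 0.02,
                                                      LTR = 0.015, Simple_repeat = 0.03,
                                                      Low_complexity = 0.03),
                      g4_density_per_kb = 0.5,
                      pause_multipliers = list(
                        WT = c(E1 = 3, A = 2.5, AD = 2.5, I = 1.5, D = 1.5,
                               dsE = 1, flank = 1, body = 1),
                        KD = c(E1 = 1.2, A = 1.2, AD = 1.2, I = 1.5, D = 1.2,
                               dsE = 2.5, flank = 1, body = 1)),
                      coverage_depth = 10,
                      gene_rate_sdlog = 0.3,
                      nb_mean = 500,
                      nb_dispersion = 0.05,
                      n_replicates = 3L,
                      n_probe_genes = 26L,
                      n_housekeeping = 4L,
                      conditions = c("WT", "PARPi", "KD"),
                      reference = "WT",
                      condition_logfc = NULL,
                      n_chromosomes = 1L,
                      gene_length_budget = 5e5,
                      seed = 1L) {
  p <- as.list(environment())
  means <- c(p$background_intron_mean, p$background_exon_mean,
             p$host_flank_up_mean, p$host_flank_down_mean,
             p$host_internal_intron_mean, p$circ_exon_mean, p$intergenic_mean,
             p$nb_mean)
  if (any(means <= 0)) stop("configuration error: all mean lengths must be > 0")
  if (p$dispersion <= 0) stop("configuration error: dispersion must be > 0")
  if (length(p$exons_per_gene) != 2 || p$exons_per_gene[1] > p$exons_per_gene[2])
    stop("configuration error: exons_per_gene must be an increasing range")
  if (p$n_host_genes > 0 && p$exons_per_gene[1] < 4)
    stop("configuration error: host genes need at least 4 exons")
  fr <- c(p$minus_strand_fraction, p$intronic_circ_fraction,
          p$repeat_flank_densities, p$repeat_background_densities)
  if (any(fr < 0 | fr > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (sum(p$repeat_flank_densities) > 0.5 || sum(p$repeat_background_densities) > 0.5)
    stop("configuration error: repeat densities too high to place without overlap")
  if (p$g4_density_per_kb < 0 || p$g4_density_per_kb > 15)
    stop("configuration error: G4 density out of range")
  if (p$coverage_depth < 0)
    stop("configuration error: coverage depth must be >= 0")
  if (p$nb_dispersion < 0)
    stop("configuration error: nb_dispersion must be >= 0")
  if (!p$reference %in% p$conditions)
    stop("configuration error: missing reference condition")
  if (p$n_housekeeping < 3)
    stop("configuration error: need >= 3 housekeeping probes")
  exp_host_len <- p$host_flank_up_mean + p$host_flank_down_mean +
    p$exons_per_gene[2] * max(p$background_exon_mean, p$circ_exon_mean) +
    p$exons_per_gene[2] * max(p$background_intron_mean, p$host_internal_intron_mean)
  if (exp_host_len >= p$gene_length_budget)
    stop("configuration error: expected gene length exceeds gene budget")
  mult_labels <- c("E1", "A", "AD", "I", "D", "dsE", "flank", "body")
  for (cond in names(p$pause_multipliers)) {
    miss <- setdiff(mult_labels, names(p$pause_multipliers[[cond]]))
    if (length(miss))
      stop("configuration error: pause multipliers missing label(s) ",
           paste(miss, collapse = ", "), " for ", cond)
    if (any(p$pause_multipliers[[cond]] < 0))
      stop("configuration error: pause multipliers must be >= 0")
  }
  p$seed <- as.integer(p$seed)
  class(p) <- "simParams"
  p
}

# lognormal lengths with the configured arithmetic mean
.rlen <- function(n, mean, sdlog, minlen) {
  if (n == 0) return(integer(0))
  pmax(as.integer(round(stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog))),
       as.integer(minlen))
}

#' Simulate the miniature genome and annotation
#'
#' Lays host and background genes along `n_chromosomes` synthetic
#' chromosomes (random order, ~half on the minus strand), draws all
#' feature lengths from the configured lognormal laws, plants one
#' backsplice junction per host gene (exonic, or intronic for a
#' configured fraction), and records every planted parameter in the
#' ground-truth sidecar.
#'
#' @param params a [simParams()] object.
#' @param emit_sequence generate the random genome sequence (disable for
#'   annotation-only studies; [plantSequenceFeatures()] requires it).
#' @return list with `genes` ([GeneModelSet-class]), `sequences`
#'   (`DNAStringSet` or NULL), `junctions` (`GRanges` with `condition`),
#'   `truth` (ground-truth list), `params`.
#' @export
simulateGenome <- function(params, emit_sequence = TRUE) {
  stopifnot(inherits(params, "simParams"))
  set.seed(params$seed)
  nH <- params$n_host_genes; nB <- params$n_background_genes
  n <- nH + nB
  if (n == 0) stop("configuration error: no genes requested")
  ids <- c(if (nH) sprintf("hg%03d", seq_len(nH)),
           if (nB) sprintf("bg%03d", seq_len(nB)))
  role <- c(rep("host", nH), rep("background", nB))
  ord <- sample(n)                       # placement order along chromosomes
  s <- params$dispersion
  chroms <- sprintf("chrS%d", seq_len(params$n_chromosomes))
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)

  exl <- vector("list", n); names(exl) <- ids
  gchrom <- gstrand <- rep(NA_character_, n)
  truth_rows <- vector("list", n)
  jlist <- list()
  for (pos in seq_len(n)) {
    i <- ord[pos]
    gid <- ids[i]
    chrom <- chroms[(pos - 1L) %% length(chroms) + 1L]
    strd <- if (stats::runif(1) < params$minus_strand_fraction) "-" else "+"
    nex <- sample(seq(params$exons_per_gene[1], params$exons_per_gene[2]), 1L)

    exon_len <- .rlen(nex, params$background_exon_mean, s, 50L)
    intron_len <- .rlen(nex - 1L, params$background_intron_mean, s, 60L)
    circ_class <- NA_character_; cond <- NA_character_
    a <- d <- NA_integer_; flank_up <- flank_dn <- NA_integer_
    intronic_intron <- NA_integer_

    if (role[i] == "host") {
      cond <- params$conditions[(i - 1L) %% length(params$conditions) + 1L]
      if (stats::runif(1) < params$intronic_circ_fraction) {
        circ_class <- "intronic"
        intronic_intron <- sample(nex - 1L, 1L)
      } else {
        a <- sample(2:(nex - 1L), 1L)
        ncirc <- sample(seq_len(min(3L, nex - a)), 1L)
        d <- a + ncirc - 1L
        circ_class <- if (a == d) "exonic_single" else "exonic_multi"
        exon_len[a:d] <- .rlen(ncirc, params$circ_exon_mean, s, 50L)
        flank_up <- .rlen(1L, params$host_flank_up_mean, s, 60L)
        flank_dn <- .rlen(1L, params$host_flank_down_mean, s, 60L)
        intron_len[a - 1L] <- flank_up
        intron_len[d] <- flank_dn
        if (d > a) intron_len[a:(d - 1L)] <-
          .rlen(d - a, params$host_internal_intron_mean, s, 60L)
      }
    }

    # transcript-orientation lengths -> genomic order
    exon_g <- if (strd == "+") exon_len else rev(exon_len)
    intron_g <- if (strd == "+") intron_len else rev(intron_len)
    gap <- .rlen(1L, params$intergenic_mean, s, 200L)
    gstart <- cursor[[chrom]] + gap + 1L
    starts <- integer(nex); ends <- integer(nex)
    at <- gstart
    for (e in seq_len(nex)) {
      starts[e] <- at; ends[e] <- at + exon_g[e] - 1L
      at <- ends[e] + (if (e < nex) intron_g[e] else 0L) + 1L
    }
    cursor[[chrom]] <- ends[nex]
    exl[[gid]] <- GRanges(chrom, IRanges(starts, ends), strand = strd)
    gchrom[i] <- chrom; gstrand[i] <- strd

    js <- je <- NA_integer_
    if (role[i] == "host") {
      if (circ_class == "intronic") {
        k <- intronic_intron          # genomic intron index
        gk <- if (strd == "+") k else nex - k
        js <- ends[gk] + 2L; je <- starts[gk + 1L] - 2L
      } else {
        ga <- if (strd == "+") a else nex - a + 1L
        gd <- if (strd == "+") d else nex - d + 1L
        js <- min(starts[ga], starts[gd]); je <- max(ends[ga], ends[gd])
      }
      jr <- GRanges(chrom, IRanges(js, je), strand = strd)
      mcols(jr)$condition <- cond
      mcols(jr)$n_reads <- stats::rpois(1L, 10) + 2L
      mcols(jr)$gene <- gid
      jlist[[length(jlist) + 1L]] <- jr
    }
    truth_rows[[i]] <- data.frame(
      gene_id = gid, role = role[i], chrom = chrom, strand = strd,
      n_exons = nex, circ_class = circ_class, condition = cond,
      acceptor_exon = a, donor_exon = d,
      flank_up_length = flank_up, flank_down_length = flank_dn,
      junction_start = js, junction_end = je, stringsAsFactors = FALSE)
  }

  genes <- GeneModelSet(GenomicRanges::GRangesList(exl))
  junctions <- if (length(jlist)) do.call(c, jlist) else GRanges()
  chrom_len <- cursor + 500L
  sequences <- NULL
  if (emit_sequence) {
    sequences <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), chrom_len[[ch]], replace = TRUE),
            collapse = ""), ""))
    names(sequences) <- chroms
  }
  truth <- list(
    genes = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
    chrom_lengths = as.list(chrom_len),
    params = list(seed = params$seed,
                  background_intron_mean = params$background_intron_mean,
                  background_exon_mean = params$background_exon_mean,
                  host_flank_up_mean = params$host_flank_up_mean,
                  host_flank_down_mean = params$host_flank_down_mean,
                  circ_exon_mean = params$circ_exon_mean,
                  dispersion = params$dispersion))
  list(genes = genes, sequences = sequences, junctions = junctions,
       truth = truth, params = params)
}

# flanking introns (genomic coords) of all exonic host circRNAs, from truth
.truthFlankIntrons <- function(sim) {
  tg <- sim$truth$genes
  inl <- intronRanges(sim$genes)
  out <- list()
  for (i in which(tg$circ_class %in% c("exonic_single", "exonic_multi"))) {
    nex <- tg$n_exons[i]; a <- tg$acceptor_exon[i]; d <- tg$donor_exon[i]
    plus <- tg$strand[i] == "+"
    gi_up <- if (plus) a - 1L else nex - a + 1L
    gi_dn <- if (plus) d else nex - d
    ins <- inl[[tg$gene_id[i]]]
    for (side in c("upstream", "downstream")) {
      gi <- if (side == "upstream") gi_up else gi_dn
      r <- ins[gi]
      mcols(r)$gene <- tg$gene_id[i]; mcols(r)$side <- side
      out[[length(out) + 1L]] <- r
    }
  }
  if (length(out)) do.call(c, out) else GRanges()
}

#' Plant G-quadruplex motifs and repeat intervals into flanking introns
#'
#' Writes canonical G-quadruplex motifs (4 runs of GGG, loops of 1-7
#' non-G bases; the complemented C-pattern for minus-strand genes) into
#' the flanking introns of exonic host circRNAs at the configured
#' density, surrounded by short non-run buffers so every planted motif
#' is re-detectable at exactly its recorded coordinates. Repeat-class
#' intervals are placed (annotation only, non-overlapping within an
#' intron) into flanking introns and background-gene introns at their
#' configured bp fractions. No planted feature crosses an exon boundary.
#'
#' @param sim result of [simulateGenome()] with sequences.
#' @param params the same [simParams()] object.
#' @return `sim` with modified `sequences` and `truth` gaining `g4` and
#'   `repeats` tables, plus `repeats` as a `GRanges` (class in `name`).
#' @export
plantSequenceFeatures <- function(sim, params) {
  stopifnot(inherits(params, "simParams"))
  if (is.null(sim$sequences))
    stop("plantSequenceFeatures requires simulated sequences")
  set.seed(params$seed + 1L)
  seqs <- as.character(sim$sequences)
  flanks <- .truthFlankIntrons(sim)
  bg_ids <- sim$truth$genes$gene_id[sim$truth$genes$role == "background"]
  bg_introns <- unlist(intronRanges(sim$genes)[bg_ids], use.names = FALSE)

  rep_rows <- list(); g4_rows <- list()
  repl <- list()  # per chrom: list(at = IRanges, value = character)
  for (ch in names(seqs)) repl[[ch]] <- list(at = IRanges(), value = character(0))

  placeRepeats <- function(intr, densities, gene, side, occupied) {
    len <- width(intr); chrom <- as.character(seqnames(intr))
    for (cl in names(densities)) {
      # hit the target bp exactly (chunks of <= 300 bp) so measured
      # fractions are unbiased regardless of intron length
      target <- round(densities[[cl]] * len)
      if (target < 10L) next
      cuts <- round(seq(0L, target, length.out = ceiling(target / 300) + 1L))
      sizes <- diff(cuts); sizes <- sizes[sizes > 0L]
      for (el in sizes) {
        if (el > len) break
        placed_ok <- FALSE
        for (try in 1:400) {
          st <- sample(len - el + 1L, 1L)
          iv <- c(st, st + el - 1L)
          if (any(occupied$s <= iv[2] & occupied$e >= iv[1])) next
          occupied$s <- c(occupied$s, iv[1]); occupied$e <- c(occupied$e, iv[2])
          rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
            chrom = chrom, start = start(intr) + iv[1] - 1L,
            end = start(intr) + iv[2] - 1L, class = cl, gene = gene,
            side = side, stringsAsFactors = FALSE)
          placed_ok <- TRUE
          break
        }
        if (!placed_ok)
          stop("configuration error: repeat density too high to place ",
               "without overlap in ", gene)
      }
    }
    occupied
  }

  buildG4 <- function(minus) {
    run <- if (minus) "CCC" else "GGG"
    loop_alpha <- if (minus) c("A", "G", "T") else c("A", "C", "T")
    loops <- vapply(1:3, function(...) paste(
      sample(loop_alpha, sample(1:7, 1L), replace = TRUE), collapse = ""), "")
    paste0(run, loops[1], run, loops[2], run, loops[3], run)
  }

  for (k in seq_along(flanks)) {
    intr <- flanks[k]
    gene <- mcols(intr)$gene; side <- mcols(intr)$side
    len <- width(intr); chrom <- as.character(seqnames(intr))
    minus <- as.character(strand(intr)) == "-"
    occupied <- list(s = integer(0), e = integer(0))
    n_g4 <- round(params$g4_density_per_kb * len / 1000)
    buf <- 8L
    if (n_g4 > 0) {
      for (m in seq_len(n_g4)) {
        motif <- buildG4(minus)
        slot <- nchar(motif) + 2L * buf
        if (slot > len)
          stop("configuration error: G4 density too high for intron length")
        ok <- FALSE
        for (try in 1:400) {
          st <- sample(len - slot + 1L, 1L)
          if (!any(occupied$s <= st + slot - 1L & occupied$e >= st)) { ok <- TRUE; break }
        }
        if (!ok) stop("configuration error: G4 density too high to place ",
                      "without overlap in ", gene)
        occupied$s <- c(occupied$s, st); occupied$e <- c(occupied$e, st + slot - 1L)
        pad <- if (minus) "AGTAGTAG" else "ACTACTAC"
        insert <- paste0(pad, motif, pad)
        abs_start <- start(intr) + st - 1L
        repl[[chrom]]$at <- c(repl[[chrom]]$at,
                              IRanges(abs_start, abs_start + nchar(insert) - 1L))
        repl[[chrom]]$value <- c(repl[[chrom]]$value, insert)
        g4_rows[[length(g4_rows) + 1L]] <- data.frame(
          chrom = chrom, start = abs_start + buf,
          end = abs_start + buf + nchar(motif) - 1L,
          strand = if (minus) "-" else "+", gene = gene, side = side,
          stringsAsFactors = FALSE)
      }
    }
    occupied <- placeRepeats(intr, params$repeat_flank_densities, gene, side,
                             occupied)
  }
  for (k in seq_along(bg_introns)) {
    intr <- bg_introns[k]
    gene <- "background"
    placeRepeats(intr, params$repeat_background_densities, gene, "background",
                 list(s = integer(0), e = integer(0)))
  }

  newseqs <- lapply(names(seqs), function(ch) {
    if (length(repl[[ch]]$value))
      Biostrings::replaceAt(sim$sequences[[ch]], repl[[ch]]$at,
                            Biostrings::DNAStringSet(repl[[ch]]$value))
    else sim$sequences[[ch]]
  })
  sim$sequences <- Biostrings::DNAStringSet(newseqs)
  names(sim$sequences) <- names(seqs)
  g4 <- if (length(g4_rows))
    do.call(rbind, c(g4_rows, list(make.row.names = FALSE))) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), gene = character(0), side = character(0))
  reps <- if (length(rep_rows))
    do.call(rbind, c(rep_rows, list(make.row.names = FALSE))) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               class = character(0), gene = character(0), side = character(0))
  sim$truth$g4 <- g4
  sim$truth$repeats <- reps
  sim$repeats <- if (nrow(reps))
    GRanges(reps$chrom, IRanges(reps$start, reps$end), name = reps$class)
  else GRanges()
  sim
}

# CircRNASet of the planted exonic junctions, built from ground truth
.truthCircs <- function(sim) {
  tg <- sim$truth$genes
  keep <- which(!is.na(tg$circ_class))
  gr <- GRanges(tg$chrom[keep], IRanges(tg$junction_start[keep],
                                        tg$junction_end[keep]),
                strand = tg$strand[keep])
  mcols(gr)$condition <- tg$condition[keep]
  mcols(gr)$n_reads <- NA_integer_
  mcols(gr)$circ_class <- tg$circ_class[keep]
  mcols(gr)$host_gene <- tg$gene_id[keep]
  mcols(gr)$acceptor_exon <- tg$acceptor_exon[keep]
  mcols(gr)$donor_exon <- tg$donor_exon[keep]
  new("CircRNASet", gr)
}

#' Simulate strand-resolved nascent-RNA coverage
#'
#' Per-base counts are Poisson with rate `depth x gene_rate x region
#' multiplier`; the region labels come from the circRNA-anchored schema
#' of each host gene (E1 / A / I / D / dsE, `flank` for the 300 bp exon
#' flanks, `body` elsewhere), background genes are all `body`. Gene
#' rates are drawn once and shared across conditions; coverage is zero
#' outside genes and lands on the gene's strand.
#'
#' @param sim result of [simulateGenome()].
#' @param params a [simParams()] object; one coverage condition per
#'   element of `pause_multipliers`.
#' @param flank flank width for the region schema (default 300).
#' @return named list of [CoverageTrack-class], one per condition.
#' @export
simulateCoverage <- function(sim, params, flank = 300L) {
  stopifnot(inherits(params, "simParams"))
  if (params$coverage_depth < 0) stop("configuration error: negative depth")
  set.seed(params$seed + 2L)
  tg <- sim$truth$genes
  chrom_len <- vapply(sim$truth$chrom_lengths, as.integer, 1L)
  spans <- geneRanges(sim$genes)
  strd <- geneStrand(sim$genes)
  gene_rate <- stats::setNames(
    stats::rlnorm(nrow(tg), -params$gene_rate_sdlog^2 / 2,
                  params$gene_rate_sdlog), tg$gene_id)

  circs <- .truthCircs(sim)
  exonic <- mcols(circs)$circ_class %in% c("exonic_single", "exonic_multi")
  schemas <- lapply(which(exonic), function(i)
    defineRegions(circs[i], sim$genes, flank = flank))
  names(schemas) <- mcols(circs)$host_gene[exonic]

  # plain-vector gene geometry (S4 accessors are too slow inside the loop)
  g_start <- stats::setNames(start(spans), names(spans))
  g_end <- stats::setNames(end(spans), names(spans))
  g_chrom <- stats::setNames(as.character(seqnames(spans)), names(spans))
  schema_off <- lapply(schemas, function(sc) {
    labs <- mcols(sc)$label
    list(lo = start(sc), hi = end(sc),
         base = ifelse(grepl("_(up|dn)$", labs), "flank", labs))
  })

  out <- list()
  for (cond in names(params$pause_multipliers)) {
    mult <- params$pause_multipliers[[cond]]
    tracks <- list()
    for (side in c("plus", "minus")) {
      want <- if (side == "plus") "+" else "-"
      rles <- list()
      for (ch in names(chrom_len)) {
        v <- numeric(chrom_len[[ch]])
        for (i in which(tg$strand == want & tg$chrom == ch)) {
          gid <- tg$gene_id[i]
          gs <- g_start[[gid]]; ge <- g_end[[gid]]
          L <- ge - gs + 1L
          lam <- rep(params$coverage_depth * gene_rate[[gid]] * mult[["body"]], L)
          so <- schema_off[[gid]]
          if (!is.null(so)) {
            for (r in seq_along(so$base)) {
              lo <- max(so$lo[r], gs) - gs + 1L
              hi <- min(so$hi[r], ge) - gs + 1L
              if (lo <= hi)
                lam[lo:hi] <- params$coverage_depth * gene_rate[[gid]] *
                  mult[[so$base[r]]]
            }
          }
          v[gs:ge] <- v[gs:ge] + stats::rpois(L, lam)
        }
        rles[[ch]] <- S4Vectors::Rle(v)
      }
      tracks[[side]] <- methods::as(rles, "RleList")
    }
    out[[cond]] <- CoverageTrack(plus = tracks$plus, minus = tracks$minus)
  }
  out
}

#' Simulate the probe-count matrix
#'
#' One circular and one linear junction probe per panel gene plus
#' housekeeping probes; counts are negative binomial around a per-probe
#' lognormal baseline, multiplied by `2^lfc` for planted condition
#' effects. Housekeeping probes never carry effects. With
#' `nb_dispersion = 0` counts equal their means exactly.
#'
#' @param params a [simParams()] object.
#' @param gene_ids panel gene ids (default the first `n_probe_genes`
#'   host gene ids, `hg001`...).
#' @return list: `counts` ([ProbeCountMatrix-class]), `truth`
#'   (data.frame of planted per-probe log2 effects).
#' @export
simulateCounts <- function(params, gene_ids = NULL) {
  stopifnot(inherits(params, "simParams"))
  if (!params$reference %in% params$conditions)
    stop("configuration error: missing reference condition")
  set.seed(params$seed + 3L)
  if (is.null(gene_ids))
    gene_ids <- sprintf("hg%03d", seq_len(params$n_probe_genes))
  probes <- rbind(
    data.frame(gene_id = rep(gene_ids, each = 2),
               probe_type = rep(c("circ", "linear"), length(gene_ids)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("hk%02d", seq_len(params$n_housekeeping)),
               probe_type = "housekeeping", stringsAsFactors = FALSE))
  probes$probe_id <- paste(probes$gene_id, probes$probe_type, sep = "_")
  base <- params$nb_mean * stats::rlnorm(nrow(probes), -0.125, 0.5)

  lfc <- params$condition_logfc
  getLfc <- function(g, pt, cond) {
    if (is.null(lfc) || cond == params$reference) return(0)
    hit <- lfc$gene_id == g & lfc$probe_type == pt & lfc$condition == cond
    if (any(hit)) lfc$lfc[hit][1] else 0
  }
  cols <- expand.grid(replicate = seq_len(params$n_replicates),
                      condition = params$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cols <- cols[, c("condition", "replicate")]
  cnt <- matrix(0, nrow(probes), nrow(cols),
                dimnames = list(probes$probe_id,
                                paste(cols$condition, cols$replicate, sep = "_")))
  truth_rows <- list()
  for (j in seq_len(nrow(cols))) {
    for (i in seq_len(nrow(probes))) {
      e <- if (probes$probe_type[i] == "housekeeping") 0 else
        getLfc(probes$gene_id[i], probes$probe_type[i], cols$condition[j])
      mu <- base[i] * 2^e
      cnt[i, j] <- if (params$nb_dispersion == 0) round(mu) else
        stats::rnbinom(1L, mu = mu, size = 1 / params$nb_dispersion)
    }
  }
  for (i in seq_len(nrow(probes)))
    for (cond in setdiff(params$conditions, params$reference))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = probes$gene_id[i], probe_type = probes$probe_type[i],
        condition = cond,
        lfc = if (probes$probe_type[i] == "housekeeping") 0 else
          getLfc(probes$gene_id[i], probes$probe_type[i], cond),
        stringsAsFactors = FALSE)
  pcm <- ProbeCountMatrix(cnt, gene_id = probes$gene_id,
                          probe_type = probes$probe_type,
                          condition = cols$condition,
                          replicate = cols$replicate)
  list(counts = pcm,
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
}

#' Run the full generator and optionally write the bundle
#'
#' genome -> sequence features -> coverage -> probe counts, with a
#' merged ground-truth sidecar. When `dir` is given, writes
#' `genome.gtf`, `genome.fa`, `junctions.tsv`, `repeats.bed`,
#' `<condition>.plus/.minus.bedgraph`, `probe_counts.tsv` and
#' `ground_truth.json` (all plain text, byte-deterministic under a fixed
#' seed).
#'
#' @param params a [simParams()] object.
#' @param dir output directory, or NULL to skip writing.
#' @param emit_sequence,flank passed through.
#' @return list: `genes`, `sequences`, `junctions`, `repeats`,
#'   `coverage` (named list of tracks), `counts`, `truth`, `params`.
#' @export
simulateBundle <- function(params, dir = NULL, emit_sequence = TRUE,
                           flank = 300L) {
  sim <- simulateGenome(params, emit_sequence = emit_sequence)
  if (emit_sequence) sim <- plantSequenceFeatures(sim, params)
  sim$coverage <- simulateCoverage(sim, params, flank = flank)
  cc <- simulateCounts(params)
  sim$counts <- cc$counts
  sim$truth$probe_effects <- cc$truth
  sim$truth$pause_multipliers <- lapply(params$pause_multipliers, as.list)
  if (!is.null(dir)) writeSimulation(sim, dir)
  sim
}

#' @rdname simulateBundle
#' @param sim a bundle from [simulateBundle()].
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGtf(sim$genes, file.path(dir, "genome.gtf"))
  if (!is.null(sim$sequences))
    writeFasta(sim$sequences, file.path(dir, "genome.fa"))
  writeJunctions(sim$junctions, file.path(dir, "junctions.tsv"))
  if (!is.null(sim$repeats))
    writeBed(sim$repeats, file.path(dir, "repeats.bed"))
  for (cond in names(sim$coverage))
    writeBedGraphPair(sim$coverage[[cond]], file.path(dir, cond))
  if (!is.null(sim$counts))
    writeProbeCounts(sim$counts, file.path(dir, "probe_counts.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", na = "null")
  invisible(dir)
}

#' Read a ground-truth sidecar
#' @param path path to `ground_truth.json`.
#' @return the ground-truth list.
#' @export
readGroundTruth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
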
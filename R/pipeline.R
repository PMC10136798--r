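#' Run every analysis stage from one configuration
#'
#' Orchestrates classify -> architecture -> sequence bias -> pausing ->
#' output ratio over a set of input files, writing one TSV per stage and
#' a machine-readable JSON report. The configuration is a named list (or
#' a YAML file path) with entries:
#' \describe{
#'   \item{gtf, fasta, junctions}{annotation, genome, junction-call TSV.}
#'   \item{repeats}{repeat BED (optional; skips repeat enrichment).}
#'   \item{coverage}{named list condition -> bedGraph pair prefix
#'     (optional; skips pausing).}
#'   \item{counts}{probe-count TSV (optional; skips the output-ratio
#'     stage).}
#'   \item{reference}{reference condition (default `"WT"`).}
#'   \item{outdir}{output directory.}
#'   \item{tolerance, flank, alpha, lfc_threshold, delta_cl, tau}{stage
#'     parameter overrides (defaults 0, 300, 0.05, 2, 1, log2(1.5)).}
#' }
#' A stage failure aborts with the stage name; outputs written so far
#' are kept with a `.partial` marker file.
#'
#' @param config named list or path to a YAML file.
#' @return the report list, invisibly; also written as `report.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(k, default = NULL) if (!is.null(config[[k]])) config[[k]] else default
  outdir <- cfg("outdir", stop("config requires an outdir"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "outdir")])
  marker <- file.path(outdir, "report.partial")
  file.create(marker)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genes <- stage("classify", function() readGtf(cfg("gtf", stop("need gtf"))))
  juncs <- stage("classify", function()
    readJunctions(cfg("junctions", stop("need junctions"))))
  circs <- stage("classify", function()
    classifyJunctions(juncs, genes, tolerance = cfg("tolerance", 0L)))
  writeJunctions(circs, file.path(outdir, "classified.tsv"))
  ids <- paste(as.character(seqnames(circs)), start(circs), end(circs),
               as.character(strand(circs)), sep = ":")
  by_cond <- split(ids, mcols(circs)$condition)
  report$classify <- list(
    n_calls = length(circs),
    n_distinct = length(unique(ids)),
    class_counts = as.list(table(mcols(circs)$circ_class)),
    condition_overlap = if (length(by_cond) >= 2)
      stats::setNames(as.list(conditionOverlap(by_cond)$count),
                      conditionOverlap(by_cond)$region) else NULL)

  arch <- stage("architecture", function() {
    rec <- architectureRecords(circs, genes)
    summ <- summarizeArchitecture(rec, genes)
    utils::write.table(rec, file.path(outdir, "architecture.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(outdir, "architecture_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(records = rec, summary = summ)
  })
  report$architecture <- list(
    n_records = nrow(arch$records),
    summary = arch$summary)

  report$seqbias <- stage("seqbias", function() {
    if (is.null(cfg("fasta"))) return(list(skipped = TRUE))
    seqs <- readFasta(cfg("fasta"))
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    g4 <- scanG4(seqs)
    flanks <- flankWindows(circs, genes, width = cfg("flank_window", 500L))
    out <- list(n_g4_genome = length(g4))
    if (length(flanks)) {
      out$g4_density_flanks <- g4Density(g4, flanks)
      exonic <- mcols(circs)$circ_class %in% c("exonic_single", "exonic_multi")
      host_ids <- unique(mcols(circs)$host_gene[exonic])
      bg_ids <- setdiff(geneIds(genes), unique(mcols(circs)$host_gene))
      bg_intr <- unlist(intronRanges(genes)[bg_ids], use.names = FALSE)
      if (length(bg_intr)) out$g4_density_background <- g4Density(g4, bg_intr)
      if (!is.null(cfg("repeats"))) {
        reps <- readBed(cfg("repeats"))
        flank_intr <- do.call(c, lapply(which(exonic), function(i) {
          fl <- flankingIntrons(circs[i], genes)
          c(if (fl$upstream_defined) fl$upstream,
            if (fl$downstream_defined) fl$downstream)
        }))
        enr <- repeatEnrichment(flank_intr, bg_intr, reps,
                                B = cfg("bootstrap", 200L), seed = cfg("seed", 1L))
        utils::write.table(enr, file.path(outdir, "repeat_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$repeat_enrichment <- enr
      }
    }
    out
  })

  report$pausing <- stage("pausing", function() {
    cov <- cfg("coverage")
    if (is.null(cov)) return(list(skipped = TRUE))
    tracks <- lapply(cov, readBedGraphPair)
    profs <- lapply(tracks, function(tr) pausingProfile(circs, genes, tr,
                                                        flank = cfg("flank", 300L),
                                                        collapse_flanks = TRUE))
    metas <- lapply(profs, metaprofile)
    ref <- cfg("reference", "WT")
    out <- list(metaprofiles = metas)
    if (ref %in% names(tracks)) {
      for (cond in setdiff(names(tracks), ref)) {
        dp <- deltaPausing(profs[[ref]], profs[[cond]], tau = cfg("tau", log2(1.5)))
        utils::write.table(dp, file.path(outdir, paste0("pausing_delta_",
                                                        cond, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out[[paste0("delta_", cond)]] <-
          as.list(table(dp$class))
      }
    }
    out
  })

  report$output_ratio <- stage("output-ratio", function() {
    if (is.null(cfg("counts"))) return(list(skipped = TRUE))
    pcm <- normalizeCounts(readProbeCounts(cfg("counts")))
    ref <- cfg("reference", "WT")
    conds <- setdiff(unique(SummarizedExperiment::colData(pcm)$condition), ref)
    out <- list()
    for (cond in conds) {
      ch <- probeLog2FC(pcm, cond, ref = ref)
      ce <- classifyExpression(ch, alpha = cfg("alpha", 0.05),
                               lfc_threshold = cfg("lfc_threshold", 2))
      cl <- clRatioClass(ch, delta = cfg("delta_cl", 1),
                         alpha = cfg("alpha", 0.05))
      utils::write.table(
        merge(ch, cl$genes[, c("gene_id", "class")], by = "gene_id",
              all.x = TRUE),
        file.path(outdir, paste0("clratio_", cond, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out[[cond]] <- list(pct_altered = ce$pct_altered,
                          n_genes = ce$n_genes,
                          cl_percentages = as.list(cl$percentages))
    }
    out
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  file.remove(marker)
  invisible(report)
}

#' Compare pipeline estimates with generator ground truth
#'
#' Side-by-side table of planted versus recovered parameters with
#' z-scores (difference over the recovered standard error): flanking
#' intron means per condition and planted probe log2 effects.
#'
#' @param sim a [simulateBundle()] result (or a list with `truth`).
#' @param circs classified junctions over the simulated annotation.
#' @param genes the simulated [GeneModelSet-class].
#' @param changes optional [probeLog2FC()] output per condition (named
#'   list) for probe-effect recovery.
#' @return data.frame: `parameter`, `planted`, `recovered`, `se`, `z`.
#' @export
reportValidate <- function(sim, circs, genes, changes = NULL) {
  truth <- sim$truth
  if (is.null(truth)) stop("ground truth missing; nothing to validate")
  rows <- list()
  rec <- architectureRecords(circs, genes)
  for (side in c("up", "down")) {
    planted <- truth$params[[paste0("host_flank_", side, "_mean")]]
    obs <- rec[[paste0(c(up = "upstream", down = "downstream")[side], "_length")]]
    obs <- obs[!is.na(obs)]
    if (length(obs) > 1 && !is.null(planted)) {
      se <- stats::sd(obs) / sqrt(length(obs))
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = paste0("flank_", side, "_mean"), planted = planted,
        recovered = mean(obs), se = se, z = (mean(obs) - planted) / se,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(changes) && !is.null(truth$probe_effects)) {
    pe <- truth$probe_effects
    for (cond in names(changes)) {
      ch <- changes[[cond]]
      m <- merge(ch, pe[pe$condition == cond, ],
                 by = c("gene_id", "probe_type"))
      eff <- m[m$lfc != 0, , drop = FALSE]
      if (nrow(eff) > 1) {
        err <- eff$log2fc - eff$lfc
        se <- stats::sd(err) / sqrt(nrow(eff))
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = paste0("probe_lfc_bias_", cond), planted = 0,
          recovered = mean(err), se = se, z = mean(err) / se,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(parameter = character(0), planted = numeric(0),
                      recovered = numeric(0), se = numeric(0), z = numeric(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
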
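#' Run the full Amp-seq pipeline on one pool
#'
#' Orchestrates simulate -> demux -> call -> annotate -> popgen with one
#' seed, writing each stage's outputs plus a JSON manifest (inputs,
#' parameters, output checksums, counts) under \code{outDir}. Re-running
#' with the same seed and configuration reproduces byte-identical variant
#' tables: all text outputs are LF-terminated with fixed 6-significant-digit
#' float formatting and no timestamps.
#'
#' @param outDir output directory (created).
#' @param panel An \linkS4class{AmpliconPanel}; default
#'   \code{\link{buildDefaultPanel}()}.
#' @param sheet A \linkS4class{SampleSheet}; default generated for
#'   \code{simCfg@nSamples} samples.
#' @param simCfg A \linkS4class{SimulationConfig} (required when the
#'   "simulate" stage runs); its seed is overridden by \code{seed} when
#'   given.
#' @param reads optional list(r1, r2) FASTQ paths to use instead of
#'   simulation.
#' @param cfg A \linkS4class{FilterConfig}.
#' @param stages character subset of
#'   c("simulate", "demux", "call", "annotate", "popgen"), in order.
#' @param seed integer master seed recorded in the manifest.
#' @param phyloAmplicons amplicons used for consensus/popgen (default
#'   ITS2 and CO1).
#' @return the manifest list, invisibly; on stage failure a FAILED marker
#'   file is left beside the partial outputs and the error is re-thrown.
#' @export
runPipeline <- function(outDir, panel = buildDefaultPanel(), sheet = NULL,
                        simCfg = NULL, reads = NULL, cfg = filterConfig(),
                        stages = c("simulate", "demux", "call", "annotate",
                                   "popgen"),
                        seed = 1L,
                        phyloAmplicons = c("ITS2", "CO1")) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = stages,
                   parameters = list(
                     minBaseQual = cfg@minBaseQual, minDepth = cfg@minDepth,
                     minAltDepth = cfg@minAltDepth,
                     minSiteQual = cfg@minSiteQual,
                     minSamples = cfg@minSamples, minPools = cfg@minPools),
                   outputs = list(), counts = list())
  fail <- function(stage, e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop(e)
  }
  addOutput <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }

  if (is.null(sheet) && !is.null(simCfg))
    sheet <- makeSampleSheet(simCfg@nSamples, seed = seed)
  sim <- NULL
  if ("simulate" %in% stages) {
    tryCatch({
      simCfg@seed <- as.integer(seed)
      sim <- simulatePool(panel, simCfg, sheet,
                          outDir = file.path(outDir, "reads"))
      reads <- list(r1 = sim$files$r1, r2 = sim$files$r2)
      addOutput("r1", reads$r1); addOutput("r2", reads$r2)
      manifest$counts$read_pairs <- length(sim$ids)
    }, error = function(e) fail("simulate", e))
  }

  dm <- NULL
  if ("demux" %in% stages) {
    tryCatch({
      dm <- demultiplexPool(reads$r1, reads$r2, sheet, panel,
                            outDir = file.path(outDir, "demux"))
      manifest$counts$assigned <- dm$coverage$perPool$assigned
      manifest$counts$unassigned <- dm$coverage$perPool$unassigned
      addOutput("coverage", file.path(outDir, "demux", "coverage.tsv"))
    }, error = function(e) fail("demux", e))
  }

  pileups <- NULL; filtered <- NULL
  if ("call" %in% stages && !is.null(dm)) {
    tryCatch({
      pileups <- pileupsForPool(dm, panel, minBaseQual = cfg@minBaseQual)
      gts <- do.call(rbind, lapply(pileups, callSample, cfg = cfg))
      if (is.null(gts)) gts <- cbind(emptyCallTable(),
                                     data.frame(sample_id = character(0)))
      filtered <- crossSampleFilter(gts, sheet, cfg)
      vcf <- file.path(outDir, "variants.vcf")
      writePoolVcf(filtered$genotypes, panel, sheet, vcf)
      addOutput("vcf", vcf)
      manifest$counts$variant_keys <- nrow(filtered$retainedKeys)
    }, error = function(e) fail("call", e))
  }

  if ("annotate" %in% stages && !is.null(filtered) &&
      nrow(filtered$genotypes)) {
    tryCatch({
      ann <- annotateCalls(filtered$genotypes, panel)
      annPath <- file.path(outDir, "annotations.tsv")
      utils::write.table(ann, annPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addOutput("annotations", annPath)
      vcfA <- file.path(outDir, "variants.annotated.vcf")
      writePoolVcf(filtered$genotypes, panel, sheet, vcfA,
                   annotations = ann)
      addOutput("vcf_annotated", vcfA)
      rep <- resistanceReport(filtered$genotypes, panel, pileups, cfg)
      repPath <- file.path(outDir, "marker_report.tsv")
      writeResistanceReport(rep, repPath)
      addOutput("marker_report", repPath)
    }, error = function(e) fail("annotate", e))
  }

  if ("popgen" %in% stages && !is.null(pileups)) {
    tryCatch({
      d <- sheetData(sheet)
      for (a in intersect(phyloAmplicons, ampliconNames(panel))) {
        seqs <- character(0); labs <- character(0)
        for (s in d$sample_id) {
          p <- pileups[[paste(s, a, sep = "|")]]
          if (is.null(p)) next
          cons <- consensusFromPileup(p)
          if (!cons$rejected) {
            seqs <- c(seqs, cons$seq); labs <- c(labs, s)
          }
        }
        if (length(seqs) >= 2L) {
          h <- haplotypeSet(seqs, sample = labs,
                            population = d$pool_id[match(labs, d$sample_id)])
          base <- file.path(outDir, sanitizeName(a))
          fa <- paste0(base, "_consensus.fasta")
          x <- Biostrings::DNAStringSet(seqs)
          names(x) <- paste(labs, h@population, sep = "|")
          Biostrings::writeXStringSet(x, fa)
          addOutput(paste0(a, "_fasta"), fa)
          st <- paste0(base, "_stats.tsv")
          popgenStatsTable(h, st)
          addOutput(paste0(a, "_stats"), st)
          net <- buildNetwork(h)
          gml <- paste0(base, "_network.gml")
          writeNetwork(net, gml, "gml")
          addOutput(paste0(a, "_network"), gml)
          if (length(unique(labs)) >= 3L) {
            tr <- njTree(h)
            nwk <- paste0(base, "_nj.nwk")
            ape::write.tree(tr, nwk)
            addOutput(paste0(a, "_tree"), nwk)
          }
        }
      }
    }, error = function(e) fail("popgen", e))
  }

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Coverage and variant-count summary table
#'
#' One row per amplicon in the style of the assay's coverage summary: the
#' mean read-pair coverage across samples, and the number of distinct
#' retained SNPs and indels — overall and per population label. Shared
#' variants are counted once in the overall column, so population columns
#' can sum to more than it.
#'
#' @param coverage coverage report from \code{\link{demultiplexPool}}.
#' @param genotypes flagged call records (after
#'   \code{\link{crossSampleFilter}}).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param populations optional named character mapping sample_id ->
#'   population label.
#' @return data.frame with \code{amplicon}, \code{mean_coverage},
#'   \code{snps}, \code{indels}, then per-population variant counts.
#' @export
coverageTable <- function(coverage, genotypes, panel,
                          populations = NULL) {
  amps <- ampliconNames(panel)
  ret <- genotypes[genotypes$retained %||% rep(TRUE, nrow(genotypes)), ,
                   drop = FALSE]
  keyOf <- function(g) paste(g$amplicon, g$pos, g$ref, g$alt, sep = "\r")
  out <- data.frame(amplicon = amps)
  out$mean_coverage <- coverage$perAmplicon$mean_coverage[
    match(amps, coverage$perAmplicon$amplicon)]
  countFor <- function(g, type) {
    vapply(amps, function(a) {
      gg <- g[g$amplicon == a &
                (if (type == "snp") g$type == "snp" else g$type != "snp"), ,
              drop = FALSE]
      length(unique(keyOf(gg)))
    }, integer(1))
  }
  out$snps <- countFor(ret, "snp")
  out$indels <- countFor(ret, "indel")
  if (!is.null(populations)) {
    carriers <- ret[ret$genotype %in% c("het", "hom_alt"), , drop = FALSE]
    for (p in unique(populations)) {
      inPop <- carriers[populations[carriers$sample_id] == p, ,
                        drop = FALSE]
      out[[paste0("variants_", p)]] <- countFor(inPop, "snp") +
        countFor(inPop, "indel")
    }
  }
  rownames(out) <- NULL
  out
}
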
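#' Construct a SimulationConfig
#'
#' Defaults mirror the study design the simulator emulates: ~500 bp
#' amplicons sequenced 2 x 250 bp to a mean of 250 read pairs per
#' amplicon-sample unit (50,000 pairs for a full pool of 200 units), with
#' mostly high-quality bases (phred 37, 10\% at phred 20) and a mean
#' per-base substitution error rate of 0.1\%.
#'
#' @param nSamples samples in the pool.
#' @param amplicons character vector of panel amplicon names.
#' @param plantedVariants data.frame of planted biallelic variants
#'   (\code{amplicon}, \code{pos} 0-based, \code{ref}, \code{alt},
#'   \code{freq}); see \linkS4class{SimulationConfig} for the indel syntax.
#' @param readsPerAmplicon mean read pairs per sample-amplicon unit.
#' @param readLength read length including the 6-bp inline barcode.
#' @param baseErrorRate mean per-base substitution probability.
#' @param qualityModel named numeric: \code{high_q}, \code{low_q},
#'   \code{fraction_low}.
#' @param seed master seed; all randomness in \code{\link{simulatePool}}
#'   derives from it.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples, amplicons,
                             plantedVariants = emptyVariantTable(),
                             readsPerAmplicon = 250,
                             readLength = 250L,
                             baseErrorRate = 0.001,
                             qualityModel = c(high_q = 37, low_q = 20,
                                              fraction_low = 0.1),
                             seed = 1L) {
  new("SimulationConfig", nSamples = as.integer(nSamples),
      amplicons = amplicons, plantedVariants = plantedVariants,
      readsPerAmplicon = readsPerAmplicon,
      readLength = as.integer(readLength),
      baseErrorRate = baseErrorRate, qualityModel = qualityModel,
      seed = as.integer(seed))
}

emptyVariantTable <- function() {
  data.frame(amplicon = character(0), pos = integer(0), ref = character(0),
             alt = character(0), freq = numeric(0))
}

# Apply a set of variant records to a template (plain character), descending
# position so earlier coordinates stay valid. alt: base, "+SEQ" or "-N".
applyVariants <- function(template, vars) {
  if (nrow(vars) == 0L) return(template)
  vars <- vars[order(-vars$pos), , drop = FALSE]
  for (i in seq_len(nrow(vars))) {
    pos <- vars$pos[i]; alt <- vars$alt[i]
    if (startsWith(alt, "+")) {
      ins <- substring(alt, 2)
      template <- paste0(substr(template, 1L, pos + 1L), ins,
                         substring(template, pos + 2L))
    } else if (startsWith(alt, "-")) {
      n <- as.integer(substring(alt, 2))
      template <- paste0(substr(template, 1L, pos),
                         substring(template, pos + n + 1L))
    } else {
      substr(template, pos + 1L, pos + 1L) <- alt
    }
  }
  template
}

#' Simulate one pooled, barcoded amplicon-sequencing run
#'
#' Emulates the output of the wet-lab protocol for one pool: every sample is
#' amplified at every configured amplicon; read 1 of each fragment is the
#' sample's forward barcode + forward primer + template; read 2 is the
#' reverse barcode + reverse primer + template reverse complement. Per-site
#' genotypes are drawn per sample from Hardy-Weinberg proportions at the
#' planted population allele frequencies; heterozygous samples emit
#' alt-bearing template strands with probability 0.5 per fragment.
#' Substitution errors are applied per base with a probability proportional
#' to the base's phred error probability, scaled so that the mean rate
#' equals \code{baseErrorRate}. Fragment length equals amplicon length
#' (amplicon sequencing, no shearing), so mates overlap mid-amplicon when
#' 2 x (readLength - 6) exceeds the amplicon length.
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param sheet A \linkS4class{SampleSheet} covering exactly one pool with
#'   \code{cfg@nSamples} rows.
#' @param outDir optional directory; when given, gzip FASTQ mates
#'   (\code{<pool>_R1.fastq.gz}, \code{<pool>_R2.fastq.gz}), a genotype
#'   truth table and a per-read truth table are written there.
#' @return list with \code{ids}, \code{seq1}, \code{qual1}, \code{seq2},
#'   \code{qual2} (parallel character vectors), \code{truth} (sample x site
#'   genotypes: \code{sample_id}, \code{amplicon}, \code{pos}, \code{ref},
#'   \code{alt}, \code{genotype}), \code{readTruth} (\code{read_id},
#'   \code{sample_id}, \code{amplicon}), and file paths when \code{outDir}
#'   was given.
#' @examples
#' panel <- buildDefaultPanel()
#' sheet <- makeSampleSheet(2, seed = 7)
#' cfg <- simulationConfig(2, c("Rdl1", "VGSCII"), readsPerAmplicon = 40,
#'                         seed = 7)
#' sim <- simulatePool(panel, cfg, sheet)
#' length(sim$ids)
#' @export
simulatePool <- function(panel, cfg, sheet, outDir = NULL) {
  validObject(cfg)
  d <- sheetData(sheet)
  if (length(unique(d$pool_id)) != 1L)
    stop("simulatePool expects a sheet covering exactly one pool")
  if (nrow(d) != cfg@nSamples)
    stop("sheet rows must equal cfg nSamples")
  if (anyDuplicated(c(d$fwd_barcode, d$rev_barcode)))
    stop("barcode collision in sheet: barcodes must be unique in the pool")
  amps <- cfg@amplicons
  if (!all(amps %in% ampliconNames(panel)))
    stop("unknown amplicon in config")
  nUnits <- cfg@nSamples * length(amps)
  if (nUnits > 200L)
    stop("pool exceeds 200 amplicon-sample units (", nUnits, ")")
  rl <- cfg@readLength
  tlen <- rl - 6L     # template bases carried by each mate
  pv <- cfg@plantedVariants
  # planted sites must avoid primer/barcode regions and be read-covered
  for (i in seq_len(nrow(pv))) {
    a <- pv$amplicon[i]; pos <- pv$pos[i]
    pp <- primerPair(panel, a)
    L <- nchar(refSequence(panel, a))
    if (pos < nchar(pp$fwd) || pos >= L - nchar(pp$rev))
      stop("planted site inside a primer region: ", a, ":", pos)
    if (pos >= tlen && pos < L - tlen)
      stop("planted site not covered by read geometry: ", a, ":", pos)
    refBase <- substr(refSequence(panel, a), pos + 1L, pos + 1L)
    if (!startsWith(pv$alt[i], "+") && !startsWith(pv$alt[i], "-") &&
        pv$ref[i] != refBase)
      stop("planted ref base disagrees with panel reference at ", a, ":", pos)
  }

  qm <- cfg@qualityModel
  hq <- as.integer(qm[["high_q"]]); lq <- as.integer(qm[["low_q"]])
  fl <- qm[["fraction_low"]]
  meanE <- fl * phredToProb(lq) + (1 - fl) * phredToProb(hq)
  errScale <- if (cfg@baseErrorRate > 0) cfg@baseErrorRate / meanE else 0

  withSeed(cfg@seed, {
    # genotypes per sample x planted site
    truth <- NULL
    gtList <- list()   # [[amplicon]] -> data.frame(sample rows x variant idx)
    for (a in amps) {
      va <- pv[pv$amplicon == a, , drop = FALSE]
      if (nrow(va) == 0L) { gtList[[a]] <- NULL; next }
      g <- matrix(0L, nrow = cfg@nSamples, ncol = nrow(va))
      for (j in seq_len(nrow(va))) {
        p <- va$freq[j]
        g[, j] <- sample(0:2, cfg@nSamples, replace = TRUE,
                         prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
      }
      gtList[[a]] <- g
      truth <- rbind(truth, data.frame(
        sample_id = rep(d$sample_id, times = nrow(va)),
        amplicon = a,
        pos = rep(va$pos, each = cfg@nSamples),
        ref = rep(va$ref, each = cfg@nSamples),
        alt = rep(va$alt, each = cfg@nSamples),
        genotype = c("0/0", "0/1", "1/1")[as.vector(g) + 1L]))
    }

    ids <- seq1 <- qual1 <- seq2 <- qual2 <- character(0)
    rtSample <- rtAmp <- character(0)
    counter <- 0L
    for (si in seq_len(cfg@nSamples)) {
      bcf <- d$fwd_barcode[si]; bcr <- d$rev_barcode[si]
      for (a in amps) {
        ref <- refSequence(panel, a)
        va <- pv[pv$amplicon == a, , drop = FALSE]
        g <- if (!is.null(gtList[[a]])) gtList[[a]][si, ] else integer(0)
        # two template haplotypes: hap0 carries hom-alt sites only, hap1
        # additionally carries the het sites
        hap0 <- applyVariants(ref, va[g == 2L, , drop = FALSE])
        hap1 <- applyVariants(ref, va[g >= 1L, , drop = FALSE])
        anyHet <- any(g == 1L)
        n <- stats::rpois(1L, cfg@readsPerAmplicon)
        if (n == 0L) next
        useAlt <- if (anyHet) stats::runif(n) < 0.5 else rep(FALSE, n)
        for (hap in c(FALSE, TRUE)) {
          nh <- sum(useAlt == hap)
          if (nh == 0L) next
          tpl <- if (hap) hap1 else hap0
          tl <- min(tlen, nchar(tpl))
          fwdT <- substr(tpl, 1L, tl)
          revT <- substr(revComp(tpl), 1L, tl)
          for (mate in 1:2) {
            tchars <- strsplit(if (mate == 1L) fwdT else revT, "",
                               fixed = TRUE)[[1]]
            m <- matrix(tchars, nrow = nh, ncol = tl, byrow = TRUE)
            qmx <- matrix(ifelse(stats::runif(nh * tl) < fl, lq, hq),
                          nrow = nh)
            if (errScale > 0) {
              perr <- pmin(errScale * phredToProb(qmx), 0.5)
              emask <- matrix(stats::runif(nh * tl), nrow = nh) < perr
              idx <- which(emask)
              if (length(idx)) {
                old <- m[idx]
                m[idx] <- vapply(old, function(b)
                  sample(setdiff(DNA_BASES4, b), 1L), character(1))
              }
            }
            bc <- if (mate == 1L) bcf else bcr
            rseq <- paste0(bc, collapseRows(m))
            rqual <- paste0(strrep(rawToChar(as.raw(hq + 33L)), 6L),
                            qualMatrixToStrings(qmx))
            if (mate == 1L) {
              seq1 <- c(seq1, rseq); qual1 <- c(qual1, rqual)
            } else {
              seq2 <- c(seq2, rseq); qual2 <- c(qual2, rqual)
            }
          }
          newIds <- sprintf("%s:%07d", d$pool_id[1], counter + seq_len(nh))
          counter <- counter + nh
          ids <- c(ids, newIds)
          rtSample <- c(rtSample, rep(d$sample_id[si], nh))
          rtAmp <- c(rtAmp, rep(a, nh))
        }
      }
    }
    # shuffle pool order (libraries are sequenced interleaved)
    ord <- sample(length(ids))
    ids <- ids[ord]; seq1 <- seq1[ord]; qual1 <- qual1[ord]
    seq2 <- seq2[ord]; qual2 <- qual2[ord]
    readTruth <- data.frame(read_id = ids, sample_id = rtSample[ord],
                            amplicon = rtAmp[ord])
    out <- list(ids = ids, seq1 = seq1, qual1 = qual1, seq2 = seq2,
                qual2 = qual2, truth = truth %||% data.frame(),
                readTruth = readTruth, pool = d$pool_id[1])
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      pool <- sanitizeName(d$pool_id[1])
      f1 <- file.path(outDir, paste0(pool, "_R1.fastq.gz"))
      f2 <- file.path(outDir, paste0(pool, "_R2.fastq.gz"))
      writeFastq(ids, seq1, qual1, f1)
      writeFastq(ids, seq2, qual2, f2)
      ft <- file.path(outDir, paste0(pool, "_truth.tsv"))
      utils::write.table(out$truth, ft, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fr <- file.path(outDir, paste0(pool, "_read_truth.tsv"))
      utils::write.table(readTruth, fr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$files <- list(r1 = f1, r2 = f2, truth = ft, readTruth = fr)
    }
    out
  })
}

#' Simulate several pools of one study
#'
#' Splits the sample sheet by pool and runs \code{\link{simulatePool}} on
#' each, deriving a distinct per-pool seed from the master seed
#' (\code{seed + pool index - 1}). Planted allele frequencies are shared
#' across pools, as for samples of one population sequenced in independent
#' pools.
#'
#' @inheritParams simulatePool
#' @param sheet A \linkS4class{SampleSheet} covering one or more pools;
#'   \code{cfg@nSamples} must equal the rows of each pool.
#' @return named list of per-pool simulation results.
#' @export
simulatePools <- function(panel, cfg, sheet, outDir = NULL) {
  d <- sheetData(sheet)
  pools <- unique(d$pool_id)
  out <- list()
  for (k in seq_along(pools)) {
    sub <- sampleSheet(d[d$pool_id == pools[k], , drop = FALSE])
    cfgk <- cfg
    cfgk@nSamples <- nrow(sub@data)
    cfgk@seed <- cfg@seed + k - 1L
    out[[pools[k]]] <- simulatePool(panel, cfgk, sub, outDir = outDir)
  }
  out
}

#' Write / read gzip FASTQ (phred+33)
#'
#' Thin wrappers around \code{Biostrings} FASTQ I/O used by the simulator
#' and demultiplexer.
#'
#' @param ids,seqs,quals parallel character vectors.
#' @param path output path (".gz" gives gzip).
#' @export
writeFastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' @rdname writeFastq
#' @return \code{readFastq}: list of \code{ids}, \code{seqs}, \code{quals}.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(ids = names(x), seqs = unname(as.character(x)),
       quals = unname(as.character(S4Vectors::mcols(x)$qualities)))
}
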
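#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
NULL

#' AmpliconPanel: the assay definition
#'
#' An \code{AmpliconPanel} bundles everything that defines a multiplex
#' amplicon-sequencing assay: the amplicon reference sequences, the forward
#' and reverse primers synthesized onto each amplicon, the locus each
#' amplicon targets, minimal gene models for the coding loci (CDS intervals,
#' strand, codon numbering and cross-species ortholog offsets), and the
#' catalogue of known resistance markers scored by the assay.
#'
#' Amplicon references are stored as a named \link[Biostrings]{DNAStringSet}.
#' Each reference begins with its forward primer and ends with the reverse
#' complement of its reverse primer (the reverse primer is recorded as
#' synthesized, i.e. in reverse-complement orientation relative to the
#' reference 3' end).
#'
#' @slot amplicons named \code{DNAStringSet} of amplicon reference sequences.
#' @slot primers data.frame with columns \code{amplicon}, \code{fwd},
#'   \code{rev}.
#' @slot targetLocus named character; gene targeted by each amplicon.
#' @slot genomicOffset named integer; 0-based position of each amplicon
#'   start on its source contig.
#' @slot geneModels named list (by amplicon) of gene models: \code{gene},
#'   \code{strand} ("+"/"-"), \code{cds_intervals} (two-column matrix of
#'   0-based half-open contig intervals, ordered 5'->3' in transcription
#'   direction), \code{codon_offset} (codon number of the first complete
#'   codon in the modelled region), \code{ortholog_numbering} (named integer
#'   offsets added to native codon numbers).
#' @slot markers data.frame of resistance markers: \code{gene},
#'   \code{native_codon}, \code{ref_aa}, \code{alt_aa}, \code{ortholog_label},
#'   \code{known_association}.
#'
#' @seealso \code{\link{buildDefaultPanel}}, \code{\link{readPanel}}
#' @export
setClass("AmpliconPanel",
  slots = c(
    amplicons = "DNAStringSet",
    primers = "data.frame",
    targetLocus = "character",
    genomicOffset = "integer",
    geneModels = "list",
    markers = "data.frame"
  )
)

setValidity("AmpliconPanel", function(object) {
  msgs <- character(0)
  nm <- names(object@amplicons)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "amplicon names must be present and unique")
  len <- Biostrings::width(object@amplicons)
  if (any(len < 150 | len > 1000))
    msgs <- c(msgs, "amplicon reference lengths must lie in [150, 1000]")
  refs <- as.character(object@amplicons)
  for (i in seq_along(refs)) {
    p <- object@primers[object@primers$amplicon == nm[i], ]
    if (nrow(p) != 1L) {
      msgs <- c(msgs, sprintf("amplicon %s needs exactly one primer row", nm[i]))
      next
    }
    if (!startsWith(refs[i], p$fwd))
      msgs <- c(msgs, sprintf("%s: reference must start with fwd primer", nm[i]))
    if (!endsWith(refs[i], revComp(p$rev)))
      msgs <- c(msgs,
        sprintf("%s: reference must end with revcomp of rev primer", nm[i]))
  }
  mk <- object@markers
  if (nrow(mk)) {
    if (any(mk$ref_aa == mk$alt_aa))
      msgs <- c(msgs, "marker ref_aa must differ from alt_aa")
    if (anyDuplicated(mk[, c("gene", "native_codon", "alt_aa")]))
      msgs <- c(msgs, "(gene, native_codon, alt_aa) must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel with", length(object@amplicons), "amplicons across",
      length(unique(object@targetLocus)), "loci\n")
  len <- Biostrings::width(object@amplicons)
  cat(sprintf("  amplicons: %s\n",
              paste(names(object@amplicons), collapse = ", ")))
  cat(sprintf("  reference lengths: %d-%d bp\n", min(len), max(len)))
  cat("  resistance markers:", nrow(object@markers), "\n")
})

#' SampleSheet: sample / barcode / pool assignments
#'
#' Maps each sample to the 6-bp forward and reverse inline barcodes
#' synthesized onto its primers and to the sequencing pool it was
#' multiplexed in. Barcode pairs must be unique within a pool; the
#' generator additionally guarantees pairwise Hamming distance >= 3 among
#' barcodes used in one pool so that single-mismatch demultiplexing is
#' unambiguous.
#'
#' @slot data data.frame with columns \code{sample_id}, \code{fwd_barcode},
#'   \code{rev_barcode}, \code{pool_id}.
#' @seealso \code{\link{makeSampleSheet}}, \code{\link{readSampleSheet}}
#' @export
setClass("SampleSheet", slots = c(data = "data.frame"))

setValidity("SampleSheet", function(object) {
  d <- object@data
  need <- c("sample_id", "fwd_barcode", "rev_barcode", "pool_id")
  if (!all(need %in% names(d)))
    return(paste("sample sheet needs columns:", paste(need, collapse = ", ")))
  bcs <- c(d$fwd_barcode, d$rev_barcode)
  if (any(nchar(bcs) != 6L))
    return("every barcode must be exactly 6 bases")
  if (any(!grepl("^[ACGT]+$", bcs)))
    return("barcodes must contain only A/C/G/T")
  if (anyDuplicated(d$sample_id))
    return("sample_id must be unique")
  for (p in unique(d$pool_id)) {
    dp <- d[d$pool_id == p, ]
    if (anyDuplicated(dp[, c("fwd_barcode", "rev_barcode")]))
      return(sprintf("barcode pair collision within pool %s", p))
  }
  TRUE
})

setMethod("show", "SampleSheet", function(object) {
  d <- object@data
  cat("SampleSheet:", nrow(d), "samples in", length(unique(d$pool_id)),
      "pool(s)\n")
})

#' SimulationConfig: parameters of the synthetic pool generator
#'
#' Describes one simulated sequencing pool: how many samples, which panel
#' amplicons, which biallelic variants are planted at which population
#' allele frequencies, sequencing depth and read geometry, and the
#' base-quality / substitution-error model. One integer seed drives all
#' randomness.
#'
#' @slot nSamples integer number of mosquito samples in the pool.
#' @slot amplicons character; amplicon names drawn from the panel.
#' @slot plantedVariants data.frame: \code{amplicon}, \code{pos} (0-based on
#'   the amplicon), \code{ref}, \code{alt}, \code{freq} (population allele
#'   frequency in [0,1]). \code{alt} may be a base (SNP), \code{"+SEQ"}
#'   (insertion after \code{pos}) or \code{"-N"} (deletion of N bases).
#' @slot readsPerAmplicon positive mean read pairs per sample-amplicon unit.
#' @slot readLength integer read length (inline barcode included).
#' @slot baseErrorRate mean per-base substitution probability in [0, 0.1].
#' @slot qualityModel numeric: \code{high_q}, \code{low_q}, \code{fraction_low}.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  slots = c(
    nSamples = "integer", amplicons = "character",
    plantedVariants = "data.frame", readsPerAmplicon = "numeric",
    readLength = "integer", baseErrorRate = "numeric",
    qualityModel = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nSamples < 1L) return("nSamples must be >= 1")
  if (object@baseErrorRate < 0 || object@baseErrorRate > 0.1)
    return("baseErrorRate must lie in [0, 0.1]")
  pv <- object@plantedVariants
  if (nrow(pv) && (any(pv$freq < 0) || any(pv$freq > 1)))
    return("planted allele frequencies must lie in [0, 1]")
  qm <- object@qualityModel
  if (!all(c("high_q", "low_q", "fraction_low") %in% names(qm)))
    return("qualityModel needs high_q, low_q, fraction_low")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples x",
      length(object@amplicons), "amplicons;",
      nrow(object@plantedVariants), "planted variants; mean",
      object@readsPerAmplicon, "pairs/unit; error rate",
      object@baseErrorRate, "\n")
})

#' PileupMatrix: per-position base and quality counts for one sample/amplicon
#'
#' The substrate for variant calling and consensus building. Holds, for one
#' demultiplexed (sample, amplicon) bin, counts of A/C/G/T and
#' deletion-spanned reads at every 0-based reference position, plus counts
#' stratified by phred quality (needed by the genotype-likelihood caller),
#' and single-event insertion/deletion records. Bases below the
#' base-quality floor are excluded at construction time.
#'
#' @slot amplicon,sample character identifiers.
#' @slot ref character reference sequence of the amplicon.
#' @slot counts 5 x L integer matrix, rows A,C,G,T,DEL.
#' @slot qualCounts 4 x L x Q integer array of base counts by phred level.
#' @slot qlevels integer phred values indexing the third dimension.
#' @slot insertions data.frame of insertion events: \code{pos}, \code{seq},
#'   \code{count}.
#' @slot deletions data.frame of deletion events: \code{pos}, \code{len},
#'   \code{count}.
#' @slot nFragments,nDiscarded integer accounting.
#' @export
setClass("PileupMatrix",
  slots = c(
    amplicon = "character", sample = "character", ref = "character",
    counts = "matrix", qualCounts = "array", qlevels = "integer",
    insertions = "data.frame", deletions = "data.frame",
    nFragments = "integer", nDiscarded = "integer"
  )
)

setValidity("PileupMatrix", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (nrow(object@counts) != 5L) return("counts needs rows A,C,G,T,DEL")
  if (ncol(object@counts) != nchar(object@ref))
    return("counts must have one column per reference position")
  TRUE
})

setMethod("show", "PileupMatrix", function(object) {
  dp <- colSums(object@counts)
  cat(sprintf("PileupMatrix %s / %s: %d positions, mean depth %.1f, %d fragments (%d discarded)\n",
              object@sample, object@amplicon, ncol(object@counts),
              mean(dp), object@nFragments, object@nDiscarded))
})

#' FilterConfig: site and cross-sample variant filters
#'
#' Thresholds of the high-quality SNP filter: minimum phred 30 per called
#' base, minimum depth 30, minimum alternate allele depth 10, minimum
#' phred-scaled site quality 30, and the replication rule that a variant
#' must be seen in at least two samples spanning at least two independent
#' pools. Genotypes are classified from the alternate-allele read fraction:
#' below \code{hetLow} homozygous reference, above \code{hetHigh} homozygous
#' alternate, the closed band in between heterozygous.
#'
#' @slot minBaseQual,minDepth,minAltDepth,minSiteQual,minSamples,minPools
#'   numeric thresholds.
#' @slot hetLow,hetHigh genotype-classification band limits in (0,1).
#' @export
setClass("FilterConfig",
  slots = c(
    minBaseQual = "numeric", minDepth = "numeric", minAltDepth = "numeric",
    minSiteQual = "numeric", minSamples = "numeric", minPools = "numeric",
    hetLow = "numeric", hetHigh = "numeric"
  ),
  prototype = prototype(
    minBaseQual = 30, minDepth = 30, minAltDepth = 10, minSiteQual = 30,
    minSamples = 2, minPools = 2, hetLow = 0.25, hetHigh = 0.75
  )
)

setValidity("FilterConfig", function(object) {
  if (!(object@hetLow >= 0 && object@hetLow < object@hetHigh &&
        object@hetHigh <= 1))
    return("need 0 <= hetLow < hetHigh <= 1")
  if (object@minDepth <= 0 || object@minAltDepth <= 0)
    return("depth thresholds must be positive")
  TRUE
})

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(
    "FilterConfig: baseQ>=%g, DP>=%g, AD_alt>=%g, siteQ>=%g, samples>=%g, pools>=%g, het band [%g, %g]\n",
    object@minBaseQual, object@minDepth, object@minAltDepth,
    object@minSiteQual, object@minSamples, object@minPools,
    object@hetLow, object@hetHigh))
})

#' HaplotypeSet: aligned consensus sequences with population labels
#'
#' Equal-length aligned sequences (A/C/G/T/N/-) with a sample identifier and
#' a population label per sequence. A site mask marks the columns with no N
#' or gap in any sequence (complete deletion); all diversity statistics,
#' haplotype networks and trees are computed on masked columns only.
#'
#' @slot seqs \code{DNAStringSet} of aligned sequences (equal width).
#' @slot sample,population character vectors parallel to \code{seqs}.
#' @slot mask logical vector, one element per alignment column.
#' @seealso \code{\link{haplotypeSet}}, \code{\link{diversityStats}}
#' @export
setClass("HaplotypeSet",
  slots = c(seqs = "DNAStringSet", sample = "character",
            population = "character", mask = "logical")
)

setValidity("HaplotypeSet", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) && length(unique(w)) != 1L)
    return("all sequences must have equal length")
  if (length(object@sample) != length(object@seqs) ||
      length(object@population) != length(object@seqs))
    return("sample and population labels must parallel the sequences")
  if (length(w) && length(object@mask) != w[1])
    return("mask must have one element per alignment column")
  TRUE
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d sequences x %d sites (%d complete), %d population(s)\n",
              length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0L,
              sum(object@mask), length(unique(object@population))))
})
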
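#' Codon-level effect annotation of a variant
#'
#' A compact effect engine against the panel's gene models: the amplicon
#' position is mapped to its source contig, then to a CDS position
#' honouring strand and phase; reference and alternate codons are built and
#' translated with the standard genetic code. Substitutions classify as
#' synonymous, missense or nonsense; indels whose length is not a multiple
#' of three are frameshifts, the rest in-frame indels; positions outside
#' every CDS interval are non-coding. Variants overlapping a CDS boundary
#' are flagged as composite rather than dropped. Alleles are always given
#' on the amplicon (plus) strand; complementation for minus-strand genes is
#' internal. Ortholog labels apply the gene model's cross-species codon
#' offsets (vgsc +56 gives L958F -> L1014F; rdl +5 gives A296S -> A301S).
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param amplicon amplicon name.
#' @param pos 0-based position on the amplicon.
#' @param ref,alt alleles; \code{alt} may be a base, \code{"+SEQ"}
#'   (insertion) or \code{"-N"} (deletion).
#' @return one-row data.frame: \code{amplicon}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene}, \code{effect}, \code{native_codon},
#'   \code{ref_aa}, \code{alt_aa}, \code{aa_change}, \code{ortholog_labels}
#'   (comma-separated), \code{marker_hit} (marker ortholog label or NA),
#'   \code{composite} (logical: overlaps a CDS boundary).
#' @examples
#' panel <- buildDefaultPanel()
#' site <- markerSite(panel, "vgsc", 958, "F")
#' annotateVariant(panel, site$amplicon, site$pos, site$ref, site$alt)
#' @export
annotateVariant <- function(panel, amplicon, pos, ref, alt) {
  gm <- geneModel(panel, amplicon)
  base <- data.frame(amplicon = amplicon, pos = pos, ref = ref, alt = alt,
                     gene = NA_character_, effect = "non_coding",
                     native_codon = NA_integer_, ref_aa = NA_character_,
                     alt_aa = NA_character_, aa_change = NA_character_,
                     ortholog_labels = NA_character_,
                     marker_hit = NA_character_, composite = FALSE)
  if (is.null(gm)) return(base)
  base$gene <- gm$gene
  off <- panel@genomicOffset[[amplicon]]
  cpos <- off + pos
  isIns <- startsWith(alt, "+")
  isDel <- startsWith(alt, "-")
  span <- if (isDel) cpos + seq_len(as.integer(substring(alt, 2))) - 1L
          else cpos
  iv <- gm$cds_intervals
  inCds <- vapply(span, function(x)
    any(x >= iv[, 1] & x < iv[, 2]), logical(1))
  if (!any(inCds)) { base$effect <- "non_coding"; return(base) }
  if (!all(inCds)) {
    base$composite <- TRUE
    base$effect <- if (isDel) "frameshift" else "non_coding"
  }
  # CDS coordinate of the (first affected) in-CDS contig position
  cdsCoord <- function(x) {
    tot <- 0L
    if (gm$strand == "+") {
      for (r in seq_len(nrow(iv))) {
        if (x >= iv[r, 1] && x < iv[r, 2]) return(tot + (x - iv[r, 1]))
        tot <- tot + (iv[r, 2] - iv[r, 1])
      }
    } else {
      for (r in seq_len(nrow(iv))) {     # intervals ordered 5'->3' on minus
        if (x >= iv[r, 1] && x < iv[r, 2]) return(tot + (iv[r, 2] - 1L - x))
        tot <- tot + (iv[r, 2] - iv[r, 1])
      }
    }
    NA_integer_
  }
  x0 <- span[inCds][1L]
  cc <- cdsCoord(x0)
  codonNum <- gm$codon_offset + cc %/% 3L
  base$native_codon <- codonNum
  if (isIns || isDel) {
    len <- if (isIns) nchar(substring(alt, 2)) else
      as.integer(substring(alt, 2))
    base$effect <- if (len %% 3L != 0L) "frameshift" else "inframe_indel"
    return(base)
  }
  # build ref and alt codons on the coding strand
  phase <- cc %% 3L
  ampSeq <- refSequence(panel, amplicon)
  if (gm$strand == "+") {
    codonStartContig <- cpos - phase
    a <- codonStartContig - off                 # 0-based amplicon coord
    refCodon <- substr(ampSeq, a + 1L, a + 3L)
    altCodon <- refCodon
    substr(altCodon, phase + 1L, phase + 1L) <- alt
  } else {
    codonPosContig <- cpos + phase - 0:2        # descending, codon base 1..3
    a <- min(codonPosContig) - off
    plusCodon <- substr(ampSeq, a + 1L, a + 3L)
    refCodon <- revComp(plusCodon)
    altCodon <- refCodon
    substr(altCodon, phase + 1L, phase + 1L) <- revComp(alt)
  }
  refAa <- translateCodon(refCodon)
  altAa <- translateCodon(altCodon)
  base$ref_aa <- refAa; base$alt_aa <- altAa
  base$aa_change <- paste0(refAa, codonNum, altAa)
  base$effect <- if (refAa == altAa) "synonymous"
                 else if (altAa == "*") "nonsense" else "missense"
  on <- gm$ortholog_numbering
  if (length(on)) {
    base$ortholog_labels <- paste(
      sprintf("%s%d%s (%s)", refAa, codonNum + on, altAa, names(on)),
      collapse = ", ")
  }
  mk <- markerTable(panel)
  hit <- which(mk$gene == gm$gene & mk$native_codon == codonNum &
                 mk$alt_aa == altAa & mk$ref_aa == refAa)
  if (length(hit)) base$marker_hit <- mk$ortholog_label[hit[1L]]
  base
}

#' Annotate a table of variant calls
#'
#' @param calls data.frame with \code{amplicon}, \code{pos}, \code{ref},
#'   \code{alt} columns (one row per variant key; duplicates are fine).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @return data.frame of annotations, one row per distinct key.
#' @export
annotateCalls <- function(calls, panel) {
  keys <- unique(calls[, c("amplicon", "pos", "ref", "alt"), drop = FALSE])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i)
    annotateVariant(panel, keys$amplicon[i], keys$pos[i], keys$ref[i],
                    keys$alt[i])))
}

#' Resistance-marker report
#'
#' Per marker: the number and percentage of samples carrying the alternate
#' allele (heterozygous or homozygous alternate), the allele frequency
#' (het + 2 x hom_alt over twice the genotyped samples), and the carrier
#' list. The denominator is the number of samples with a genotype call at
#' the marker site: samples whose pileup depth at the site reaches
#' \code{minDepth} when per-sample depths are supplied, otherwise every
#' sample present in the genotype table. Denominators are printed beside
#' every percentage.
#'
#' @param genotypes combined classified call records (all samples).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param pileups optional named list of \linkS4class{PileupMatrix}
#'   (\code{"<sample>|<amplicon>"} keys) used to count genotyped samples.
#' @param cfg A \linkS4class{FilterConfig}.
#' @return data.frame: \code{gene}, \code{native_label},
#'   \code{ortholog_label}, \code{carriers}, \code{genotyped},
#'   \code{percent}, \code{allele_frequency}, \code{carrier_samples}.
#' @export
resistanceReport <- function(genotypes, panel, pileups = NULL,
                             cfg = filterConfig()) {
  mk <- markerTable(panel)
  out <- NULL
  # sample universe: every sample with a pileup (screened), not only the
  # samples that produced variant records — no-record samples are hom-ref
  allSamples <- if (!is.null(pileups)) {
    unique(vapply(strsplit(names(pileups), "|", fixed = TRUE), `[`,
                  character(1), 1L))
  } else {
    unique(genotypes$sample_id)
  }
  for (i in seq_len(nrow(mk))) {
    site <- markerSite(panel, mk$gene[i], mk$native_codon[i], mk$alt_aa[i],
                       refAa = mk$ref_aa[i])
    natLabel <- paste0(mk$ref_aa[i], mk$native_codon[i], mk$alt_aa[i])
    if (is.null(site)) next
    rows <- genotypes[genotypes$amplicon == site$amplicon &
                        genotypes$pos == site$pos &
                        genotypes$alt == site$alt, , drop = FALSE]
    het <- rows$sample_id[rows$genotype == "het"]
    hom <- rows$sample_id[rows$genotype == "hom_alt"]
    carriers <- unique(c(het, hom))
    if (!is.null(pileups)) {
      genotyped <- sum(vapply(allSamples, function(s) {
        p <- pileups[[paste(s, site$amplicon, sep = "|")]]
        !is.null(p) && pileupDepth(p)[site$pos + 1L] >= cfg@minDepth
      }, logical(1)))
    } else {
      genotyped <- length(allSamples)
    }
    af <- if (genotyped > 0)
      (length(het) + 2L * length(hom)) / (2L * genotyped) else NA_real_
    out <- rbind(out, data.frame(
      gene = mk$gene[i], native_label = natLabel,
      ortholog_label = mk$ortholog_label[i],
      carriers = length(carriers), genotyped = genotyped,
      percent = if (genotyped > 0) 100 * length(carriers) / genotyped
                else NA_real_,
      allele_frequency = af,
      carrier_samples = paste(sort(carriers), collapse = ",")))
  }
  out %||% data.frame()
}

#' @rdname resistanceReport
#' @param report a marker report.
#' @param path output TSV path.
#' @export
writeResistanceReport <- function(report, path) {
  rep2 <- report
  rep2$percent <- fmtNum(rep2$percent)
  rep2$allele_frequency <- fmtNum(rep2$allele_frequency)
  utils::write.table(rep2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
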
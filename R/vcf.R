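#' Write a multi-sample VCF 4.2 for one pool
#'
#' One row per retained-or-flagged variant key, one genotype column per
#' sample. Positions are 1-based per VCF; internal single-event indel
#' alleles are converted to anchored REF/ALT strings. The FILTER field
#' carries the site and replication flags (\code{min_dp}, \code{min_ad},
#' \code{min_qual}, \code{singleton}, \code{single_pool},
#' \code{single_caller}); INFO carries the caller provenance and per-sample
#' alternate-allele fractions. No timestamp is written, so identical runs
#' produce byte-identical files.
#'
#' @param genotypes flagged, classified call records of all samples in the
#'   pool (output of \code{\link{crossSampleFilter}}).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param sheet A \linkS4class{SampleSheet}.
#' @param path output path.
#' @param annotations optional data.frame from \code{\link{annotateCalls}}
#'   keyed like the genotypes; adds ANN-style INFO subfields
#'   (\code{effect|gene|codon|aa_change}).
#' @return \code{path}, invisibly.
#' @export
writePoolVcf <- function(genotypes, panel, sheet, path,
                         annotations = NULL) {
  d <- sheetData(sheet)
  samples <- d$sample_id
  g <- genotypes
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=stephseq",
    vapply(ampliconNames(panel), function(a)
      sprintf("##contig=<ID=%s,length=%d>", a,
              nchar(refSequence(panel, a))), character(1)),
    "##FILTER=<ID=min_dp,Description=\"Depth below minimum\">",
    "##FILTER=<ID=min_ad,Description=\"Alternate allele depth below minimum\">",
    "##FILTER=<ID=min_qual,Description=\"Site quality below minimum\">",
    "##FILTER=<ID=singleton,Description=\"Carried by fewer samples than required\">",
    "##FILTER=<ID=single_pool,Description=\"Carriers confined to one pool\">",
    "##FILTER=<ID=single_caller,Description=\"Emitted by one caller only\">",
    "##FILTER=<ID=allele_conflict,Description=\"Conflicting alternate alleles at this position\">",
    "##INFO=<ID=CS,Number=1,Type=String,Description=\"Caller set\">",
    "##INFO=<ID=AFS,Number=.,Type=String,Description=\"Per-sample alternate allele fractions\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"effect|gene|codon|aa_change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines <- header
  if (nrow(g)) {
    key <- paste(g$amplicon, g$pos, g$ref, g$alt, sep = "\r")
    ord <- order(g$amplicon, g$pos, g$alt)
    ukey <- unique(key[ord])
    gtCode <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                no_call = "./.")
    for (k in ukey) {
      rows <- g[key == k, , drop = FALSE]
      r1 <- rows[1L, ]
      ref <- refSequence(panel, r1$amplicon)
      if (r1$type == "snp") {
        POS <- r1$pos + 1L; REF <- r1$ref; ALT <- r1$alt
      } else if (r1$type == "ins") {
        POS <- r1$pos + 1L
        REF <- substr(ref, r1$pos + 1L, r1$pos + 1L)
        ALT <- paste0(REF, substring(r1$alt, 2))
      } else {                                    # deletion of N bases
        n <- as.integer(substring(r1$alt, 2))
        POS <- r1$pos                              # anchor base before
        REF <- substr(ref, r1$pos, r1$pos + n)
        ALT <- substr(ref, r1$pos, r1$pos)
      }
      flags <- unique(unlist(strsplit(rows$flags, ";")))
      flags <- setdiff(flags, "")
      FILTER <- if (length(flags)) paste(flags, collapse = ";") else "PASS"
      afs <- paste(sprintf("%s:%s", rows$sample_id,
                           fmtNum(rows$alt_fraction)), collapse = ",")
      info <- sprintf("CS=%s;AFS=%s", r1$caller_set, afs)
      if (!is.null(annotations)) {
        ai <- which(annotations$amplicon == r1$amplicon &
                      annotations$pos == r1$pos &
                      annotations$alt == r1$alt)
        if (length(ai)) {
          a <- annotations[ai[1L], ]
          info <- paste0(info, sprintf(";ANN=%s|%s|%s|%s", a$effect,
                                       a$gene %||% ".",
                                       a$native_codon %||% ".",
                                       a$aa_change %||% "."))
        }
      }
      cols <- vapply(samples, function(s) {
        i <- which(rows$sample_id == s)
        if (!length(i)) return("./.")
        r <- rows[i[1L], ]
        sprintf("%s:%d:%d,%d:%s", gtCode[[r$genotype]], r$DP, r$AD_ref,
                r$AD_alt, fmtNum(r$alt_fraction))
      }, character(1))
      lines <- c(lines, paste(c(
        r1$amplicon, POS, ".", REF, ALT, fmtNum(min(r1$site_qual, 5000)),
        FILTER, info, "GT:DP:AD:AF", cols), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
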
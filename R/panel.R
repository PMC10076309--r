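#' Construct an AmpliconPanel
#'
#' Low-level constructor; most users start from \code{\link{buildDefaultPanel}}
#' or \code{\link{readPanel}}.
#'
#' @param amplicons named character vector or \code{DNAStringSet} of amplicon
#'   reference sequences (each starting with its forward primer and ending
#'   with the reverse complement of its reverse primer).
#' @param primers data.frame with columns \code{amplicon}, \code{fwd},
#'   \code{rev}.
#' @param targetLocus named character, gene per amplicon.
#' @param genomicOffset named integer, contig offset per amplicon.
#' @param geneModels named list of gene models (see
#'   \linkS4class{AmpliconPanel}).
#' @param markers data.frame of resistance markers.
#' @return An \linkS4class{AmpliconPanel}.
#' @export
ampliconPanel <- function(amplicons, primers, targetLocus,
                          genomicOffset = NULL, geneModels = list(),
                          markers = emptyMarkerTable()) {
  if (!is(amplicons, "DNAStringSet"))
    amplicons <- Biostrings::DNAStringSet(amplicons)
  nm <- names(amplicons)
  if (is.null(genomicOffset)) {
    genomicOffset <- setNames(rep(0L, length(nm)), nm)
  }
  new("AmpliconPanel", amplicons = amplicons, primers = primers,
      targetLocus = targetLocus,
      genomicOffset = as.integer(genomicOffset)[seq_along(nm)] |>
        setNames(nm),
      geneModels = geneModels, markers = markers)
}

emptyMarkerTable <- function() {
  data.frame(gene = character(0), native_codon = integer(0),
             ref_aa = character(0), alt_aa = character(0),
             ortholog_label = character(0),
             known_association = character(0))
}

#' Accessors for AmpliconPanel
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param amplicon Amplicon name.
#' @return \code{ampliconNames}: character vector of amplicon names.
#'   \code{refSequence}: character reference sequence.
#'   \code{primerPair}: list with \code{fwd} and \code{rev}.
#'   \code{markerTable}: data.frame of resistance markers.
#'   \code{geneModel}: the gene model list for one amplicon, or NULL.
#' @export
ampliconNames <- function(panel) names(panel@amplicons)

#' @rdname ampliconNames
#' @export
refSequence <- function(panel, amplicon) {
  as.character(panel@amplicons[[amplicon]])
}

#' @rdname ampliconNames
#' @export
primerPair <- function(panel, amplicon) {
  p <- panel@primers[panel@primers$amplicon == amplicon, ]
  list(fwd = p$fwd, rev = p$rev)
}

#' @rdname ampliconNames
#' @export
markerTable <- function(panel) panel@markers

#' @rdname ampliconNames
#' @export
geneModel <- function(panel, amplicon) panel@geneModels[[amplicon]]

# Codon table keyed by codon string
.GENETIC_CODE <- NULL

translateCodon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Internal: draw a random DNA string under the current RNG
randomDNA <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

#' Build the default An. stephensi surveillance panel
#'
#' Returns the assay used throughout the package: 10 amplicons across 6 loci
#' — four voltage-gated sodium channel domains (VGSCI, VGSCII, VGSCIII/IV),
#' two acetylcholinesterase-1 regions (ACE1_I, ACE1_II), two
#' GABA-receptor/rdl regions (Rdl1, Rdl2), GSTe2, and the phylogenetic
#' markers ITS2 and CO1 — each with a synthetic ~500 bp reference, 20 bp
#' primers, gene models for the coding loci, and the seven known resistance
#' markers scored by the assay (vgsc L958F, rdl A296S/V327I/T345S, ace1
#' G119S/N177D, GSTe2 V189L). Cross-species ortholog numbering is attached
#' to vgsc (+56, Musca domestica: L958F -> L1014F) and rdl (+5, Drosophila
#' melanogaster: A296S -> A301S).
#'
#' The reference sequences are synthetic: generated from a seeded uniform
#' base distribution, with the marker codons set so that each published
#' resistance substitution is reachable by a single nucleotide change.
#' Real primer/reference sequences can be substituted by editing the panel
#' config file written by \code{\link{writePanel}} and reloading it with
#' \code{\link{readPanel}}; coordinates are amplicon-local throughout, so no
#' genome build is required.
#'
#' @param ampliconLength integer length of each synthetic reference (bp).
#' @param primerLength integer primer length (bp).
#' @return An \linkS4class{AmpliconPanel} with 10 amplicons.
#' @examples
#' panel <- buildDefaultPanel()
#' ampliconNames(panel)
#' markerTable(panel)
#' @export
buildDefaultPanel <- function(ampliconLength = 500L, primerLength = 20L) {
  withSeed(20230405L, {
    defs <- list(
      # name, gene, strand (NA = non-coding), codon_offset, marker codons
      list("ACE1_I",      "ace1",  "+", 80L),
      list("ACE1_II",     "ace1",  "+", 140L),
      list("CO1",         "cox1",  NA,  NA),
      list("GSTe2",       "gste2", "-", 150L),
      list("ITS2",        "its2",  NA,  NA),
      list("Rdl1",        "rdl",   "+", 260L),
      list("Rdl2",        "rdl",   "+", 300L),
      list("VGSCI",       "vgsc",  "+", 880L),
      list("VGSCII",      "vgsc",  "+", 920L),
      list("VGSCIII/IV",  "vgsc",  "+", 1520L)
    )
    # marker codons to plant: amplicon, native codon, ref codon (in gene
    # reading frame), so that the published substitution is one SNP away
    plant <- list(
      list("ACE1_I",  119L, "GGC"),   # G119 -> AGC (S)
      list("ACE1_II", 177L, "AAT"),   # N177 -> GAT (D)
      list("GSTe2",   189L, "GTG"),   # V189 -> TTG (L)
      list("Rdl1",    296L, "GCA"),   # A296 -> TCA (S)
      list("Rdl2",    327L, "GTA"),   # V327 -> ATA (I)
      list("Rdl2",    345L, "ACA"),   # T345 -> TCA (S)
      list("VGSCII",  958L, "CTT")    # L958 -> TTT (F)
    )
    ortho <- list(vgsc = c("Musca domestica" = 56L),
                  rdl  = c("Drosophila melanogaster" = 5L))

    L <- ampliconLength
    cdsStart <- 60L          # amplicon-local CDS window, clear of primers
    cdsLen <- 300L
    refs <- character(0); genes <- character(0)
    primers <- NULL; models <- list(); offsets <- integer(0)

    for (d in defs) {
      nm <- d[[1]]; gene <- d[[2]]; strand <- d[[3]]; cod0 <- d[[4]]
      ref <- randomDNA(L)
      off <- 1000L
      if (!is.na(strand)) {
        iv <- c(off + cdsStart, off + cdsStart + cdsLen)
        # plant marker reference codons
        for (p in plant) if (p[[1]] == nm) {
          codon <- p[[2]]; refcodon <- p[[3]]
          idx <- codon - cod0           # 0-based codon index within window
          stopifnot(idx >= 0, idx < cdsLen %/% 3L)
          if (strand == "+") {
            a <- cdsStart + 3L * idx + 1L  # 1-based amplicon pos of codon
            substr(ref, a, a + 2L) <- refcodon
          } else {
            # minus strand: codon idx counts from the 3' (high-coordinate)
            # end of the interval; plus strand holds the revcomp codon
            a <- cdsStart + cdsLen - 3L * (idx + 1L) + 1L
            substr(ref, a, a + 2L) <- revComp(refcodon)
          }
        }
        models[[nm]] <- list(
          gene = gene, strand = strand,
          cds_intervals = matrix(iv, ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))),
          codon_offset = cod0,
          ortholog_numbering = ortho[[gene]] %||% integer(0))
      }
      fwd <- substr(ref, 1L, primerLength)
      rev <- revComp(substr(ref, L - primerLength + 1L, L))
      refs <- c(refs, setNames(ref, nm))
      genes <- c(genes, setNames(gene, nm))
      offsets <- c(offsets, setNames(off, nm))
      primers <- rbind(primers,
                       data.frame(amplicon = nm, fwd = fwd, rev = rev))
    }

    markers <- data.frame(
      gene = c("vgsc", "rdl", "rdl", "rdl", "ace1", "ace1", "gste2"),
      native_codon = c(958L, 296L, 327L, 345L, 119L, 177L, 189L),
      ref_aa = c("L", "A", "V", "T", "G", "N", "V"),
      alt_aa = c("F", "S", "I", "S", "S", "D", "L"),
      known_association = c(
        "kdr; pyrethroid/DDT resistance",
        "cyclodiene (dieldrin) resistance; fipronil/broflanilide relevance",
        "secondary rdl substitution seen in tandem with A296S",
        "secondary rdl substitution seen in tandem with A296S",
        "carbamate/organophosphate resistance",
        "not previously implicated in insecticide resistance",
        "not previously implicated in insecticide resistance"))
    markers$ortholog_label <- vapply(seq_len(nrow(markers)), function(i) {
      o <- ortho[[markers$gene[i]]]
      if (length(o))
        paste0(markers$ref_aa[i], markers$native_codon[i] + o[[1]],
               markers$alt_aa[i])
      else
        paste0(markers$ref_aa[i], markers$native_codon[i], markers$alt_aa[i])
    }, character(1))
    markers <- markers[, c("gene", "native_codon", "ref_aa", "alt_aa",
                           "ortholog_label", "known_association")]

    ampliconPanel(refs, primers, genes, offsets, models, markers)
  })
}

#' Locate a resistance-marker codon on its panel amplicon
#'
#' Maps a marker (gene + native codon + amino-acid change) back to amplicon
#' coordinates: the 0-based amplicon position, reference base and alternate
#' base (both on the amplicon's plus strand) of the single-nucleotide change
#' that produces the marker's amino-acid substitution. Used by the simulator
#' to plant resistance alleles and by the reporting layer.
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param gene,nativeCodon,altAa identify the marker.
#' @param refAa optional expected reference amino acid; amplicons whose
#'   reference codon translates differently are skipped (needed when two
#'   amplicons of one gene have overlapping codon ranges).
#' @return list(amplicon, pos, ref, alt) or NULL when no single-base change
#'   produces the substitution.
#' @export
markerSite <- function(panel, gene, nativeCodon, altAa, refAa = NULL) {
  for (nm in ampliconNames(panel)) {
    gm <- panel@geneModels[[nm]]
    if (is.null(gm) || gm$gene != gene) next
    iv <- gm$cds_intervals
    ncod <- sum(iv[, 2] - iv[, 1]) %/% 3L
    idx <- nativeCodon - gm$codon_offset
    if (idx < 0 || idx >= ncod) next
    off <- panel@genomicOffset[[nm]]
    ref <- refSequence(panel, nm)
    if (gm$strand == "+") {
      a <- (iv[1, 1] - off) + 3L * idx          # 0-based amplicon pos
      plusCodon <- substr(ref, a + 1L, a + 3L)
      codon <- plusCodon
      codonPos <- a + 0:2
    } else {
      a <- (iv[1, 2] - off) - 3L * (idx + 1L)
      plusCodon <- substr(ref, a + 1L, a + 3L)
      codon <- revComp(plusCodon)
      codonPos <- a + 2:0                       # codon base i at descending pos
    }
    if (!is.null(refAa) &&
        !identical(unname(translateCodon(codon)), refAa)) next
    for (i in 1:3) for (b in DNA_BASES4) {
      cd <- codon
      substr(cd, i, i) <- b
      if (cd == codon) next
      if (identical(unname(translateCodon(cd)), altAa)) {
        pos <- codonPos[i]
        refBase <- substr(ref, pos + 1L, pos + 1L)
        altBase <- if (gm$strand == "+") b else revComp(b)
        return(list(amplicon = nm, pos = pos, ref = refBase, alt = altBase))
      }
    }
  }
  NULL
}

#' Screen all primer pairs for 3'-end dimerization potential
#'
#' For every unordered pair of primers in the panel (forward and reverse of
#' every amplicon, including a primer against itself), computes the length
#' of the longest perfect reverse-complement match that involves either
#' primer's 3' terminus — the classic primer-dimer seed — and flags pairs
#' whose match length exceeds \code{max3primeComplement}.
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param max3primeComplement integer; pairs with a longer 3'-anchored
#'   perfect complement are flagged (default 5).
#' @return data.frame with columns \code{primer1}, \code{primer2},
#'   \code{complement_len}, \code{flagged}.
#' @examples
#' screenPrimerDimers(buildDefaultPanel())
#' @export
screenPrimerDimers <- function(panel, max3primeComplement = 5L) {
  prm <- c(setNames(panel@primers$fwd, paste0(panel@primers$amplicon, "_F")),
           setNames(panel@primers$rev, paste0(panel@primers$amplicon, "_R")))
  nms <- names(prm)
  out <- NULL
  for (i in seq_along(prm)) for (j in i:length(prm)) {
    len <- max(threePrimeComplement(prm[[i]], prm[[j]]),
               threePrimeComplement(prm[[j]], prm[[i]]))
    out <- rbind(out, data.frame(
      primer1 = nms[i], primer2 = nms[j], complement_len = len,
      flagged = len > max3primeComplement))
  }
  out
}

# Longest k such that the last k bases of `a` are the reverse complement of
# some k-window of `b` (so a's 3' end can anneal to b).
threePrimeComplement <- function(a, b) {
  la <- nchar(a)
  for (k in seq(min(la, nchar(b)), 1L)) {
    suf <- substr(a, la - k + 1L, la)
    if (grepl(revComp(suf), b, fixed = TRUE)) return(k)
  }
  0L
}

#' Write / read a panel configuration file
#'
#' The panel is serialized to a structured YAML file: one \code{amplicons}
#' section (name, target locus, genomic offset, primers, reference), one
#' \code{gene_models} section and one \code{markers} section. The file
#' round-trips byte-identically through \code{readPanel} /
#' \code{writePanel}, and is the supported route for substituting real
#' primer and reference sequences for the synthetic defaults.
#'
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param path file path of the panel config.
#' @return \code{writePanel}: \code{path}, invisibly. \code{readPanel}: an
#'   \linkS4class{AmpliconPanel}.
#' @export
writePanel <- function(panel, path) {
  nm <- ampliconNames(panel)
  amps <- lapply(nm, function(a) {
    pp <- primerPair(panel, a)
    list(name = a, target_locus = unname(panel@targetLocus[[a]]),
         genomic_offset = unname(panel@genomicOffset[[a]]),
         fwd_primer = pp$fwd, rev_primer = pp$rev,
         reference = refSequence(panel, a))
  })
  gms <- lapply(nm[nm %in% names(panel@geneModels)], function(a) {
    gm <- panel@geneModels[[a]]
    list(amplicon = a, gene = gm$gene, strand = gm$strand,
         cds_intervals = lapply(seq_len(nrow(gm$cds_intervals)), function(i)
           as.integer(gm$cds_intervals[i, ])),
         codon_offset = gm$codon_offset,
         ortholog_numbering = as.list(gm$ortholog_numbering))
  })
  mk <- lapply(seq_len(nrow(panel@markers)), function(i)
    as.list(panel@markers[i, ]))
  txt <- yaml::as.yaml(list(amplicons = amps, gene_models = gms,
                            markers = mk))
  writeLines(txt, path, sep = "")
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  cfg <- yaml::read_yaml(path)
  refs <- vapply(cfg$amplicons, `[[`, character(1), "reference")
  names(refs) <- vapply(cfg$amplicons, `[[`, character(1), "name")
  primers <- do.call(rbind, lapply(cfg$amplicons, function(a)
    data.frame(amplicon = a$name, fwd = a$fwd_primer, rev = a$rev_primer)))
  genes <- vapply(cfg$amplicons, `[[`, character(1), "target_locus")
  names(genes) <- names(refs)
  offs <- vapply(cfg$amplicons, function(a) as.integer(a$genomic_offset),
                 integer(1))
  names(offs) <- names(refs)
  models <- list()
  for (g in cfg$gene_models) {
    iv <- do.call(rbind, lapply(g$cds_intervals, as.integer))
    colnames(iv) <- c("start", "end")
    on <- unlist(g$ortholog_numbering)
    models[[g$amplicon]] <- list(
      gene = g$gene, strand = g$strand, cds_intervals = iv,
      codon_offset = as.integer(g$codon_offset),
      ortholog_numbering = if (length(on)) {
        storage.mode(on) <- "integer"; on
      } else integer(0))
  }
  mk <- if (length(cfg$markers)) {
    do.call(rbind, lapply(cfg$markers, function(m)
      data.frame(gene = m$gene, native_codon = as.integer(m$native_codon),
                 ref_aa = m$ref_aa, alt_aa = m$alt_aa,
                 ortholog_label = m$ortholog_label,
                 known_association = m$known_association)))
  } else emptyMarkerTable()
  ampliconPanel(refs, primers, genes, offs, models, mk)
}
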
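#' Align trimmed read pairs to their amplicon reference
#'
#' Amplicon-targeted alignment: because demultiplexing already fixes the
#' amplicon and the primer anchors the read, each mate has a known expected
#' placement (read 1 starts right after the forward primer; the
#' reverse-complemented read 2 ends right before the reverse primer). Reads
#' matching the reference at that placement within
#' \code{fastMismatchFrac} are placed ungapped; the remainder (indel
#' carriers, clipped or junk reads) fall through to a local affine-gap
#' alignment (\code{\link[Biostrings]{pairwiseAlignment}}). Alignments whose
#' soft-clipped run exceeds \code{maxClip} bases, or whose score falls below
#' \code{minScoreFrac} of the perfect-match score, are discarded and
#' counted. Overlapping mate bases are reconciled: agreeing calls keep the
#' higher phred; disagreeing calls keep the higher-phred base with its
#' quality capped at the difference of the two.
#'
#' @param seq1,qual1,seq2,qual2 parallel character vectors of trimmed mates
#'   (barcode and primer removed), as produced by
#'   \code{\link{demultiplexPool}}.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param amplicon amplicon name.
#' @param maxClip maximum allowed soft-clip run (default 50).
#' @param minScoreFrac score floor as a fraction of the perfect score.
#' @param fastMismatchFrac mismatch fraction admitted by the ungapped fast
#'   path.
#' @return list with \code{obs} (data.frame \code{frag}, \code{pos} 0-based,
#'   \code{base} in 1:4 = A/C/G/T, \code{qual}), \code{ins} and \code{del}
#'   event data.frames, and \code{discarded} fragment count.
#' @export
alignToAmplicon <- function(seq1, qual1, seq2, qual2, panel, amplicon,
                            maxClip = 50L, minScoreFrac = 0.6,
                            fastMismatchFrac = 0.15) {
  ref <- refSequence(panel, amplicon)
  pp <- primerPair(panel, amplicon)
  p1 <- nchar(pp$fwd); p2 <- nchar(pp$rev)
  L <- nchar(ref)
  refInt <- utf8ToInt(ref)
  n <- length(seq1)
  obsF <- obsP <- obsB <- obsQ <- vector("list", 2L * n)
  insL <- delL <- list()
  discarded <- 0L
  baseCode <- c(A = 1L, C = 2L, G = 3L, T = 4L)

  placeMate <- function(s, q, expOff) {
    # returns list(pos, base, qual) or "align" marker or NULL (unplaceable)
    len <- nchar(s)
    if (len == 0L) return(NULL)
    si <- utf8ToInt(s)
    qi <- as.integer(charToRaw(q)) - 33L
    if (expOff + len <= L) {
      rseg <- refInt[(expOff + 1L):(expOff + len)]
      mism <- sum(si != rseg)
      if (mism <= max(3L, ceiling(fastMismatchFrac * len)))
        return(list(pos = expOff + seq_len(len) - 1L, base = si, qual = qi,
                    fast = TRUE))
    }
    "align"
  }

  alignMate <- function(s, q) {
    len <- nchar(s)
    pa <- Biostrings::pairwiseAlignment(
      pattern = s, subject = ref, type = "local",
      substitutionMatrix = .nucSubMat(), gapOpening = 6, gapExtension = 3)
    if (Biostrings::score(pa) < minScoreFrac * 2 * len) return(NULL)
    ps <- Biostrings::start(Biostrings::pattern(pa))
    pe <- Biostrings::end(Biostrings::pattern(pa))
    if (max(ps - 1L, len - pe) > maxClip) return(NULL)
    pstr <- strsplit(as.character(Biostrings::pattern(pa)), "",
                     fixed = TRUE)[[1]]
    sstr <- strsplit(as.character(Biostrings::subject(pa)), "",
                     fixed = TRUE)[[1]]
    qi <- as.integer(charToRaw(q)) - 33L
    refpos <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based
    pidx <- ps - 1L                                            # consumed
    pos <- base <- qual <- integer(0)
    ins <- NULL; del <- NULL
    k <- 1L
    while (k <= length(pstr)) {
      pc <- pstr[k]; sc <- sstr[k]
      if (pc != "-" && sc != "-") {
        pidx <- pidx + 1L
        pos <- c(pos, refpos); base <- c(base, utf8ToInt(pc))
        qual <- c(qual, qi[pidx])
        refpos <- refpos + 1L
        k <- k + 1L
      } else if (sc == "-") {            # insertion relative to reference
        run <- k
        while (run <= length(sstr) && sstr[run] == "-") run <- run + 1L
        seqIns <- paste(pstr[k:(run - 1L)], collapse = "")
        pidx <- pidx + (run - k)
        ins <- rbind(ins, data.frame(pos = refpos - 1L, seq = seqIns))
        k <- run
      } else {                           # deletion in the read
        run <- k
        while (run <= length(pstr) && pstr[run] == "-") run <- run + 1L
        del <- rbind(del, data.frame(pos = refpos, len = run - k))
        refpos <- refpos + (run - k)
        k <- run
      }
    }
    list(pos = pos, base = base, qual = qual, ins = ins, del = del,
         fast = FALSE)
  }

  r2rc <- if (n) revComp(seq2) else character(0)
  q2rev <- vapply(qual2, function(q)
    intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  for (i in seq_len(n)) {
    r2 <- r2rc[i]
    q2 <- q2rev[i]
    exp2 <- L - p2 - nchar(r2)
    m1 <- placeMate(seq1[i], qual1[i], p1)
    m2 <- placeMate(r2, q2, exp2)
    if (identical(m1, "align")) m1 <- alignMate(seq1[i], qual1[i])
    if (identical(m2, "align")) m2 <- alignMate(r2, q2)
    if (is.null(m1) && is.null(m2)) { discarded <- discarded + 1L; next }
    pos <- c(m1$pos, m2$pos)
    base <- c(m1$base, m2$base)
    qual <- c(m1$qual, m2$qual)
    mate <- c(rep(1L, length(m1$pos)), rep(2L, length(m2$pos)))
    # reconcile overlapping mate bases
    if (anyDuplicated(pos)) {
      o <- order(pos, mate)
      pos <- pos[o]; base <- base[o]; qual <- qual[o]
      dup <- which(duplicated(pos))
      if (length(dup)) {
        first <- dup - 1L
        agree <- base[dup] == base[first]
        keepQ <- ifelse(agree, pmax(qual[dup], qual[first]),
                        abs(qual[dup] - qual[first]))
        keepB <- ifelse(qual[dup] >= qual[first], base[dup], base[first])
        base[first] <- keepB
        qual[first] <- keepQ
        pos <- pos[-dup]; base <- base[-dup]; qual <- qual[-dup]
      }
    }
    keep <- base %in% c(65L, 67L, 71L, 84L)   # A C G T only
    obsF[[i]] <- rep(i, sum(keep))
    obsP[[i]] <- pos[keep]
    obsB[[i]] <- baseCode[intToUtf8(base[keep], multiple = TRUE)]
    obsQ[[i]] <- qual[keep]
    for (m in list(m1, m2)) {
      if (!is.null(m$ins)) insL[[length(insL) + 1L]] <-
          cbind(frag = i, m$ins)
      if (!is.null(m$del)) delL[[length(delL) + 1L]] <-
          cbind(frag = i, m$del)
    }
  }
  obs <- data.frame(
    frag = unlist(obsF) %||% integer(0),
    pos = unlist(obsP) %||% integer(0),
    base = unname(unlist(obsB)) %||% integer(0),
    qual = unlist(obsQ) %||% integer(0))
  list(obs = obs,
       ins = if (length(insL)) do.call(rbind, insL) else
         data.frame(frag = integer(0), pos = integer(0), seq = character(0)),
       del = if (length(delL)) do.call(rbind, delL) else
         data.frame(frag = integer(0), pos = integer(0), len = integer(0)),
       discarded = discarded, nFragments = n)
}

.nucSubMatCache <- new.env(parent = emptyenv())
.nucSubMat <- function() {
  if (is.null(.nucSubMatCache$m))
    .nucSubMatCache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE)
  .nucSubMatCache$m
}

#' Build a pileup from read placements
#'
#' Collapses per-base placements into the \linkS4class{PileupMatrix}
#' substrate for calling and consensus. Bases with phred below
#' \code{minBaseQual} are excluded from all counts (the minimum called-base
#' quality filter); deletion-spanned positions are counted in the DEL row,
#' and insertion/deletion events are aggregated into single-event allele
#' records.
#'
#' @param aln result of \code{\link{alignToAmplicon}}.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param amplicon,sample identifiers for the bin.
#' @param minBaseQual minimum phred per called base (default 30).
#' @return A \linkS4class{PileupMatrix}.
#' @export
buildPileup <- function(aln, panel, amplicon, sample,
                        minBaseQual = 30L) {
  ref <- refSequence(panel, amplicon)
  L <- nchar(ref)
  obs <- aln$obs[aln$obs$qual >= minBaseQual, , drop = FALSE]
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "DEL"), NULL))
  qlevels <- sort(unique(obs$qual))
  qc <- array(0L, dim = c(4L, L, max(1L, length(qlevels))))
  if (nrow(obs)) {
    tab <- table(base = factor(obs$base, levels = 1:4),
                 pos = factor(obs$pos, levels = 0:(L - 1L)))
    counts[1:4, ] <- as.integer(tab)
    qidx <- match(obs$qual, qlevels)
    tq <- table(base = factor(obs$base, levels = 1:4),
                pos = factor(obs$pos, levels = 0:(L - 1L)),
                q = factor(qidx, levels = seq_along(qlevels)))
    qc <- array(as.integer(tq), dim = dim(tq))
  }
  dels <- aln$del
  if (nrow(dels)) {
    for (i in seq_len(nrow(dels))) {
      span <- dels$pos[i] + seq_len(dels$len[i]) - 1L
      span <- span[span < L]
      counts[5L, span + 1L] <- counts[5L, span + 1L] + 1L
    }
    delEv <- stats::aggregate(frag ~ pos + len, dels, length)
    names(delEv)[3] <- "count"
  } else {
    delEv <- data.frame(pos = integer(0), len = integer(0),
                        count = integer(0))
  }
  ins <- aln$ins
  if (nrow(ins)) {
    insEv <- stats::aggregate(frag ~ pos + seq, ins, length)
    names(insEv)[3] <- "count"
  } else {
    insEv <- data.frame(pos = integer(0), seq = character(0),
                        count = integer(0))
  }
  new("PileupMatrix", amplicon = amplicon, sample = sample, ref = ref,
      counts = counts, qualCounts = qc,
      qlevels = as.integer(if (length(qlevels)) qlevels else 0L),
      insertions = insEv, deletions = delEv,
      nFragments = as.integer(aln$nFragments),
      nDiscarded = as.integer(aln$discarded))
}

#' Depth per reference position
#'
#' Total retained observations (base counts plus deletion spans) at each
#' 0-based position.
#'
#' @param p A \linkS4class{PileupMatrix}.
#' @return integer vector of length L.
#' @export
pileupDepth <- function(p) colSums(p@counts)

#' Pileups for every (sample, amplicon) unit of a demultiplexed pool
#'
#' @param dm result of \code{\link{demultiplexPool}}.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param minBaseQual minimum phred per called base.
#' @param ... passed to \code{\link{alignToAmplicon}}.
#' @return named list of \linkS4class{PileupMatrix}, keys
#'   \code{"<sample>|<amplicon>"}.
#' @export
pileupsForPool <- function(dm, panel, minBaseQual = 30L, ...) {
  asg <- dm$assignments
  ok <- asg$reason == "assigned"
  key <- paste(asg$sample_id, asg$amplicon, sep = "|")
  out <- list()
  for (k in unique(key[ok])) {
    i <- which(ok & key == k)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    aln <- alignToAmplicon(dm$reads$seq1[i], dm$reads$qual1[i],
                           dm$reads$seq2[i], dm$reads$qual2[i],
                           panel, parts[2], ...)
    out[[k]] <- buildPileup(aln, panel, parts[2], parts[1],
                            minBaseQual = minBaseQual)
  }
  out
}
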
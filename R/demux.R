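#' Match a 6-bp read prefix against sample-sheet barcodes
#'
#' Returns the indices of all barcodes within \code{maxMismatch} Hamming
#' distance of the prefix, nearest first. With a sheet whose pairwise
#' barcode distance is >= 3 and \code{maxMismatch = 1} there is at most one
#' candidate. Two or more candidates at the same minimal distance are an
#' ambiguity the caller must treat as unassigned.
#'
#' @param prefix 6-character read prefix.
#' @param barcodes character vector of 6-bp barcodes.
#' @param maxMismatch maximum Hamming distance (default 1).
#' @return list(candidates = integer indices at the minimal distance,
#'   distance = that distance, ambiguous = logical).
#' @export
matchBarcode <- function(prefix, barcodes, maxMismatch = 1L) {
  d <- hammingTo(prefix, barcodes)
  ok <- which(d <= maxMismatch)
  if (length(ok) == 0L)
    return(list(candidates = integer(0), distance = NA_integer_,
                ambiguous = FALSE))
  dmin <- min(d[ok])
  cand <- ok[d[ok] == dmin]
  list(candidates = cand, distance = dmin, ambiguous = length(cand) > 1L)
}

#' Assign an amplicon from the primer bases following the barcode
#'
#' Compares the prefix (read bases after the 6-bp barcode) against every
#' forward (or reverse) primer in the panel and returns the amplicon whose
#' primer matches with the fewest mismatches, provided that count is within
#' \code{maxMismatch}; ties between amplicons are returned as unassigned.
#'
#' @param prefix read sequence after barcode removal (at least as long as
#'   the longest primer).
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param maxMismatch maximum primer mismatches (default 2).
#' @param which "fwd" for read 1 primers, "rev" for read 2.
#' @return list(amplicon = name or NA, mismatches, ambiguous).
#' @export
assignAmplicon <- function(prefix, panel, maxMismatch = 2L,
                           which = c("fwd", "rev")) {
  which <- match.arg(which)
  prm <- panel@primers[[which]]
  mm <- vapply(seq_along(prm), function(i) {
    pl <- nchar(prm[i])
    sum(utf8ToInt(substr(prefix, 1L, pl)) != utf8ToInt(prm[i]))
  }, integer(1))
  best <- which(mm <= maxMismatch)
  if (length(best) == 0L)
    return(list(amplicon = NA_character_, mismatches = NA_integer_,
                ambiguous = FALSE))
  mmin <- min(mm[best])
  cand <- best[mm[best] == mmin]
  if (length(cand) > 1L)
    return(list(amplicon = NA_character_, mismatches = mmin,
                ambiguous = TRUE))
  list(amplicon = panel@primers$amplicon[cand], mismatches = mmin,
       ambiguous = FALSE)
}

# Vectorized mismatch counts of fixed-start windows vs one primer
primerMismatches <- function(seqs, primer, from = 7L) {
  pl <- nchar(primer)
  pm <- charMatrix(substr(seqs, from, from + pl - 1L), pl)
  pc <- strsplit(primer, "", fixed = TRUE)[[1]]
  rowSums(pm != matrix(pc, nrow(pm), pl, byrow = TRUE))
}

# 3' quality trim: keep through the last 4-base window with mean phred >=
# minQ, then extend until the first base below minQ. Returns keep lengths.
qualityTrimLength <- function(quals, minQ = 20L, window = 4L) {
  vapply(quals, function(qs) {
    q <- as.integer(charToRaw(qs)) - 33L
    n <- length(q)
    if (n < window) return(if (all(q >= minQ)) n else 0L)
    mw <- stats::filter(q, rep(1 / window, window), sides = 1)
    lastw <- suppressWarnings(max(which(mw >= minQ)))   # window end index
    if (!is.finite(lastw)) return(0L)
    keep <- lastw
    while (keep < n && q[keep + 1L] >= minQ) keep <- keep + 1L
    keep
  }, integer(1), USE.NAMES = FALSE)
}

#' Demultiplex a pooled paired-end amplicon run
#'
#' Assigns every read pair to a (sample, amplicon) unit from its inline
#' barcodes and primer sequences. The 6-bp barcode is read from a fixed
#' window at position 0 of each mate; both mates' barcodes must map to the
#' same sample (the barcode combination), else the pair is unassigned. The
#' amplicon is assigned from the read-1 forward primer and cross-checked
#' against the read-2 reverse primer when that maps. Assigned pairs are
#' trimmed of barcode + primer and 3'-quality trimmed; unassigned pairs are
#' kept untrimmed, with a reason code. Counts are conserved:
#' assigned + unassigned = input pairs.
#'
#' @param r1,r2 FASTQ file paths (gzip fine) or lists as returned by
#'   \code{\link{readFastq}}.
#' @param sheet A \linkS4class{SampleSheet}.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param barcodeMismatch,primerMismatch allowed mismatches (defaults 1, 2).
#' @param qualTrim logical; apply the 3' quality rule (default TRUE).
#' @param outDir optional; when given, per-(sample, amplicon) gzip FASTQ
#'   pairs, an UNASSIGNED pair and a coverage TSV are written.
#' @return list with \code{assignments} (data.frame: \code{read_id},
#'   \code{sample_id}, \code{amplicon}, \code{barcode_mismatches},
#'   \code{primer_mismatches}, \code{reason}), \code{reads} (trimmed
#'   \code{seq1}, \code{qual1}, \code{seq2}, \code{qual2}) and
#'   \code{coverage} (see \code{\link{coverageReport}}).
#' @export
demultiplexPool <- function(r1, r2, sheet, panel, barcodeMismatch = 1L,
                            primerMismatch = 2L, qualTrim = TRUE,
                            outDir = NULL) {
  if (is.character(r1)) r1 <- readFastq(r1)
  if (is.character(r2)) r2 <- readFastq(r2)
  id1 <- sub("[/ ].*$", "", r1$ids)
  id2 <- sub("[/ ].*$", "", r2$ids)
  if (length(id1) != length(id2) || any(id1 != id2))
    stop("mate files are desynchronized (ids differ or out of order)")
  n <- length(id1)
  d <- sheetData(sheet)
  S <- nrow(d)
  empty <- list(
    assignments = data.frame(read_id = character(0), sample_id = character(0),
                             amplicon = character(0),
                             barcode_mismatches = integer(0),
                             primer_mismatches = integer(0),
                             reason = character(0)),
    reads = list(seq1 = character(0), qual1 = character(0),
                 seq2 = character(0), qual2 = character(0)),
    coverage = coverageReport(data.frame(sample_id = character(0),
                                         amplicon = character(0)),
                              sheet, panel, 0L))
  if (n == 0L) return(empty)

  # --- barcode combination -> sample -------------------------------------
  bc1 <- substr(r1$seqs, 1L, 6L)
  bc2 <- substr(r2$seqs, 1L, 6L)
  m1 <- charMatrix(bc1, 6L); m2 <- charMatrix(bc2, 6L)
  df <- dr <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    fc <- strsplit(d$fwd_barcode[s], "", fixed = TRUE)[[1]]
    rc <- strsplit(d$rev_barcode[s], "", fixed = TRUE)[[1]]
    df[, s] <- rowSums(m1 != matrix(fc, n, 6L, byrow = TRUE))
    dr[, s] <- rowSums(m2 != matrix(rc, n, 6L, byrow = TRUE))
  }
  okBoth <- (df <= barcodeMismatch) & (dr <= barcodeMismatch)
  tot <- df + dr
  tot[!okBoth] <- NA_integer_
  minTot <- suppressWarnings(apply(tot, 1L, min, na.rm = TRUE))
  nBest <- rowSums(tot == minTot, na.rm = TRUE)
  sampIdx <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  hasCand <- is.finite(minTot)
  sampIdx[hasCand & nBest == 1L] <-
    max.col(-replace(tot, is.na(tot), 1e9), ties.method = "first")[
      hasCand & nBest == 1L]
  reason[!hasCand] <- "barcode_nomatch"
  reason[hasCand & nBest > 1L] <- "barcode_ambiguous"
  bcMM <- ifelse(is.na(sampIdx), NA_integer_, minTot)

  # --- primer -> amplicon -------------------------------------------------
  prf <- panel@primers
  A <- nrow(prf)
  maxPl <- max(nchar(prf$fwd), nchar(prf$rev))
  longEnough <- nchar(r1$seqs) >= 6L + maxPl & nchar(r2$seqs) >= 6L + maxPl
  mmF <- mmR <- matrix(NA_integer_, n, A)
  for (a in seq_len(A)) {
    mmF[, a] <- primerMismatches(r1$seqs, prf$fwd[a])
    mmR[, a] <- primerMismatches(r2$seqs, prf$rev[a])
  }
  ampIdx <- rep(NA_integer_, n)
  mmFok <- mmF; mmFok[mmF > primerMismatch] <- NA_integer_
  minF <- suppressWarnings(apply(mmFok, 1L, min, na.rm = TRUE))
  nF <- rowSums(mmFok == minF, na.rm = TRUE)
  candF <- max.col(-replace(mmFok, is.na(mmFok), 1e9), ties.method = "first")
  pick <- is.finite(minF) & nF == 1L
  ampIdx[pick] <- candF[pick]
  noAmp <- is.na(ampIdx)
  # cross-check with read-2 primer where it maps
  mmRok <- mmR; mmRok[mmR > primerMismatch] <- NA_integer_
  minR <- suppressWarnings(apply(mmRok, 1L, min, na.rm = TRUE))
  nR <- rowSums(mmRok == minR, na.rm = TRUE)
  candR <- max.col(-replace(mmRok, is.na(mmRok), 1e9), ties.method = "first")
  r2maps <- is.finite(minR) & nR == 1L
  conflict <- !is.na(ampIdx) & r2maps & candR != ampIdx
  ampIdx[conflict] <- NA_integer_
  reason[is.na(reason) & conflict] <- "primer_conflict"
  reason[is.na(reason) & noAmp & is.finite(minF) & nF > 1L] <- "primer_tie"
  reason[is.na(reason) & noAmp] <- "primer_nomatch"
  reason[is.na(reason) & !longEnough] <- "too_short"
  ampIdx[!longEnough] <- NA_integer_

  assigned <- !is.na(sampIdx) & !is.na(ampIdx)
  reason[assigned] <- "assigned"
  reason[!assigned & is.na(reason)] <- "barcode_nomatch"

  primMM <- ifelse(assigned, mmF[cbind(seq_len(n),
                                       ifelse(is.na(ampIdx), 1L, ampIdx))],
                   NA_integer_)
  assignments <- data.frame(
    read_id = id1,
    sample_id = ifelse(assigned, d$sample_id[sampIdx], "UNASSIGNED"),
    amplicon = ifelse(assigned, prf$amplicon[ampIdx], "UNASSIGNED"),
    barcode_mismatches = bcMM,
    primer_mismatches = primMM,
    reason = reason)

  # --- trimming -----------------------------------------------------------
  seq1t <- r1$seqs; qual1t <- r1$quals
  seq2t <- r2$seqs; qual2t <- r2$quals
  ai <- which(assigned)
  if (length(ai)) {
    plF <- nchar(prf$fwd)[ampIdx[ai]]
    plR <- nchar(prf$rev)[ampIdx[ai]]
    seq1t[ai] <- substring(seq1t[ai], 7L + plF)
    qual1t[ai] <- substring(qual1t[ai], 7L + plF)
    seq2t[ai] <- substring(seq2t[ai], 7L + plR)
    qual2t[ai] <- substring(qual2t[ai], 7L + plR)
    if (qualTrim) {
      k1 <- qualityTrimLength(qual1t[ai])
      k2 <- qualityTrimLength(qual2t[ai])
      seq1t[ai] <- substr(seq1t[ai], 1L, k1)
      qual1t[ai] <- substr(qual1t[ai], 1L, k1)
      seq2t[ai] <- substr(seq2t[ai], 1L, k2)
      qual2t[ai] <- substr(qual2t[ai], 1L, k2)
    }
    # empty after trimming -> unassign as too short
    tooShort <- ai[nchar(seq1t[ai]) == 0L | nchar(seq2t[ai]) == 0L]
    if (length(tooShort)) {
      assignments$sample_id[tooShort] <- "UNASSIGNED"
      assignments$amplicon[tooShort] <- "UNASSIGNED"
      assignments$reason[tooShort] <- "too_short"
      seq1t[tooShort] <- r1$seqs[tooShort]
      qual1t[tooShort] <- r1$quals[tooShort]
      seq2t[tooShort] <- r2$seqs[tooShort]
      qual2t[tooShort] <- r2$quals[tooShort]
    }
  }

  cov <- coverageReport(
    assignments[assignments$reason == "assigned",
                c("sample_id", "amplicon")], sheet, panel, n)

  out <- list(assignments = assignments,
              reads = list(seq1 = seq1t, qual1 = qual1t,
                           seq2 = seq2t, qual2 = qual2t),
              coverage = cov)
  if (!is.null(outDir)) writeDemux(out, r1, r2, outDir)
  out
}

# Write per-unit FASTQ pairs, UNASSIGNED pair and coverage TSV
writeDemux <- function(dm, r1, r2, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  asg <- dm$assignments
  ok <- asg$reason == "assigned"
  key <- paste(sanitizeName(asg$sample_id), sanitizeName(asg$amplicon),
               sep = "_")
  for (k in unique(key[ok])) {
    i <- which(ok & key == k)
    writeFastq(asg$read_id[i], dm$reads$seq1[i], dm$reads$qual1[i],
               file.path(outDir, paste0(k, "_R1.fastq.gz")))
    writeFastq(asg$read_id[i], dm$reads$seq2[i], dm$reads$qual2[i],
               file.path(outDir, paste0(k, "_R2.fastq.gz")))
  }
  i <- which(!ok)
  if (length(i)) {
    writeFastq(asg$read_id[i], r1$seqs[i], r1$quals[i],
               file.path(outDir, "UNASSIGNED_R1.fastq.gz"))
    writeFastq(asg$read_id[i], r2$seqs[i], r2$quals[i],
               file.path(outDir, "UNASSIGNED_R2.fastq.gz"))
  }
  writeCoverageReport(dm$coverage, file.path(outDir, "coverage.tsv"))
  invisible(outDir)
}

#' Per-amplicon coverage accounting
#'
#' Builds the coverage report from assigned (sample, amplicon) pairs:
#' read-pair counts per unit, per-pool totals and the per-amplicon mean
#' coverage across samples (the layout of the assay's coverage summary
#' table).
#'
#' @param assigned data.frame of \code{sample_id}, \code{amplicon} for every
#'   assigned pair.
#' @param sheet A \linkS4class{SampleSheet}.
#' @param panel An \linkS4class{AmpliconPanel}.
#' @param total total input pair count.
#' @return list(perUnit, perAmplicon, perPool) data.frames; counts satisfy
#'   assigned + unassigned = total.
#' @export
coverageReport <- function(assigned, sheet, panel, total) {
  d <- sheetData(sheet)
  units <- expand.grid(sample_id = d$sample_id,
                       amplicon = ampliconNames(panel),
                       stringsAsFactors = FALSE)
  cnt <- table(factor(paste(assigned$sample_id, assigned$amplicon, sep = "\r"),
                      levels = paste(units$sample_id, units$amplicon,
                                     sep = "\r")))
  units$pairs <- as.integer(cnt)
  perAmp <- stats::aggregate(pairs ~ amplicon, units, mean)
  names(perAmp)[2] <- "mean_coverage"
  nAssigned <- nrow(assigned)
  perPool <- data.frame(pool_id = unique(d$pool_id)[1],
                        total = total, assigned = nAssigned,
                        unassigned = total - nAssigned)
  list(perUnit = units, perAmplicon = perAmp, perPool = perPool)
}

#' @rdname coverageReport
#' @param cov a coverage report.
#' @param path output TSV path.
#' @export
writeCoverageReport <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-amplicon mean coverage", con)
  utils::write.table(
    transform(cov$perAmplicon, mean_coverage = fmtNum(mean_coverage)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# per-pool accounting", con)
  utils::write.table(cov$perPool, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# per-unit pair counts", con)
  utils::write.table(cov$perUnit, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
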
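#' Construct a FilterConfig
#'
#' @param minBaseQual,minDepth,minAltDepth,minSiteQual,minSamples,minPools,hetLow,hetHigh
#'   see \linkS4class{FilterConfig}. Defaults are the high-quality SNP
#'   filter of the assay: base quality >= 30, depth >= 30, alternate allele
#'   depth >= 10, site quality >= 30, variant present in >= 2 samples across
#'   >= 2 independent pools, heterozygous band 25-75\% alternate reads.
#'   Single-pool runs may relax \code{minPools} to 1.
#' @return A \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(minBaseQual = 30, minDepth = 30, minAltDepth = 10,
                         minSiteQual = 30, minSamples = 2, minPools = 2,
                         hetLow = 0.25, hetHigh = 0.75) {
  new("FilterConfig", minBaseQual = minBaseQual, minDepth = minDepth,
      minAltDepth = minAltDepth, minSiteQual = minSiteQual,
      minSamples = minSamples, minPools = minPools, hetLow = hetLow,
      hetHigh = hetHigh)
}

emptyCallTable <- function() {
  data.frame(amplicon = character(0), pos = integer(0), ref = character(0),
             alt = character(0), type = character(0), DP = integer(0),
             AD_ref = integer(0), AD_alt = integer(0),
             site_qual = numeric(0), caller = character(0))
}

# mean phred error probability per position from the quality-binned counts
.siteErrorRate <- function(p) {
  L <- ncol(p@counts)
  e <- phredToProb(p@qlevels)
  tot <- apply(p@qualCounts, 2L, sum)
  wsum <- vapply(seq_len(L), function(j) {
    m <- matrix(p@qualCounts[, j, ], nrow = 4L)
    sum(colSums(m) * e)
  }, numeric(1))
  ifelse(tot > 0, wsum / tot, phredToProb(30))
}

#' Frequency-based variant caller
#'
#' Caller #1 of the dual-caller design. Emits a call at every position where
#' the most frequent non-reference allele reaches the minimum alternate
#' allele depth and the position reaches the minimum total depth. Indels
#' (single-event insertion/deletion alleles from the pileup event tables)
#' are called by this caller only. The site quality is the phred-scaled
#' binomial tail probability of seeing at least \code{AD_alt} error bases
#' at the site's mean base-error rate.
#'
#' @param p A \linkS4class{PileupMatrix} (built with the same base-quality
#'   floor as \code{cfg}).
#' @param cfg A \linkS4class{FilterConfig}.
#' @return data.frame of calls: \code{amplicon}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{type}, \code{DP}, \code{AD_ref},
#'   \code{AD_alt}, \code{site_qual}, \code{caller}.
#' @export
callVariantsFreq <- function(p, cfg = filterConfig()) {
  ref <- strsplit(p@ref, "", fixed = TRUE)[[1]]
  L <- length(ref)
  dp <- colSums(p@counts)
  err <- .siteErrorRate(p)
  refIdx <- match(ref, c("A", "C", "G", "T"))
  out <- emptyCallTable()
  bc <- p@counts[1:4, , drop = FALSE]
  nonref <- bc
  nonref[cbind(refIdx, seq_len(L))] <- -1L
  altIdx <- apply(nonref, 2L, which.max)
  adAlt <- nonref[cbind(altIdx, seq_len(L))]
  adRef <- bc[cbind(refIdx, seq_len(L))]
  hit <- which(adAlt >= cfg@minAltDepth & dp >= cfg@minDepth)
  if (length(hit)) {
    out <- rbind(out, data.frame(
      amplicon = p@amplicon, pos = hit - 1L, ref = ref[hit],
      alt = c("A", "C", "G", "T")[altIdx[hit]], type = "snp",
      DP = as.integer(dp[hit]), AD_ref = as.integer(adRef[hit]),
      AD_alt = as.integer(adAlt[hit]),
      site_qual = probToPhred(stats::pbinom(adAlt[hit] - 1L, dp[hit],
                                            err[hit], lower.tail = FALSE)),
      caller = "freq"))
  }
  addIndel <- function(ev, kind) {
    for (i in seq_len(nrow(ev))) {
      pos <- ev$pos[i]
      if (pos < 0L || pos >= L) next
      DP <- as.integer(dp[pos + 1L])
      AD <- as.integer(ev$count[i])
      if (AD < cfg@minAltDepth || DP < cfg@minDepth) next
      alt <- if (kind == "ins") paste0("+", ev$seq[i]) else
        paste0("-", ev$len[i])
      out <<- rbind(out, data.frame(
        amplicon = p@amplicon, pos = pos, ref = ref[pos + 1L], alt = alt,
        type = kind, DP = DP, AD_ref = as.integer(bc[refIdx[pos + 1L],
                                                     pos + 1L]),
        AD_alt = AD,
        site_qual = probToPhred(stats::pbinom(AD - 1L, DP, err[pos + 1L],
                                              lower.tail = FALSE)),
        caller = "freq"))
    }
  }
  addIndel(p@insertions, "ins")
  addIndel(p@deletions, "del")
  out[order(out$pos), , drop = FALSE]
}

#' Diploid genotype-likelihood variant caller
#'
#' Caller #2 of the dual-caller design. At each site, computes the
#' likelihoods of the three diploid genotypes (hom-ref, het, hom-alt) for
#' the most frequent non-reference base under a symmetric base-error model
#' driven by the observed phred scores, and emits a call when a non-hom-ref
#' genotype reaches posterior probability > \code{minPosterior} under a
#' uniform prior. The site quality is the phred of the hom-ref posterior.
#' SNVs only; indels are the frequency caller's responsibility.
#'
#' @param p A \linkS4class{PileupMatrix}.
#' @param cfg A \linkS4class{FilterConfig}.
#' @param minPosterior posterior threshold (default 0.99).
#' @return data.frame of calls in the same layout as
#'   \code{\link{callVariantsFreq}}.
#' @export
callVariantsBayes <- function(p, cfg = filterConfig(),
                              minPosterior = 0.99) {
  ref <- strsplit(p@ref, "", fixed = TRUE)[[1]]
  L <- length(ref)
  refIdx <- match(ref, c("A", "C", "G", "T"))
  bc <- p@counts[1:4, , drop = FALSE]
  dp <- colSums(p@counts)
  e <- phredToProb(p@qlevels)
  out <- emptyCallTable()
  nonref <- bc
  nonref[cbind(refIdx, seq_len(L))] <- -1L
  altIdx <- apply(nonref, 2L, which.max)
  adAlt <- nonref[cbind(altIdx, seq_len(L))]
  cand <- which(adAlt > 0L)
  for (j in cand) {
    ri <- refIdx[j]; ai <- altIdx[j]
    nq <- matrix(p@qualCounts[, j, ], nrow = 4L)
    nRef <- nq[ri, ]; nAlt <- nq[ai, ]
    nOth <- colSums(nq) - nRef - nAlt
    ll <- c(
      homref = sum(nRef * log(1 - e) + (nAlt + nOth) * log(e / 3)),
      het = sum((nRef + nAlt) * log((1 - e) / 2 + e / 6) +
                  nOth * log(e / 3)),
      homalt = sum(nAlt * log(1 - e) + (nRef + nOth) * log(e / 3)))
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    if (post["het"] > minPosterior || post["homalt"] > minPosterior) {
      out <- rbind(out, data.frame(
        amplicon = p@amplicon, pos = j - 1L, ref = ref[j],
        alt = c("A", "C", "G", "T")[ai], type = "snp",
        DP = as.integer(dp[j]), AD_ref = as.integer(bc[ri, j]),
        AD_alt = as.integer(bc[ai, j]),
        site_qual = probToPhred(post["homref"]), caller = "bayes"))
    }
  }
  out
}

#' Merge the two callers' site sets
#'
#' Union of the calls by variant key (amplicon, pos, ref, alt). Records
#' called by both carry \code{caller_set = "freq,bayes"} and the allele
#' depths of the frequency caller (identical by construction, both read the
#' same pileup); sites emitted by one caller only are flagged
#' \code{single_caller}. Conflicting alternate alleles at one position stay
#' as separate keyed records with a \code{allele_conflict} flag.
#'
#' @param freqCalls,bayesCalls data.frames from the two callers.
#' @return data.frame with \code{caller_set} and \code{flags} columns.
#' @export
mergeCallers <- function(freqCalls, bayesCalls) {
  all <- rbind(freqCalls, bayesCalls)
  if (nrow(all) == 0L) {
    out <- emptyCallTable()
    out$caller_set <- character(0); out$flags <- character(0)
    out$caller <- NULL
    return(out)
  }
  key <- paste(all$amplicon, all$pos, all$ref, all$alt, sep = "\r")
  out <- NULL
  for (k in unique(key)) {
    rows <- all[key == k, , drop = FALSE]
    rec <- rows[rows$caller == "freq", , drop = FALSE]
    if (nrow(rec) == 0L) rec <- rows[1L, , drop = FALSE]
    rec$caller_set <- paste(sort(unique(rows$caller)), collapse = ",")
    rec$flags <- if (length(unique(rows$caller)) < 2L) "single_caller" else ""
    rec$site_qual <- max(rows$site_qual)
    out <- rbind(out, rec[1L, ])
  }
  out$caller <- NULL
  # mark shared positions with conflicting alt alleles
  posKey <- paste(out$amplicon, out$pos, sep = "\r")
  dupPos <- posKey %in% posKey[duplicated(posKey)]
  out$flags[dupPos] <- vapply(out$flags[dupPos], function(f)
    paste(c(setdiff(strsplit(f, ";")[[1]], ""), "allele_conflict"),
          collapse = ";"), character(1))
  rownames(out) <- NULL
  out[order(out$amplicon, out$pos, out$alt), , drop = FALSE]
}

#' Classify genotypes from the alternate-allele read fraction
#'
#' The assay's 25/75 rule: alternate fraction below \code{hetLow} is
#' homozygous reference, above \code{hetHigh} homozygous alternate, and the
#' closed band [\code{hetLow}, \code{hetHigh}] heterozygous (both
#' boundaries classify as heterozygous). Records with zero allele depth are
#' no-calls.
#'
#' @param calls data.frame with \code{AD_ref}, \code{AD_alt} columns.
#' @param cfg A \linkS4class{FilterConfig}.
#' @return the input with \code{alt_fraction} and \code{genotype}
#'   (\code{hom_ref}/\code{het}/\code{hom_alt}/\code{no_call}) columns.
#' @export
classifyGenotype <- function(calls, cfg = filterConfig()) {
  denom <- calls$AD_ref + calls$AD_alt
  af <- ifelse(denom > 0, calls$AD_alt / denom, NA_real_)
  calls$alt_fraction <- af
  calls$genotype <- ifelse(
    is.na(af), "no_call",
    ifelse(af < cfg@hetLow, "hom_ref",
           ifelse(af > cfg@hetHigh, "hom_alt", "het")))
  calls
}

#' Per-site quality flags
#'
#' Adds \code{min_dp}, \code{min_ad}, \code{min_qual} flags to records
#' failing the depth, alternate-depth and site-quality thresholds.
#'
#' @param calls classified call data.frame.
#' @param cfg A \linkS4class{FilterConfig}.
#' @return calls with an updated \code{flags} column.
#' @export
siteFilterFlags <- function(calls, cfg = filterConfig()) {
  addFlag <- function(flags, test, flag) {
    ifelse(test, ifelse(flags == "", flag, paste(flags, flag, sep = ";")),
           flags)
  }
  f <- calls$flags %||% rep("", nrow(calls))
  f <- addFlag(f, calls$DP < cfg@minDepth, "min_dp")
  f <- addFlag(f, calls$AD_alt < cfg@minAltDepth, "min_ad")
  f <- addFlag(f, calls$site_qual < cfg@minSiteQual, "min_qual")
  calls$flags <- f
  calls
}

#' Call, merge and classify one sample's pileup
#'
#' Convenience wrapper: run both callers on the pileup, merge the site
#' sets, classify genotypes and attach site filter flags and the sample id.
#'
#' @param p A \linkS4class{PileupMatrix}.
#' @param cfg A \linkS4class{FilterConfig}.
#' @return classified, flagged call data.frame with \code{sample_id}.
#' @export
callSample <- function(p, cfg = filterConfig()) {
  calls <- mergeCallers(callVariantsFreq(p, cfg),
                        callVariantsBayes(p, cfg))
  calls <- siteFilterFlags(classifyGenotype(calls, cfg), cfg)
  if (nrow(calls)) calls$sample_id <- p@sample
  else calls$sample_id <- character(0)
  calls
}

#' Cross-sample replication filter
#'
#' The assay's final retention rule: a variant key (amplicon, pos, ref,
#' alt) is retained only when carried (non-hom-ref genotype, no site-level
#' filter flag) by at least \code{minSamples} samples spanning at least
#' \code{minPools} distinct pools. Per-sample records of dropped keys are
#' flagged \code{singleton} (too few carrier samples) or \code{single_pool}
#' (carriers confined to one pool), never deleted.
#'
#' @param genotypes combined classified calls of all samples (must carry
#'   \code{sample_id}).
#' @param sheet A \linkS4class{SampleSheet} mapping samples to pools.
#' @param cfg A \linkS4class{FilterConfig}.
#' @return list(\code{genotypes} = flagged records with logical
#'   \code{retained}, \code{retainedKeys} = data.frame of retained keys).
#' @export
crossSampleFilter <- function(genotypes, sheet, cfg = filterConfig()) {
  d <- sheetData(sheet)
  if (nrow(genotypes)) {
    missing <- setdiff(unique(genotypes$sample_id), d$sample_id)
    if (length(missing))
      stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  }
  key <- paste(genotypes$amplicon, genotypes$pos, genotypes$ref,
               genotypes$alt, sep = "\r")
  carrier <- genotypes$genotype %in% c("het", "hom_alt") &
    (genotypes$flags %||% "") == ""
  pool <- d$pool_id[match(genotypes$sample_id, d$sample_id)]
  retainedKey <- vapply(unique(key), function(k) {
    i <- key == k & carrier
    sum(i) >= cfg@minSamples &&
      length(unique(pool[i])) >= cfg@minPools
  }, logical(1))
  genotypes$retained <- retainedKey[key]
  drop <- !genotypes$retained
  if (any(drop)) {
    reason <- vapply(key[drop], function(k) {
      i <- key == k & carrier
      if (sum(i) < cfg@minSamples) "singleton" else "single_pool"
    }, character(1))
    genotypes$flags[drop] <- ifelse(
      genotypes$flags[drop] == "", reason,
      paste(genotypes$flags[drop], reason, sep = ";"))
  }
  keys <- unique(genotypes[genotypes$retained,
                           c("amplicon", "pos", "ref", "alt"),
                           drop = FALSE])
  rownames(keys) <- NULL
  list(genotypes = genotypes, retainedKeys = keys)
}
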
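panel <- buildDefaultPanel()

mkReads <- function(amplicon, n = 1L, mutate = NULL, tlen = 200L) {
  # error-free trimmed mates straight from the reference (or a mutated
  # template), as demux would emit them
  ref <- refSequence(panel, amplicon)
  if (!is.null(mutate)) ref <- mutate(ref)
  pp <- primerPair(panel, amplicon)
  s1 <- substr(ref, nchar(pp$fwd) + 1L, nchar(pp$fwd) + tlen)
  rc <- stephseq:::revComp(ref)
  s2 <- substr(rc, nchar(pp$rev) + 1L, nchar(pp$rev) + tlen)
  list(seq1 = rep(s1, n), qual1 = rep(strrep("I", nchar(s1)), n),
       seq2 = rep(s2, n), qual2 = rep(strrep("I", nchar(s2)), n))
}

test_that("reference-identical reads place ungapped with zero mismatches", {
  r <- mkReads("VGSCI", n = 5L)
  aln <- alignToAmplicon(r$seq1, r$qual1, r$seq2, r$qual2, panel, "VGSCI")
  expect_equal(aln$discarded, 0L)
  p <- buildPileup(aln, panel, "VGSCI", "s")
  ref <- strsplit(refSequence(panel, "VGSCI"), "")[[1]]
  dp <- pileupDepth(p)
  covered <- which(dp > 0)
  # every covered position carries only the reference base
  for (j in covered) {
    expect_equal(unname(p@counts[ref[j], j]), unname(dp[j]))
  }
  expect_equal(nrow(p@insertions), 0L)
  expect_equal(nrow(p@deletions), 0L)
})

test_that("a planted substitution appears as exactly that mismatch", {
  pos <- 150L   # 0-based; covered by read 1
  ref <- refSequence(panel, "Rdl2")
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, pos + 1, pos + 1))[1]
  r <- mkReads("Rdl2", n = 10L, mutate = function(x) {
    substr(x, pos + 1L, pos + 1L) <- alt; x
  })
  aln <- alignToAmplicon(r$seq1, r$qual1, r$seq2, r$qual2, panel, "Rdl2")
  p <- buildPileup(aln, panel, "Rdl2", "s")
  expect_equal(unname(p@counts[alt, pos + 1L]), 10L)
  expect_equal(unname(p@counts[substr(ref, pos + 1, pos + 1), pos + 1L]), 0L)
})

test_that("reads with a long non-reference prefix are clipped or discarded", {
  r <- mkReads("CO1", n = 1L, tlen = 150L)
  junk <- stephseq:::withSeed(99L, stephseq:::randomDNA(70L))
  s1 <- paste0(junk, substr(r$seq1, 1, 150))
  q1 <- strrep("I", nchar(s1))
  # 70-base foreign prefix exceeds the 50-base clip cap: mate 1 is
  # dropped, so nothing is observed in the span only mate 1 could cover
  aln <- alignToAmplicon(s1, q1, r$seq2, r$qual2, panel, "CO1",
                         maxClip = 50L)
  expect_equal(sum(aln$obs$pos < 100L), 0L)
  # with both mates junked the whole fragment is discarded and counted
  aln2 <- alignToAmplicon(s1, q1, paste0(junk, substr(r$seq2, 1, 150)),
                          q1, panel, "CO1", maxClip = 50L)
  expect_equal(aln2$discarded, 1L)
  # a 40-base prefix is within the cap: clipped, fragment kept
  s3 <- paste0(substr(junk, 1, 40), substr(r$seq1, 1, 150))
  aln3 <- alignToAmplicon(s3, strrep("I", nchar(s3)), r$seq2, r$qual2,
                          panel, "CO1", maxClip = 50L)
  expect_equal(aln3$discarded, 0L)
  expect_gt(sum(aln3$obs$pos < 100L), 0L)
})

test_that("bases below the quality floor are excluded from the pileup", {
  r <- mkReads("ITS2", n = 4L, tlen = 100L)
  # phred 20 ('5') everywhere on mate 1, phred 40 ('I') on mate 2
  q1 <- vapply(r$seq1, function(s) strrep("5", nchar(s)), "",
               USE.NAMES = FALSE)
  aln <- alignToAmplicon(r$seq1, q1, r$seq2, r$qual2, panel, "ITS2")
  p30 <- buildPileup(aln, panel, "ITS2", "s", minBaseQual = 30L)
  p15 <- buildPileup(aln, panel, "ITS2", "s", minBaseQual = 15L)
  pp <- primerPair(panel, "ITS2")
  j <- nchar(pp$fwd) + 10L   # covered by mate 1 only
  expect_equal(unname(pileupDepth(p30)[j]), 0L)
  expect_equal(unname(pileupDepth(p15)[j]), 4L)
})

test_that("overlapping mates reconcile by phred with disagreement capping", {
  # construct one fragment whose mates overlap the whole amplicon interior
  ref <- refSequence(panel, "GSTe2")
  pp <- primerPair(panel, "GSTe2")
  L <- nchar(ref)
  tlen <- L - nchar(pp$fwd)   # mate 1 spans to the amplicon end
  r <- mkReads("GSTe2", n = 1L, tlen = tlen)
  # disagree at one interior position: mutate mate 1 only
  pos <- 250L
  s1 <- r$seq1
  old <- substr(ref, pos + 1L, pos + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), old)[1]
  off1 <- pos - nchar(pp$fwd)     # position within mate 1
  substr(s1, off1 + 1L, off1 + 1L) <- alt
  # mate 1 phred 40 at that base, mate 2 phred 20: keep mate 1's base at
  # qual 40 - 20 = 20 -> excluded at the default floor of 30
  q2 <- strrep("5", nchar(r$seq2))
  aln <- alignToAmplicon(s1, r$qual1, r$seq2, q2, panel, "GSTe2")
  p <- buildPileup(aln, panel, "GSTe2", "s", minBaseQual = 30L)
  expect_equal(unname(p@counts[alt, pos + 1L]), 0L)
  p2 <- buildPileup(aln, panel, "GSTe2", "s", minBaseQual = 15L)
  expect_equal(unname(p2@counts[alt, pos + 1L]), 1L)
  # agreement keeps the higher phred
  alnOK <- alignToAmplicon(r$seq1, r$qual1, r$seq2, q2, panel, "GSTe2")
  pOK <- buildPileup(alnOK, panel, "GSTe2", "s", minBaseQual = 30L)
  expect_equal(unname(pOK@counts[old, pos + 1L]), 1L)
})

test_that("sequencing-error fraction in deep pileups matches the binomial model", {
  # 1% substitution error: a specific non-ref base accumulates at rate
  # ~ e/3; check the pooled non-ref fraction against binomial bounds
  cfg <- simulationConfig(1, "VGSCI", readsPerAmplicon = 150,
                          baseErrorRate = 0.01,
                          qualityModel = c(high_q = 37, low_q = 37,
                                           fraction_low = 0),
                          seed = 23)
  sheet <- makeSampleSheet(1, seed = 23)
  res <- runCallChain(panel, cfg, sheet)
  p <- res$pileups[[1]]
  ref <- strsplit(p@ref, "")[[1]]
  dp <- pileupDepth(p)
  refIdx <- match(ref, c("A", "C", "G", "T"))
  nonref <- sum(dp) - sum(p@counts[1:4, ][cbind(refIdx, seq_along(ref))])
  n <- sum(dp)
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.01)
  expect_gte(nonref, bounds[1])
  expect_lte(nonref, bounds[2])
})

test_that("planted deletions are recovered as single events", {
  site <- 120L
  pv <- data.frame(amplicon = "Rdl1", pos = site, ref = "N", alt = "-4",
                   freq = 1.0)
  cfg <- simulationConfig(1, "Rdl1", plantedVariants = pv,
                          readsPerAmplicon = 40, baseErrorRate = 0,
                          seed = 29)
  sheet <- makeSampleSheet(1, seed = 29)
  res <- runCallChain(panel, cfg, sheet)
  p <- res$pileups[[1]]
  expect_gt(nrow(p@deletions), 0L)
  expect_equal(p@deletions$pos[which.max(p@deletions$count)], site)
  expect_equal(p@deletions$len[which.max(p@deletions$count)], 4L)
})
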
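panel <- buildDefaultPanel()

test_that("frequency caller enforces depth and alternate-depth floors", {
  # alt fraction 0.5 at depth 200 -> called
  expect_equal(nrow(callVariantsFreq(onePosPileup(100, 100))), 1L)
  # AD_alt 9 under the threshold of 10 -> not called
  expect_equal(nrow(callVariantsFreq(onePosPileup(91, 9))), 0L)
  expect_equal(nrow(callVariantsFreq(onePosPileup(90, 10))), 1L)
  # DP 29 under the threshold of 30 -> not called, 30 is
  expect_equal(nrow(callVariantsFreq(onePosPileup(14, 15))), 0L)
  expect_equal(nrow(callVariantsFreq(onePosPileup(15, 15))), 1L)
  call <- callVariantsFreq(onePosPileup(90, 10))
  expect_equal(call$AD_ref + call$AD_alt, call$DP)
  expect_equal(call$ref, "A")
  expect_equal(call$alt, "T")
})

# independent likelihood oracle: per-read products, no binning
bayesOracle <- function(nRef, nAlt, q) {
  e <- 10^(-q / 10)
  pr <- c(homref = nRef * log(1 - e) + nAlt * log(e / 3),
          het = (nRef + nAlt) * log((1 - e) / 2 + e / 6),
          homalt = nAlt * log(1 - e) + nRef * log(e / 3))
  post <- exp(pr - max(pr)); post / sum(post)
}

test_that("likelihood caller matches a direct posterior computation", {
  # 50% alt at depth 100, phred 30 -> het posterior > 0.99, called
  post <- bayesOracle(50, 50, 30)
  expect_gt(post[["het"]], 0.99)
  expect_equal(nrow(callVariantsBayes(onePosPileup(50, 50, qual = 30))), 1L)
  # 2% alt at depth 100, phred 30 is error-consistent -> no call
  post2 <- bayesOracle(98, 2, 30)
  expect_lt(max(post2[["het"]], post2[["homalt"]]), 0.99)
  expect_equal(nrow(callVariantsBayes(onePosPileup(98, 2, qual = 30))), 0L)
  # 0 alt reads -> hom ref, no call
  expect_equal(nrow(callVariantsBayes(onePosPileup(100, 0, qual = 30))), 0L)
  # pure alt -> hom alt call with high site quality
  call <- callVariantsBayes(onePosPileup(0, 60, qual = 30))
  expect_equal(nrow(call), 1L)
  expect_gt(call$site_qual, 30)
  # threshold tracks the oracle across a depth sweep
  for (nAlt in c(3, 5, 8, 12)) {
    post <- bayesOracle(60 - nAlt, nAlt, 30)
    called <- nrow(callVariantsBayes(onePosPileup(60 - nAlt, nAlt,
                                                  qual = 30))) > 0
    expect_equal(called,
                 post[["het"]] > 0.99 || post[["homalt"]] > 0.99)
  }
})

test_that("caller merge equals the brute-force set union", {
  set.seed(41)
  for (trial in 1:20) {
    ref <- stephseq:::randomDNA(40L)
    refc <- strsplit(ref, "")[[1]]
    counts <- matrix(0L, 4, 40, dimnames = list(c("A", "C", "G", "T"),
                                                NULL))
    counts[cbind(match(refc, rownames(counts)), 1:40)] <- 60L
    # random alt signal at random positions
    for (j in sample(40, 6)) {
      altb <- sample(setdiff(c("A", "C", "G", "T"), refc[j]), 1)
      counts[altb, j] <- sample(c(0L, 5L, 15L, 40L, 60L), 1)
    }
    p <- pileupFromCounts(ref, counts, qual = 35L)
    f <- callVariantsFreq(p)
    b <- callVariantsBayes(p)
    m <- mergeCallers(f, b)
    keyOf <- function(x) paste(x$pos, x$ref, x$alt)
    expect_setequal(keyOf(m), union(keyOf(f), keyOf(b)))
    both <- intersect(keyOf(f), keyOf(b))
    expect_equal(sort(keyOf(m)[m$caller_set == "bayes,freq"]), sort(both))
    expect_true(all(grepl("single_caller",
                          m$flags[!(keyOf(m) %in% both)])))
  }
})

test_that("genotype classification honours the 25/75 band inclusively", {
  cls <- function(nAlt) {
    calls <- classifyGenotype(data.frame(AD_ref = 100 - nAlt,
                                         AD_alt = nAlt))
    calls$genotype
  }
  expect_equal(cls(24), "hom_ref")
  expect_equal(cls(25), "het")    # 25% belongs to the het band
  expect_equal(cls(50), "het")
  expect_equal(cls(75), "het")    # 75% belongs to the het band
  expect_equal(cls(76), "hom_alt")
  expect_equal(cls(80), "hom_alt")
  expect_equal(cls(0), "hom_ref")
  expect_equal(cls(100), "hom_alt")
  # zero allele depth is a no-call
  nc <- classifyGenotype(data.frame(AD_ref = 0, AD_alt = 0))
  expect_equal(nc$genotype, "no_call")
  # boundary pileups through the full caller path give the same answers
  for (case in list(c(24, "hom_ref"), c(25, "het"), c(75, "het"),
                    c(76, "hom_alt"))) {
    nAlt <- as.integer(case[1])
    p <- onePosPileup(100 - nAlt, nAlt)
    g <- classifyGenotype(mergeCallers(callVariantsFreq(p),
                                       callVariantsBayes(p)))
    expect_equal(g$genotype[1], case[2])
  }
})

# brute-force replication-filter oracle over explicit key enumeration
filterOracle <- function(gts, sheet, minSamples = 2, minPools = 2) {
  d <- sheetData(sheet)
  keys <- unique(gts[, c("amplicon", "pos", "ref", "alt")])
  keep <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    rows <- gts[gts$amplicon == keys$amplicon[i] & gts$pos == keys$pos[i] &
                  gts$ref == keys$ref[i] & gts$alt == keys$alt[i], ]
    carriers <- rows$sample_id[rows$genotype %in% c("het", "hom_alt") &
                                 rows$flags == ""]
    pools <- unique(d$pool_id[d$sample_id %in% carriers])
    keep[i] <- length(unique(carriers)) >= minSamples &&
      length(pools) >= minPools
  }
  keys[keep, , drop = FALSE]
}

test_that("cross-sample filter equals the brute-force oracle on random sets", {
  sheet <- makeSampleSheet(8, nPools = 3, seed = 12)
  set.seed(55)
  for (trial in 1:60) {
    gts <- randomCallSet(sheet)
    res <- crossSampleFilter(gts, sheet)
    oracle <- filterOracle(gts, sheet)
    keyStr <- function(k) if (nrow(k)) paste(k$amplicon, k$pos, k$ref, k$alt)
                          else character(0)
    expect_setequal(keyStr(res$retainedKeys), keyStr(oracle))
    # dropped records are flagged, not deleted
    expect_equal(nrow(res$genotypes), nrow(gts))
    expect_true(all(grepl("singleton|single_pool",
                          res$genotypes$flags[!res$genotypes$retained]) |
                      res$genotypes$flags[!res$genotypes$retained] != ""))
  }
})

test_that("examples of the replication rule behave as specified", {
  sheet <- makeSampleSheet(6, nPools = 2, seed = 3)
  d <- sheetData(sheet)
  mkGts <- function(samples) data.frame(
    amplicon = "X", pos = 5L, ref = "A", alt = "T", type = "snp", DP = 50L,
    AD_ref = 25L, AD_alt = 25L, site_qual = 60, caller_set = "bayes,freq",
    flags = "", alt_fraction = 0.5, genotype = "het", sample_id = samples)
  # 3 samples across 2 pools -> retained
  s3 <- d$sample_id[c(1, 2, 3)]   # round-robin pools -> both pools hit
  expect_equal(nrow(crossSampleFilter(mkGts(s3), sheet)$retainedKeys), 1L)
  # 2 samples in the same pool -> dropped as single_pool
  samePool <- d$sample_id[d$pool_id == d$pool_id[1]][1:2]
  res <- crossSampleFilter(mkGts(samePool), sheet)
  expect_equal(nrow(res$retainedKeys), 0L)
  expect_true(all(grepl("single_pool", res$genotypes$flags)))
  # 1 sample -> singleton
  res1 <- crossSampleFilter(mkGts(d$sample_id[1]), sheet)
  expect_true(all(grepl("singleton", res1$genotypes$flags)))
  # sample missing from the sheet is a hard error
  expect_error(crossSampleFilter(mkGts("GHOST"), sheet), "absent")
})

test_that("lowering the alternate-depth floor never drops a retained variant", {
  sheet <- makeSampleSheet(8, nPools = 2, seed = 20)
  set.seed(71)
  for (trial in 1:10) {
    gts <- randomCallSet(sheet)
    keyStr <- function(k) if (nrow(k)) paste(k$amplicon, k$pos, k$ref, k$alt)
                          else character(0)
    strict <- crossSampleFilter(
      siteFilterFlags(gts, filterConfig(minAltDepth = 20)), sheet)
    relaxed <- crossSampleFilter(
      siteFilterFlags(gts, filterConfig(minAltDepth = 10)), sheet)
    expect_true(all(keyStr(strict$retainedKeys) %in%
                      keyStr(relaxed$retainedKeys)))
  }
})

test_that("clean planted data yields identical site sets from both callers", {
  site <- markerSite(panel, "rdl", 296, "S")
  pv <- data.frame(amplicon = site$amplicon, pos = site$pos,
                   ref = site$ref, alt = site$alt, freq = 0.5)
  for (seed in c(101, 202, 303)) {
    cfg <- simulationConfig(3, site$amplicon, plantedVariants = pv,
                            readsPerAmplicon = 120, baseErrorRate = 0,
                            seed = seed)
    sheet <- makeSampleSheet(3, seed = seed)
    res <- runCallChain(panel, cfg, sheet)
    for (p in res$pileups) {
      f <- callVariantsFreq(p)
      b <- callVariantsBayes(p)
      expect_setequal(paste(f$pos, f$alt), paste(b$pos, b$alt))
    }
  }
})
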
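test_that("pi, Hd and theta_W match brute-force enumeration on random sets", {
  set.seed(17)
  for (trial in 1:60) {
    n <- sample(2:8, 1); L <- sample(10:50, 1)
    seqs <- randomSeqSet(n, L)
    h <- haplotypeSet(seqs)
    st <- diversityStats(h)
    o <- popgenOracle(seqs)
    expect_equal(st$pi, o$pi)
    expect_equal(st$Hd, o$Hd)
    expect_equal(st$theta_W, o$thetaW)
    expect_equal(st$S, o$S)
    expect_equal(st$k, o$k)
  }
})

test_that("the worked 4-sequence example gives the enumerated values", {
  h <- haplotypeSet(c("AAA", "AAT", "ATT", "TTT"))
  st <- diversityStats(h)
  # pairwise differences: 1+2+3+1+2+1 = 10 over 6 pairs and 3 sites
  expect_equal(st$pi, 10 / 6 / 3)
  expect_equal(st$Hd, 1)           # all four haplotypes distinct
  expect_equal(st$theta_W, 3 / (1 + 1 / 2 + 1 / 3))
  expect_equal(st$S, 3L)
  expect_equal(st$k, 4L)
})

test_that("identical sequences give pi = 0, Hd = 0 and undefined D", {
  h <- haplotypeSet(rep("ACGTACGT", 5))
  st <- diversityStats(h)
  expect_equal(st$pi, 0)
  expect_equal(st$Hd, 0)
  expect_equal(st$S, 0L)
  expect_true(is.na(st$D))
  expect_error(diversityStats(haplotypeSet("ACGT")), "two sequences")
})

test_that("Tajima's D is defined exactly when segregating sites exist", {
  set.seed(23)
  for (trial in 1:30) {
    # n >= 4: at n = 3 the variance coefficient e1 vanishes and D is
    # degenerate for S = 1
    seqs <- randomSeqSet(sample(4:8, 1), 30, nMut = sample(0:5, 1))
    st <- diversityStats(haplotypeSet(seqs))
    expect_equal(is.na(st$D), st$S == 0L)
  }
})

test_that("pi is order-invariant and duplication-invariant; Hd shifts predictably", {
  set.seed(9)
  seqs <- randomSeqSet(6, 40)
  st <- diversityStats(haplotypeSet(seqs))
  stPerm <- diversityStats(haplotypeSet(sample(seqs)))
  expect_equal(st$pi, stPerm$pi)
  expect_equal(st$Hd, stPerm$Hd)
  dup <- diversityStats(haplotypeSet(c(seqs, seqs)))
  # duplicating the set adds C(n,1) zero-distance self pairs: pi scales by
  # the exact factor 2(n-1)/(2n-1) and converges to pi as n grows
  n <- 6
  expect_equal(dup$pi, st$pi * 2 * (n - 1) / (2 * n - 1))
  # haplotype freqs unchanged, only the n/(n-1) correction moves
  sumP2 <- 1 - st$Hd * (n - 1) / n
  expect_equal(dup$Hd, (2 * n) / (2 * n - 1) * (1 - sumP2))
})

test_that("sites with N or gaps are masked set-wide before statistics", {
  h <- haplotypeSet(c("ANGT", "AAGT", "AAGA"))
  expect_equal(sum(h@mask), 3L)       # column 2 masked out
  st <- diversityStats(h)
  expect_equal(st$L, 3L)
  expect_equal(st$S, 1L)              # only the last column segregates
})

test_that("Tajima's D hovers near zero on neutral-like frequency spectra", {
  # scatter mutations with derived counts ~ 1/i, the neutral SFS
  set.seed(31)
  Ds <- replicate(150, {
    n <- 10; L <- 80; S <- 12
    seqs <- rep(strrep("A", L), n)
    sites <- sample(L, S)
    for (s in sites) {
      i <- sample(1:(n - 1), 1, prob = 1 / (1:(n - 1)))
      for (k in sample(n, i)) substr(seqs[k], s, s) <- "T"
    }
    diversityStats(haplotypeSet(seqs))$D
  })
  expect_lt(abs(mean(Ds, na.rm = TRUE)), 0.5)
})

# exhaustive minimum spanning tree by enumerating all spanning edge subsets
mstOracleWeight <- function(d) {
  k <- nrow(d)
  if (k < 2) return(0)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(edges), k - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(edges[sel, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < k) next
    if (igraph::is_connected(g))
      best <- min(best, sum(d[edges[sel, , drop = FALSE]]))
  }
  best
}

test_that("network MST weight equals the exhaustive spanning-tree minimum", {
  set.seed(42)
  for (trial in 1:12) {
    k <- sample(3:6, 1)
    seqs <- unique(replicate(k, stephseq:::randomDNA(12L)))
    h <- haplotypeSet(seqs)
    net <- buildNetwork(h)
    expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
    expect_equal(sum(net$edges$weight), mstOracleWeight(net$distances))
    expect_true(all(net$edges$weight >= 1))
  }
})

test_that("haplotype collapsing keeps population-stratified counts", {
  h <- haplotypeSet(c("AAAA", "AAAA", "AAAT", "AAAA"),
                    sample = paste0("s", 1:4),
                    population = c("Ethiopia", "Pakistan", "Ethiopia",
                                   "Ethiopia"))
  net <- buildNetwork(h)
  expect_equal(sum(net$nodes$count), 4L)
  shared <- net$nodes[net$nodes$count == 3, ]
  expect_match(shared$populations, "Ethiopia:2")
  expect_match(shared$populations, "Pakistan:1")
  # 3 haplotypes with pairwise distances 1,1,2 keep the two 1-edges
  h2 <- haplotypeSet(c("AA", "AT", "TT"))
  net2 <- buildNetwork(h2)
  expect_equal(sum(net2$edges$weight), 2L)
  expect_true(all(net2$edges$weight == 1L))
})

test_that("network exports parse as GML and DOT", {
  h <- haplotypeSet(c("AAAA", "AAAT", "AATT"), population = c("a", "a", "b"))
  net <- buildNetwork(h)
  g1 <- tempfile(fileext = ".gml"); g2 <- tempfile(fileext = ".dot")
  writeNetwork(net, g1, "gml")
  writeNetwork(net, g2, "dot")
  back <- igraph::read_graph(g1, format = "gml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)
  expect_true(any(grepl("graph", readLines(g2))))
})

test_that("neighbour joining recovers additive trees exactly", {
  # 4 taxa, the classic additive matrix
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  ref <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # branch lengths: cophenetic distances reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]],
               d, tolerance = 1e-12)
  # 5-taxon additive distances from random trees
  set.seed(7)
  for (trial in 1:10) {
    tr0 <- ape::rtree(5)
    d5 <- ape::cophenetic.phylo(tr0)
    tr5 <- njTree(d5)
    expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(tr0)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr5)[rownames(d5), colnames(d5)],
                 d5, tolerance = 1e-9)
  }
})

test_that("three taxa give the closed-form star lengths", {
  d <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- njTree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["x"]), (4 + 6 - 8) / 2)
  expect_equal(unname(lens["y"]), (4 + 8 - 6) / 2)
  expect_equal(unname(lens["z"]), (6 + 8 - 4) / 2)
  expect_error(njTree(matrix(c(0, 1, 1, 0), 2, 2)), "3 taxa")
  d2 <- d; d2[1, 2] <- 99
  expect_error(njTree(d2), "symmetric")
})

test_that("NJ on ultrametric distances reproduces the UPGMA topology", {
  set.seed(13)
  for (trial in 1:8) {
    x <- matrix(rnorm(6 * 4), 6)
    rownames(x) <- paste0("t", 1:6)
    hc <- stats::hclust(stats::dist(x), method = "average")
    d <- stats::cophenetic(hc)
    tr <- njTree(as.matrix(d))
    up <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(up)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative NJ branch lengths are clamped with the deficit moved", {
  # a non-additive matrix known to produce a negative branch
  d <- matrix(c(0, 2, 2, 9, 2, 0, 1, 9, 2, 1, 0, 9, 9, 9, 9, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("consensus respects coverage thresholds and N-fills gaps", {
  ref <- strrep("ACGT", 25)   # 100 bp
  counts <- matrix(0L, 4, 100, dimnames = list(c("A", "C", "G", "T"), NULL))
  refc <- strsplit(ref, "")[[1]]
  counts[cbind(match(refc, rownames(counts)), 1:100)] <- 49L
  p49 <- pileupFromCounts(ref, counts)
  # mean depth 49 at threshold 50 -> rejected (strictly greater required)
  expect_true(consensusFromPileup(p49, minFold = 50)$rejected)
  counts2 <- counts; counts2[] <- 0L
  counts2[cbind(match(refc, rownames(counts)), 1:100)] <- 60L
  counts2[, 7] <- 0L                       # one zero-depth position
  p60 <- pileupFromCounts(ref, counts2)
  cons <- consensusFromPileup(p60, minFold = 50)
  expect_false(cons$rejected)
  expect_equal(substr(cons$seq, 7, 7), "N")
  expect_equal(substr(cons$seq, 1, 6), substr(ref, 1, 6))
  # heterozygous site -> IUPAC code when asked, major allele by default
  counts3 <- counts2
  counts3["A", 10] <- 30L; counts3["G", 10] <- 30L
  counts3[setdiff(rownames(counts), c("A", "G")), 10] <- 0L
  p3 <- pileupFromCounts(ref, counts3)
  expect_equal(substr(consensusFromPileup(p3, minFold = 50,
                                          iupacHet = TRUE)$seq, 10, 10),
               "R")
  expect_true(substr(consensusFromPileup(p3, minFold = 50)$seq, 10, 10)
              %in% c("A", "G"))
  # empty pileup is rejected with a reason
  empty <- pileupFromCounts(ref, matrix(0L, 4, 100,
                                        dimnames = list(c("A", "C", "G",
                                                          "T"), NULL)))
  expect_true(consensusFromPileup(empty)$rejected)
})

test_that("error-free homozygous samples reproduce the planted haplotype", {
  panel <- buildDefaultPanel()
  site <- randomPlantSite(panel, "CO1")
  pv <- data.frame(amplicon = "CO1", pos = site$pos, ref = site$ref,
                   alt = site$alt, freq = 1.0)
  cfg <- simulationConfig(1, "CO1", plantedVariants = pv,
                          readsPerAmplicon = 80, baseErrorRate = 0,
                          seed = 47)
  sheet <- makeSampleSheet(1, seed = 47)
  res <- runCallChain(panel, cfg, sheet)
  cons <- consensusFromPileup(res$pileups[[1]], minFold = 50)
  expect_false(cons$rejected)
  planted <- refSequence(panel, "CO1")
  substr(planted, site$pos + 1, site$pos + 1) <- site$alt
  covered <- pileupDepth(res$pileups[[1]]) >= 5
  consc <- strsplit(cons$seq, "")[[1]]
  plantc <- strsplit(planted, "")[[1]]
  expect_equal(consc[covered], plantc[covered])
  expect_true(all(consc[!covered] == "N"))
})

test_that("populations split by at least five fixed differences are monophyletic", {
  set.seed(3)
  base <- stephseq:::randomDNA(60L)
  other <- base
  for (j in c(5, 15, 25, 35, 45)) substr(other, j, j) <-
    setdiff(c("A", "C", "G", "T"), substr(other, j, j))[1]
  jitter1 <- function(s) {
    j <- sample(50:60, 1)
    substr(s, j, j) <- setdiff(c("A", "C", "G", "T"), substr(s, j, j))[1]
    s
  }
  seqs <- c(base, jitter1(base), jitter1(base), other, jitter1(other),
            jitter1(other))
  labs <- paste0(rep(c("popA", "popB"), each = 3), "_", 1:3)
  h <- haplotypeSet(seqs, sample = labs,
                    population = rep(c("A", "B"), each = 3))
  tr <- njTree(h)
  expect_true(ape::is.monophyletic(tr, labs[1:3]))
  expect_true(ape::is.monophyletic(tr, labs[4:6]))
})
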
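# Shared fixtures, all generated in code.

# A minimal two-amplicon panel with one plus-strand and one minus-strand
# coding gene, used by the annotation oracle tests. CDS window [30, 330)
# on a contig starting at `offset`.
toyCodingPanel <- function(seed = 42L, offset = 500L) {
  stephseq:::withSeed(seed, {
    mkamp <- function(strand) {
      L <- 360L
      ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      ref
    }
    refP <- mkamp("+"); refM <- mkamp("-")
    primers <- data.frame(
      amplicon = c("TOYP", "TOYM"),
      fwd = c(substr(refP, 1, 20), substr(refM, 1, 20)),
      rev = c(stephseq:::revComp(substr(refP, 341, 360)),
              stephseq:::revComp(substr(refM, 341, 360))))
    models <- list(
      TOYP = list(gene = "genP", strand = "+",
                  cds_intervals = matrix(c(offset + 30L, offset + 330L),
                                         ncol = 2),
                  codon_offset = 10L, ortholog_numbering = integer(0)),
      TOYM = list(gene = "genM", strand = "-",
                  cds_intervals = matrix(c(offset + 30L, offset + 330L),
                                         ncol = 2),
                  codon_offset = 1L, ortholog_numbering = integer(0)))
    ampliconPanel(c(TOYP = refP, TOYM = refM), primers,
                  c(TOYP = "genP", TOYM = "genM"),
                  c(TOYP = offset, TOYM = offset), models)
  })
}

# Construct a PileupMatrix directly from per-base counts (single phred
# level), for boundary and caller tests.
pileupFromCounts <- function(ref, counts, qual = 40L, sample = "S1",
                             amplicon = "AMP") {
  L <- nchar(ref)
  stopifnot(ncol(counts) == L)
  full <- matrix(0L, 5, L, dimnames = list(c("A", "C", "G", "T", "DEL"),
                                           NULL))
  full[rownames(counts), ] <- counts
  qc <- array(0L, dim = c(4L, L, 1L))
  qc[, , 1] <- full[1:4, ]
  new("PileupMatrix", amplicon = amplicon, sample = sample, ref = ref,
      counts = full, qualCounts = qc, qlevels = as.integer(qual),
      insertions = data.frame(pos = integer(0), seq = character(0),
                              count = integer(0)),
      deletions = data.frame(pos = integer(0), len = integer(0),
                             count = integer(0)),
      nFragments = as.integer(sum(full)), nDiscarded = 0L)
}

# A pileup over a 1-base "reference" with given ref/alt counts at one phred
onePosPileup <- function(nRef, nAlt, qual = 40L, refBase = "A",
                         altBase = "T") {
  counts <- matrix(0L, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[refBase, 1] <- nRef
  counts[altBase, 1] <- nAlt
  pileupFromCounts(refBase, counts, qual = qual)
}

# Simulate -> demux -> pileup -> per-sample calls across all pools of a
# sheet. Returns genotypes, pileups, per-pool sims and demux results.
runCallChain <- function(panel, cfg, sheet, ...) {
  sims <- simulatePools(panel, cfg, sheet)
  d <- sheetData(sheet)
  gts <- NULL; piles <- list(); dms <- list()
  for (pool in names(sims)) {
    sim <- sims[[pool]]
    sub <- sampleSheet(d[d$pool_id == pool, , drop = FALSE])
    dm <- demultiplexPool(
      list(ids = sim$ids, seqs = sim$seq1, quals = sim$qual1),
      list(ids = sim$ids, seqs = sim$seq2, quals = sim$qual2),
      sub, panel, ...)
    pp <- pileupsForPool(dm, panel)
    piles <- c(piles, pp)
    dms[[pool]] <- dm
    gts <- rbind(gts, do.call(rbind, lapply(pp, callSample)))
  }
  list(genotypes = gts, pileups = piles, sims = sims, demux = dms)
}

# Random call-record sets for replication-filter oracle tests
randomCallSet <- function(sheet, nKeys = 8) {
  d <- sheetData(sheet)
  keys <- data.frame(amplicon = sample(c("A1", "A2"), nKeys, TRUE),
                     pos = sample(50, nKeys, TRUE),
                     ref = sample(c("A", "C"), nKeys, TRUE),
                     alt = sample(c("G", "T"), nKeys, TRUE))
  keys <- unique(keys)
  out <- NULL
  for (i in seq_len(nrow(keys))) {
    sam <- sample(d$sample_id, sample(nrow(d), 1))
    adAlt <- sample(c(8L, 15L, 25L), 1)
    out <- rbind(out, data.frame(
      keys[i, ], type = "snp", DP = 50L, AD_ref = 50L - adAlt,
      AD_alt = adAlt,
      site_qual = 60, caller_set = "bayes,freq",
      flags = sample(c("", "", "", "min_dp"), length(sam), TRUE),
      alt_fraction = 0.5,
      genotype = sample(c("hom_ref", "het", "hom_alt"), length(sam), TRUE),
      sample_id = sam, row.names = NULL))
  }
  out
}

# Random aligned sequence sets (occasional N) for diversity oracles
randomSeqSet <- function(n, L, nMut = 6) {
  base <- stephseq:::randomDNA(L)
  seqs <- rep(base, n)
  for (m in seq_len(nMut)) {
    i <- sample(n, 1); j <- sample(L, 1)
    b <- sample(c("A", "C", "G", "T", "N"), 1, prob = c(rep(0.23, 4), 0.08))
    substr(seqs[i], j, j) <- b
  }
  seqs
}

# Brute-force popgen oracle: explicit pair enumeration, complete deletion
popgenOracle <- function(seqs) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  L0 <- nchar(seqs[1])
  keep <- vapply(seq_len(L0), function(j)
    all(vapply(chars, function(s) s[j] %in% c("A", "C", "G", "T"),
               logical(1))), logical(1))
  m <- lapply(chars, function(s) s[keep])
  L <- sum(keep)
  sumd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sumd <- sumd + sum(m[[i]] != m[[j]])
  npairs <- n * (n - 1) / 2
  S <- sum(vapply(seq_len(L), function(j)
    length(unique(vapply(m, `[`, "", j))) > 1, logical(1)))
  haps <- table(vapply(m, paste, "", collapse = ""))
  list(pi = if (L) sumd / npairs / L else 0,
       Hd = n / (n - 1) * (1 - sum((haps / n)^2)),
       thetaW = S / sum(1 / seq_len(n - 1)),
       S = S, k = length(haps), kbar = sumd / npairs)
}

# Random planted SNP outside primers and inside read-covered span
randomPlantSite <- function(panel, amplicon, readLength = 250L) {
  ref <- refSequence(panel, amplicon)
  pp <- primerPair(panel, amplicon)
  lo <- nchar(pp$fwd)
  hi <- min(readLength - 6L, nchar(ref) - nchar(pp$rev)) - 1L
  pos <- sample(lo:hi, 1L)
  rb <- substr(ref, pos + 1L, pos + 1L)
  list(pos = pos, ref = rb,
       alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1L))
}
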
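#' Construct a HaplotypeSet
#'
#' @param seqs character vector or \code{DNAStringSet} of equal-length
#'   aligned sequences (A/C/G/T/N/-).
#' @param sample,population parallel label vectors (population defaults to
#'   a single "pop").
#' @return A \linkS4class{HaplotypeSet}; the site mask (columns free of N
#'   and gaps in every sequence) is computed on construction.
#' @export
haplotypeSet <- function(seqs, sample = NULL, population = NULL) {
  s <- as.character(seqs)
  n <- length(s)
  sample <- sample %||% (names(seqs) %||% paste0("seq", seq_len(n)))
  population <- population %||% rep("pop", n)
  mask <- if (n) {
    m <- charMatrix(s)
    apply(m, 2L, function(col) all(col %in% DNA_BASES4))
  } else logical(0)
  new("HaplotypeSet", seqs = Biostrings::DNAStringSet(s),
      sample = as.character(sample), population = as.character(population),
      mask = mask)
}

#' Read an aligned FASTA with sample|population headers
#'
#' @param path FASTA of equal-length aligned sequences; headers
#'   \code{sample} or \code{sample|population}.
#' @return A \linkS4class{HaplotypeSet}.
#' @export
readAlignedFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  haplotypeSet(as.character(x),
               sample = vapply(parts, `[`, character(1), 1L),
               population = vapply(parts, function(p)
                 if (length(p) > 1L) p[2L] else "pop", character(1)))
}

# Masked sequences as a character matrix
maskedMatrix <- function(h) {
  m <- charMatrix(as.character(h@seqs))
  m[, h@mask, drop = FALSE]
}

#' Consensus sequence from a pileup
#'
#' Converts one sample's pileup at a phylogenetic amplicon into a consensus
#' haplotype. Samples whose mean depth across the amplicon does not exceed
#' \code{minFold} are rejected (the assay keeps samples with > 50-fold
#' coverage); retained samples emit the majority base per position, N where
#' depth falls below \code{minSiteDepth}, and — optionally — an IUPAC
#' ambiguity code at heterozygous sites (alternate fraction inside the
#' het band); the default reports the major allele.
#'
#' @param p A \linkS4class{PileupMatrix}.
#' @param minFold mean-coverage threshold (default 50; strictly greater
#'   required).
#' @param minSiteDepth per-position depth below which N is emitted.
#' @param iupacHet logical; encode het sites as IUPAC codes.
#' @param cfg A \linkS4class{FilterConfig} (supplies the het band).
#' @return list(\code{seq} = consensus string, \code{rejected} = logical,
#'   \code{reason}, \code{meanDepth}).
#' @export
consensusFromPileup <- function(p, minFold = 50, minSiteDepth = 5L,
                                iupacHet = FALSE, cfg = filterConfig()) {
  dp <- pileupDepth(p)
  md <- mean(dp)
  if (ncol(p@counts) == 0L || sum(dp) == 0L)
    return(list(seq = NA_character_, rejected = TRUE,
                reason = "empty pileup", meanDepth = 0))
  if (!(md > minFold))
    return(list(seq = NA_character_, rejected = TRUE,
                reason = sprintf("mean depth %.1f <= %g", md, minFold),
                meanDepth = md))
  bc <- p@counts[1:4, , drop = FALSE]
  tot <- colSums(bc)
  major <- apply(bc, 2L, which.max)
  cons <- DNA_BASES4[major]
  if (iupacHet) {
    iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
    for (j in which(tot >= minSiteDepth)) {
      o <- order(bc[, j], decreasing = TRUE)
      frac <- bc[o[2L], j] / tot[j]
      if (frac >= cfg@hetLow && frac <= cfg@hetHigh) {
        pair <- paste(sort(DNA_BASES4[o[1:2]]), collapse = "")
        cons[j] <- iupac[[pair]]
      }
    }
  }
  cons[tot < minSiteDepth] <- "N"
  list(seq = paste(cons, collapse = ""), rejected = FALSE, reason = "",
       meanDepth = md)
}

#' Diversity statistics of a haplotype set
#'
#' Computed on the masked (complete) sites: nucleotide diversity per site
#' pi = sum of pairwise differences / (C(n,2) * L); haplotype diversity
#' Hd = n/(n-1) * (1 - sum p_i^2) over haplotype frequencies; Watterson's
#' theta per locus theta_W = S / a1 with a1 the harmonic number of n-1; and
#' Tajima's D = (pi*L - theta_W) / sqrt(e1*S + e2*S*(S-1)) with the
#' standard variance coefficients. D is reported NA (flagged undefined)
#' when there are no segregating sites.
#'
#' @param h A \linkS4class{HaplotypeSet} with at least two sequences.
#' @return data.frame: \code{n}, \code{L} (analysed sites), \code{S}
#'   (segregating sites), \code{pi}, \code{Hd}, \code{theta_W}, \code{D},
#'   \code{k} (haplotype count).
#' @examples
#' h <- haplotypeSet(c("AAA", "AAT", "ATT", "TTT"))
#' diversityStats(h)
#' @export
diversityStats <- function(h) {
  n <- length(h@seqs)
  if (n < 2L) stop("diversity statistics need at least two sequences")
  m <- maskedMatrix(h)
  L <- ncol(m)
  S <- if (L) sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
       else 0L
  seqsM <- collapseRows(m)
  dmat <- pairwiseDifferences(m)
  npairs <- n * (n - 1) / 2
  sumd <- sum(dmat[upper.tri(dmat)])
  pi <- if (L > 0) sumd / (npairs * L) else 0
  pfreq <- table(seqsM) / n
  Hd <- n / (n - 1) * (1 - sum(pfreq^2))
  a1 <- sum(1 / seq_len(n - 1L))
  thetaW <- S / a1
  D <- tajimasD(n, S, sumd / npairs)
  data.frame(n = n, L = L, S = S, pi = pi, Hd = Hd, theta_W = thetaW,
             D = D, k = length(pfreq))
}

#' Tajima's D from n, S and the mean pairwise difference
#'
#' @param n sequences; \code{S} segregating sites; \code{kbar} mean number
#'   of pairwise differences (per locus).
#' @param S,kbar see above.
#' @return numeric D, NA when S = 0.
#' @export
tajimasD <- function(n, S, kbar) {
  if (S == 0L) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)   # degenerate variance (e.g. n = 3, S = 1)
  (kbar - S / a1) / sqrt(v)
}

# Pairwise Hamming differences over the columns of a character matrix
pairwiseDifferences <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' Minimum-spanning haplotype network
#'
#' Collapses identical (masked) sequences into haplotype nodes with
#' population-stratified sample counts, computes the full pairwise
#' nucleotide-difference matrix, and returns a minimum spanning tree over
#' it (Prim's algorithm with a deterministic lexicographic tie-break on
#' node labels). Edge weights are the number of nucleotide differences
#' between haplotypes — the tick marks of the classic haplotype-network
#' figure.
#'
#' @param h A \linkS4class{HaplotypeSet}.
#' @return list: \code{nodes} (data.frame \code{label}, \code{count},
#'   \code{populations} — "pop:count" strings — and \code{sequence}),
#'   \code{edges} (data.frame \code{from}, \code{to}, \code{weight}),
#'   \code{distances} (matrix).
#' @export
buildNetwork <- function(h) {
  m <- maskedMatrix(h)
  seqsM <- collapseRows(m)
  if (length(seqsM) == 0L)
    return(list(nodes = data.frame(), edges = data.frame(),
                distances = matrix(0, 0, 0)))
  uniq <- sort(unique(seqsM))
  labels <- paste0("H", seq_along(uniq))
  idx <- match(seqsM, uniq)
  counts <- tabulate(idx, length(uniq))
  pops <- vapply(seq_along(uniq), function(i) {
    t <- table(h@population[idx == i])
    paste(sprintf("%s:%d", names(t), as.integer(t)), collapse = ",")
  }, character(1))
  nodes <- data.frame(label = labels, count = counts, populations = pops,
                      sequence = uniq)
  k <- length(uniq)
  dm <- pairwiseDifferences(charMatrix(uniq))
  dimnames(dm) <- list(labels, labels)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = integer(0))
  if (k > 1L) {
    inTree <- c(TRUE, rep(FALSE, k - 1L))
    while (!all(inTree)) {
      best <- NULL
      for (i in which(inTree)) for (j in which(!inTree)) {
        cand <- list(w = dm[i, j], from = min(i, j), to = max(i, j))
        if (is.null(best) || cand$w < best$w ||
            (cand$w == best$w && (cand$from < best$from ||
              (cand$from == best$from && cand$to < best$to))))
          best <- cand
      }
      inTree[c(best$from, best$to)] <- TRUE
      edges <- rbind(edges, data.frame(from = labels[best$from],
                                       to = labels[best$to],
                                       weight = as.integer(best$w)))
    }
  }
  list(nodes = nodes, edges = edges, distances = dm)
}

#' Export a haplotype network as GML or DOT
#'
#' @param net result of \code{\link{buildNetwork}}.
#' @param path output path.
#' @param format "gml" or "dot".
#' @export
writeNetwork <- function(net, path, format = c("gml", "dot")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Neighbour-joining tree
#'
#' Classical neighbour joining on the pairwise nucleotide-difference matrix
#' of a haplotype set (or any symmetric distance matrix): at each step the
#' pair minimizing the Q criterion is joined, with a deterministic
#' tie-break by label order. Negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch, preserving the joined
#' distance. An optional Jukes-Cantor correction converts raw differences
#' to distances before agglomeration.
#'
#' @param x A \linkS4class{HaplotypeSet} or a symmetric numeric matrix with
#'   zero diagonal and dimnames.
#' @param jc logical; apply the Jukes-Cantor correction (only when \code{x}
#'   is a HaplotypeSet).
#' @return an \code{ape} \code{phylo} object (unrooted).
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' njTree(d)
#' @export
njTree <- function(x, jc = FALSE) {
  if (is(x, "HaplotypeSet")) {
    m <- maskedMatrix(x)
    d <- pairwiseDifferences(m)
    if (jc) {
      pdist <- d / ncol(m)
      d <- -3 / 4 * log(1 - 4 / 3 * pdist) * ncol(m)
    }
    dimnames(d) <- list(x@sample, x@sample)
  } else {
    d <- as.matrix(x)
  }
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  nodeId <- seq_len(n)            # phylo ids of active nodes
  repLab <- labels                # representative label per active node
  nextInternal <- n + 1L          # phylo internal ids grow upward
  edges <- NULL; elens <- NULL
  D <- d
  while (length(nodeId) > 3L) {
    k <- length(nodeId)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-9, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pairLab <- apply(ties, 1L, function(ij)
      paste(sort(c(repLab[ij[1]], repLab[ij[2]])), collapse = "\r"))
    pick <- ties[order(pairLab)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    newId <- nextInternal; nextInternal <- nextInternal + 1L
    edges <- rbind(edges, c(newId, nodeId[i]), c(newId, nodeId[j]))
    elens <- c(elens, li, lj)
    newD <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newD[keep]),
               c(newD[keep], 0))
    newLab <- min(repLab[c(i, j)])
    nodeId <- c(nodeId[keep], newId)
    repLab <- c(repLab[keep], newLab)
  }
  # final star join of the remaining three nodes
  newId <- nextInternal
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(newId, nodeId[1]), c(newId, nodeId[2]),
                 c(newId, nodeId[3]))
  elens <- c(elens, pmax(c(l1, l2, l3), 0))
  nInternal <- newId - n
  # renumber internal nodes so the root (last created) is n+1, per phylo
  # convention edges point parent -> child with internals > n
  remap <- c(seq_len(n), rev(seq.int(n + 1L, newId)))
  edges <- matrix(remap[edges], ncol = 2)
  tr <- list(edge = edges, edge.length = unname(elens),
             tip.label = labels, Nnode = nInternal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Write diversity statistics per population and pooled
#'
#' @param h A \linkS4class{HaplotypeSet}.
#' @param path output TSV path.
#' @return the statistics data.frame (one row per population with >= 2
#'   sequences, plus a pooled "all" row), invisibly when written.
#' @export
popgenStatsTable <- function(h, path = NULL) {
  pops <- unique(h@population)
  rows <- NULL
  for (p in c(pops, "all")) {
    i <- if (p == "all") seq_along(h@seqs) else which(h@population == p)
    if (length(i) < 2L) next
    sub <- haplotypeSet(as.character(h@seqs[i]), h@sample[i],
                        h@population[i])
    st <- diversityStats(sub)
    rows <- rbind(rows, cbind(population = p, st))
  }
  if (!is.null(path) && !is.null(rows)) {
    out <- rows
    for (cn in c("pi", "Hd", "theta_W", "D"))
      out[[cn]] <- fmtNum(out[[cn]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rows)
}
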
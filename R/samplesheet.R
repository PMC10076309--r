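#' Construct a SampleSheet
#'
#' @param data data.frame with columns \code{sample_id}, \code{fwd_barcode},
#'   \code{rev_barcode}, \code{pool_id}.
#' @return A \linkS4class{SampleSheet}.
#' @export
sampleSheet <- function(data) {
  data$pool_id <- as.character(data$pool_id)
  data$sample_id <- as.character(data$sample_id)
  new("SampleSheet", data = data)
}

#' @rdname sampleSheet
#' @param sheet A \linkS4class{SampleSheet}.
#' @export
sheetData <- function(sheet) sheet@data

#' Generate a set of 6-bp barcodes with pairwise Hamming distance >= 3
#'
#' Greedy rejection sampling under the current RNG: candidate 6-mers are
#' drawn uniformly and kept when at least \code{minDist} substitutions away
#' from every barcode already accepted. Distance >= 3 makes demultiplexing
#' with one allowed mismatch unambiguous (single-substitution errors cannot
#' reach within 1 of a second barcode).
#'
#' @param n number of barcodes (at most 64 per call; the maximum size of a
#'   6-mer code at distance 4 over a 4-letter alphabet is limited, and 64
#'   comfortably covers a 200-amplicon pool at two barcodes per sample).
#' @param minDist minimum pairwise Hamming distance (default 3).
#' @return character vector of \code{n} distinct 6-mers.
#' @export
generateBarcodes <- function(n, minDist = 3L) {
  if (minDist > 4L)
    stop("construction guarantees pairwise distance 4; minDist <= 4")
  codes <- hexacodeWords()                   # 64 codewords, min distance 4
  if (n > nrow(codes))
    stop("could not generate ", n, " barcodes at distance ", minDist,
         " (max ", nrow(codes), " per pool)")
  # distance-preserving random isometry under the current RNG: permute
  # positions, relabel symbols per position, add a random offset
  codes <- codes[, sample.int(6L), drop = FALSE]
  for (j in seq_len(6L))
    codes[, j] <- (sample.int(4L) - 1L)[codes[, j] + 1L]
  codes <- codes[sample.int(nrow(codes)), , drop = FALSE]
  apply(codes[seq_len(n), , drop = FALSE], 1L,
        function(r) paste(DNA_BASES4[r + 1L], collapse = ""))
}

# The hexacode: the [6,3,4] linear code over GF(4) (addition = XOR,
# multiplication by the field table). Its 64 codewords give the largest
# convenient 6-mer barcode set with guaranteed pairwise distance >= 4.
.hexacodeCache <- new.env(parent = emptyenv())
hexacodeWords <- function() {
  if (!is.null(.hexacodeCache$w)) return(.hexacodeCache$w)
  gmul <- matrix(c(0L, 0L, 0L, 0L,
                   0L, 1L, 2L, 3L,
                   0L, 2L, 3L, 1L,
                   0L, 3L, 1L, 2L), 4, 4, byrow = TRUE)
  P <- matrix(c(1L, 1L, 1L,
                1L, 2L, 3L,
                1L, 3L, 2L), 3, 3, byrow = TRUE)
  msgs <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  words <- matrix(0L, 64L, 6L)
  for (r in seq_len(64L)) {
    m <- as.integer(msgs[r, ])
    par <- integer(3L)
    for (j in 1:3) {
      acc <- 0L
      for (i in 1:3) acc <- bitwXor(acc, gmul[m[i] + 1L, P[i, j] + 1L])
      par[j] <- acc
    }
    words[r, ] <- c(m, par)
  }
  # verify the minimum Hamming distance once at first use
  mind <- 6L
  for (i in 1:63) for (j in (i + 1):64)
    mind <- min(mind, sum(words[i, ] != words[j, ]))
  stopifnot(mind >= 4L)
  .hexacodeCache$w <- words
  words
}

#' Build a sample sheet with distance-guaranteed barcodes
#'
#' Assigns each sample one unique forward and one unique reverse 6-bp
#' barcode (all barcodes within a pool at pairwise Hamming distance >= 3)
#' and distributes samples across \code{nPools} pools round-robin.
#'
#' @param nSamples number of samples.
#' @param nPools number of pools (default 1).
#' @param seed integer seed for barcode generation.
#' @param prefix sample-id prefix.
#' @return A \linkS4class{SampleSheet}.
#' @examples
#' makeSampleSheet(8, nPools = 2, seed = 1)
#' @export
makeSampleSheet <- function(nSamples, nPools = 1L, seed = 1L,
                            prefix = "S") {
  withSeed(seed, {
    pool <- paste0("pool", ((seq_len(nSamples) - 1L) %% nPools) + 1L)
    fwd <- rev <- character(nSamples)
    for (p in unique(pool)) {          # distance guarantee is per pool
      i <- which(pool == p)
      bcs <- generateBarcodes(2L * length(i))
      fwd[i] <- bcs[seq_along(i)]
      rev[i] <- bcs[length(i) + seq_along(i)]
    }
    sampleSheet(data.frame(
      sample_id = sprintf("%s%03d", prefix, seq_len(nSamples)),
      fwd_barcode = fwd, rev_barcode = rev, pool_id = pool))
  })
}

#' Read / write a sample sheet TSV
#'
#' Tab-separated with header \code{sample_id}, \code{fwd_barcode},
#' \code{rev_barcode}, \code{pool_id}.
#'
#' @param sheet A \linkS4class{SampleSheet}.
#' @param path file path.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  sampleSheet(utils::read.table(path, sep = "\t", header = TRUE,
                                colClasses = "character"))
}

#' Minimum pairwise barcode Hamming distance within each pool
#'
#' @param sheet A \linkS4class{SampleSheet}.
#' @return named integer, one entry per pool.
#' @export
minBarcodeDistance <- function(sheet) {
  d <- sheet@data
  vapply(split(d, d$pool_id), function(dp) {
    bc <- unique(c(dp$fwd_barcode, dp$rev_barcode))
    if (length(bc) < 2L) return(6L)
    m <- hammingMatrix(bc)
    as.integer(min(m[upper.tri(m)]))
  }, integer(1))
}
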
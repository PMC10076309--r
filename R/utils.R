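# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of plain character DNA
#' @noRd
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fixed-width strings to a character matrix (one row per string)
#' @noRd
charMatrix <- function(x, width = NULL) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  width <- width %||% nchar(x[1])
  stopifnot(all(nchar(x) == width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

#' Collapse a character matrix back to one string per row
#' @noRd
collapseRows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Hamming distances from one k-mer to a set of equal-length k-mers
#' @noRd
hammingTo <- function(prefix, barcodes) {
  k <- nchar(prefix)
  p <- utf8ToInt(prefix)
  vapply(barcodes, function(b) sum(utf8ToInt(b) != p), integer(1),
         USE.NAMES = FALSE)
}

#' Pairwise Hamming distance matrix over equal-length strings
#' @noRd
hammingMatrix <- function(x) {
  m <- charMatrix(x)
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Phred integer vector <-> probability of error
#' @noRd
phredToProb <- function(q) 10^(-q / 10)

probToPhred <- function(p, cap = 5000) {
  q <- -10 * log10(p)
  q[!is.finite(q) | q > cap] <- cap
  q
}

#' Phred+33 string to integer vector(s)
#' @noRd
qualToInt <- function(qstr) {
  lapply(qstr, function(s) as.integer(charToRaw(s)) - 33L)
}

intToQual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

#' Quality integer matrix to phred+33 strings, row-wise
#' @noRd
qualMatrixToStrings <- function(qm) {
  if (nrow(qm) == 0L) return(character(0))
  letters <- strsplit(rawToChar(as.raw(as.vector(t(qm)) + 33L)), "",
                      fixed = TRUE)[[1]]
  collapseRows(matrix(letters, nrow = nrow(qm), byrow = TRUE))
}

#' Make an identifier safe for use as a file name
#' @noRd
sanitizeName <- function(x) gsub("[^A-Za-z0-9_.-]", "-", x)

#' Evaluate expr under a temporary RNG seed, restoring global RNG state
#' @noRd
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Fixed-precision number formatting used in all text outputs
#' @noRd
fmtNum <- function(x) sprintf("%.6g", x)

DNA_BASES4 <- c("A", "C", "G", "T")
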
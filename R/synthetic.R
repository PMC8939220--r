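#' Random genome with controlled repeat content
#'
#' Generates an i.i.d. uniform DNA sequence in which approximately
#' \code{repeatFraction} of the bases belong to re-inserted copies of
#' earlier segments of length \code{repeatUnitBp}, so that k-mers inside
#' repeats acquire counts >= 2 while the unique backbone stays mostly
#' count-1 (the whole-genome regime: for a 1 Mbp repeat-free sequence at
#' k = 15 the distinct-k-mer space of size 4^15 makes chance collisions
#' negligible). Deterministic given the seed.
#'
#' @param lengthBp target sequence length in base pairs.
#' @param repeatFraction fraction of the sequence built from copies of
#'   earlier segments, in [0, 1).
#' @param repeatUnitBp length of each copied segment.
#' @param seed RNG seed.
#' @return a single DNA string of (approximately, up to one repeat unit)
#'   \code{lengthBp} bases.
#' @examples
#' nchar(randomGenome(1e4, repeatFraction = 0.2, seed = 1))
#' @export
randomGenome <- function(lengthBp, repeatFraction = 0, repeatUnitBp = 1000L,
                         seed = 1L) {
  if (repeatFraction < 0 || repeatFraction >= 1)
    stop("repeatFraction must be in [0, 1)")
  lengthBp <- as.integer(lengthBp)
  repeatUnitBp <- as.integer(repeatUnitBp)
  stopifnot(lengthBp >= 1L, repeatUnitBp >= 1L)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  chunks <- character(0)
  built <- 0L
  while (built < lengthBp) {
    unit <- min(repeatUnitBp, lengthBp - built)
    if (length(chunks) && stats::runif(1) < repeatFraction) {
      # re-insert a copy of an earlier segment
      src <- chunks[[sample.int(length(chunks), 1L)]]
      chunks <- c(chunks, substr(src, 1L, unit))
    } else {
      chunks <- c(chunks, paste(sample(bases, unit, replace = TRUE),
                                collapse = ""))
    }
    built <- built + unit
  }
  paste(chunks, collapse = "")
}

#' Random count table with power-law counts
#'
#' \code{nKeys} distinct random k-mers with counts drawn from the
#' truncated power law P(c) proportional to c^(-exponent) on
#' 1..maxCount, by inverse-CDF sampling -- the typical shape of k-mer
#' spectra, where most k-mers occur once.
#'
#' @param nKeys number of distinct k-mers (<= 4^k).
#' @param exponent power-law exponent (> 1).
#' @param maxCount truncation point of the count distribution.
#' @param k k-mer length.
#' @param seed RNG seed.
#' @return a [KmerCountTable-class].
#' @examples
#' powerlawTable(100, exponent = 2.5, maxCount = 50, k = 9, seed = 1)
#' @export
powerlawTable <- function(nKeys, exponent, maxCount = 255L, k, seed = 1L) {
  if (exponent <= 1) stop("exponent must be > 1")
  maxCount <- as.integer(maxCount)
  set.seed(as.integer(seed))
  keys <- .random_kmers(nKeys, k)
  cnt <- if (maxCount == 1L) rep(1L, nKeys)
         else sample.int(maxCount, nKeys, replace = TRUE,
                         prob = (seq_len(maxCount))^(-exponent))
  new("KmerCountTable", kmer = keys, count = cnt, k = as.integer(k))
}

#' Random count table with a controlled dominant fraction
#'
#' Exactly \code{round(alpha * nKeys)} keys carry the dominant value
#' \code{v0}; the remaining counts are drawn from \code{otherValues}
#' (default: values v0+1 .. v0+9 with spectrum-like decreasing weights
#' proportional to rank^-2.5). Direct control of alpha for Bloom
#' dimensioning experiments.
#'
#' @param nKeys number of distinct k-mers (<= 4^k).
#' @param alpha target dominant fraction, in (0, 1].
#' @param v0 the dominant count value (>= 1).
#' @param otherValues named numeric histogram of non-dominant values and
#'   their relative weights.
#' @param k k-mer length.
#' @param seed RNG seed.
#' @return a [KmerCountTable-class] whose realized dominant fraction is
#'   within 1/nKeys of \code{alpha}.
#' @examples
#' tab <- dominantTable(1000, alpha = 0.97, v0 = 1, k = 13, seed = 2)
#' dominantFraction(tab)
#' @export
dominantTable <- function(nKeys, alpha, v0 = 1L,
                          otherValues = setNames((1:9)^(-2.5), v0 + 1:9),
                          k, seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  v0 <- as.integer(v0)
  if (v0 < 1L) stop("v0 must be >= 1 (0 is reserved)")
  nKeys <- as.integer(nKeys)
  set.seed(as.integer(seed))
  keys <- .random_kmers(nKeys, k)
  nDom <- as.integer(round(alpha * nKeys))
  others <- as.integer(names(otherValues))
  if (anyNA(others) || any(others < 1L) || any(others == v0))
    stop("otherValues names must be counts >= 1 distinct from v0")
  cnt <- rep(v0, nKeys)
  if (nDom < nKeys) {
    drawn <- if (length(others) == 1L) rep(others, nKeys - nDom)
             else sample(others, nKeys - nDom, replace = TRUE,
                         prob = as.numeric(otherValues))
    cnt[sample.int(nKeys, nKeys - nDom)] <- drawn
  }
  new("KmerCountTable", kmer = keys, count = cnt, k = as.integer(k))
}

# distinct random k-mers, uniform over the 4^k universe
.random_kmers <- function(n, k) {
  k <- .check_k(k)
  n <- as.integer(n)
  if (n < 1L) stop("need at least one k-mer")
  if (n > 4^k) stop(sprintf("nKeys = %d exceeds 4^%d distinct k-mers", n, k))
  if (k <= 25L) {
    ids <- sample(4^k, n) - 1 # exact doubles below 2^53
  } else {
    ids <- numeric(0)
    while (length(ids) < n) {
      more <- floor(stats::runif(n - length(ids) + 100L) * 4^k)
      ids <- unique(c(ids, more))
    }
    ids <- ids[seq_len(n)]
  }
  .ids_to_kmers(ids, k)
}

.ids_to_kmers <- function(ids, k) {
  bases <- c("A", "C", "G", "T")
  cols <- vector("list", k)
  x <- ids
  for (j in k:1) {
    cols[[j]] <- bases[(x %% 4) + 1]
    x <- floor(x / 4)
  }
  do.call(paste0, cols)
}
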
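#' Build a Bloom filter
#'
#' Dimensioned from the target false-positive rate epsilon as
#' m = ceil(n * log2(e) * log2(1/epsilon)) bits -- about
#' 1.44 * log2(1/epsilon) bits per key -- with
#' round(ln(2) * m / n) probe positions (at least one), derived by double
#' hashing from two seeded 64-bit hashes. Inserted keys are always
#' reported present (no false negatives); absent keys are reported present
#' with probability close to epsilon.
#'
#' @param keys character vector of distinct DNA keys (length <= 31).
#' @param epsilon target false-positive rate, in (0, 1).
#' @param seed integer hash seed (stored in the filter).
#' @return a [BloomFilter-class]. An empty key set yields a degenerate
#'   one-bit filter that answers negative for every query.
#' @examples
#' bf <- buildBloom(c("ACGT", "TTTT"), epsilon = 0.01)
#' bloomQuery(bf, c("ACGT", "AAAA"))
#' @export
buildBloom <- function(keys, epsilon, seed = 0L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be a single number in (0, 1)")
  keys <- as.character(keys)
  n <- length(keys)
  if (n == 0L)
    return(new("BloomFilter", bits = raw(1L), mBits = 1, numHashes = 1L,
               targetFp = epsilon, seed = as.integer(seed), nInserted = 0))
  mBits <- ceiling(n * log2(exp(1)) * log2(1 / epsilon))
  numHashes <- max(1L, as.integer(round(log(2) * mBits / n)))
  bits <- .bloom_build_cpp(keys, mBits, numHashes, as.integer(seed))
  new("BloomFilter", bits = bits, mBits = mBits, numHashes = numHashes,
      targetFp = epsilon, seed = as.integer(seed), nInserted = n)
}

#' @rdname buildBloom
#' @param filter a built [BloomFilter-class].
#' @return \code{bloomQuery}: logical vector, TRUE where the key is
#'   (possibly falsely) reported present.
#' @export
bloomQuery <- function(filter, keys) {
  stopifnot(is(filter, "BloomFilter"))
  if (filter@nInserted == 0) return(rep(FALSE, length(keys)))
  .bloom_query_cpp(filter@bits, filter@mBits, filter@numHashes, filter@seed,
                   as.character(keys))
}

setMethod("show", "BloomFilter", function(object)
  cat(sprintf(
    "BloomFilter: %s bits, %d hashes, %s keys, target FP %.4g (%.2f bits/key)\n",
    format(object@mBits, big.mark = ","), object@numHashes,
    format(object@nInserted, big.mark = ","), object@targetFp,
    if (object@nInserted > 0) object@mBits / object@nInserted else 0)))

#' @rdname structureBits
#' @export
setMethod("structureBits", "BloomFilter", function(x) {
  payload <- x@mBits
  total <- 8 * length(serialize(x, NULL, version = 3L))
  c(bloom = payload, metadata = total - payload, total = total)
})
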
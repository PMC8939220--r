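#' k-mer count table
#'
#' A static associative array from distinct k-mers (strings over A,C,G,T of a
#' common length \code{k}) to positive integer counts. Count 0 is reserved:
#' it marks ambiguous buckets in the AMB cascade, so it may never appear as
#' a real count.
#'
#' @slot kmer character vector of distinct k-mers.
#' @slot count integer vector of counts, all >= 1.
#' @slot k the k-mer length in bases (1..31, so a k-mer packs into 64 bits).
#'
#' @seealso [countKmers()], [readCountTable()], [powerlawTable()]
#' @exportClass KmerCountTable
setClass("KmerCountTable",
  representation(kmer = "character", count = "integer", k = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@k) != 1L || is.na(object@k))
      msg <- c(msg, "k must be a single integer")
    else {
      if (object@k < 1L || object@k > 31L)
        msg <- c(msg, "k must be in [1, 31]")
      if (length(object@kmer) == 0L)
        msg <- c(msg, "table must hold at least one k-mer")
      if (length(object@kmer) != length(object@count))
        msg <- c(msg, "kmer and count lengths differ")
      if (length(object@kmer)) {
        if (!all(nchar(object@kmer) == object@k))
          msg <- c(msg, sprintf("all k-mers must have length %d", object@k))
        if (any(grepl("[^ACGT]", object@kmer)))
          msg <- c(msg, "k-mers may only contain A, C, G, T")
        if (anyDuplicated(object@kmer))
          msg <- c(msg, "k-mers must be distinct")
        if (anyNA(object@count) || any(object@count < 1L))
          msg <- c(msg, "all counts must be >= 1 (0 is reserved)")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Minimizer scheme
#'
#' A total, deterministic order on m-mers: m-mers are compared by a seeded
#' 64-bit hash (splitmix64), with ties between equal-hash windows broken by
#' leftmost occurrence. A lexicographic order is deliberately not offered
#' (it has poor statistical properties for bucketing).
#'
#' @slot m minimizer length in bases, 1 <= m <= 31.
#' @slot seed integer seeding the hash that defines the m-mer order.
#'
#' @seealso [minimizers()], [bucketCounts()]
#' @exportClass MinimizerScheme
setClass("MinimizerScheme",
  representation(m = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@m) != 1L || is.na(object@m) || object@m < 1L ||
        object@m > 31L)
      return("m must be a single integer in [1, 31]")
    if (length(object@seed) != 1L || is.na(object@seed))
      return("seed must be a single integer")
    TRUE
  }
)

#' Bloom filter
#'
#' Standard Bloom filter with double hashing. Sized at build time as
#' ceil(n * log2(e) * log2(1/epsilon)) bits, i.e. about 1.44 * log2(1/eps)
#' bits per key, with round(ln 2 * m/n) hash functions (at least one).
#'
#' @slot bits raw vector holding the bit array (little-endian within bytes).
#' @slot mBits number of bits (numeric, may exceed integer range).
#' @slot numHashes number of probe positions per key.
#' @slot targetFp the false-positive rate the filter was dimensioned for.
#' @slot seed hash seed (stored so queries are bit-reproducible).
#' @slot nInserted number of keys inserted at build time.
#'
#' @seealso [buildBloom()], [bloomQuery()]
#' @exportClass BloomFilter
setClass("BloomFilter",
  representation(bits = "raw", mBits = "numeric", numHashes = "integer",
                 targetFp = "numeric", seed = "integer",
                 nInserted = "numeric"))

#' Canonical length-limited prefix code
#'
#' Optimal length-limited (package-merge) codeword lengths over the observed
#' value alphabet, with canonical codeword assignment ordered by
#' (length, symbol). The decode tables are fully determined by
#' \code{symbols} and \code{lengths}.
#'
#' @slot symbols integer symbols in canonical order (length, then value).
#' @slot lengths codeword length in bits per symbol (0 allowed only for a
#'   single-symbol alphabet).
#' @slot codes numeric codeword values (MSB first), derived canonically.
#' @slot maxLen largest codeword length in bits.
#' @slot lenCount,lenFirst,lenOffset per-length decode tables (indexed
#'   1..maxLen offset by one: element l+1 describes length l).
#'
#' @seealso [buildCode()], [encodeValue()], [decodeValue()]
#' @exportClass PrefixCode
setClass("PrefixCode",
  representation(symbols = "integer", lengths = "integer", codes = "numeric",
                 maxLen = "integer", lenCount = "integer",
                 lenFirst = "numeric", lenOffset = "integer"),
  validity = function(object) {
    n <- length(object@symbols)
    if (n == 0L) return("code must have at least one symbol")
    if (length(object@lengths) != n) return("lengths/symbols mismatch")
    if (anyDuplicated(object@symbols)) return("symbols must be distinct")
    if (n == 1L) {
      if (object@lengths != 0L) return("single-symbol code must use 0 bits")
      return(TRUE)
    }
    if (any(object@lengths < 1L)) return("codeword lengths must be >= 1")
    if (sum(2^(-object@lengths)) > 1 + 1e-12)
      return("Kraft inequality violated")
    TRUE
  }
)

#' Compressed static function
#'
#' Keyless storage of a map from k-mers to values: each key's codeword is
#' the XOR of three hash-positioned windows of a per-chunk bit array, the
#' arrays being solved over GF(2) at build time (peeling plus dense
#' elimination on the 2-core). Querying a key outside the build set returns
#' an arbitrary symbol of the code alphabet.
#'
#' @slot code the [PrefixCode-class] over the value alphabet.
#' @slot arrays list of raw per-chunk bit arrays.
#' @slot arrayBits per-chunk bit-array lengths.
#' @slot attempts per-chunk seed-bump counter (needed to replay hashing).
#' @slot nChunks number of chunks.
#' @slot gamma bit-array expansion factor (>= 1.05).
#' @slot chunkTarget targeted keys per chunk.
#' @slot seed global build seed.
#' @slot nKeys number of keys the structure was built on.
#' @slot maxLen codeword window width in bits.
#'
#' @seealso [buildCSF()], [csfQuery()]
#' @exportClass CSF
setClass("CSF",
  representation(code = "PrefixCode", arrays = "list", arrayBits = "numeric",
                 attempts = "integer", nChunks = "numeric", gamma = "numeric",
                 chunkTarget = "integer", seed = "integer", nKeys = "numeric",
                 maxLen = "integer"))

setClassUnion("BloomFilterOrNULL", c("BloomFilter", "NULL"))
setClassUnion("CSFOrNULL", c("CSF", "NULL"))

#' Bloom-enhanced compressed static function
#'
#' A CSF optionally fronted by a Bloom filter holding the keys whose value
#' is not the dominant one. A Bloom-negative query answers the dominant
#' value immediately (correct, since the filter has no false negatives);
#' Bloom positives fall through to a CSF built on all filter positives,
#' where false positives are stored with the dominant value. Whether the
#' filter pays off, and its false-positive rate, are decided analytically
#' from the dominant fraction alpha and the per-key cost coefficients.
#'
#' @slot v0 the dominant value.
#' @slot bloom the Bloom filter, or NULL when alpha is below the threshold.
#' @slot csf the value CSF, or NULL for a single-valued (alpha = 1) table.
#' @slot epsilon realized Bloom false-positive target (NA if no filter).
#' @slot alpha dominant-value fraction of the build table.
#' @slot h0 zero-order empirical entropy of the build table (bits).
#' @slot cCsf,cBf per-key cost coefficients used for dimensioning.
#' @slot nKeys number of keys.
#' @slot seed build seed.
#'
#' @seealso [buildBCSF()], [bcsfQuery()], [optimalEpsilon()]
#' @exportClass BCSF
setClass("BCSF",
  representation(v0 = "integer", bloom = "BloomFilterOrNULL",
                 csf = "CSFOrNULL", epsilon = "numeric", alpha = "numeric",
                 h0 = "numeric", cCsf = "numeric", cBf = "numeric",
                 nKeys = "numeric", seed = "integer"))

setClassUnion("BCSFOrNULL", c("BCSF", "NULL"))

#' AMB index: ambiguity-marked minimizer cascade
#'
#' Ordered layers of minimizer-keyed bucket tables. Each layer stores, per
#' bucket, the bucket minimum when all member counts agree to within delta
#' and the reserved marker 0 otherwise; k-mers of marked buckets cascade to
#' the next layer, and any still unresolved after the last layer are stored
#' exactly in a terminal k-mer-keyed BCSF. Queries are exact for delta = 0
#' and within +/- delta otherwise.
#'
#' @slot k k-mer length of the build table.
#' @slot delta maximum absolute error (0 = exact).
#' @slot minimizerLengths strictly increasing minimizer lengths, all <= k.
#' @slot layerSeeds per-layer minimizer-order seeds (derived from seed).
#' @slot layers list of [BCSF-class] bucket tables over m-mers.
#' @slot residual terminal BCSF over unresolved k-mers, or NULL.
#' @slot nKeys number of build keys.
#' @slot seed build seed.
#'
#' @seealso [buildAMB()], [ambQuery()]
#' @exportClass AMBIndex
setClass("AMBIndex",
  representation(k = "integer", delta = "integer",
                 minimizerLengths = "integer", layerSeeds = "integer",
                 layers = "list", residual = "BCSFOrNULL", nKeys = "numeric",
                 seed = "integer"))

#' FIL index: majority-representative minimizer cascade
#'
#' Each layer stores a per-bucket majority representative of the current
#' residual values over all build k-mers; the final residuals (zigzag-coded
#' corrections, mostly 0 by the majority rule) live in a terminal
#' k-mer-keyed BCSF. A query sums the layer representatives along the
#' k-mer's minimizers and adds its correction; answers are always exact.
#'
#' @slot k k-mer length of the build table.
#' @slot minimizerLengths strictly increasing minimizer lengths, all <= k.
#' @slot layerSeeds per-layer minimizer-order seeds.
#' @slot layers list of [BCSF-class] representative tables over m-mers.
#' @slot corrections BCSF over all k-mers storing zigzag-coded residuals.
#' @slot nKeys number of build keys.
#' @slot seed build seed.
#'
#' @seealso [buildFIL()], [filQuery()]
#' @exportClass FILIndex
setClass("FILIndex",
  representation(k = "integer", minimizerLengths = "integer",
                 layerSeeds = "integer", layers = "list",
                 corrections = "BCSF", nKeys = "numeric", seed = "integer"))
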
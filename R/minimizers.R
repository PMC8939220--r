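#' Create a minimizer scheme
#'
#' @param m minimizer length in bases (1..31).
#' @param seed integer seeding the hash order on m-mers.
#' @return a [MinimizerScheme-class].
#' @examples
#' minimizers("ACGTAC", MinimizerScheme(3, seed = 42))
#' @export
MinimizerScheme <- function(m, seed = 0L) {
  new("MinimizerScheme", m = as.integer(m), seed = as.integer(seed))
}

setMethod("show", "MinimizerScheme", function(object)
  cat(sprintf("MinimizerScheme: m = %d, order seed = %d\n",
              object@m, object@seed)))

#' Hash-ordered minimizers of k-mers
#'
#' The minimizer of a k-mer is its length-m window with the smallest seeded
#' hash value; ties between equal-hash windows are broken by leftmost
#' occurrence. The result is always a substring of the k-mer, and is
#' computed on the key exactly as stored in the table (i.e. on the
#' canonical form if the table is canonical).
#'
#' @param kmers character vector of k-mers.
#' @param scheme a [MinimizerScheme-class].
#' @return character vector of m-mers, one per input k-mer.
#' @export
minimizers <- function(kmers, scheme) {
  stopifnot(is(scheme, "MinimizerScheme"))
  .minimizers_cpp(as.character(kmers), scheme@m, scheme@seed)
}

#' Hash values of the m-mer order
#'
#' The 53-bit hash values that define the total order used by
#' [minimizers()] (smaller hash = smaller m-mer). Exposed so that the
#' minimizer choice can be verified independently by enumerating windows.
#'
#' @param mmers character vector of m-mers.
#' @param seed order seed.
#' @return numeric vector of hash values (exact integers below 2^53).
#' @export
mmerOrderHash <- function(mmers, seed = 0L)
  .mmer_order_hash_cpp(as.character(mmers), as.integer(seed))

#' Group count values into minimizer buckets
#'
#' Buckets the table's counts by the minimizer of each k-mer and reports,
#' per bucket, the running minimum and maximum, the bucket size, and the
#' ambiguity flag: a bucket is ambiguous iff it holds two counts differing
#' by more than \code{delta} (for \code{delta = 0}, iff it holds at least
#' two distinct values).
#'
#' @param table a [KmerCountTable-class].
#' @param scheme a [MinimizerScheme-class] with m <= k.
#' @param delta maximum tolerated within-bucket count spread (>= 0).
#' @return data.frame with columns \code{minimizer}, \code{min},
#'   \code{max}, \code{size}, \code{ambiguous}; attribute \code{"group"}
#'   maps each table key (in order) to its row.
#' @export
bucketCounts <- function(table, scheme, delta = 0L) {
  stopifnot(is(table, "KmerCountTable"), is(scheme, "MinimizerScheme"))
  delta <- as.integer(delta)
  if (length(delta) != 1L || is.na(delta) || delta < 0L)
    stop("delta must be a single integer >= 0")
  mins <- minimizers(table@kmer, scheme)
  st <- .bucket_stats_cpp(mins, table@count)
  out <- data.frame(minimizer = st$minimizer, min = st$min, max = st$max,
                    size = st$size,
                    ambiguous = (st$max - st$min) > delta,
                    stringsAsFactors = FALSE)
  attr(out, "group") <- st$group
  out
}

#' Exact majority value per minimizer bucket
#'
#' The modal count of each bucket's value multiset, computed from a full
#' per-bucket histogram (two passes); ties are broken toward the smallest
#' value, a deterministic choice aligned with the decreasing k-mer
#' spectrum (smaller counts are the more frequent ones).
#'
#' @inheritParams bucketCounts
#' @return named integer vector: majority count per minimizer.
#' @export
bucketMajority <- function(table, scheme) {
  stopifnot(is(table, "KmerCountTable"), is(scheme, "MinimizerScheme"))
  mins <- minimizers(table@kmer, scheme)
  mj <- .bucket_majority_cpp(mins, table@count)
  setNames(mj$majority, mj$minimizer)
}
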
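#' Accessors for k-mer count tables
#'
#' @param x a [KmerCountTable-class].
#' @return \code{kmers()} the character vector of keys; \code{counts()} the
#'   integer counts; \code{kmerLength()} the k-mer length k;
#'   \code{totalCount()} the sum of all counts (the L1 norm of the table).
#' @examples
#' tab <- countKmers("ACGTACGT", k = 4)
#' kmers(tab); counts(tab); kmerLength(tab); totalCount(tab)
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @rdname kmers
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname kmers
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))

#' @rdname kmers
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' Query an index for k-mer counts
#'
#' Uniform query interface over every index type in the package. All
#' indexes are static functions: only k-mers present in the build table may
#' be queried meaningfully; any other key yields an arbitrary value.
#'
#' @param x a [CSF-class], [BCSF-class], [AMBIndex-class] or
#'   [FILIndex-class].
#' @param keys character vector of k-mers to look up.
#' @return integer vector of counts, one per key.
#' @examples
#' tab <- powerlawTable(200, exponent = 2, maxCount = 10, k = 11, seed = 1)
#' idx <- buildBCSF(tab, seed = 1)
#' all(queryCount(idx, kmers(tab)) == counts(tab))
#' @export
setGeneric("queryCount", function(x, keys) standardGeneric("queryCount"))

#' Measured size of an index, in bits by component
#'
#' @param x an index structure (or a [BloomFilter-class] / [PrefixCode-class]
#'   component).
#' @return named numeric vector of bit counts; components always sum to the
#'   \code{total} element. \code{payload} entries are the data-bearing bits
#'   (Bloom arrays, CSF arrays, code tables); \code{metadata} is the
#'   serialized remainder (seeds, sizes, class scaffolding).
#' @seealso [bitsPerKmer()]
#' @export
setGeneric("structureBits", function(x) standardGeneric("structureBits"))
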
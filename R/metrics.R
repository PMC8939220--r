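#' Zero-order empirical entropy of a count distribution
#'
#' H0 = sum_l (n_l / n) * log2(n / n_l) over the value multiplicities
#' n_l, the information-theoretic lower bound in bits per key for storing
#' the values without structural assumptions. 0 for a single-valued
#' input; at most log2(number of distinct values).
#'
#' @param x a [KmerCountTable-class] (entropy of its count values), a
#'   named numeric histogram / \code{table} (names = values, entries =
#'   multiplicities), or an unnamed vector of raw value observations.
#' @return entropy in bits.
#' @examples
#' entropyH0(c(`1` = 97, `2` = 2, `3` = 1))
#' @export
entropyH0 <- function(x) {
  freq <- .as_histogram(x)
  p <- freq / sum(freq)
  -sum(p * log2(p))
}

#' Dominant value and its fraction
#'
#' @param x as in [entropyH0()].
#' @return list with \code{value} (the modal value; ties broken toward the
#'   smaller value) and \code{alpha} (its fraction of all keys).
#' @examples
#' dominantFraction(c(`1` = 2, `2` = 1))   # value 1, alpha 2/3
#' @export
dominantFraction <- function(x) {
  freq <- .as_histogram(x)
  vals <- as.integer(names(freq))
  imax <- which(freq == max(freq))
  v0 <- min(vals[imax])
  list(value = v0, alpha = as.numeric(freq[[match(v0, vals)]]) / sum(freq))
}

.as_histogram <- function(x) {
  if (is(x, "KmerCountTable")) x <- table(x@count)
  x <- unclass(x)
  if (is.null(names(x))) x <- table(x) # raw observations
  freq <- as.numeric(x)
  if (!length(freq) || any(freq <= 0) || anyNA(freq))
    stop("histogram must be non-empty with positive multiplicities")
  names(freq) <- names(unclass(x))
  freq
}

#' Measured space per k-mer
#'
#' 8 * serialized-bytes / number of keys, with a per-component breakdown
#' (Bloom bits, CSF arrays, code tables, metadata). The breakdown always
#' sums to the total.
#'
#' @param structure any index structure with a [structureBits()] method.
#' @param nKeys number of keys to normalize by; defaults to the number of
#'   keys the structure was built on.
#' @return named numeric vector of bits per k-mer; last element
#'   \code{total}.
#' @export
bitsPerKmer <- function(structure, nKeys = structure@nKeys) {
  structureBits(structure) / nKeys
}

#' Candidate minimizer lengths for a genome
#'
#' Useful first-layer minimizer lengths satisfy m > m_s = log4(|G|) + 2
#' with |G| the genome size in base pairs: shorter minimizers can no
#' longer partition the k-mers meaningfully. Candidates are the integers
#' strictly between m_s and k. When no candidate exists (k too small),
#' the recommendation is the delta-approximate mode with bucketing layers
#' as long as possible (k-2, k-1); for degenerate k a plain BCSF.
#'
#' The true optimum is found empirically: compressed size decreases
#' monotonically in m down to a minimum and grows again, so candidates
#' should be tried in increasing order, stopping once the built size
#' starts to increase (see the \code{suggest} and \code{build} CLI verbs).
#'
#' @param genomeSizeBp genome size |G| in base pairs (>= 1).
#' @param k k-mer length of the table to compress.
#' @return list with \code{ms} (the threshold, fractional), integer
#'   \code{candidates}, \code{mode} ("exact", "approximate" or "bcsf")
#'   and \code{approxLengths} (layer lengths for the approximate mode, or
#'   NULL).
#' @examples
#' suggestMinimizerLengths(4^10, k = 15)   # ms = 12, candidates 13, 14
#' @export
suggestMinimizerLengths <- function(genomeSizeBp, k) {
  if (!is.numeric(genomeSizeBp) || genomeSizeBp < 1)
    stop("genomeSizeBp must be >= 1")
  k <- .check_k(k)
  ms <- log(genomeSizeBp, base = 4) + 2
  lo <- as.integer(floor(ms)) + 1L # smallest integer strictly above ms
  candidates <- if (lo <= k - 1L) seq.int(lo, k - 1L) else integer(0)
  if (length(candidates))
    return(list(ms = ms, candidates = candidates, mode = "exact",
                approxLengths = NULL))
  if (k > 2L)
    return(list(ms = ms, candidates = integer(0), mode = "approximate",
                approxLengths = c(k - 2L, k - 1L)))
  list(ms = ms, candidates = integer(0), mode = "bcsf", approxLengths = NULL)
}
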
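#' Build a compressed static function
#'
#' Stores the map \code{keys -> values} in about
#' \code{gamma * sum(codeword lengths)} bits with O(1) retrieval and no key
#' storage. Values are coded with a canonical length-limited prefix code
#' built on their histogram; every key contributes one XOR equation per
#' codeword bit -- bit j must equal
#' \code{W[p1+j] xor W[p2+j] xor W[p3+j]} for three hash-derived window
#' positions -- and the per-chunk systems are solved over GF(2) by
#' hypergraph peeling with dense Gaussian elimination on the residual
#' 2-core. A chunk whose system is singular is rebuilt with a bumped seed
#' (up to 16 attempts; late attempts widen the chunk's array slightly).
#'
#' Chunks target \code{chunkTarget} keys but are additionally capped at
#' roughly 1024 equations each, which keeps the dense 2-core elimination
#' (a constant fraction of the system at gamma = 1.10, which is below the
#' pure-peeling threshold of about 1.23) to at most a couple of thousand
#' variables.
#'
#' @param keys character vector of distinct DNA keys (A/C/G/T, common
#'   length <= 31).
#' @param values integer values, one per key.
#' @param gamma bit-array expansion factor (>= 1.05; default 1.10, just
#'   above the GF(2) solvability threshold of ~1.09 for 3-XOR systems).
#' @param chunkTarget targeted number of keys per chunk.
#' @param seed global build seed; identical inputs and seed give a
#'   bit-identical structure regardless of input order.
#' @param maxLen codeword length cap passed to [buildCode()].
#' @return a [CSF-class].
#' @examples
#' tab <- powerlawTable(500, exponent = 2, maxCount = 8, k = 9, seed = 3)
#' csf <- buildCSF(kmers(tab), counts(tab), seed = 1)
#' all(csfQuery(csf, kmers(tab)) == counts(tab))
#' @export
buildCSF <- function(keys, values, gamma = 1.10, chunkTarget = 8192L,
                     seed = 1L, maxLen = 32L) {
  keys <- as.character(keys)
  values <- as.integer(values)
  if (!length(keys)) stop("CSF input must be non-empty")
  if (length(values) != length(keys)) stop("keys/values length mismatch")
  if (!is.numeric(gamma) || gamma < 1.05)
    stop("gamma must be >= 1.05")
  seed <- as.integer(seed)
  code <- buildCode(table(values), maxLen = maxLen)
  if (length(code@symbols) == 1L) {
    # H0 = 0: no equations are needed, the payload is empty
    return(new("CSF", code = code, arrays = list(), arrayBits = numeric(0),
               attempts = integer(0), nChunks = 0, gamma = gamma,
               chunkTarget = as.integer(chunkTarget), seed = seed,
               nKeys = length(keys), maxLen = code@maxLen))
  }
  idx <- match(values, code@symbols)
  built <- .csf_build_cpp(keys, code@lengths[idx], code@codes[idx], gamma,
                          as.integer(chunkTarget), 1024L, seed, code@maxLen,
                          16L)
  new("CSF", code = code, arrays = built$arrays,
      arrayBits = built$arrayBits, attempts = built$attempts,
      nChunks = built$nChunks, gamma = gamma,
      chunkTarget = as.integer(chunkTarget), seed = seed,
      nKeys = length(keys), maxLen = code@maxLen)
}

#' @rdname buildCSF
#' @param csf a built [CSF-class].
#' @return \code{csfQuery}: integer vector of stored values; for keys
#'   outside the build set the result is an arbitrary symbol of the code
#'   alphabet (the static-function contract).
#' @export
csfQuery <- function(csf, keys) {
  stopifnot(is(csf, "CSF"))
  keys <- as.character(keys)
  if (length(csf@code@symbols) == 1L)
    return(rep(csf@code@symbols[1L], length(keys)))
  idx <- .csf_query_cpp(keys, csf@seed, csf@nChunks, csf@arrays,
                        csf@arrayBits, csf@attempts, csf@maxLen,
                        csf@code@lenCount, csf@code@lenFirst,
                        csf@code@lenOffset)
  csf@code@symbols[idx + 1L]
}

#' Solve a sparse linear system over GF(2)
#'
#' The substrate of CSF construction, exposed directly: each equation is
#' the XOR of a set of bit positions constrained to a right-hand bit.
#' Failure (an inconsistent system) is a value, not an error.
#'
#' @param positions list of integer vectors of 1-based variable positions.
#' @param rhs logical right-hand side, one bit per equation.
#' @param nvars number of variables.
#' @return logical assignment of length \code{nvars} satisfying every
#'   equation (free variables FALSE), or NULL if the system is
#'   inconsistent.
#' @examples
#' solveGF2(list(c(1, 4, 8)), TRUE, 8)
#' @export
solveGF2 <- function(positions, rhs, nvars) {
  if (!is.list(positions)) positions <- list(positions)
  positions <- lapply(positions, function(p) as.integer(p) - 1L)
  res <- .gf2_solve_cpp(positions, as.logical(rhs), as.integer(nvars))
  if (is.null(res)) NULL else res
}

setMethod("show", "CSF", function(object) {
  b <- structureBits(object)
  cat(sprintf(
    "CSF: %s keys, %d symbols, %s chunks, gamma %.2f, %.3f payload bits/key\n",
    format(object@nKeys, big.mark = ","), length(object@code@symbols),
    format(object@nChunks, big.mark = ","), object@gamma,
    b[["csf"]] / object@nKeys))
})

#' @rdname structureBits
#' @export
setMethod("structureBits", "CSF", function(x) {
  payload <- sum(x@arrayBits)
  codeTable <- 8 * length(serialize(list(x@code@symbols, x@code@lengths),
                                    NULL, version = 3L))
  total <- 8 * length(serialize(x, NULL, version = 3L))
  c(csf = payload, codeTable = codeTable,
    metadata = total - payload - codeTable, total = total)
})

#' @rdname queryCount
#' @export
setMethod("queryCount", "CSF", function(x, keys) csfQuery(x, keys))

# deterministic derived seeds, kept inside 32-bit integer range
.derive_seed <- function(seed, i)
  as.integer((as.numeric(seed) * 48271 + i * 8191) %% 2147483647)
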